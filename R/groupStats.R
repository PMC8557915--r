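#' Kruskal-Wallis rank-sum test
#'
#' Treatment-level differences on a numeric response; mid-ranks with the
#' standard tie correction and a chi-square reference distribution with
#' (groups - 1) degrees of freedom.
#'
#' @param values numeric response.
#' @param groups parallel vector of group labels (>= 2 groups).
#' @return list with \code{statistic} (H), \code{df} and \code{p.value}.
#' @export
kruskalWallis <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L)
    stop("Kruskal-Wallis needs at least 2 groups")
  if (length(values) != length(groups))
    stop("'values' and 'groups' must have equal length")
  if (length(unique(values)) == 1L)   # all tied: no rank variance, H = 0
    return(list(statistic = 0, df = nlevels(groups) - 1L, p.value = 1))
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Dunn's multiple-comparison test
#'
#' Post hoc for a significant Kruskal-Wallis test: for every pair of groups
#' the difference in mean mid-ranks is standardised by the tie-corrected
#' pooled variance,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12 (N-1)}\right)
#'   \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}},}
#' with two-sided normal p-values adjusted across all pairs
#' (Benjamini-Hochberg by default).
#'
#' @param values,groups as in [kruskalWallis()].
#' @param pAdjust adjustment method understood by [stats::p.adjust()].
#' @return data.frame with columns \code{group_a}, \code{group_b}, \code{z},
#'   \code{p_raw}, \code{p_adjusted}; one row per unordered pair, groups in
#'   lexicographic order.
#' @export
dunnTest <- function(values, groups, pAdjust = "BH") {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stop("need at least 2 groups")
  if (any(tabulate(factor(groups, lev)) == 0L)) stop("empty group")
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, factor(groups, lev), mean)
  n <- tapply(r, factor(groups, lev), length)
  ties <- table(values)
  tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tieTerm
  pairs <- utils::combn(lev, 2L)
  z <- apply(pairs, 2L, function(p) {
    (rbar[[p[1L]]] - rbar[[p[2L]]]) /
      sqrt(v0 * (1 / n[[p[1L]]] + 1 / n[[p[2L]]]))
  })
  pRaw <- 2 * stats::pnorm(-abs(z))
  data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ], z = z,
             p_raw = pRaw, p_adjusted = stats::p.adjust(pRaw, pAdjust))
}

#' Wilcoxon rank-sum test for a two-group comparison
#'
#' Thin two-group special case used where only a pair of strains is
#' contrasted.
#'
#' @param valuesA,valuesB numeric samples.
#' @return list with \code{statistic} (W) and \code{p.value}.
#' @export
rankSumTest <- function(valuesA, valuesB) {
  wt <- suppressWarnings(stats::wilcox.test(valuesA, valuesB))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Benjamini-Hochberg and Bonferroni adjustment
#'
#' Step-up false-discovery-rate control with enforced monotonicity
#' (\code{bhAdjust}), and the family-wise bound \eqn{\min(1, p \cdot m)}
#' (\code{bonferroniAdjust}), where \code{m} may exceed the number of
#' p-values supplied (e.g. when only the top hits of a larger family are in
#' hand).
#'
#' @param p numeric p-values in [0, 1].
#' @param m size of the test family (default \code{length(p)}).
#' @return adjusted p-values, capped at 1.
#' @export
bhAdjust <- function(p) {
  .checkP(p)
  stats::p.adjust(p, method = "BH")
}

#' @rdname bhAdjust
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  .checkP(p)
  if (m < length(p)) stop("'m' cannot be smaller than the number of p-values")
  stats::p.adjust(p, method = "bonferroni", n = m)
}

.checkP <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
}

#' Two-sample log-rank test
#'
#' Compares the survival curves of two treatments from per-fly records: at
#' each distinct event time the observed deaths in one group are contrasted
#' with their hypergeometric expectation, and the summed difference squared
#' over the summed variance is referred to chi-square with 1 df.
#'
#' @param records data.frame as produced by [toSurvivalRecords()]
#'   (\code{treatment}, \code{time_days}, \code{event}).
#' @param groupA,groupB the two treatment labels.
#' @return list with \code{chisq}, \code{df} and \code{p.value}.
#' @export
logrankTest <- function(records, groupA, groupB) {
  sub <- records[records$treatment %in% c(groupA, groupB), , drop = FALSE]
  if (!all(c(groupA, groupB) %in% sub$treatment))
    stop("both treatments must be present in the records")
  if (sum(sub$event) == 0L)
    stop("no events in either group; log-rank is undefined")
  sd <- survival::survdiff(survival::Surv(time_days, event) ~ treatment,
                           data = sub)
  list(chisq = unname(sd$chisq), df = 1L,
       p.value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' All pairwise log-rank tests
#'
#' @param records as in [logrankTest()].
#' @param pAdjust adjustment across pairs (default Benjamini-Hochberg).
#' @return data.frame with \code{group_a}, \code{group_b}, \code{chisq},
#'   \code{p_raw}, \code{p_adjusted}.
#' @export
pairwiseLogrank <- function(records, pAdjust = "BH") {
  lev <- sort(unique(records$treatment))
  if (length(lev) < 2L) stop("need at least 2 treatments")
  pairs <- utils::combn(lev, 2L)
  res <- apply(pairs, 2L, function(p) {
    lr <- logrankTest(records, p[1L], p[2L])
    c(lr$chisq, lr$p.value)
  })
  data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
             chisq = res[1L, ], p_raw = res[2L, ],
             p_adjusted = stats::p.adjust(res[2L, ], pAdjust))
}

#' Compact letter display
#'
#' Assigns letter codes to groups from adjusted pairwise p-values by the
#' insert-and-absorb algorithm: two groups share at least one letter if and
#' only if they are not significantly different at level \code{alpha}.
#' Letters are assigned in lexicographic group order so displays are
#' deterministic.
#'
#' @param pairwise data.frame with columns \code{group_a}, \code{group_b}
#'   and \code{p_adjusted} covering every unordered pair of groups (as
#'   returned by [dunnTest()] or [pairwiseLogrank()]).
#' @param alpha significance level (default 0.05).
#' @return named character vector, one letter string per group.
#' @examples
#' pw <- data.frame(group_a = c("A", "A", "B"), group_b = c("B", "C", "C"),
#'                  p_adjusted = c(0.01, 0.2, 0.4))
#' compactLetterDisplay(pw)   # A and B differ; C is compatible with both
#' @export
compactLetterDisplay <- function(pairwise, alpha = 0.05) {
  req <- c("group_a", "group_b", "p_adjusted")
  if (!all(req %in% names(pairwise)))
    stop("'pairwise' needs columns ", paste(req, collapse = ", "))
  groups <- sort(unique(c(pairwise$group_a, pairwise$group_b)))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pmap <- stats::setNames(pairwise$p_adjusted,
                          key(pairwise$group_a, pairwise$group_b))
  allPairs <- utils::combn(groups, 2L)
  wanted <- key(allPairs[1L, ], allPairs[2L, ])
  if (anyDuplicated(names(pmap)))
    stop("duplicate pairwise comparisons")
  if (!all(wanted %in% names(pmap)))
    stop("pairwise results do not cover every pair of groups")
  if (any(is.na(pmap)))
    stop("pairwise p-values must not be NA")
  # start with one column holding every group; split it at each significant
  # pair (insert), then drop columns contained in another (absorb)
  cols <- list(groups)
  sig <- allPairs[, pmap[wanted] < alpha, drop = FALSE]
  if (ncol(sig)) {
    for (j in seq_len(ncol(sig))) {
      a <- sig[1L, j]; b <- sig[2L, j]
      nxt <- list()
      for (col in cols) {
        if (all(c(a, b) %in% col)) {
          nxt <- c(nxt, list(setdiff(col, a)), list(setdiff(col, b)))
        } else nxt <- c(nxt, list(col))
      }
      cols <- .absorb(nxt)
    }
  }
  ord <- order(vapply(cols, function(col) match(col[1L], groups), numeric(1)),
               vapply(cols, length, numeric(1)))
  cols <- cols[ord]
  letters_pool <- c(letters, paste0(rep(letters, each = 26L), letters))
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols))
    out[cols[[i]]] <- paste0(out[cols[[i]]], letters_pool[i])
  out
}

# drop letter columns that are subsets (or later duplicates) of another
.absorb <- function(cols) {
  keep <- rep(TRUE, length(cols))
  for (i in seq_along(cols)) {
    for (k in seq_along(cols)) {
      if (i == k) next
      if (all(cols[[i]] %in% cols[[k]]) &&
          (length(cols[[i]]) < length(cols[[k]]) ||
           (length(cols[[i]]) == length(cols[[k]]) && i > k))) {
        keep[i] <- FALSE
        break
      }
    }
  }
  cols[keep]
}
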