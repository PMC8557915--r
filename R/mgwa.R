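#' Collapse ortholog groups into phylogenetic distribution groups
#'
#' A phylogenetic distribution group (PDG) is the exact set of strains in
#' which an OG is present; all OGs with an identical presence pattern form
#' one PDG and are tested together.  PDGs are ordered lexicographically by
#' pattern so the grouping is deterministic under any row order of the
#' input.
#'
#' @param og an \linkS4class{OGMatrix}.
#' @return data.frame with one row per PDG: \code{pdg_id}, \code{pattern}
#'   (the 0/1 string over strains, in column order of \code{og}),
#'   \code{n_ogs}, \code{member_ogs} (list column), \code{strains_present}
#'   (comma-separated names) and \code{testable} (FALSE for all-absent or
#'   all-present patterns, which carry no contrast).
#' @export
groupPDGs <- function(og) {
  m <- og@presence
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty OG matrix")
  pat <- apply(m, 1L, paste0, collapse = "")
  members <- split(rownames(m), pat)
  pats <- sort(names(members))
  members <- members[pats]
  strains <- colnames(m)
  present <- vapply(pats, function(p) {
    paste(strains[strsplit(p, "")[[1L]] == "1"], collapse = ",")
  }, character(1))
  data.frame(
    pdg_id = sprintf("PDG%04d", seq_along(pats)),
    pattern = pats,
    n_ogs = lengths(members),
    member_ogs = I(unname(members)),
    strains_present = unname(present),
    testable = vapply(pats, function(p) {
      b <- strsplit(p, "")[[1L]]
      any(b == "1") && any(b == "0")
    }, logical(1)),
    row.names = NULL)
}

#' Shapiro-Wilk normality check
#'
#' Logged pre-check on the fitness response before the association stage
#' (never used as a gate).
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @return list with \code{W} and \code{p.value}.
#' @export
shapiroCheck <- function(x) {
  if (length(x) < 3L) stop("Shapiro-Wilk needs at least 3 observations")
  if (stats::sd(x) == 0) stop("constant vector: normality check undefined")
  st <- stats::shapiro.test(x)
  list(W = unname(st$statistic), p.value = st$p.value)
}

#' Test one PDG against per-vial fitness
#'
#' Fits the linear mixed model
#' \deqn{\lambda_{vial} = \beta_0 + \beta_1 \cdot presence(strain)
#'   + u_{experiment} + \varepsilon}
#' by REML, with the experimental replicate (the time-staggered experiment)
#' as a random intercept, and reports a two-sided Wald p-value for
#' \eqn{\beta_1}.  With \code{df = "satterthwaite"} the small-sample
#' Satterthwaite approximation is used instead (requires lmerTest).
#'
#' @param panel fitness panel: data.frame with columns \code{vial_id},
#'   \code{strain_id}, \code{experiment}, \code{lambda}.
#' @param pattern presence indicator over strains; either a named 0/1
#'   vector or a 0/1 string in the panel's strain order (see
#'   \code{strainIds}).
#' @param strainIds strain order used to interpret an unnamed or string
#'   \code{pattern}.
#' @param df \code{"wald"} (normal reference) or \code{"satterthwaite"}.
#' @param meanMode how the Table-style mean fitness columns pool vials:
#'   \code{"vial"} pools per-vial lambda over all strains with/without the
#'   PDG; \code{"strain"} averages strain means.
#' @return list with \code{beta}, \code{se}, \code{p}, \code{meanPresent},
#'   \code{meanAbsent}, \code{testable}.  Degenerate patterns (all present
#'   or all absent among the panel's strains) return \code{testable = FALSE}
#'   and NA statistics.
#' @export
fitPDGAssociation <- function(panel, pattern, strainIds = NULL,
                              df = c("wald", "satterthwaite"),
                              meanMode = c("vial", "strain")) {
  df <- match.arg(df)
  meanMode <- match.arg(meanMode)
  pres <- .resolvePattern(pattern, strainIds, panel)
  presence <- pres[panel$strain_id]
  if (any(is.na(presence)))
    stop("pattern does not cover panel strain(s): ",
         paste(unique(panel$strain_id[is.na(presence)]), collapse = ", "))
  untestable <- list(beta = NA_real_, se = NA_real_, p = NA_real_,
                     meanPresent = NA_real_, meanAbsent = NA_real_,
                     testable = FALSE)
  if (all(presence == 1) || all(presence == 0)) return(untestable)
  dat <- data.frame(lambda = panel$lambda, presence = as.numeric(presence),
                    experiment = factor(panel$experiment))
  if (nlevels(dat$experiment) >= 2L) {
    fit <- lme4::lmer(lambda ~ presence + (1 | experiment), data = dat,
                      REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular = "ignore"))
    if (df == "satterthwaite") {
      if (!requireNamespace("lmerTest", quietly = TRUE))
        stop("'satterthwaite' degrees of freedom require the lmerTest package")
      fit2 <- lmerTest::as_lmerModLmerTest(fit)
      co <- stats::coef(summary(fit2))["presence", ]
      beta <- co[["Estimate"]]; se <- co[["Std. Error"]]
      p <- co[["Pr(>|t|)"]]
    } else {
      co <- stats::coef(summary(fit))["presence", ]
      beta <- co[["Estimate"]]; se <- co[["Std. Error"]]
      p <- 2 * stats::pnorm(-abs(beta / se))
    }
  } else {
    # single replicate level: the random effect is unidentifiable, use OLS
    fit <- stats::lm(lambda ~ presence, data = dat)
    co <- stats::coef(summary(fit))["presence", ]
    beta <- co[["Estimate"]]; se <- co[["Std. Error"]]
    p <- 2 * stats::pnorm(-abs(beta / se))
  }
  if (meanMode == "vial") {
    mp <- mean(dat$lambda[dat$presence == 1])
    ma <- mean(dat$lambda[dat$presence == 0])
  } else {
    sm <- tapply(dat$lambda, panel$strain_id, mean)
    mp <- mean(sm[names(pres)[pres == 1]], na.rm = TRUE)
    ma <- mean(sm[names(pres)[pres == 0]], na.rm = TRUE)
  }
  list(beta = unname(beta), se = unname(se), p = unname(p),
       meanPresent = mp, meanAbsent = ma, testable = TRUE)
}

.resolvePattern <- function(pattern, strainIds, panel) {
  if (is.character(pattern) && length(pattern) == 1L)
    pattern <- as.integer(strsplit(pattern, "")[[1L]])
  if (is.null(names(pattern))) {
    if (is.null(strainIds))
      stop("an unnamed pattern needs 'strainIds'")
    if (length(pattern) != length(strainIds))
      stop("pattern length does not match 'strainIds'")
    names(pattern) <- strainIds
  }
  if (!all(pattern %in% c(0, 1))) stop("pattern must be 0/1")
  pattern
}

#' Metagenome-wide association of PDG presence with fly fitness
#'
#' Collapses the OG matrix into PDGs, fits the mixed model of
#' [fitPDGAssociation()] for every testable PDG, and Bonferroni-corrects
#' the p-values by the number of testable PDGs.  Strains excluded from the
#' panel (e.g. a pathogen-like strain whose fitness values break the
#' normality of the response) do not contribute observations, and
#' testability is re-assessed on the remaining strains.
#'
#' @param panel fitness panel (see [fitPDGAssociation()]); its strains must
#'   be a subset of the OG matrix's strains.
#' @param og an \linkS4class{OGMatrix}.
#' @param annotations optional named character vector (or data.frame with
#'   columns \code{og_id}, \code{annotation}) mapping OG ids to gene
#'   annotations.
#' @param excludeStrains strain ids dropped from the panel first.
#' @param ... passed on to [fitPDGAssociation()] (\code{df},
#'   \code{meanMode}).
#' @return the PDG table of [groupPDGs()] augmented with \code{beta},
#'   \code{p_raw}, \code{p_bonferroni}, \code{mean_fitness_present},
#'   \code{mean_fitness_absent} and \code{annotations}, sorted by
#'   \code{p_raw} (untestable PDGs last with NA p-values).
#' @export
runMGWA <- function(panel, og, annotations = NULL,
                    excludeStrains = character(0), ...) {
  panel <- panel[!(panel$strain_id %in% excludeStrains), , drop = FALSE]
  strains <- colnames(og@presence)
  missing <- setdiff(unique(panel$strain_id), strains)
  if (length(missing))
    stop("panel strain(s) absent from the OG matrix: ",
         paste(missing, collapse = ", "))
  if (nrow(panel) == 0L)
    stop("no panel observations left after strain exclusion")
  pdg <- groupPDGs(og)
  if (is.data.frame(annotations))
    annotations <- stats::setNames(annotations$annotation, annotations$og_id)
  fits <- lapply(pdg$pattern, function(p) {
    fitPDGAssociation(panel, p, strainIds = strains, ...)
  })
  pdg$beta <- vapply(fits, `[[`, numeric(1), "beta")
  pdg$p_raw <- vapply(fits, `[[`, numeric(1), "p")
  pdg$mean_fitness_present <- vapply(fits, `[[`, numeric(1), "meanPresent")
  pdg$mean_fitness_absent <- vapply(fits, `[[`, numeric(1), "meanAbsent")
  pdg$testable <- vapply(fits, `[[`, logical(1), "testable")
  nTest <- sum(pdg$testable)
  pdg$p_bonferroni <- ifelse(pdg$testable, pmin(1, pdg$p_raw * nTest), NA_real_)
  pdg$annotations <- vapply(pdg$member_ogs, function(ogs) {
    if (is.null(annotations)) return("")
    paste(unique(stats::na.omit(annotations[ogs])), collapse = "; ")
  }, character(1))
  pdg[order(pdg$p_raw, pdg$pdg_id, na.last = TRUE), , drop = FALSE]
}
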