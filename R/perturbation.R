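#' Default perturbation factor grid
#'
#' Reductions of survival or fecundity by factors of 2, 10, 20, 100, 200,
#' 1,000, 10,000 and 100,000, expressed as multipliers.
#'
#' @return numeric vector of multipliers in (0, 1].
#' @export
defaultFactorGrid <- function() 1 / c(2, 10, 20, 100, 200, 1e3, 1e4, 1e5)

#' Scale one age class of a vital schedule
#'
#' Multiplies a single fecundity or survival entry by \code{spec@factor},
#' leaving every other entry bit-identical.  For \code{trait = "survival"}
#' the class index selects the transition out of that class (\code{s[i]});
#' index 1 is the assumed pre-adult transition, index 2 the first adult
#' (first reproductive) transition.  For \code{trait = "fecundity"} the index
#' selects \code{f[i]} directly.  Scaled survival is clamped to [0, 1]
#' (never triggered by reduction factors).
#'
#' @param schedule a \linkS4class{VitalSchedule}.
#' @param spec a \linkS4class{PerturbationSpec}, or the trait name if
#'   \code{classIndex} and \code{factor} are given separately.
#' @param classIndex,factor used when \code{spec} is a trait name.
#' @return the perturbed \linkS4class{VitalSchedule}.
#' @export
scaleClass <- function(schedule, spec, classIndex = NULL, factor = NULL) {
  if (!is(spec, "PerturbationSpec"))
    spec <- PerturbationSpec(spec, classIndex, factor)
  f <- schedule@f
  s <- schedule@s
  i <- spec@classIndex
  if (spec@trait == "fecundity") {
    if (i > length(f)) stop("fecundity class index ", i, " out of range")
    f[i] <- f[i] * spec@factor
  } else {
    if (i > length(s))
      stop("survival class index ", i, " out of range (", length(s),
           " transitions)")
    s[i] <- min(1, s[i] * spec@factor)
  }
  VitalSchedule(f, s, schedule@classLabels)
}

#' Spearman rank correlation
#'
#' Rho on mid-ranks (average ranks for ties) with a p-value from the
#' large-sample t approximation; an exact permutation p-value is available
#' for small, tie-free samples.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param pMethod \code{"t"} (default) or \code{"exact"}.
#' @return list with elements \code{rho} and \code{p} (both \code{NA}, with
#'   a warning, when either vector is constant).
#' @export
spearmanRho <- function(x, y, pMethod = c("t", "exact")) {
  pMethod <- match.arg(pMethod)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman rho is undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = (pMethod == "exact")))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Run the fitness permutation grid
#'
#' For every combination of age class and reduction factor, rescales the
#' chosen trait of each vial's schedule (per vial, one class at a time),
#' recomputes fitness lambda, and summarises the relationship between
#' observed and permuted fitness: the Spearman correlation across vials and
#' a Kruskal-Wallis test of treatment differences on the permuted lambda,
#' followed by a Benjamini-Hochberg-corrected Dunn test when significant.
#' Pathogen-like treatments are conventionally excluded before calling this
#' (see \code{excludeTreatments}).
#'
#' @param vials a \linkS4class{VialRecordList}.
#' @param trait \code{"survival"} or \code{"fecundity"}.
#' @param factors multipliers in (0, 1]; default [defaultFactorGrid()].
#' @param classes age-class indices to perturb; default 2, the first adult
#'   (first reproductive) class.
#' @param excludeTreatments treatments dropped before the analysis (e.g. a
#'   pathogen-like treatment); default none.
#' @param alpha significance level gating the Dunn post hoc.
#' @param ... passed to [assembleSchedule()].
#' @return list of \linkS4class{PermutationResult}, one per (class, factor).
#' @seealso [permutationSummary()] to flatten the results.
#' @export
permutationGrid <- function(vials, trait = c("survival", "fecundity"),
                            factors = defaultFactorGrid(), classes = 2L,
                            excludeTreatments = character(0), alpha = 0.05,
                            ...) {
  trait <- match.arg(trait)
  keep <- vapply(vials, function(v) !(v@treatment %in% excludeTreatments),
                 logical(1))
  vials <- VialRecordList(as.list(vials)[keep])
  if (length(vials) == 0L)
    stop("no vials left after treatment exclusion")
  schedules <- lapply(vials, assembleSchedule, ...)
  meta <- data.frame(
    vial_id = vapply(vials, vialId, character(1)),
    treatment = vapply(vials, treatment, character(1)))
  lamObs <- vapply(schedules, dominantEigenvalue, numeric(1))
  out <- list()
  for (cls in classes) {
    for (fac in factors) {
      spec <- PerturbationSpec(trait, cls, fac)
      lamPerm <- vapply(schedules, function(sc)
        as.numeric(dominantEigenvalue(scaleClass(sc, spec))), numeric(1))
      perVial <- data.frame(meta, lambda_observed = as.numeric(lamObs),
                            lambda_permuted = lamPerm, row.names = NULL)
      sr <- if (nrow(perVial) < 3L) list(rho = NA_real_, p = NA_real_)
      else withCallingHandlers(
        spearmanRho(perVial$lambda_observed, perVial$lambda_permuted),
        warning = function(w) invokeRestart("muffleWarning"))
      kw <- if (length(unique(perVial$treatment)) < 2L)
        list(statistic = NA_real_, df = NA_real_, p.value = NA_real_)
      else kruskalWallis(perVial$lambda_permuted, perVial$treatment)
      dunn <- if (is.finite(kw$p.value) && kw$p.value < alpha)
        dunnTest(perVial$lambda_permuted, perVial$treatment)
      else
        data.frame(group_a = character(0), group_b = character(0),
                   z = numeric(0), p_raw = numeric(0), p_adjusted = numeric(0))
      out[[length(out) + 1L]] <- new("PermutationResult", spec = spec,
                                     perVial = perVial,
                                     rho = as.numeric(sr$rho),
                                     rhoP = as.numeric(sr$p),
                                     kwP = kw$p.value, dunn = dunn)
    }
  }
  out
}

#' Flatten permutation results
#'
#' @param results list of \linkS4class{PermutationResult} from
#'   [permutationGrid()].
#' @param what \code{"summary"} for one row per (trait, class, factor) or
#'   \code{"vials"} for the per-vial observed/permuted lambda pairs.
#' @return data.frame.
#' @export
permutationSummary <- function(results, what = c("summary", "vials")) {
  what <- match.arg(what)
  rows <- lapply(results, function(r) {
    base <- data.frame(trait = r@spec@trait, class_index = r@spec@classIndex,
                       factor = r@spec@factor)
    if (what == "summary")
      cbind(base, data.frame(rho = r@rho, rho_p = r@rhoP, kw_p = r@kwP))
    else
      cbind(base[rep(1L, nrow(r@perVial)), , drop = FALSE], r@perVial)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
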