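#' Assemble the vital schedule of one vial
#'
#' Builds the per-age-class fecundity and survival schedule that the Leslie
#' matrix is populated from.  Three boundary conventions frame the measured
#' intervals: (i) a pre-adult class with f = 0 and assumed complete survival
#' (s = 1) covers egg collection to the first transfer, (ii) each measured
#' interval contributes one class with f from [perClassFecundity()] and s
#' from [intervalSurvival()], and (iii) a terminal class with f = 0 truncates
#' reproduction at the end of the experiment.  A vial with 8 measured
#' intervals therefore yields 10 age classes.  After the cohort goes extinct
#' (no females left at an interval start) the remaining classes keep f = 0
#' and s = 0 so that matrix dimensions stay uniform within an experiment;
#' this leaves lambda unchanged.
#'
#' @param vial a \linkS4class{VialRecord}.
#' @param extrapolation passed to [perClassFecundity()].
#' @param censoring passed to [intervalSurvival()].
#' @return a \linkS4class{VitalSchedule} with \code{nrow(intervals) + 2}
#'   classes.
#' @export
assembleSchedule <- function(vial, extrapolation = c("rate", "raw"),
                             censoring = c("exclude", "deaths")) {
  extrapolation <- match.arg(extrapolation)
  censoring <- match.arg(censoring)
  iv <- intervals(vial)
  if (all(iv$females_at_start == 0))
    stop("vial ", vialId(vial), " has no interval with females present")
  n <- nrow(iv)
  fAdult <- numeric(n)
  sAdult <- numeric(n)
  for (i in seq_len(n)) {
    if (iv$females_at_start[i] == 0L) {
      fAdult[i] <- 0
      sAdult[i] <- 0
    } else {
      fAdult[i] <- perClassFecundity(iv$pupae_count[i], iv$females_at_start[i],
                                     iv$laying_window_hours[i],
                                     iv$class_length_days[i],
                                     extrapolation = extrapolation)
      s <- intervalSurvival(iv$females_at_start[i], iv$female_deaths[i],
                            iv$females_censored[i], censoring = censoring)
      sAdult[i] <- if (is.na(s)) 0 else s
    }
  }
  labels <- c("pre-adult",
              sprintf("d%g-%g", iv$start_day, iv$start_day + iv$class_length_days),
              "terminal")
  VitalSchedule(f = c(0, fAdult, 0), s = c(1, sAdult), classLabels = labels)
}

#' Build the Leslie matrix of a vital schedule
#'
#' Places the fecundities across the top row and the survival fractions on
#' the subdiagonal of a k x k matrix; all other entries are exactly zero.
#'
#' @param schedule a \linkS4class{VitalSchedule}, or a numeric vector of
#'   fecundities if \code{s} is also given.
#' @param s survival fractions when \code{schedule} is a plain vector.
#' @return a \linkS4class{LeslieMatrix}.
#' @examples
#' as.matrix(buildLeslie(VitalSchedule(c(0, 4, 2, 0), c(1, 0.9, 0.8))))
#' @export
buildLeslie <- function(schedule, s = NULL) {
  if (!is(schedule, "VitalSchedule")) {
    if (is.null(s)) stop("supply a VitalSchedule or both f and s")
    schedule <- VitalSchedule(schedule, s)
  }
  f <- schedule@f
  sv <- schedule@s
  k <- length(f)
  if (length(sv) != k - 1L)
    stop("mismatched lengths: ", k, " fecundities need ", k - 1L,
         " survival fractions")
  m <- matrix(0, k, k)
  m[1L, ] <- f
  m[cbind(2:k, 1:(k - 1L))] <- sv
  lbl <- if (length(schedule@classLabels)) schedule@classLabels
         else sprintf("class%d", seq_len(k))
  dimnames(m) <- list(lbl, lbl)
  new("LeslieMatrix", entries = m, classLabels = lbl)
}

#' @rdname dominantEigenvalue
#' @export
setMethod("dominantEigenvalue", "LeslieMatrix", function(x, tol = 1e-9) {
  .dominantEigen(x@entries, tol)
})

#' @rdname dominantEigenvalue
#' @export
setMethod("dominantEigenvalue", "VitalSchedule", function(x, tol = 1e-9) {
  .dominantEigen(buildLeslie(x)@entries, tol)
})

#' @rdname dominantEigenvalue
#' @export
setMethod("dominantEigenvalue", "matrix", function(x, tol = 1e-9) {
  .dominantEigen(as.matrix(buildLeslie(x[1L, ],
                                       x[cbind(2:nrow(x), 1:(nrow(x) - 1L))])@entries),
                 tol)
})

.dominantEigen <- function(m, tol) {
  ev <- eigen(m, only.values = TRUE)$values
  lead <- ev[which.max(Mod(ev))]
  resid <- abs(Im(lead))
  if (resid > tol)
    stop(sprintf(paste0("dominant eigenvalue has imaginary residual %.3e ",
                        "(tolerance %.1e); eigenvalues: %s"),
                 resid, tol, paste(signif(ev, 6), collapse = ", ")))
  structure(Re(lead), imagResidual = resid)
}

#' Fitness lambda by the Euler-Lotka equation
#'
#' Independent cross-check of [dominantEigenvalue()]: solves the scalar
#' characteristic equation
#' \deqn{\sum_x l_x f_x \lambda^{-x} = 1,}
#' where \eqn{l_x} is the cumulative survival to class x (\eqn{l_1 = 1}),
#' by bracketed root-finding.  The left-hand side is strictly decreasing in
#' lambda, so the positive root is unique; it equals the dominant eigenvalue
#' of the corresponding Leslie matrix.
#'
#' @param schedule a \linkS4class{VitalSchedule} (or numeric fecundities
#'   with \code{s} supplied).
#' @param s survival fractions when \code{schedule} is a plain vector.
#' @param tol relative root tolerance.
#' @return numeric(1) lambda; 0 when no reproduction is reachable (all
#'   \eqn{l_x f_x = 0}).
#' @examples
#' eulerLotkaLambda(VitalSchedule(c(0, 2), 1))  # sqrt(2)
#' @export
eulerLotkaLambda <- function(schedule, s = NULL, tol = 1e-12) {
  if (!is(schedule, "VitalSchedule")) {
    if (is.null(s)) stop("supply a VitalSchedule or both f and s")
    schedule <- VitalSchedule(schedule, s)
  }
  f <- schedule@f
  l <- c(1, cumprod(schedule@s))
  a <- l * f
  x <- which(a > 0)
  if (!length(x)) return(0)
  a <- a[x]
  g <- function(lam) sum(a * lam^(-x))
  # g is strictly decreasing with g(0+) = Inf on its support; bracket the root
  hi <- max(1, max(a)^(1 / min(x)))
  while (g(hi) > 1) hi <- hi * 2
  lo <- hi
  while (g(lo) < 1) lo <- lo / 2
  if (lo == hi) return(lo)
  r <- stats::uniroot(function(lam) g(lam) - 1, c(lo, hi),
                      tol = tol * max(1, hi), maxiter = 2000L)
  r$root
}

#' Fitness of every vial in a study
#'
#' Assembles each vial's vital schedule, builds its Leslie matrix and
#' extracts fitness lambda as the dominant eigenvalue.
#'
#' @param vials a \linkS4class{VialRecordList}.
#' @param ... passed to [assembleSchedule()].
#' @return data.frame with columns \code{vial_id}, \code{treatment},
#'   \code{experiment_day}, \code{replicate}, \code{lambda}.
#' @export
vialFitness <- function(vials, ...) {
  rows <- lapply(vials, function(v) {
    lam <- dominantEigenvalue(assembleSchedule(v, ...))
    data.frame(vial_id = v@vialId, treatment = v@treatment,
               experiment_day = v@experimentDay, replicate = v@replicate,
               lambda = as.numeric(lam))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
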