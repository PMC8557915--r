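#' @import methods
#' @importFrom S4Vectors SimpleList
NULL

.INTERVAL_COLS <- c("start_day", "class_length_days", "laying_window_hours",
                    "pupae_count", "females_at_start", "female_deaths",
                    "females_censored")

#' VialRecord: one vial of the fecundity/life-span assay
#'
#' A \code{VialRecord} holds everything recorded for a single vial of
#' gnotobiotic flies: its treatment labels and an ordered table of
#' measurement intervals.  Each interval row carries the pupae count from the
#' 18-h egg-laying window, the number of females alive at the start of the
#' interval, and the deaths and transfer losses observed during it.  Only
#' female flies are represented; the assay discards male data because
#' fecundity is normalised per female.
#'
#' The initial egg count is back-computed under the assumption of complete
#' egg-to-adult survival: every female ever observed (alive at the end plus
#' all recorded deaths and losses) is assumed to have been transferred as a
#' female egg, so \code{initialEggCount} equals \code{females_at_start} of
#' the first interval.
#'
#' @slot vialId character(1), unique vial identifier.
#' @slot treatment character(1), microbial treatment label.
#' @slot experimentDay integer(1), which of the time-staggered experiments
#'   (1--3) the vial belongs to.
#' @slot replicate integer(1), replicate index within the experiment.
#' @slot intervals data.frame with columns \code{start_day},
#'   \code{class_length_days}, \code{laying_window_hours},
#'   \code{pupae_count}, \code{females_at_start}, \code{female_deaths},
#'   \code{females_censored}; rows are strictly ordered by \code{start_day}
#'   and tile the experiment without overlap.
#' @slot initialEggCount integer(1), back-computed female egg input.
#'
#' @seealso [VialRecord()] for the constructor, [assembleSchedule()] for the
#'   conversion to per-class vital rates.
#' @exportClass VialRecord
setClass("VialRecord",
         representation(vialId = "character",
                        treatment = "character",
                        experimentDay = "integer",
                        replicate = "integer",
                        intervals = "data.frame",
                        initialEggCount = "integer"))

setValidity("VialRecord", function(object) {
  msg <- character(0)
  iv <- object@intervals
  if (length(object@vialId) != 1L || !nzchar(object@vialId))
    msg <- c(msg, "'vialId' must be a single non-empty string")
  if (length(object@treatment) != 1L)
    msg <- c(msg, "'treatment' must be a single string")
  if (length(object@experimentDay) != 1L || is.na(object@experimentDay))
    msg <- c(msg, "'experimentDay' must be a single integer")
  missing_cols <- setdiff(.INTERVAL_COLS, names(iv))
  if (length(missing_cols))
    return(paste0("interval table is missing column(s): ",
                  paste(missing_cols, collapse = ", ")))
  if (nrow(iv) == 0L)
    return("interval table has no rows")
  counts <- c("pupae_count", "females_at_start", "female_deaths",
              "females_censored")
  for (col in counts) {
    x <- iv[[col]]
    if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
      msg <- c(msg, sprintf("'%s' must be nonnegative integers", col))
  }
  if (any(diff(iv$start_day) <= 0))
    msg <- c(msg, "intervals must be strictly ordered by 'start_day'")
  if (nrow(iv) > 1L) {
    gap <- iv$start_day[-1L] -
      (iv$start_day[-nrow(iv)] + iv$class_length_days[-nrow(iv)])
    if (any(abs(gap) > 1e-8))
      msg <- c(msg, "interval boundaries must tile the experiment without overlap")
  }
  if (any(iv$laying_window_hours > 24 * iv$class_length_days))
    msg <- c(msg, "'laying_window_hours' cannot exceed the interval length")
  bad <- iv$female_deaths + iv$females_censored > iv$females_at_start
  if (any(bad))
    msg <- c(msg, sprintf("deaths + censored exceed females_at_start in interval row(s) %s",
                          paste(which(bad), collapse = ", ")))
  if (nrow(iv) > 1L) {
    expected <- iv$females_at_start[-nrow(iv)] - iv$female_deaths[-nrow(iv)] -
      iv$females_censored[-nrow(iv)]
    off <- expected != iv$females_at_start[-1L]
    if (any(off))
      msg <- c(msg, sprintf("female counts are not conserved between interval row(s) %s",
                            paste(which(off), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VialRecord
#'
#' @param vialId,treatment,experimentDay,replicate vial-level labels.
#' @param intervals data.frame of interval measurements (see
#'   \linkS4class{VialRecord} for the schema).
#' @return A validated \linkS4class{VialRecord}.
#' @examples
#' iv <- data.frame(start_day = c(10, 13), class_length_days = c(3, 4),
#'                  laying_window_hours = 18, pupae_count = c(40, 55),
#'                  females_at_start = c(20, 18), female_deaths = c(2, 1),
#'                  females_censored = c(0, 0))
#' VialRecord("v1", "A_pomorum_like", 1L, 1L, iv)
#' @export
VialRecord <- function(vialId, treatment, experimentDay, replicate, intervals) {
  intervals <- as.data.frame(intervals)
  intervals <- intervals[order(intervals$start_day), , drop = FALSE]
  rownames(intervals) <- NULL
  new("VialRecord",
      vialId = as.character(vialId),
      treatment = as.character(treatment),
      experimentDay = as.integer(experimentDay),
      replicate = as.integer(replicate),
      intervals = intervals,
      initialEggCount = as.integer(intervals$females_at_start[1L]))
}

#' List of VialRecord objects
#'
#' A \code{SimpleList} whose elements are all \linkS4class{VialRecord}s,
#' named by vial id.
#'
#' @exportClass VialRecordList
setClass("VialRecordList", contains = "SimpleList",
         prototype = prototype(elementType = "VialRecord"))

#' @rdname VialRecordList-class
#' @param ... \linkS4class{VialRecord} objects (or a single list of them).
#' @export
VialRecordList <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && !is(args[[1L]], "VialRecord"))
    args <- args[[1L]]
  ids <- vapply(args, function(v) v@vialId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate vial ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ans <- new("VialRecordList", S4Vectors::SimpleList(args))
  names(ans) <- ids
  ans
}

#' VitalSchedule: per-age-class vital rates of one vial
#'
#' Ordered fecundities \code{f} (offspring per female per age class, length
#' k) and between-class survival fractions \code{s} (length k-1).  When built
#' from a \linkS4class{VialRecord} the first class is the pre-adult class
#' (f = 0, s = 1 by the complete-egg-survival assumption) and the last is a
#' terminal class with f = 0 that truncates reproduction at the end of the
#' experiment.
#'
#' @slot f numeric, per-class fecundities, all >= 0.
#' @slot s numeric, survival fractions in [0, 1], one per class transition.
#' @slot classLabels character, descriptors for each class.
#' @exportClass VitalSchedule
setClass("VitalSchedule",
         representation(f = "numeric", s = "numeric", classLabels = "character"))

setValidity("VitalSchedule", function(object) {
  msg <- character(0)
  k <- length(object@f)
  if (k < 2L) msg <- c(msg, "a schedule needs at least 2 age classes")
  if (length(object@s) != k - 1L)
    msg <- c(msg, "'s' must have length(f) - 1 entries")
  if (any(is.na(object@f)) || any(object@f < 0))
    msg <- c(msg, "all fecundities must be nonnegative")
  if (any(is.na(object@s)) || any(object@s < 0) || any(object@s > 1))
    msg <- c(msg, "all survival fractions must lie in [0, 1]")
  if (length(object@classLabels) &&
      length(object@classLabels) != k)
    msg <- c(msg, "'classLabels' must be empty or one per class")
  if (length(msg)) msg else TRUE
})

#' @rdname VitalSchedule-class
#' @param f,s,classLabels see the class slots.
#' @export
VitalSchedule <- function(f, s, classLabels = character(0)) {
  new("VitalSchedule", f = as.numeric(f), s = as.numeric(s),
      classLabels = as.character(classLabels))
}

#' LeslieMatrix: the age-structured projection matrix of one vial
#'
#' A k x k nonnegative matrix with the per-class fecundities on the first
#' row and the between-class survival fractions on the subdiagonal; every
#' other entry is exactly zero.  Its dominant eigenvalue is the vial's
#' fitness lambda, the asymptotic per-class multiplicative growth rate.
#'
#' @slot entries numeric matrix in Leslie form.
#' @slot classLabels character, one descriptor per age class.
#' @seealso [buildLeslie()], [dominantEigenvalue()]
#' @exportClass LeslieMatrix
setClass("LeslieMatrix",
         representation(entries = "matrix", classLabels = "character"))

setValidity("LeslieMatrix", function(object) {
  m <- object@entries
  if (!is.numeric(m) || nrow(m) != ncol(m))
    return("'entries' must be a square numeric matrix")
  k <- nrow(m)
  if (k < 2L) return("a Leslie matrix needs at least 2 classes")
  if (any(is.na(m))) return("entries must not be NA")
  if (any(m[1L, ] < 0)) return("first-row fecundities must be nonnegative")
  sub <- m[cbind(2:k, 1:(k - 1L))]
  if (any(sub < 0) || any(sub > 1))
    return("subdiagonal survival fractions must lie in [0, 1]")
  zero <- m
  zero[1L, ] <- 0
  zero[cbind(2:k, 1:(k - 1L))] <- 0
  if (any(zero != 0))
    return("all entries off the first row and subdiagonal must be exactly 0")
  TRUE
})

#' PerturbationSpec: one (trait, age class, factor) perturbation
#'
#' @slot trait character(1), \code{"survival"} or \code{"fecundity"}.
#' @slot classIndex integer(1), 1-based age class.  For survival this indexes
#'   the transition out of the class (class 1 is the assumed pre-adult
#'   transition); for fecundity it indexes the class itself.
#' @slot factor numeric(1), positive multiplier applied to the observed
#'   value; the study's grid uses reductions (factor <= 1).
#' @exportClass PerturbationSpec
setClass("PerturbationSpec",
         representation(trait = "character", classIndex = "integer",
                        factor = "numeric"))

setValidity("PerturbationSpec", function(object) {
  msg <- character(0)
  if (!object@trait %in% c("survival", "fecundity"))
    msg <- c(msg, "'trait' must be \"survival\" or \"fecundity\"")
  if (length(object@classIndex) != 1L || is.na(object@classIndex) ||
      object@classIndex < 1L)
    msg <- c(msg, "'classIndex' must be a positive integer")
  if (length(object@factor) != 1L || is.na(object@factor) || object@factor <= 0)
    msg <- c(msg, "'factor' must be a positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname PerturbationSpec-class
#' @param trait,classIndex,factor see the class slots.
#' @export
PerturbationSpec <- function(trait, classIndex, factor) {
  new("PerturbationSpec", trait = as.character(trait),
      classIndex = as.integer(classIndex), factor = as.numeric(factor))
}

#' PermutationResult: observed vs permuted fitness for one perturbation
#'
#' @slot spec the \linkS4class{PerturbationSpec} applied.
#' @slot perVial data.frame with columns \code{vial_id}, \code{treatment},
#'   \code{lambda_observed}, \code{lambda_permuted}.
#' @slot rho,rhoP Spearman correlation between observed and permuted lambda
#'   across vials and its p-value (NA when either vector is constant).
#' @slot kwP Kruskal-Wallis p-value across treatments on the permuted lambda.
#' @slot dunn data.frame of pairwise Dunn comparisons on permuted lambda
#'   (computed when the Kruskal-Wallis test is significant; otherwise empty).
#' @exportClass PermutationResult
setClass("PermutationResult",
         representation(spec = "PerturbationSpec", perVial = "data.frame",
                        rho = "numeric", rhoP = "numeric", kwP = "numeric",
                        dunn = "data.frame"))

#' OGMatrix: ortholog-group presence/absence across bacterial strains
#'
#' A binary matrix (rows = ortholog groups, columns = strains) recording in
#' which genomes each OG was found.  This is the input to the
#' metagenome-wide association; the protein clustering that produces it is
#' upstream of this package.
#'
#' @slot presence binary matrix with unique rownames (OG ids) and unique
#'   colnames (strain ids).
#' @seealso [groupPDGs()], [runMGWA()]
#' @exportClass OGMatrix
setClass("OGMatrix", representation(presence = "matrix"))

setValidity("OGMatrix", function(object) {
  m <- object@presence
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("'presence' needs OG ids as rownames and strain ids as colnames")
  if (anyDuplicated(rownames(m))) return("duplicate OG ids")
  if (anyDuplicated(colnames(m))) return("duplicate strain ids")
  if (!all(m %in% c(0, 1))) return("entries must be 0 or 1")
  TRUE
})

#' @rdname OGMatrix-class
#' @param presence binary matrix, OGs x strains, with dimnames.
#' @export
OGMatrix <- function(presence) {
  storage.mode(presence) <- "numeric"
  new("OGMatrix", presence = presence)
}

#' TreatmentArchetype: generative parameters of one microbial treatment
#'
#' Encodes how a treatment shapes the flies' life history in the simulator:
#' a gamma-kernel daily fecundity curve
#' \deqn{m(t) = A (t/p)^{g} \exp(g (1 - t/p))}
#' with mode at the peak day \eqn{p} and peak per-female daily rate \eqn{A},
#' plus a piecewise-constant daily death probability.  Acetic-acid-bacteria
#' style treatments peak early and die fast; lactic-acid-bacteria style
#' treatments peak late and live long; a pathogen-like treatment combines
#' low fecundity with high mortality.
#'
#' @slot name character(1) treatment label.
#' @slot fecundityPeakDay positive, day (since egg collection) of peak laying.
#' @slot fecundityAmplitude nonnegative, offspring per female per day at peak.
#' @slot fecundityShape positive gamma-kernel shape; larger is narrower.
#' @slot hazardBreaks increasing numeric, left edges of hazard phases
#'   (first must be 0).
#' @slot hazardRates per-day death probability for each phase, in [0, 1].
#' @slot pathogenLike logical(1); pathogen-like treatments are excluded from
#'   the permutation and association analyses by default.
#' @exportClass TreatmentArchetype
setClass("TreatmentArchetype",
         representation(name = "character", fecundityPeakDay = "numeric",
                        fecundityAmplitude = "numeric", fecundityShape = "numeric",
                        hazardBreaks = "numeric", hazardRates = "numeric",
                        pathogenLike = "logical"))

setValidity("TreatmentArchetype", function(object) {
  msg <- character(0)
  if (object@fecundityPeakDay <= 0) msg <- c(msg, "'fecundityPeakDay' must be positive")
  if (object@fecundityAmplitude < 0) msg <- c(msg, "'fecundityAmplitude' must be nonnegative")
  if (object@fecundityShape <= 0) msg <- c(msg, "'fecundityShape' must be positive")
  if (length(object@hazardBreaks) != length(object@hazardRates))
    msg <- c(msg, "'hazardBreaks' and 'hazardRates' must have equal length")
  if (object@hazardBreaks[1L] != 0 || is.unsorted(object@hazardBreaks, strictly = TRUE))
    msg <- c(msg, "'hazardBreaks' must start at 0 and increase")
  if (any(object@hazardRates < 0) || any(object@hazardRates > 1))
    msg <- c(msg, "'hazardRates' must be daily probabilities in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname TreatmentArchetype-class
#' @param name,peakDay,amplitude,shape,hazardBreaks,hazardRates,pathogenLike
#'   see the class slots.
#' @export
treatmentArchetype <- function(name, peakDay, amplitude, shape = 5,
                               hazardBreaks = 0, hazardRates = 0.01,
                               pathogenLike = FALSE) {
  new("TreatmentArchetype", name = as.character(name),
      fecundityPeakDay = as.numeric(peakDay),
      fecundityAmplitude = as.numeric(amplitude),
      fecundityShape = as.numeric(shape),
      hazardBreaks = as.numeric(hazardBreaks),
      hazardRates = as.numeric(hazardRates),
      pathogenLike = isTRUE(pathogenLike))
}

#' StudyDesign: layout of a simulated vial study
#'
#' Defaults mirror the study design the package analyses: three
#' time-staggered experiments with triplicate vials per treatment, 30--60
#' females per vial, and 8 twice-weekly 18-h fecundity measures (alternating
#' 3- and 4-day age classes) starting when the adults have eclosed.
#'
#' @slot treatments list of \linkS4class{TreatmentArchetype}.
#' @slot nExperiments,vialsPerExperiment integers.
#' @slot fliesPerVial integer(2), inclusive range of starting females.
#' @slot nIntervals integer, number of fecundity measures.
#' @slot intervalPatternDays numeric, recycled class lengths in days.
#' @slot layingWindowHours numeric, egg-laying window per measure.
#' @slot firstTransferDay numeric, day (since egg collection) of the first
#'   measure.
#' @slot lossProb per-transfer probability that a surviving fly is lost
#'   (censored).
#' @slot dispersion negative-binomial size parameter of the pupae counts.
#' @slot seed integer random seed.
#' @exportClass StudyDesign
setClass("StudyDesign",
         representation(treatments = "list", nExperiments = "integer",
                        vialsPerExperiment = "integer", fliesPerVial = "integer",
                        nIntervals = "integer", intervalPatternDays = "numeric",
                        layingWindowHours = "numeric", firstTransferDay = "numeric",
                        lossProb = "numeric", dispersion = "numeric",
                        seed = "integer"))

setValidity("StudyDesign", function(object) {
  msg <- character(0)
  if (!length(object@treatments) ||
      !all(vapply(object@treatments, is, logical(1), "TreatmentArchetype")))
    msg <- c(msg, "'treatments' must be a nonempty list of TreatmentArchetype")
  if (length(object@fliesPerVial) != 2L || object@fliesPerVial[1L] > object@fliesPerVial[2L])
    msg <- c(msg, "'fliesPerVial' must be an increasing integer range")
  if (object@nIntervals < 1L) msg <- c(msg, "'nIntervals' must be >= 1")
  if (object@lossProb < 0 || object@lossProb > 1)
    msg <- c(msg, "'lossProb' must be a probability")
  if (length(msg)) msg else TRUE
})

#' @rdname StudyDesign-class
#' @param treatments,nExperiments,vialsPerExperiment,fliesPerVial,nIntervals,intervalPatternDays,layingWindowHours,firstTransferDay,lossProb,dispersion,seed
#'   see the class slots.
#' @export
studyDesign <- function(treatments = defaultArchetypes(),
                        nExperiments = 3L, vialsPerExperiment = 3L,
                        fliesPerVial = c(30L, 60L), nIntervals = 8L,
                        intervalPatternDays = c(3, 4), layingWindowHours = 18,
                        firstTransferDay = 10, lossProb = 0.01,
                        dispersion = 8, seed = 1L) {
  new("StudyDesign", treatments = treatments,
      nExperiments = as.integer(nExperiments),
      vialsPerExperiment = as.integer(vialsPerExperiment),
      fliesPerVial = as.integer(fliesPerVial),
      nIntervals = as.integer(nIntervals),
      intervalPatternDays = as.numeric(intervalPatternDays),
      layingWindowHours = as.numeric(layingWindowHours),
      firstTransferDay = as.numeric(firstTransferDay),
      lossProb = as.numeric(lossProb), dispersion = as.numeric(dispersion),
      seed = as.integer(seed))
}
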