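#' Accessors for vial and fitness objects
#'
#' @param x an object of one of the package's classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vialId", function(x) standardGeneric("vialId"))

#' @rdname accessors
#' @export
setGeneric("treatment", function(x) standardGeneric("treatment"))

#' @rdname accessors
#' @export
setGeneric("experimentDay", function(x) standardGeneric("experimentDay"))

#' @rdname accessors
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @rdname accessors
#' @export
setGeneric("initialEggCount", function(x) standardGeneric("initialEggCount"))

#' @rdname accessors
#' @export
setGeneric("fecundities", function(x) standardGeneric("fecundities"))

#' @rdname accessors
#' @export
setGeneric("survivals", function(x) standardGeneric("survivals"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Dominant eigenvalue (fitness lambda) of a Leslie matrix
#'
#' @param x a \linkS4class{LeslieMatrix}, \linkS4class{VitalSchedule} or
#'   plain matrix in Leslie form.
#' @param tol absolute tolerance on the imaginary part of the dominant
#'   eigenvalue; a nonnegative Leslie matrix has a real dominant root
#'   (Perron-Frobenius), so a larger residual signals a numerical problem.
#' @return numeric(1), the fitness lambda, with attribute
#'   \code{"imagResidual"} carrying the imaginary residual actually observed.
#' @export
setGeneric("dominantEigenvalue",
           function(x, tol = 1e-9) standardGeneric("dominantEigenvalue"))

setMethod("vialId", "VialRecord", function(x) x@vialId)
setMethod("treatment", "VialRecord", function(x) x@treatment)
setMethod("experimentDay", "VialRecord", function(x) x@experimentDay)
setMethod("intervals", "VialRecord", function(x) x@intervals)
setMethod("initialEggCount", "VialRecord", function(x) x@initialEggCount)

setMethod("fecundities", "VitalSchedule", function(x) x@f)
setMethod("survivals", "VitalSchedule", function(x) x@s)
setMethod("classLabels", "VitalSchedule", function(x) x@classLabels)

setMethod("fecundities", "LeslieMatrix", function(x) x@entries[1L, ])
setMethod("survivals", "LeslieMatrix", function(x) {
  k <- nrow(x@entries)
  x@entries[cbind(2:k, 1:(k - 1L))]
})
setMethod("classLabels", "LeslieMatrix", function(x) x@classLabels)

#' @rdname LeslieMatrix-class
#' @param x a LeslieMatrix.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "LeslieMatrix", function(x, ...) x@entries)

setMethod("show", "VialRecord", function(object) {
  iv <- object@intervals
  cat("VialRecord ", object@vialId, " [", object@treatment,
      ", experiment ", object@experimentDay, ", replicate ", object@replicate,
      "]\n", sep = "")
  cat("  ", nrow(iv), " intervals, days ", iv$start_day[1L], "-",
      iv$start_day[nrow(iv)] + iv$class_length_days[nrow(iv)],
      "; initial egg count ", object@initialEggCount, "\n", sep = "")
})

setMethod("show", "VitalSchedule", function(object) {
  cat("VitalSchedule with", length(object@f), "age classes\n")
  cat("  f:", paste(signif(object@f, 4), collapse = " "), "\n")
  cat("  s:", paste(signif(object@s, 4), collapse = " "), "\n")
})

setMethod("show", "LeslieMatrix", function(object) {
  cat("LeslieMatrix (", nrow(object@entries), " age classes), lambda = ",
      signif(dominantEigenvalue(object), 6), "\n", sep = "")
  print(signif(object@entries, 4))
})

setMethod("show", "PermutationResult", function(object) {
  sp <- object@spec
  cat(sprintf("PermutationResult: %s, class %d, factor %g (%d vials)\n",
              sp@trait, sp@classIndex, sp@factor, nrow(object@perVial)))
  cat(sprintf("  Spearman rho = %s (p = %s); Kruskal-Wallis p = %s\n",
              signif(object@rho, 4), signif(object@rhoP, 4),
              signif(object@kwP, 4)))
})

setMethod("show", "OGMatrix", function(object) {
  cat("OGMatrix:", nrow(object@presence), "ortholog groups x",
      ncol(object@presence), "strains\n")
})

setMethod("show", "TreatmentArchetype", function(object) {
  cat(sprintf("TreatmentArchetype '%s': peak day %g, amplitude %g/day%s\n",
              object@name, object@fecundityPeakDay, object@fecundityAmplitude,
              if (object@pathogenLike) " (pathogen-like)" else ""))
})

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf("StudyDesign: %d treatments x %d experiments x %d vials, %d intervals, seed %d\n",
              length(object@treatments), object@nExperiments,
              object@vialsPerExperiment, object@nIntervals, object@seed))
})
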