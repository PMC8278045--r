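#' Normalization state of a PulldownExperiment
#'
#' @param x a \linkS4class{PulldownExperiment}.
#' @return \code{"raw"}, \code{"total_normalized"} or
#'   \code{"bait_normalized"}.
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))

#' @rdname scaleTag
#' @export
setMethod("scaleTag", "PulldownExperiment",
          function(x) S4Vectors::metadata(x)$scaleTag)

setGeneric(".scaleTag<-", function(x, value) standardGeneric(".scaleTag<-"))
setMethod(".scaleTag<-", "PulldownExperiment", function(x, value) {
  S4Vectors::metadata(x)$scaleTag <- value
  x
})

#' Protein-to-complex membership of a ComplexMap
#'
#' @param x a \linkS4class{ComplexMap}.
#' @return named character vector, protein -> complex.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname membership
#' @export
setMethod("membership", "ComplexMap", function(x) x@membership)

#' Reserved GFP marker identifier of a ComplexMap
#'
#' @param x a \linkS4class{ComplexMap}.
#' @export
setGeneric("gfpId", function(x) standardGeneric("gfpId"))

#' @rdname gfpId
#' @export
setMethod("gfpId", "ComplexMap", function(x) x@gfpId)

#' Known complex identifiers of a ComplexMap
#'
#' @param x a \linkS4class{ComplexMap}.
#' @export
setGeneric("complexIds", function(x) standardGeneric("complexIds"))

#' @rdname complexIds
#' @export
setMethod("complexIds", "ComplexMap", function(x) x@complexes)

#' Subunits of one complex
#'
#' @param x a \linkS4class{ComplexMap}.
#' @param complex a complex id.
#' @return character vector of protein ids mapped to \code{complex}.
#' @export
setGeneric("complexSubunits",
           function(x, complex) standardGeneric("complexSubunits"))

#' @rdname complexSubunits
#' @export
setMethod("complexSubunits", "ComplexMap", function(x, complex) {
  names(x@membership)[x@membership == complex]
})

#' Replicate ratios of an AssociationEstimate
#'
#' @param x an \linkS4class{AssociationEstimate}.
#' @export
setGeneric("replicateRatios", function(x) standardGeneric("replicateRatios"))

#' @rdname replicateRatios
#' @export
setMethod("replicateRatios", "AssociationEstimate", function(x) x@ratios)

#' Mean association percentage
#'
#' 100 times the arithmetic mean of the replicate ratios.
#'
#' @param x an \linkS4class{AssociationEstimate}.
#' @export
setGeneric("meanPercent", function(x) standardGeneric("meanPercent"))

#' @rdname meanPercent
#' @export
setMethod("meanPercent", "AssociationEstimate",
          function(x) 100 * mean(x@ratios))

#' Height grid of a Topograph
#'
#' @param x a \linkS4class{Topograph}.
#' @export
setGeneric("heights", function(x) standardGeneric("heights"))

#' @rdname heights
#' @export
setMethod("heights", "Topograph", function(x) x@heights)

#' Pixel size (nm) of a Topograph
#'
#' @param x a \linkS4class{Topograph}.
#' @export
setGeneric("pixelNm", function(x) standardGeneric("pixelNm"))

#' @rdname pixelNm
#' @export
setMethod("pixelNm", "Topograph", function(x) x@pixelNm)

#' Did validation pass?
#'
#' @param x a \linkS4class{ValidationReport}.
#' @return \code{TRUE} iff no errors were found.
#' @export
setGeneric("isOK", function(x) standardGeneric("isOK"))

#' @rdname isOK
#' @export
setMethod("isOK", "ValidationReport", function(x) length(x@errors) == 0L)

#' Errors found by validation
#'
#' @param x a \linkS4class{ValidationReport}.
#' @export
setGeneric("validationErrors",
           function(x) standardGeneric("validationErrors"))

#' @rdname validationErrors
#' @export
setMethod("validationErrors", "ValidationReport", function(x) x@errors)

#' Warnings found by validation
#'
#' @param x a \linkS4class{ValidationReport}.
#' @export
setGeneric("validationWarnings",
           function(x) standardGeneric("validationWarnings"))

#' @rdname validationWarnings
#' @export
setMethod("validationWarnings", "ValidationReport", function(x) x@warnings)

#' Ground-truth association fractions
#'
#' Derived fractions \code{f[B][A] = n_AB / N_B} for every ordered pair of
#' complexes with a configured supercomplex count, the quantities the
#' association estimator targets.
#'
#' @param x a \linkS4class{GroundTruth}.
#' @return data.frame with columns \code{bait}, \code{partner},
#'   \code{fraction}.
#' @export
setGeneric("associationTruth",
           function(x) standardGeneric("associationTruth"))

#' @rdname associationTruth
#' @export
setMethod("associationTruth", "GroundTruth", function(x) {
  p <- x@pairs
  if (!nrow(p))
    return(data.frame(bait = character(0), partner = character(0),
                      fraction = numeric(0)))
  out <- rbind(
    data.frame(bait = p$a, partner = p$b, fraction = p$n / x@copyNumber[p$a]),
    data.frame(bait = p$b, partner = p$a, fraction = p$n / x@copyNumber[p$b]))
  rownames(out) <- NULL
  out[order(out$bait, out$partner), , drop = FALSE]
})

setMethod("show", "ComplexMap", function(object) {
  cat(sprintf("ComplexMap: %d proteins in %d complexes (GFP marker '%s')\n",
              length(object@membership), length(object@complexes),
              object@gfpId))
  tab <- table(object@membership)
  for (cx in object@complexes)
    cat(sprintf("  %-8s %d subunits\n", cx,
                if (cx %in% names(tab)) tab[[cx]] else 0L))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth (pull-down observation model)\n")
  cat("  copy numbers:",
      paste(sprintf("%s=%g", names(object@copyNumber), object@copyNumber),
            collapse = ", "), "\n")
  cat(sprintf("  %d supercomplex pair(s); noise SD (log) %g; seed %d\n",
              nrow(object@pairs), object@noiseSd, object@seed))
  if (nrow(object@pairs)) {
    f <- associationTruth(object)
    cat(sprintf("  fractions: %s\n",
                paste(sprintf("f[%s][%s]=%.3g", f$bait, f$partner,
                              f$fraction), collapse = ", ")))
  }
})

setMethod("show", "AssociationEstimate", function(object) {
  cat(sprintf(
    "AssociationEstimate: %.3g%% of %s associated with %s (n = %d)\n",
    meanPercent(object), object@bait, object@partner,
    length(object@ratios)))
  cat("  replicate ratios:", paste(signif(object@ratios, 4),
                                   collapse = ", "), "\n")
})

setMethod("show", "Topograph", function(object) {
  cat(sprintf("Topograph: %d x %d pixels, %.3g nm/px, height range [%.3g, %.3g] nm\n",
              nrow(object@heights), ncol(object@heights), object@pixelNm,
              min(object@heights), max(object@heights)))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %s (%d error(s), %d warning(s))\n",
              if (isOK(object)) "OK" else "NOT OK",
              length(object@errors), length(object@warnings)))
  for (e in object@errors) cat("  error:", e, "\n")
  for (w in object@warnings) cat("  warning:", w, "\n")
})
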