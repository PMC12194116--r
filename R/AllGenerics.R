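#' Accessors for EchoDose objects
#'
#' `pixelData()` returns the gray-level matrix of a frame, `pixelSpacing()`
#' its physical spacing (cm/pixel) and `doseLabel()` its dose label (mA).
#' `labelMatrix()`, `regionCount()` and `regionSizes()` access a segmented
#' [RegionSet-class]; `lesionMask()` and `fociCount()` access a
#' [GroundTruth-class].
#'
#' @param object an EchoDose S4 object.
#' @return The accessed component.
#' @name accessors
#' @examples
#' frm <- ultrasoundFrame(matrix(60, 8, 8), dose = 2)
#' doseLabel(frm)
NULL

#' @rdname accessors
#' @export
setGeneric("pixelData", function(object) standardGeneric("pixelData"))
#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setGeneric("doseLabel", function(object) standardGeneric("doseLabel"))
#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setGeneric("regionCount", function(object) standardGeneric("regionCount"))
#' @rdname accessors
#' @export
setGeneric("regionSizes", function(object) standardGeneric("regionSizes"))
#' @rdname accessors
#' @export
setGeneric("lesionMask", function(object) standardGeneric("lesionMask"))
#' @rdname accessors
#' @export
setGeneric("fociCount", function(object) standardGeneric("fociCount"))

#' @rdname accessors
#' @export
setMethod("pixelData", "UltrasoundFrame", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "UltrasoundFrame", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("doseLabel", "UltrasoundFrame", function(object) object@dose)
#' @rdname accessors
#' @export
setMethod("labelMatrix", "RegionSet", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("regionCount", "RegionSet", function(object) {
  if (length(object@labels)) max(object@labels) else 0L
})
#' @rdname accessors
#' @export
setMethod("regionSizes", "RegionSet", function(object) {
  n <- regionCount(object)
  if (n == 0L) integer(0) else tabulate(object@labels[object@labels > 0L], n)
})
#' @rdname accessors
#' @export
setMethod("lesionMask", "GroundTruth", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("fociCount", "GroundTruth", function(object) nrow(object@centers))
#' @rdname accessors
#' @export
setMethod("doseLabel", "GroundTruth", function(object) object@dose)

setMethod("show", "UltrasoundFrame", function(object) {
  cat(sprintf("UltrasoundFrame: %d x %d px, %.4g cm/px, dose %s mA\n",
              nrow(object@pixels), ncol(object@pixels), object@spacing,
              if (is.na(object@dose)) "NA" else format(object@dose)))
  cat(sprintf("  gray levels: %d..%d (mean %.1f)\n", min(object@pixels),
              max(object@pixels), mean(object@pixels)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d planted foci at dose %.2f mA (mask area %d px)\n",
              fociCount(object), object@dose, sum(object@mask)))
})

setMethod("show", "RegionSet", function(object) {
  sz <- regionSizes(object)
  cat(sprintf("RegionSet: %d affected area(s), %d-connectivity\n",
              regionCount(object), object@connectivity))
  if (length(sz))
    cat("  sizes (px): ", paste(sz, collapse = ", "), "\n", sep = "")
})

setMethod("show", "DoseModel", function(object) {
  cat("DoseModel (composite electrolysis dose index):\n")
  cat(sprintf("  dose = %.3f %+.3f*A_Area %+.3f*A_Number %+.3f*A_Perimeter\n",
              object@intercept, object@coefArea, object@coefNumber,
              object@coefPerimeter))
})

setMethod("show", "StatReport", function(object) {
  cat("StatReport\n")
  cat(sprintf("  Spearman screen:    %d variables (%d with p < 0.05)\n",
              nrow(object@correlations),
              sum(object@correlations$p < 0.05, na.rm = TRUE)))
  cat(sprintf("  simple regressions: %d variables\n", nrow(object@simpleFits)))
  ret <- object@multiModel$retained
  cat(sprintf("  multiple regression: retained %s (R2 = %.3f)\n",
              paste(ret, collapse = ", "), object@multiModel$r.squared))
  cat(sprintf("  group comparison:   %d variables x 3 dose groups\n",
              nrow(object@groupTests)))
})
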