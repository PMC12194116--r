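#' @import methods
NULL

#' UltrasoundFrame: an 8-bit grayscale B-mode frame
#'
#' Container for a single B-mode ultrasound frame: an integer pixel matrix on
#' the 0--255 gray scale, the physical pixel spacing, and (optionally) the
#' galvanic-current dose that was applied before the frame was acquired.
#'
#' @slot pixels integer matrix of gray levels in `[0, 255]`; rows are image
#'   rows (depth increases downwards, as on a B-mode display).
#' @slot spacing numeric(1), physical pixel spacing in cm/pixel (isotropic).
#' @slot dose numeric(1), applied current intensity in mA; `NA` when unknown.
#'
#' @seealso [ultrasoundFrame()], [simulateSpeckleBackground()]
#' @exportClass UltrasoundFrame
setClass("UltrasoundFrame",
  representation(pixels = "matrix", spacing = "numeric", dose = "numeric"),
  prototype(pixels = matrix(0L, 1, 1), spacing = 0.01, dose = NA_real_)
)

setValidity("UltrasoundFrame", function(object) {
  msg <- character()
  px <- object@pixels
  if (!is.numeric(px) || length(dim(px)) != 2L)
    msg <- c(msg, "'pixels' must be a numeric matrix")
  else {
    if (any(px < 0 | px > 255, na.rm = TRUE))
      msg <- c(msg, "'pixels' must lie in [0, 255]")
    if (anyNA(px)) msg <- c(msg, "'pixels' must not contain NA")
  }
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    msg <- c(msg, "'spacing' must be a single positive number (cm/pixel)")
  if (length(object@dose) != 1L)
    msg <- c(msg, "'dose' must be a single number (mA) or NA")
  else if (!is.na(object@dose) && object@dose < 0)
    msg <- c(msg, "'dose' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an UltrasoundFrame
#'
#' @param pixels numeric matrix of gray levels in `[0, 255]`; coerced to
#'   integer by rounding.
#' @param spacing pixel spacing in cm/pixel (default 0.01, i.e. 100 um).
#' @param dose applied current intensity in mA, or `NA`.
#' @return An [UltrasoundFrame-class] object.
#' @examples
#' frm <- ultrasoundFrame(matrix(60, 16, 16))
#' dim(pixelData(frm))
#' @export
ultrasoundFrame <- function(pixels, spacing = 0.01, dose = NA_real_) {
  storage.mode(pixels) <- "integer"
  new("UltrasoundFrame", pixels = pixels, spacing = as.numeric(spacing),
      dose = as.numeric(dose))
}

#' GroundTruth: planted-lesion ground truth for a synthetic frame
#'
#' Records where hyperechoic foci were planted in a synthetic frame: focus
#' centers and radii (pixels), the binary union mask of all planted discs,
#' and the dose that drove the planting model.
#'
#' @slot centers numeric matrix with one row per focus, columns `row`, `col`
#'   (pixel coordinates).
#' @slot radii numeric vector of focus radii in pixels.
#' @slot mask logical matrix, union of the planted discs.
#' @slot dose numeric(1), applied dose in mA.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(centers = "matrix", radii = "numeric", mask = "matrix",
                 dose = "numeric")
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  n <- nrow(object@centers)
  if (length(object@radii) != n)
    msg <- c(msg, "one radius per focus center required")
  if (n > 0 && ncol(object@centers) != 2L)
    msg <- c(msg, "'centers' must have columns (row, col)")
  if (!is.logical(object@mask))
    msg <- c(msg, "'mask' must be logical")
  if (length(object@dose) != 1L || is.na(object@dose) || object@dose < 0)
    msg <- c(msg, "'dose' must be a single non-negative number")
  if (n == 0 && any(object@mask))
    msg <- c(msg, "mask must be empty when no foci are planted")
  if (n > 0) {
    expected <- discUnionMask(dim(object@mask), object@centers, object@radii)
    if (!identical(expected, object@mask))
      msg <- c(msg, "mask must equal the union of the planted discs")
  }
  if (length(msg)) msg else TRUE
})

#' RegionSet: labeled affected areas within a frame
#'
#' Result of segmenting hyperechoic "affected areas": a label matrix in which
#' background is 0 and each connected component carries a contiguous positive
#' label, plus the ROI the segmentation was restricted to.
#'
#' @slot labels integer matrix; 0 = background, 1..n = region labels.
#' @slot roi integer(4): first row, last row, first column, last column of the
#'   region of interest (pixel indices, inclusive).
#' @slot connectivity integer(1), 4 or 8.
#' @exportClass RegionSet
setClass("RegionSet",
  representation(labels = "matrix", roi = "integer", connectivity = "integer")
)

setValidity("RegionSet", function(object) {
  msg <- character()
  lab <- object@labels
  n <- if (length(lab)) max(lab) else 0L
  if (n > 0 && !identical(sort(unique(lab[lab > 0L])), seq_len(n)))
    msg <- c(msg, "region labels must be contiguous from 1")
  if (length(object@roi) != 4L || object@roi[1] > object@roi[2] ||
      object@roi[3] > object@roi[4])
    msg <- c(msg, "'roi' must be (row0, row1, col0, col1) with row0<=row1, col0<=col1")
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "'connectivity' must be 4 or 8")
  if (length(msg)) msg else TRUE
})

#' SpeckleParams: parameters of the speckle background simulator
#'
#' @slot width,height frame dimensions in pixels.
#' @slot spacing pixel spacing in cm/pixel.
#' @slot backgroundMean mean background gray level in `[0, 255]`.
#' @slot speckleScale dimensionless speckle strength: 0 gives a constant
#'   frame, 1 gives a fully developed Rayleigh envelope whose mean equals
#'   `backgroundMean`.
#' @exportClass SpeckleParams
setClass("SpeckleParams",
  representation(width = "integer", height = "integer", spacing = "numeric",
                 backgroundMean = "numeric", speckleScale = "numeric")
)

setValidity("SpeckleParams", function(object) {
  msg <- character()
  if (object@width < 1L || object@height < 1L)
    msg <- c(msg, "frame dimensions must be positive")
  if (object@spacing <= 0) msg <- c(msg, "'spacing' must be > 0")
  if (object@backgroundMean < 0 || object@backgroundMean > 255)
    msg <- c(msg, "'backgroundMean' must lie in [0, 255]")
  if (object@speckleScale < 0)
    msg <- c(msg, "'speckleScale' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct speckle-background parameters
#'
#' @param width,height frame size in pixels (defaults 256 x 256).
#' @param spacing pixel spacing in cm/pixel (default 0.01).
#' @param backgroundMean mean background gray level (default 60, a typical
#'   mid-dark muscle echogenicity on an 8-bit scale).
#' @param speckleScale speckle strength; 1 = fully developed speckle.
#' @return A [SpeckleParams-class] object.
#' @export
speckleParams <- function(width = 256, height = 256, spacing = 0.01,
                          backgroundMean = 60, speckleScale = 1) {
  if (any(c(width, height) < 1))
    stop("frame dimensions must be positive")
  new("SpeckleParams", width = as.integer(width), height = as.integer(height),
      spacing = as.numeric(spacing), backgroundMean = as.numeric(backgroundMean),
      speckleScale = as.numeric(speckleScale))
}

#' LesionModel: dose-dependent hyperechoic focus model
#'
#' Parametric model of how electrolysis changes a frame. The expected focus
#' count follows a saturating curve `rMax * d^2 / (d^2 + halfDose^2)` and the
#' mean focus radius grows along the same saturating curve from `radiusBase`
#' to `radiusBase + radiusGain`. Foci cluster around the needle-tip region
#' (bivariate normal, sd `clusterSpread`). Above `shadowThreshold` mA, pixels
#' below each focus are attenuated to emulate posterior acoustic shadowing by
#' accumulated gas.
#'
#' @slot rMax asymptotic mean focus count.
#' @slot halfDose dose (mA) at which the focus rate reaches half of `rMax`.
#' @slot radiusBase,radiusGain mean focus radius in cm at dose 0+ and its
#'   saturating increment.
#' @slot clusterSpread standard deviation (cm) of focus centers around the
#'   needle-tip point.
#' @slot intensityBoost gray-level increment of the focus plateau above the
#'   robust background level.
#' @slot focusSpeckle fraction of the background speckle fluctuation
#'   retained inside a focus, in `[0, 1)`; gas foci return a strong,
#'   relatively coherent echo, so their speckle is damped.
#' @slot shadowThreshold dose (mA) above which posterior shadowing is applied.
#' @slot shadowAttenuation multiplicative attenuation in (0, 1) applied to
#'   pixels below a focus.
#' @exportClass LesionModel
setClass("LesionModel",
  representation(rMax = "numeric", halfDose = "numeric",
                 radiusBase = "numeric", radiusGain = "numeric",
                 clusterSpread = "numeric", intensityBoost = "numeric",
                 focusSpeckle = "numeric", shadowThreshold = "numeric",
                 shadowAttenuation = "numeric")
)

setValidity("LesionModel", function(object) {
  msg <- character()
  if (object@rMax < 0) msg <- c(msg, "'rMax' must be >= 0")
  if (object@halfDose <= 0) msg <- c(msg, "'halfDose' must be > 0")
  if (object@radiusBase <= 0) msg <- c(msg, "'radiusBase' must be > 0")
  if (object@radiusGain < 0) msg <- c(msg, "'radiusGain' must be >= 0")
  if (object@clusterSpread <= 0) msg <- c(msg, "'clusterSpread' must be > 0")
  if (object@focusSpeckle < 0 || object@focusSpeckle >= 1)
    msg <- c(msg, "'focusSpeckle' must lie in [0, 1)")
  if (object@shadowAttenuation <= 0 || object@shadowAttenuation >= 1)
    msg <- c(msg, "'shadowAttenuation' must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a lesion model
#'
#' Defaults are calibrated to the qualitative dose-response trends reported
#' for muscle electrolysis: minimal response below 1 mA, clear growth over
#' 1--4 mA, and a plateau above 4--6 mA.
#'
#' @param rMax asymptotic mean focus count (default 8).
#' @param halfDose half-saturation dose in mA (default 3).
#' @param radiusBase mean focus radius (cm) near dose 0 (default 0.04).
#' @param radiusGain saturating radius increment in cm (default 0.03).
#' @param clusterSpread sd (cm) of focus placement around the needle tip
#'   (default 0.12).
#' @param intensityBoost gray-level increment of foci above the background
#'   level (default 160).
#' @param focusSpeckle fraction of speckle retained inside foci
#'   (default 0.3).
#' @param shadowThreshold dose (mA) above which posterior shadowing appears
#'   (default 4).
#' @param shadowAttenuation multiplicative shadow factor (default 0.6).
#' @return A [LesionModel-class] object.
#' @export
lesionModel <- function(rMax = 8, halfDose = 3, radiusBase = 0.04,
                        radiusGain = 0.03, clusterSpread = 0.12,
                        intensityBoost = 160, focusSpeckle = 0.3,
                        shadowThreshold = 4, shadowAttenuation = 0.6) {
  new("LesionModel", rMax = as.numeric(rMax), halfDose = as.numeric(halfDose),
      radiusBase = as.numeric(radiusBase), radiusGain = as.numeric(radiusGain),
      clusterSpread = as.numeric(clusterSpread),
      intensityBoost = as.numeric(intensityBoost),
      focusSpeckle = as.numeric(focusSpeckle),
      shadowThreshold = as.numeric(shadowThreshold),
      shadowAttenuation = as.numeric(shadowAttenuation))
}

#' SegmentationConfig: affected-area detection settings
#'
#' Affected areas are connected components of pixels brighter than
#' `median + k * SD` of the ROI background, where the background statistics
#' are robust (median and MAD) so that the lesions themselves do not inflate
#' the threshold. Components smaller than `minSize` pixels are discarded.
#'
#' @slot roi integer(4) `(row0, row1, col0, col1)` or all-`NA` for the whole
#'   frame.
#' @slot k threshold factor in background-SD multiples.
#' @slot minSize minimum region size in pixels.
#' @slot connectivity 4 or 8.
#' @exportClass SegmentationConfig
setClass("SegmentationConfig",
  representation(roi = "integer", k = "numeric", minSize = "integer",
                 connectivity = "integer")
)

setValidity("SegmentationConfig", function(object) {
  msg <- character()
  if (object@k <= 0) msg <- c(msg, "'k' must be > 0")
  if (object@minSize < 1L) msg <- c(msg, "'minSize' must be >= 1")
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "'connectivity' must be 4 or 8")
  if (length(object@roi) != 4L)
    msg <- c(msg, "'roi' must have length 4")
  if (length(msg)) msg else TRUE
})

#' Construct segmentation settings
#'
#' @param roi `(row0, row1, col0, col1)` in pixels, or `NULL` for the whole
#'   frame.
#' @param k threshold in background-SD multiples (default 3).
#' @param minSize minimum region size in pixels (default 20).
#' @param connectivity 4 or 8 (default 8).
#' @return A [SegmentationConfig-class] object.
#' @export
segmentationConfig <- function(roi = NULL, k = 3, minSize = 20,
                               connectivity = 8) {
  if (is.null(roi)) roi <- rep(NA_integer_, 4L)
  new("SegmentationConfig", roi = as.integer(roi), k = as.numeric(k),
      minSize = as.integer(minSize), connectivity = as.integer(connectivity))
}

#' TextureConfig: quantization and offset geometry for texture features
#'
#' @slot levels number of gray levels after quantization.
#' @slot offsets integer matrix, one `(drow, dcol)` displacement per row,
#'   pooled into a single symmetric co-occurrence matrix.
#' @slot delta integer(2), displacement for gray-level difference statistics.
#' @exportClass TextureConfig
setClass("TextureConfig",
  representation(levels = "integer", offsets = "matrix", delta = "integer")
)

setValidity("TextureConfig", function(object) {
  msg <- character()
  if (object@levels < 2L) msg <- c(msg, "'levels' must be >= 2")
  if (ncol(object@offsets) != 2L)
    msg <- c(msg, "'offsets' must have two columns (drow, dcol)")
  if (all(object@delta == 0L))
    msg <- c(msg, "'delta' must be a non-zero displacement")
  if (length(msg)) msg else TRUE
})

#' Construct texture settings
#'
#' Defaults: 32 gray levels and the four distance-1 directions (0, 45, 90,
#' 135 degrees) pooled into one symmetric co-occurrence matrix, with a
#' one-pixel horizontal displacement for the difference statistics. Pooling
#' the four directions removes directional bias of the speckle pattern.
#'
#' @param levels quantization levels (default 32).
#' @param offsets integer matrix of `(drow, dcol)` displacements.
#' @param delta displacement for gray-level difference statistics.
#' @return A [TextureConfig-class] object.
#' @export
textureConfig <- function(levels = 32,
                          offsets = rbind(c(0L, 1L), c(-1L, 1L),
                                          c(-1L, 0L), c(-1L, -1L)),
                          delta = c(0L, 1L)) {
  offsets <- matrix(as.integer(offsets), ncol = 2L,
                    dimnames = list(NULL, c("drow", "dcol")))
  new("TextureConfig", levels = as.integer(levels), offsets = offsets,
      delta = as.integer(delta))
}

#' DoseModel: the composite electrolysis dose index
#'
#' Linear model mapping the three retained geometric features (area, focus
#' count, perimeter of the affected regions) to an estimated applied current
#' intensity. The defaults are the published multiple-regression
#' coefficients that define the Muscle_Electrolysis_Dose (UZ_eDosis) index.
#'
#' @slot intercept mA.
#' @slot coefArea mA per cm^2.
#' @slot coefNumber mA per focus.
#' @slot coefPerimeter mA per cm.
#' @seealso [muscleElectrolysisDose()]
#' @exportClass DoseModel
setClass("DoseModel",
  representation(intercept = "numeric", coefArea = "numeric",
                 coefNumber = "numeric", coefPerimeter = "numeric")
)

setValidity("DoseModel", function(object) {
  v <- c(object@intercept, object@coefArea, object@coefNumber,
         object@coefPerimeter)
  if (length(v) != 4L || !all(is.finite(v)))
    "all four coefficients must be single finite numbers"
  else TRUE
})

#' Construct a dose model
#'
#' @param intercept intercept in mA (default 0.542).
#' @param coefArea coefficient of the affected area in mA/cm^2
#'   (default -316.88).
#' @param coefNumber coefficient of the focus count in mA/count
#'   (default -2.678).
#' @param coefPerimeter coefficient of the summed perimeter in mA/cm
#'   (default 20.284).
#' @return A [DoseModel-class] object.
#' @examples
#' muscleElectrolysisDose(0, 0, 0, doseModel())  # the model intercept
#' @export
doseModel <- function(intercept = 0.542, coefArea = -316.88,
                      coefNumber = -2.678, coefPerimeter = 20.284) {
  new("DoseModel", intercept = as.numeric(intercept),
      coefArea = as.numeric(coefArea), coefNumber = as.numeric(coefNumber),
      coefPerimeter = as.numeric(coefPerimeter))
}

#' FeatureGenModel: latent-factor generator for feature/dose tables
#'
#' Generates feature vectors `(A_Area, A_Number, A_Perimeter)` from three
#' standard-normal latent factors through a lower-triangular loading matrix,
#' then doses through a [DoseModel-class] plus Gaussian residual noise. Used
#' for parameter-recovery experiments on the regression stage.
#'
#' @slot means numeric(3): means of `(A_Area, A_Number, A_Perimeter)` in
#'   (cm^2, count, cm).
#' @slot loadings 3x3 lower-triangular matrix of latent-factor loadings
#'   (rows: area, number, perimeter; columns: z1..z3).
#' @slot doseModel the generating [DoseModel-class].
#' @slot sigma residual standard deviation of the dose (mA).
#' @exportClass FeatureGenModel
setClass("FeatureGenModel",
  representation(means = "numeric", loadings = "matrix",
                 doseModel = "DoseModel", sigma = "numeric")
)

setValidity("FeatureGenModel", function(object) {
  msg <- character()
  if (length(object@means) != 3L) msg <- c(msg, "'means' must have length 3")
  if (!all(dim(object@loadings) == c(3L, 3L)) ||
      !all(is.finite(object@loadings)))
    msg <- c(msg, "'loadings' must be a finite 3x3 matrix")
  else {
    ev <- eigen(tcrossprod(object@loadings), symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) <= 0)
      msg <- c(msg, "implied feature covariance must be positive definite")
  }
  if (object@sigma < 0) msg <- c(msg, "'sigma' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a feature-table generator model
#'
#' Default means are typical mid-dose values (area 0.030 cm^2, 2 foci,
#' perimeter 0.80 cm); default loadings give feature variances
#' (1e-4, 0.64, 0.06125) and positive cross-correlations, and the default
#' dose model is the published coefficient set.
#'
#' @param means numeric(3): means of `(A_Area, A_Number, A_Perimeter)`.
#' @param loadings 3x3 lower-triangular loading matrix (rows area, number,
#'   perimeter).
#' @param doseModel generating [DoseModel-class].
#' @param sigma residual dose standard deviation in mA (default 0.3).
#' @return A [FeatureGenModel-class] object.
#' @export
featureGenModel <- function(means = c(A_Area = 0.030, A_Number = 2.0,
                                      A_Perimeter = 0.80),
                            loadings = rbind(A_Area = c(0.006, 0.008, 0),
                                             A_Number = c(0.8, 0, 0),
                                             A_Perimeter = c(0.125, 0.075, 0.20)),
                            doseModel = EchoDose::doseModel(),
                            sigma = 0.3) {
  new("FeatureGenModel", means = as.numeric(means),
      loadings = matrix(as.numeric(loadings), 3L, 3L,
                        dimnames = list(c("A_Area", "A_Number", "A_Perimeter"),
                                        NULL)),
      doseModel = doseModel, sigma = as.numeric(sigma))
}

#' StatReport: the full dose-response statistical report
#'
#' @slot correlations data.frame: Spearman screen, one row per feature.
#' @slot simpleFits data.frame: per-feature simple OLS table.
#' @slot multiModel list: backward-elimination multiple-regression summary.
#' @slot features data.frame: the input feature table plus the composite
#'   `UZ_eDosis` column and the dose-group label.
#' @slot groupTests data.frame: Kruskal-Wallis table per variable.
#' @slot pairwise data.frame: Bonferroni-adjusted Mann-Whitney post hocs.
#' @exportClass StatReport
setClass("StatReport",
  representation(correlations = "data.frame", simpleFits = "data.frame",
                 multiModel = "list", features = "data.frame",
                 groupTests = "data.frame", pairwise = "data.frame")
)
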