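#' Simulate a fully developed speckle background
#'
#' Draws a B-mode-like background frame under the canonical fully developed
#' speckle model: the echo envelope is Rayleigh distributed, rescaled so its
#' mean equals `backgroundMean`, and mapped to the 8-bit gray scale with a
#' fixed gain. `speckleScale` interpolates linearly between a constant frame
#' (0) and the pure Rayleigh envelope (1), which keeps the mean gray level
#' fixed while tuning speckle strength.
#'
#' @param params a [SpeckleParams-class] object.
#' @param seed integer seed for reproducibility, or `NULL` to draw from the
#'   current RNG stream.
#' @return An [UltrasoundFrame-class].
#' @examples
#' frm <- simulateSpeckleBackground(speckleParams(width = 64, height = 64),
#'                                  seed = 1)
#' mean(pixelData(frm))
#' @export
simulateSpeckleBackground <- function(params = speckleParams(), seed = NULL) {
  stopifnot(is(params, "SpeckleParams"))
  validObject(params)
  stopifnot_scalar_seed(seed)
  h <- params@height; w <- params@width
  px <- withSeed(seed, {
    if (params@speckleScale == 0) {
      matrix(params@backgroundMean, h, w)
    } else {
      # Rayleigh(sigma = 1) envelope, normalized to unit mean
      env <- sqrt(-2 * log(stats::runif(h * w))) / sqrt(pi / 2)
      matrix(params@backgroundMean * (1 + params@speckleScale * (env - 1)),
             h, w)
    }
  })
  ultrasoundFrame(round(clip255(px)), spacing = params@spacing)
}

fociRate <- function(model, dose) {
  model@rMax * dose^2 / (dose^2 + model@halfDose^2)
}

focusRadius <- function(model, dose) {
  model@radiusBase + model@radiusGain * dose^2 / (dose^2 + model@halfDose^2)
}

#' Plant dose-dependent hyperechoic foci in a frame
#'
#' Adds bright foci emulating the hydrogen-gas microbubbles formed by
#' electrolysis. The focus count is Poisson with mean `fociRate(dose)`
#' (saturating in dose), centers cluster around the needle-tip point at the
#' frame center, and each focus is a disc raised `intensityBoost` gray
#' levels above the robust background level, with its speckle fluctuation
#' damped by `focusSpeckle` (gas foci echo coherently). Above `shadowThreshold` mA the column strip below each
#' focus is attenuated multiplicatively, emulating posterior acoustic
#' shadowing by accumulated gas.
#'
#' @param frame an [UltrasoundFrame-class] background.
#' @param dose applied current intensity in mA (>= 0).
#' @param model a [LesionModel-class].
#' @param seed integer seed, or `NULL` for the current RNG stream.
#' @return A list with elements `frame` (the modified
#'   [UltrasoundFrame-class], carrying the dose label) and `truth` (a
#'   [GroundTruth-class]).
#' @examples
#' bg <- simulateSpeckleBackground(speckleParams(width = 96, height = 96),
#'                                 seed = 1)
#' res <- plantLesions(bg, dose = 6, seed = 2)
#' fociCount(res$truth)
#' @export
plantLesions <- function(frame, dose, model = lesionModel(), seed = NULL) {
  stopifnot(is(frame, "UltrasoundFrame"), is(model, "LesionModel"))
  if (length(dose) != 1L || is.na(dose) || dose < 0)
    stop("'dose' must be a single non-negative intensity in mA")
  stopifnot_scalar_seed(seed)
  px <- pixelData(frame)
  dims <- dim(px)
  spacing <- pixelSpacing(frame)

  out <- withSeed(seed, {
    n <- stats::rpois(1L, fociRate(model, dose))
    if (n == 0L) {
      list(centers = matrix(numeric(0), 0L, 2L,
                            dimnames = list(NULL, c("row", "col"))),
           radii = numeric(0))
    } else {
      spread <- model@clusterSpread / spacing
      ctr <- c(dims[1] / 2, dims[2] / 2)
      margin <- ceiling((model@radiusBase + model@radiusGain) / spacing) + 2
      rows <- pmin(dims[1] - margin,
                   pmax(margin + 1, round(ctr[1] + stats::rnorm(n, 0, spread))))
      cols <- pmin(dims[2] - margin,
                   pmax(margin + 1, round(ctr[2] + stats::rnorm(n, 0, spread))))
      radii <- focusRadius(model, dose) / spacing *
        stats::runif(n, 0.8, 1.2)
      list(centers = cbind(row = rows, col = cols), radii = radii)
    }
  })

  mask <- discUnionMask(dims, out$centers, out$radii)
  if (any(mask)) {
    bg <- stats::median(px)
    px[mask] <- clip255(round(bg + model@intensityBoost +
                              model@focusSpeckle * (px[mask] - bg)))
  }

  if (dose > model@shadowThreshold && nrow(out$centers) > 0L) {
    shadow <- matrix(FALSE, dims[1], dims[2])
    for (i in seq_len(nrow(out$centers))) {
      r0 <- out$centers[i, 1]; c0 <- out$centers[i, 2]; rad <- out$radii[i]
      rFrom <- min(dims[1], floor(r0 + rad) + 1L)
      cc <- max(1L, ceiling(c0 - rad)):min(dims[2], floor(c0 + rad))
      if (rFrom <= dims[1]) shadow[rFrom:dims[1], cc] <- TRUE
    }
    shadow <- shadow & !mask
    px[shadow] <- round(px[shadow] * model@shadowAttenuation)
  }

  truth <- new("GroundTruth", centers = out$centers, radii = out$radii,
               mask = mask, dose = as.numeric(dose))
  list(frame = ultrasoundFrame(px, spacing = spacing, dose = dose),
       truth = truth)
}

#' Generate a full synthetic imaging experiment
#'
#' One frame per schedule entry: a speckle background with planted
#' dose-dependent foci. Per-frame seeds are derived as `seed + frame index`,
#' so the dataset is bit-reproducible from the master seed while frames stay
#' mutually independent.
#'
#' @param schedule numeric vector of doses in mA (default
#'   [makeDoseSchedule()]).
#' @param params a [SpeckleParams-class].
#' @param model a [LesionModel-class].
#' @param seed master integer seed (default 1).
#' @return A list with one element per dose, each a list `frame` / `truth`
#'   as returned by [plantLesions()].
#' @examples
#' ds <- generateImageDataset(schedule = c(0, 5),
#'                            params = speckleParams(width = 64, height = 64),
#'                            seed = 1)
#' vapply(ds, function(x) fociCount(x$truth), integer(1))
#' @export
generateImageDataset <- function(schedule = makeDoseSchedule(),
                                 params = speckleParams(),
                                 model = lesionModel(), seed = 1) {
  stopifnot(is.numeric(schedule), all(schedule >= 0))
  stopifnot_scalar_seed(seed)
  lapply(seq_along(schedule), function(i) {
    withSeed(as.integer(seed) + i, {
      bg <- simulateSpeckleBackground(params, seed = NULL)
      plantLesions(bg, dose = schedule[i], model = model, seed = NULL)
    })
  })
}

#' Generate a tabular feature/dose dataset with known parameters
#'
#' Draws `(A_Area, A_Number, A_Perimeter)` feature vectors from the
#' latent-factor model of a [FeatureGenModel-class] (unclipped Gaussian, so
#' least-squares recovery of the generating coefficients is unbiased), then
#' doses through its [DoseModel-class] plus `Normal(0, sigma)` residuals.
#'
#' @param n number of rows (>= 4, so a three-predictor regression retains
#'   residual degrees of freedom).
#' @param model a [FeatureGenModel-class].
#' @param seed integer seed, or `NULL`.
#' @return A data.frame with columns `A_Area`, `A_Number`, `A_Perimeter`,
#'   `dose_mA`.
#' @examples
#' tab <- generateFeatureTable(5, featureGenModel(sigma = 0), seed = 1)
#' tab$dose_mA - muscleElectrolysisDose(tab$A_Area, tab$A_Number,
#'                                      tab$A_Perimeter)
#' @export
generateFeatureTable <- function(n, model = featureGenModel(), seed = NULL) {
  stopifnot(is(model, "FeatureGenModel"))
  validObject(model)
  if (length(n) != 1L || is.na(n) || n < 4)
    stop("'n' must be at least 4 (regression needs residual df)")
  n <- as.integer(n)
  stopifnot_scalar_seed(seed)
  withSeed(seed, {
    z <- matrix(stats::rnorm(3L * n), nrow = 3L)
    feat <- t(model@means + model@loadings %*% z)
    dm <- model@doseModel
    dose <- dm@intercept + dm@coefArea * feat[, 1] +
      dm@coefNumber * feat[, 2] + dm@coefPerimeter * feat[, 3] +
      stats::rnorm(n, 0, model@sigma)
    data.frame(A_Area = feat[, 1], A_Number = feat[, 2],
               A_Perimeter = feat[, 3], dose_mA = dose)
  })
}
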