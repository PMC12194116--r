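# End-to-end orchestration: simulate -> extract -> analyze -> report,
# reproducible from one master seed, with a YAML-configurable pipeline.

#' Build a pipeline configuration
#'
#' Collects every tunable of the pipeline into one object: the master seed,
#' the dose schedule, speckle and lesion simulation parameters,
#' segmentation and texture settings, and the statistics settings.
#'
#' @param seed master seed (non-negative integer, default 1).
#' @param schedule dose schedule in mA (default [makeDoseSchedule()]).
#' @param speckle a [SpeckleParams-class].
#' @param lesion a [LesionModel-class].
#' @param segmentation a [SegmentationConfig-class].
#' @param texture a [TextureConfig-class].
#' @param boundaries dose-group boundaries (default `c(1, 4)`).
#' @param pRemove backward-elimination threshold (default 0.10).
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1, schedule = makeDoseSchedule(),
                           speckle = speckleParams(),
                           lesion = lesionModel(),
                           segmentation = segmentationConfig(),
                           texture = textureConfig(),
                           boundaries = c(1, 4), pRemove = 0.10) {
  stopifnot_scalar_seed(seed)
  structure(list(seed = as.integer(seed), schedule = schedule,
                 speckle = speckle, lesion = lesion,
                 segmentation = segmentation, texture = texture,
                 boundaries = boundaries, pRemove = pRemove),
            class = "PipelineConfig")
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig: seed", x$seed, "|", length(x$schedule), "doses",
      sprintf("(%.2f..%.2f mA)", min(x$schedule), max(x$schedule)), "\n")
  cat(sprintf("  frames %dx%d px @ %.3g cm/px | segmentation k=%.2g minSize=%d conn=%d\n",
              x$speckle@height, x$speckle@width, x$speckle@spacing,
              x$segmentation@k, x$segmentation@minSize,
              x$segmentation@connectivity))
  cat(sprintf("  texture L=%d | groups at %.2f/%.2f mA | p-remove %.2f\n",
              x$texture@levels, x$boundaries[1], x$boundaries[2], x$pRemove))
  invisible(x)
}

# keys understood in each YAML section, with coercion targets
.configSchema <- list(
  seed = "integer", schedule = "numeric",
  speckle = c(width = "integer", height = "integer", spacing = "numeric",
              background_mean = "numeric", speckle_scale = "numeric"),
  lesion = c(r_max = "numeric", half_dose = "numeric",
             radius_base = "numeric", radius_gain = "numeric",
             cluster_spread = "numeric", intensity_boost = "numeric",
             focus_speckle = "numeric", shadow_threshold = "numeric",
             shadow_attenuation = "numeric"),
  segmentation = c(roi = "integer", k = "numeric", min_size = "integer",
                   connectivity = "integer"),
  texture = c(levels = "integer", delta = "integer"),
  statistics = c(boundaries = "numeric", p_remove = "numeric")
)

# yaml returns mixed int/double sequences as lists; flatten scalar lists
normalizeYaml <- function(value) {
  if (is.list(value) && length(value) &&
      all(vapply(value, function(v) is.numeric(v) && length(v) == 1L,
                 logical(1))))
    unlist(value)
  else value
}

checkType <- function(value, type, path, errors) {
  value <- normalizeYaml(value)
  ok <- switch(type,
    integer = is.numeric(value) && all(value == trunc(value)),
    numeric = is.numeric(value))
  if (!ok) c(errors, sprintf("%s: expected %s, got '%s'", path, type,
                             paste(class(value), collapse = "/")))
  else errors
}

#' Validate a YAML pipeline configuration file
#'
#' Reads a YAML file, checks every key against the configuration schema
#' (unknown keys are rejected; type mismatches are listed with their key
#' paths), fills unset values with the documented defaults, and returns a
#' typed [pipelineConfig()]. An empty file yields the all-default
#' configuration.
#'
#' @param file path to a YAML configuration file.
#' @return A `PipelineConfig` on success; stops with the collected error
#'   list otherwise.
#' @export
validateConfig <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  raw <- yaml::read_yaml(file)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping")
  errors <- character(0)
  unknown <- setdiff(names(raw), names(.configSchema))
  if (length(unknown))
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown, collapse = ", ")))
  for (sec in intersect(names(raw), c("speckle", "lesion", "segmentation",
                                      "texture", "statistics"))) {
    val <- raw[[sec]]
    if (!is.list(val)) {
      errors <- c(errors, sprintf("%s: expected a mapping", sec))
      next
    }
    schema <- .configSchema[[sec]]
    bad <- setdiff(names(val), names(schema))
    if (length(bad))
      errors <- c(errors, sprintf("%s: unknown key(s): %s", sec,
                                  paste(bad, collapse = ", ")))
    for (key in intersect(names(val), names(schema)))
      errors <- checkType(val[[key]], schema[[key]],
                          paste(sec, key, sep = "."), errors)
  }
  if ("seed" %in% names(raw)) {
    errors <- checkType(raw$seed, "integer", "seed", errors)
    if (is.numeric(raw$seed) && length(raw$seed) == 1L && raw$seed < 0)
      errors <- c(errors, "seed: must be non-negative")
  }
  if ("schedule" %in% names(raw))
    errors <- checkType(raw$schedule, "numeric", "schedule", errors)
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))

  pick <- function(sec, key, default) {
    v <- normalizeYaml(raw[[sec]][[key]])
    if (is.null(v)) default else v
  }
  sp <- speckleParams(
    width = pick("speckle", "width", 256),
    height = pick("speckle", "height", 256),
    spacing = pick("speckle", "spacing", 0.01),
    backgroundMean = pick("speckle", "background_mean", 60),
    speckleScale = pick("speckle", "speckle_scale", 1))
  lm_ <- lesionModel(
    rMax = pick("lesion", "r_max", 8),
    halfDose = pick("lesion", "half_dose", 3),
    radiusBase = pick("lesion", "radius_base", 0.04),
    radiusGain = pick("lesion", "radius_gain", 0.03),
    clusterSpread = pick("lesion", "cluster_spread", 0.12),
    intensityBoost = pick("lesion", "intensity_boost", 160),
    focusSpeckle = pick("lesion", "focus_speckle", 0.3),
    shadowThreshold = pick("lesion", "shadow_threshold", 4),
    shadowAttenuation = pick("lesion", "shadow_attenuation", 0.6))
  sg <- segmentationConfig(
    roi = raw$segmentation$roi,
    k = pick("segmentation", "k", 3),
    minSize = pick("segmentation", "min_size", 20),
    connectivity = pick("segmentation", "connectivity", 8))
  tx <- textureConfig(
    levels = pick("texture", "levels", 32),
    delta = pick("texture", "delta", c(0L, 1L)))
  pipelineConfig(seed = if (is.null(raw$seed)) 1L else raw$seed,
                 schedule = if (is.null(raw$schedule)) makeDoseSchedule()
                            else normalizeYaml(raw$schedule),
                 speckle = sp, lesion = lm_, segmentation = sg, texture = tx,
                 boundaries = pick("statistics", "boundaries", c(1, 4)),
                 pRemove = pick("statistics", "p_remove", 0.10))
}

#' Write a synthetic imaging dataset to disk
#'
#' Frames as 8-bit grayscale PNG (`frame_001.png`, ...), the dose table as
#' `doses.csv` (columns `frame`, `dose_mA`), and the planted ground truth
#' as `ground_truth.json` (per frame: dose, focus centers, radii).
#'
#' @param dataset list as returned by [generateImageDataset()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the dose table data.frame.
#' @export
writeImageDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("frame_%03d.png", seq_along(dataset))
  for (i in seq_along(dataset)) {
    px <- pixelData(dataset[[i]]$frame)
    png::writePNG(px / 255, file.path(dir, files[i]))
  }
  doses <- data.frame(
    frame = files,
    dose_mA = vapply(dataset, function(x) doseLabel(x$frame), numeric(1)))
  utils::write.csv(doses, file.path(dir, "doses.csv"), row.names = FALSE)
  truth <- lapply(seq_along(dataset), function(i) {
    tr <- dataset[[i]]$truth
    list(frame = files[i], dose_mA = tr@dose,
         centers = if (fociCount(tr)) unname(apply(tr@centers, 1L, as.list))
                   else list(),
         radii_px = as.list(tr@radii))
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(doses)
}

#' Read a PNG/TIFF frame from disk
#'
#' @param path path to an 8-bit grayscale PNG or TIFF image.
#' @param spacing pixel spacing in cm/pixel.
#' @param dose dose label in mA, or `NA`.
#' @return An [UltrasoundFrame-class].
#' @export
readFrame <- function(path, spacing = 0.01, dose = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, " (expected png)"))
  if (length(dim(img)) == 3L) img <- img[, , 1L]   # grayscale channel
  ultrasoundFrame(round(img * 255), spacing = spacing, dose = dose)
}

#' Extract the per-frame feature table of an image directory
#'
#' Reads every frame listed in the dose table, extracts the 7 A_ and 13 B_
#' features, and returns them as one row per frame with the dose label in
#' column `dose_mA`.
#'
#' @param imagesDir directory containing the frames.
#' @param dosesCsv CSV with columns `frame`, `dose_mA` (default
#'   `doses.csv` inside `imagesDir`).
#' @param segConfig a [SegmentationConfig-class].
#' @param texConfig a [TextureConfig-class].
#' @param spacing pixel spacing in cm/pixel.
#' @return data.frame with columns `dose_mA` + the 20 features.
#' @export
extractFeatureTable <- function(imagesDir,
                                dosesCsv = file.path(imagesDir, "doses.csv"),
                                segConfig = segmentationConfig(),
                                texConfig = textureConfig(),
                                spacing = 0.01) {
  if (!dir.exists(imagesDir))
    stop("image directory not found: ", imagesDir)
  if (!file.exists(dosesCsv)) stop("dose table not found: ", dosesCsv)
  doses <- utils::read.csv(dosesCsv)
  if (!all(c("frame", "dose_mA") %in% names(doses)))
    stop("dose table must have columns 'frame' and 'dose_mA'")
  rows <- lapply(seq_len(nrow(doses)), function(i) {
    frm <- readFrame(file.path(imagesDir, doses$frame[i]), spacing = spacing,
                     dose = doses$dose_mA[i])
    c(dose_mA = doses$dose_mA[i],
      extractAFeatures(frm, segConfig, texConfig),
      extractBFeatures(frm, config = texConfig))
  })
  as.data.frame(do.call(rbind, rows))
}

writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report@correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(report@simpleFits, file.path(dir, "simple_regression.csv"),
                   row.names = FALSE)
  utils::write.csv(report@multiModel$coefficients,
                   file.path(dir, "multiple_regression.csv"),
                   row.names = FALSE)
  utils::write.csv(report@groupTests, file.path(dir, "kruskal_wallis.csv"),
                   row.names = FALSE)
  utils::write.csv(report@pairwise, file.path(dir, "pairwise_mannwhitney.csv"),
                   row.names = FALSE)
  mm <- report@multiModel
  jsonlite::write_json(
    list(retained = mm$retained, dropped = mm$dropped, R = mm$R,
         r.squared = mm$r.squared, adj.r.squared = mm$adj.r.squared,
         F = mm$F, p = mm$p, n = mm$n),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full pipeline
#'
#' simulate -> extract -> analyze -> report, reproducibly from the config's
#' master seed. The run directory receives `frames/` (PNG + dose CSV +
#' ground-truth JSON), `features.csv` (one row per frame: `dose_mA` + 7 A_
#' + 13 B_ columns), `report/` (CSV tables + JSON summary) and
#' `manifest.json` (package version, seed and the full configuration). Two
#' runs with the same configuration produce byte-identical CSV outputs.
#'
#' @param config a `PipelineConfig` (see [pipelineConfig()] /
#'   [validateConfig()]).
#' @param outDir output directory (created if missing).
#' @return The [StatReport-class], invisibly; side effect: the run
#'   directory.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (missing(outDir)) stop("'outDir' is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  dataset <- generateImageDataset(schedule = config$schedule,
                                  params = config$speckle,
                                  model = config$lesion, seed = config$seed)
  framesDir <- file.path(outDir, "frames")
  writeImageDataset(dataset, framesDir)

  features <- extractFeatureTable(framesDir,
                                  segConfig = config$segmentation,
                                  texConfig = config$texture,
                                  spacing = config$speckle@spacing)
  utils::write.csv(features, file.path(outDir, "features.csv"),
                   row.names = FALSE)

  report <- runFullAnalysis(features, boundaries = config$boundaries,
                            pRemove = config$pRemove)
  writeReport(report, file.path(outDir, "report"))

  manifest <- list(
    package = "EchoDose",
    version = as.character(utils::packageVersion("EchoDose")),
    seed = config$seed,
    n_frames = length(config$schedule),
    schedule = config$schedule,
    speckle = list(width = config$speckle@width,
                   height = config$speckle@height,
                   spacing = config$speckle@spacing,
                   background_mean = config$speckle@backgroundMean,
                   speckle_scale = config$speckle@speckleScale),
    lesion = list(r_max = config$lesion@rMax,
                  half_dose = config$lesion@halfDose,
                  radius_base = config$lesion@radiusBase,
                  radius_gain = config$lesion@radiusGain,
                  cluster_spread = config$lesion@clusterSpread,
                  intensity_boost = config$lesion@intensityBoost,
                  focus_speckle = config$lesion@focusSpeckle,
                  shadow_threshold = config$lesion@shadowThreshold,
                  shadow_attenuation = config$lesion@shadowAttenuation),
    segmentation = list(k = config$segmentation@k,
                        min_size = config$segmentation@minSize,
                        connectivity = config$segmentation@connectivity),
    texture = list(levels = config$texture@levels,
                   delta = config$texture@delta),
    statistics = list(boundaries = config$boundaries,
                      p_remove = config$pRemove))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
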