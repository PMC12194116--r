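# Affected-area detection and the region-level (A_) feature family.

# label connected components of a logical mask by iterative minimum-label
# propagation; supports 4- and 8-connectivity. Background = 0, labels are
# contiguous from 1 in first-encounter (column-major) order.
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), connectivity %in% c(4L, 8L))
  dims <- dim(mask)
  lab <- matrix(0, dims[1], dims[2])
  lab[mask] <- which(mask)            # unique provisional labels
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  shift <- function(m, dr, dc, fill) {
    out <- matrix(fill, dims[1], dims[2])
    rs <- max(1L, 1L + dr):min(dims[1], dims[1] + dr)
    cs <- max(1L, 1L + dc):min(dims[2], dims[2] + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  if (any(mask)) {
    repeat {
      nb <- lab
      for (o in offs) {
        sh <- shift(lab, o[1], o[2], Inf)
        sh[sh == 0] <- Inf
        nb <- pmin(nb, sh)
      }
      nb[!mask] <- 0
      if (identical(nb, lab)) break
      lab <- nb
    }
  }
  ids <- unique(lab[lab > 0])
  relab <- lab
  if (length(ids))
    relab[lab > 0] <- match(lab[lab > 0], sort(ids))
  storage.mode(relab) <- "integer"
  relab
}

#' Segment the affected areas of a frame
#'
#' Detects hyperechoic "affected areas": connected components of ROI pixels
#' brighter than `median + k * SD`, where the background statistics are the
#' ROI median and a MAD-based SD estimate (robust, so the lesions themselves
#' do not inflate the threshold). Components smaller than `minSize` pixels
#' are discarded; the remaining components are relabeled contiguously.
#'
#' Because the threshold is relative to the ROI's own background statistics,
#' the detector is invariant to adding a constant gray offset to the frame.
#'
#' @param frame an [UltrasoundFrame-class].
#' @param config a [SegmentationConfig-class].
#' @return A [RegionSet-class].
#' @examples
#' frm <- simulateSpeckleBackground(speckleParams(width = 96, height = 96),
#'                                  seed = 1)
#' regionCount(segmentAffectedAreas(frm))
#' @export
segmentAffectedAreas <- function(frame, config = segmentationConfig()) {
  stopifnot(is(frame, "UltrasoundFrame"), is(config, "SegmentationConfig"))
  validObject(config)
  px <- pixelData(frame)
  roi <- resolveRoi(config@roi, dim(px))
  win <- px[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  if (length(win) == 0L) stop("empty ROI")
  med <- stats::median(win)
  sdRob <- stats::mad(win)
  if (sdRob == 0) sdRob <- stats::sd(win)          # near-constant fallback
  mask <- win > med + config@k * sdRob
  lab <- labelComponents(mask, config@connectivity)
  n <- max(lab)
  if (n > 0L) {
    sizes <- tabulate(lab[lab > 0L], n)
    keep <- which(sizes >= config@minSize)
    lab[!(lab %in% keep)] <- 0L
    if (length(keep))
      lab[lab > 0L] <- match(lab[lab > 0L], keep)
    storage.mode(lab) <- "integer"
  }
  full <- matrix(0L, nrow(px), ncol(px))
  full[roi[1]:roi[2], roi[3]:roi[4]] <- lab
  new("RegionSet", labels = full, roi = roi,
      connectivity = config@connectivity)
}

# Moore-neighbour boundary tracing of a single-region logical mask.
# Returns the ordered boundary pixel coordinates (row, col) of the outer
# contour. Jacob's stopping criterion (start pixel re-entered from the same
# backtrack direction).
traceBoundary <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(numeric(0), 0, 2))
  # start: topmost pixel of the leftmost column containing the region
  cols <- (idx - 1L) %/% dims[1] + 1L
  rows <- (idx - 1L) %% dims[1] + 1L
  cmin <- min(cols)
  r0 <- min(rows[cols == cmin])
  start <- c(r0, cmin)
  if (length(idx) == 1L) return(matrix(start, 1, 2))
  # clockwise Moore neighbourhood starting west (row down, col right)
  nbr <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
               c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  inside <- function(p) p[1] >= 1 && p[1] <= dims[1] &&
    p[2] >= 1 && p[2] <= dims[2] && mask[p[1], p[2]]
  path <- list(start)
  cur <- start
  back <- 1L                  # scan starts at the backtrack cell (west of start)
  firstDir <- NA_integer_
  maxSteps <- 8L * (length(idx) + 4L)
  for (step in seq_len(maxSteps)) {
    k <- NA_integer_
    for (j in 0:7) {
      kk <- ((back - 1L + j) %% 8L) + 1L
      if (inside(cur + nbr[kk, ])) { k <- kk; break }
    }
    if (is.na(k)) break                            # isolated pixel
    if (is.na(firstDir)) firstDir <- k
    else if (all(cur == start) && k == firstDir) break   # loop closed (Jacob)
    cand <- cur + nbr[k, ]
    # next scan starts at the background cell examined just before the hit
    prevP <- cur + nbr[((k - 2L) %% 8L) + 1L, ]
    dd <- prevP - cand
    back <- which(nbr[, 1] == dd[1] & nbr[, 2] == dd[2])
    cur <- cand
    if (!all(cur == start)) path[[length(path) + 1L]] <- cur
  }
  do.call(rbind, path)
}

# chain-code boundary length of an ordered closed contour: 1 per axial step,
# sqrt(2) per diagonal step ("crack length with diagonal correction").
chainLength <- function(path) {
  n <- nrow(path)
  if (n < 2L) return(if (n == 1L) 4 else 0)   # lone pixel: unit-square crack
  nxt <- rbind(path[-1L, , drop = FALSE], path[1L, , drop = FALSE])
  d <- abs(nxt - path)
  sum(ifelse(d[, 1] + d[, 2] == 2L, sqrt(2), 1))
}

# perimeter of the convex hull of a point set (pixel centers)
hullPerimeter <- function(pts) {
  if (nrow(pts) == 1L) return(4)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  if (length(h) < 2L) return(4)
  hp <- pts[h, , drop = FALSE]
  nxt <- rbind(hp[-1L, , drop = FALSE], hp[1L, , drop = FALSE])
  sum(sqrt(rowSums((nxt - hp)^2)))
}

regionMaskList <- function(regions) {
  lab <- labelMatrix(regions)
  n <- regionCount(regions)
  lapply(seq_len(n), function(i) lab == i)
}

#' Geometric features of the affected areas
#'
#' Computes the region-level geometry of a segmentation:
#' * `A_Number` - number of affected areas;
#' * `A_Area` - total pixel count times `spacing^2` (cm^2);
#' * `A_Perimeter` - summed boundary length (chain code with diagonal
#'   correction) times `spacing` (cm);
#' * `A_Convexity` - summed convex-hull perimeter over summed region
#'   perimeter, in `(0, 1]`; 1 for convex regions, decreasing with boundary
#'   irregularity. Defined as 1 when there are no regions.
#'
#' @param regions a [RegionSet-class].
#' @param spacing pixel spacing in cm/pixel.
#' @return Named numeric vector `(A_Number, A_Area, A_Perimeter,
#'   A_Convexity)`.
#' @export
geometricFeatures <- function(regions, spacing = 0.01) {
  stopifnot(is(regions, "RegionSet"), spacing > 0)
  n <- regionCount(regions)
  if (n == 0L)
    return(c(A_Number = 0, A_Area = 0, A_Perimeter = 0, A_Convexity = 1))
  masks <- regionMaskList(regions)
  areaPx <- sum(regionSizes(regions))
  perims <- vapply(masks, function(m) chainLength(traceBoundary(m)), numeric(1))
  # hull over the pixel corners: the convex envelope of the region's
  # occupied area, comparable to the chain-code boundary length
  hulls <- vapply(masks, function(m) {
    pts <- which(m, arr.ind = TRUE)
    corners <- rbind(sweep(pts, 2, c(0.5, 0.5)), sweep(pts, 2, c(0.5, -0.5)),
                     sweep(pts, 2, c(-0.5, 0.5)), sweep(pts, 2, c(-0.5, -0.5)))
    hullPerimeter(corners)
  }, numeric(1))
  c(A_Number = as.numeric(n),
    A_Area = areaPx * spacing^2,
    A_Perimeter = sum(perims) * spacing,
    A_Convexity = min(1, sum(hulls) / sum(perims)))
}

#' Echotexture of the treated region
#'
#' GLCM-based texture of the union bounding window of the affected areas:
#' `A_Homogeneity` (inverse difference moment), `A_Contrast` and `A_ASM`
#' (angular second moment), using the offsets and quantization of a
#' [TextureConfig-class]. The window is recentered at its median gray level
#' before quantization, so the A_ texture - like the detector itself - is
#' invariant to a constant echogenicity offset. When there are no affected areas the frame is
#' unperturbed and the conventional degenerate values `(1, 0, 1)` are
#' returned - maximal homogeneity and uniformity, zero lesion contrast.
#'
#' @param frame an [UltrasoundFrame-class].
#' @param regions a [RegionSet-class] for the same frame.
#' @param config a [TextureConfig-class].
#' @return Named numeric vector `(A_Homogeneity, A_Contrast, A_ASM)`.
#' @export
regionTextureFeatures <- function(frame, regions, config = textureConfig()) {
  stopifnot(is(frame, "UltrasoundFrame"), is(regions, "RegionSet"))
  if (regionCount(regions) == 0L)
    return(c(A_Homogeneity = 1, A_Contrast = 0, A_ASM = 1))
  lab <- labelMatrix(regions)
  idx <- which(lab > 0L)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  win <- pixelData(frame)[min(rows):max(rows), min(cols):max(cols),
                          drop = FALSE]
  win <- clip255(win - stats::median(win) + 128)
  q <- quantizeGray(win, config@levels)
  m <- glcm(q, offsets = config@offsets, levels = config@levels)
  p <- m$p
  i <- row(p) - 1L
  j <- col(p) - 1L
  c(A_Homogeneity = sum(p / (1 + (i - j)^2)),
    A_Contrast = sum((i - j)^2 * p),
    A_ASM = sum(p^2))
}

#' Extract the full A_ feature vector of a frame
#'
#' Composes [segmentAffectedAreas()], [geometricFeatures()] and
#' [regionTextureFeatures()] into the seven region-level descriptors
#' `A_Number`, `A_Area`, `A_Perimeter`, `A_Convexity`, `A_Homogeneity`,
#' `A_Contrast`, `A_ASM`.
#'
#' @param frame an [UltrasoundFrame-class].
#' @param segConfig a [SegmentationConfig-class].
#' @param texConfig a [TextureConfig-class].
#' @return Named numeric vector of the seven A_ features.
#' @examples
#' frm <- simulateSpeckleBackground(speckleParams(width = 96, height = 96),
#'                                  seed = 1)
#' extractAFeatures(frm)
#' @export
extractAFeatures <- function(frame, segConfig = segmentationConfig(),
                             texConfig = textureConfig()) {
  regions <- segmentAffectedAreas(frame, segConfig)
  c(geometricFeatures(regions, spacing = pixelSpacing(frame)),
    regionTextureFeatures(frame, regions, texConfig))
}
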