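# Whole-ROI echotexture descriptors: GLCM (Haralick), gray-level difference
# statistics, and one-level Haar detail statistics (the B_ feature family).

#' Quantize an 8-bit raster to L gray levels
#'
#' Uniform binning of the `[0, 255]` range into `levels` bins; a full-range
#' input maps onto every level `0 .. levels - 1`. Quantization is monotone
#' in the input gray level.
#'
#' @param x numeric matrix of gray levels in `[0, 255]`, or an
#'   [UltrasoundFrame-class].
#' @param levels number of output levels (>= 2).
#' @return Integer matrix with values in `0 .. levels - 1`.
#' @examples
#' range(quantizeGray(matrix(0:255, 16), levels = 32))
#' @export
quantizeGray <- function(x, levels = 32) {
  if (is(x, "UltrasoundFrame")) x <- pixelData(x)
  if (levels < 2) stop("'levels' must be >= 2")
  q <- pmin(as.integer(levels) - 1L, floor(x / 256 * as.integer(levels)))
  storage.mode(q) <- "integer"
  matrix(q, nrow(x), ncol(x))
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of quantized gray-level pairs over a set of pixel
#' displacements, pools them, symmetrizes, and normalizes to a joint
#' distribution `p(i, j)`.
#'
#' @param q integer matrix of quantized levels `0 .. levels - 1`.
#' @param offsets integer matrix of `(drow, dcol)` displacements (one per
#'   row); pairs falling outside the raster are skipped.
#' @param levels number of gray levels `L`.
#' @param symmetric symmetrize by also counting each pair reversed
#'   (default `TRUE`).
#' @return A list with `p` (the L x L normalized matrix) and `levels`.
#' @examples
#' q <- rbind(c(0L, 1L), c(0L, 1L))
#' glcm(q, offsets = c(0L, 1L), levels = 2)$p
#' @export
glcm <- function(q, offsets = textureConfig()@offsets, levels = max(q) + 1L,
                 symmetric = TRUE) {
  stopifnot(is.matrix(q), length(q) > 0)
  offsets <- matrix(as.integer(offsets), ncol = 2L)
  L <- as.integer(levels)
  counts <- matrix(0, L, L)
  nr <- nrow(q); nc <- ncol(q)
  used <- 0L
  for (i in seq_len(nrow(offsets))) {
    dr <- offsets[i, 1]; dc <- offsets[i, 2]
    rs <- max(1L, 1L - dr):min(nr, nr - dr)
    cs <- max(1L, 1L - dc):min(nc, nc - dc)
    if (length(rs) < 1L || length(cs) < 1L || nr - abs(dr) < 1L ||
        nc - abs(dc) < 1L) next
    a <- q[rs, cs, drop = FALSE]
    b <- q[rs + dr, cs + dc, drop = FALSE]
    tab <- tabulate(a * L + b + 1L, nbins = L * L)
    counts <- counts + matrix(tab, L, L, byrow = TRUE)
    used <- used + 1L
  }
  if (used == 0L) stop("all offsets fall outside the raster")
  if (symmetric) counts <- counts + t(counts)
  list(p = counts / sum(counts), levels = L)
}

#' Haralick features of a co-occurrence matrix
#'
#' The six GLCM descriptors of the B_ family, with `i, j` the zero-based
#' gray levels and `p` the normalized matrix:
#' contrast `sum (i-j)^2 p`; sum average `sum k p_{x+y}(k)`;
#' sum-of-squares variance `sum (i - mu)^2 p` with `mu` the marginal mean;
#' difference variance (variance of the absolute-difference distribution
#' `p_{|x-y|}`; for a symmetric matrix the signed-difference distribution is
#' symmetric, which would make its variance collapse into the contrast);
#' correlation `(sum i j p - mu_x mu_y) / (sigma_x sigma_y)`
#' (defined 0 when a marginal is degenerate); inverse difference moment
#' `sum p / (1 + (i-j)^2)`.
#'
#' @param m a co-occurrence matrix as returned by [glcm()].
#' @return Named numeric vector of the six `B_GLCM_*` features.
#' @export
glcmFeatures <- function(m) {
  p <- m$p
  L <- m$levels
  stopifnot(abs(sum(p) - 1) < 1e-9)
  i <- row(p) - 1
  j <- col(p) - 1
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum((0:(L - 1)) * px)
  muy <- sum((0:(L - 1)) * py)
  sx <- sqrt(sum(((0:(L - 1)) - mux)^2 * px))
  sy <- sqrt(sum(((0:(L - 1)) - muy)^2 * py))
  # p_{x+y}(k), k = 0..2L-2 and absolute p_{|x-y|}(k), k = 0..L-1
  psum <- vapply(0:(2 * L - 2), function(k) sum(p[i + j == k]), numeric(1))
  kd <- 0:(L - 1)
  pdiff <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))
  mud <- sum(kd * pdiff)
  corr <- if (sx * sy == 0) 0 else (sum(i * j * p) - mux * muy) / (sx * sy)
  c(B_GLCM_Contrast = sum((i - j)^2 * p),
    B_GLCM_SumAverage = sum((0:(2 * L - 2)) * psum),
    B_GLCM_SoSVariance = sum((i - mux)^2 * p),
    B_GLCM_DVariance = sum((kd - mud)^2 * pdiff),
    B_GLCM_Correlation = corr,
    B_GLCM_IDMoment = sum(p / (1 + (i - j)^2)))
}

#' Gray-level difference statistics histogram
#'
#' Distribution of absolute quantized gray-level differences
#' `|I(x) - I(x + delta)|` over all pixels with a valid displaced partner.
#'
#' @param q integer matrix of quantized levels.
#' @param delta integer(2) displacement `(drow, dcol)`, non-zero.
#' @param levels number of gray levels.
#' @return Numeric vector `g[k]`, `k = 0 .. levels - 1`, summing to 1.
#' @examples
#' glds(rbind(c(0L, 1L), c(0L, 1L)), delta = c(0L, 1L), levels = 2)
#' @export
glds <- function(q, delta = c(0L, 1L), levels = max(q) + 1L) {
  stopifnot(is.matrix(q))
  delta <- as.integer(delta)
  if (all(delta == 0L)) stop("'delta' must be a non-zero displacement")
  nr <- nrow(q); nc <- ncol(q)
  if (abs(delta[1]) >= nr || abs(delta[2]) >= nc)
    stop("'delta' exceeds the raster extent")
  dr <- delta[1]; dc <- delta[2]
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  d <- abs(q[rs, cs, drop = FALSE] - q[rs + dr, cs + dc, drop = FALSE])
  g <- tabulate(d + 1L, nbins = as.integer(levels))
  g / sum(g)
}

#' Features of a gray-level difference histogram
#'
#' With `g(k)` the difference distribution: mean `sum k g(k)`; contrast
#' `sum k^2 g(k)`; angular second moment `sum g(k)^2`; entropy
#' `-sum g(k) log g(k)` (natural log, `0 log 0 := 0`); homogeneity
#' `sum g(k) / (1 + k)`.
#'
#' @param g numeric histogram as returned by [glds()].
#' @return Named numeric vector of the five `B_GLDS_*` features.
#' @export
gldsFeatures <- function(g) {
  stopifnot(abs(sum(g) - 1) < 1e-9, all(g >= 0))
  k <- seq_along(g) - 1
  pos <- g > 0
  c(B_GLDS_Homogeneity = sum(g / (1 + k)),
    B_GLDS_Contrast = sum(k^2 * g),
    B_GLDS_ASM = sum(g^2),
    B_GLDS_Entropy = -sum(g[pos] * log(g[pos])),
    B_GLDS_Mean = sum(k * g))
}

#' One-level Haar detail statistics
#'
#' Applies a one-level 2-D orthonormal Haar transform (odd trailing edges
#' cropped), pools the three detail subbands (LH, HL, HH) and returns the
#' mean and variance of their absolute values. The approximation band is
#' discarded, so the statistics are invariant to a constant gray offset.
#'
#' @param x numeric matrix (gray levels) or an [UltrasoundFrame-class];
#'   both dimensions must be >= 2.
#' @return Named numeric vector `(B_haar_mean, B_haar_variance)`.
#' @examples
#' haarFeatures(matrix(60, 16, 16))  # constant frame: both zero
#' @export
haarFeatures <- function(x) {
  if (is(x, "UltrasoundFrame")) x <- pixelData(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("frame must be at least 2 x 2")
  nr <- 2L * (nrow(x) %/% 2L)
  nc <- 2L * (ncol(x) %/% 2L)
  x <- x[seq_len(nr), seq_len(nc), drop = FALSE]
  a <- x[seq(1, nr, 2), seq(1, nc, 2), drop = FALSE]   # top-left
  b <- x[seq(1, nr, 2), seq(2, nc, 2), drop = FALSE]   # top-right
  cc <- x[seq(2, nr, 2), seq(1, nc, 2), drop = FALSE]  # bottom-left
  d <- x[seq(2, nr, 2), seq(2, nc, 2), drop = FALSE]   # bottom-right
  lh <- (a - b + cc - d) / 2       # horizontal detail (vertical edges)
  hl <- (a + b - cc - d) / 2       # vertical detail (horizontal edges)
  hh <- (a - b - cc + d) / 2       # diagonal detail
  det <- abs(c(lh, hl, hh))
  v <- if (length(det) > 1L) stats::var(det) else 0
  c(B_haar_mean = mean(det), B_haar_variance = as.numeric(v))
}

#' Extract the full B_ feature vector of a frame
#'
#' Composes the whole-ROI texture descriptors: six GLCM (Haralick) features,
#' five gray-level difference statistics and the two Haar detail statistics,
#' using the quantization and offset geometry of a [TextureConfig-class].
#'
#' @param frame an [UltrasoundFrame-class].
#' @param roi `(row0, row1, col0, col1)` in pixels, or `NULL` for the whole
#'   frame.
#' @param config a [TextureConfig-class].
#' @return Named numeric vector of the 13 B_ features.
#' @examples
#' frm <- simulateSpeckleBackground(speckleParams(width = 64, height = 64),
#'                                  seed = 1)
#' extractBFeatures(frm)
#' @export
extractBFeatures <- function(frame, roi = NULL, config = textureConfig()) {
  stopifnot(is(frame, "UltrasoundFrame"), is(config, "TextureConfig"))
  px <- pixelData(frame)
  r <- resolveRoi(if (is.null(roi)) rep(NA_integer_, 4L) else roi, dim(px))
  win <- px[r[1]:r[2], r[3]:r[4], drop = FALSE]
  q <- quantizeGray(win, config@levels)
  m <- glcm(q, offsets = config@offsets, levels = config@levels)
  g <- glds(q, delta = config@delta, levels = config@levels)
  c(glcmFeatures(m), gldsFeatures(g), haarFeatures(win))
}
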