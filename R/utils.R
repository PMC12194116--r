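# internal helpers shared across modules

# union of filled discs on a pixel grid; centers in (row, col), radii in px.
# A pixel belongs to a disc when its center lies within the radius.
discUnionMask <- function(dims, centers, radii) {
  mask <- matrix(FALSE, dims[1], dims[2])
  if (is.null(centers) || nrow(centers) == 0L) return(mask)
  rows <- seq_len(dims[1])
  cols <- seq_len(dims[2])
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]; rad <- radii[i]
    rr <- rows[abs(rows - r0) <= rad]
    cc <- cols[abs(cols - c0) <= rad]
    if (!length(rr) || !length(cc)) next
    d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
    mask[rr, cc] <- mask[rr, cc] | (d2 <= rad^2)
  }
  mask
}

clip255 <- function(x) {
  y <- pmin(255, pmax(0, x))
  attributes(y) <- attributes(x)
  y
}

# resolve a possibly-NA ROI against frame dimensions; returns integer(4)
resolveRoi <- function(roi, dims) {
  if (anyNA(roi)) roi <- c(1L, dims[1], 1L, dims[2])
  roi <- as.integer(roi)
  if (roi[1] < 1L || roi[2] > dims[1] || roi[3] < 1L || roi[4] > dims[2] ||
      roi[1] > roi[2] || roi[3] > roi[4])
    stop("ROI (", paste(roi, collapse = ","), ") outside frame bounds ",
         dims[1], "x", dims[2])
  roi
}

stopifnot_scalar_seed <- function(seed) {
  if (!is.null(seed)) {
    if (length(seed) != 1L || is.na(seed) || seed != trunc(seed) || seed < 0)
      stop("'seed' must be a single non-negative integer or NULL")
  }
  invisible(seed)
}

# run code under a fixed seed when given, or in the current RNG stream
withSeed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
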