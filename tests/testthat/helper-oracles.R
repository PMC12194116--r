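# Independent brute-force oracles and fixture builders used across tests.

# literal double-loop co-occurrence oracle
oracleGlcm <- function(q, offsets, L, symmetric = TRUE) {
  counts <- matrix(0, L, L)
  offsets <- matrix(as.integer(offsets), ncol = 2)
  for (o in seq_len(nrow(offsets))) {
    dr <- offsets[o, 1]; dc <- offsets[o, 2]
    for (r in seq_len(nrow(q))) for (cl in seq_len(ncol(q))) {
      r2 <- r + dr; c2 <- cl + dc
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        counts[q[r, cl] + 1, q[r2, c2] + 1] <-
          counts[q[r, cl] + 1, q[r2, c2] + 1] + 1
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# literal-formula Haralick oracle on a normalized matrix p
oracleGlcmFeatures <- function(p) {
  L <- nrow(p)
  con <- sa <- sos <- idm <- cross <- 0
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((0:(L - 1)) * px); muy <- sum((0:(L - 1)) * py)
  sx <- sqrt(sum((0:(L - 1) - mux)^2 * px))
  sy <- sqrt(sum((0:(L - 1) - muy)^2 * py))
  mu <- mux
  psum <- rep(0, 2 * L - 1)
  pdiff <- rep(0, L)           # index |i - j| + 1
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    v <- p[i + 1, j + 1]
    con <- con + (i - j)^2 * v
    sos <- sos + (i - mu)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    cross <- cross + i * j * v
    psum[i + j + 1] <- psum[i + j + 1] + v
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + v
  }
  sa <- sum((0:(2 * L - 2)) * psum)
  kd <- 0:(L - 1)
  mud <- sum(kd * pdiff)
  dvar <- sum((kd - mud)^2 * pdiff)
  corr <- if (sx * sy == 0) 0 else (cross - mux * muy) / (sx * sy)
  c(B_GLCM_Contrast = con, B_GLCM_SumAverage = sa, B_GLCM_SoSVariance = sos,
    B_GLCM_DVariance = dvar, B_GLCM_Correlation = corr, B_GLCM_IDMoment = idm)
}

oracleGlds <- function(q, delta, L) {
  g <- rep(0, L)
  for (r in seq_len(nrow(q))) for (cl in seq_len(ncol(q))) {
    r2 <- r + delta[1]; c2 <- cl + delta[2]
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
      d <- abs(q[r, cl] - q[r2, c2])
      g[d + 1] <- g[d + 1] + 1
    }
  }
  g / sum(g)
}

# breadth-first flood-fill labeling oracle
oracleLabel <- function(mask, connectivity = 8) {
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1) %% nrow(mask) + 1; cl <- (cur - 1) %/% nrow(mask) + 1
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs[k, 1]; c2 <- cl + offs[k, 2]
        if (r2 >= 1 && r2 <= nrow(mask) && c2 >= 1 && c2 <= ncol(mask) &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nxt
          queue <- c(queue, (c2 - 1) * nrow(mask) + r2)
        }
      }
    }
  }
  lab
}

# speckle frame with discs planted directly at boostSD background-SD units
# above the background (independent of the LesionModel recipe)
plantedDiscFrame <- function(centers, radius = 10, boostSD = 5,
                             dims = c(128, 128), seed = 1, cap = NULL) {
  frm <- simulateSpeckleBackground(
    speckleParams(width = dims[2], height = dims[1]), seed = seed)
  px <- pixelData(frm)
  sdr <- stats::mad(px)
  mask <- EchoDose:::discUnionMask(dims, centers,
                                   rep(radius, nrow(centers)))
  px[mask] <- pmin(255, round(px[mask] + boostSD * sdr))
  if (!is.null(cap)) px <- pmin(px, cap)
  list(frame = ultrasoundFrame(px), mask = mask)
}
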