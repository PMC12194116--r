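test_that("quantization bins uniformly, monotonically and surjectively", {
  expect_identical(unique(as.vector(quantizeGray(matrix(123, 4, 4), 32))),
                   15L)
  ramp <- matrix(0:255, 16, 16)
  q <- quantizeGray(ramp, 32)
  expect_identical(sort(unique(as.vector(q))), 0:31)
  x <- matrix(sample(0:255, 64, TRUE), 8, 8)
  q8 <- quantizeGray(x, 8)
  ord <- order(as.vector(x))
  expect_true(all(diff(as.vector(q8)[ord]) >= 0))
  expect_error(quantizeGray(ramp, 1), ">= 2")
})

test_that("co-occurrence matrices match hand enumeration and the oracle", {
  q <- rbind(c(0L, 1L), c(0L, 1L))
  p <- glcm(q, offsets = c(0L, 1L), levels = 2)$p
  expect_equal(p, rbind(c(0, 0.5), c(0.5, 0)))

  pc <- glcm(matrix(3L, 5, 5), offsets = c(0L, 1L), levels = 8)$p
  expect_equal(pc[4, 4], 1)
  expect_equal(sum(pc), 1)

  offsets <- rbind(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  set.seed(31)
  for (i in 1:50) {
    q <- matrix(sample(0:7, 16 * 16, TRUE), 16, 16)
    m <- glcm(q, offsets = offsets, levels = 8)
    expect_equal(m$p, oracleGlcm(q, offsets, 8), tolerance = 1e-12)
    expect_equal(sum(m$p), 1, tolerance = 1e-9)
    expect_equal(m$p, t(m$p), tolerance = 1e-12)
  }
  expect_error(glcm(matrix(0L, 2, 2), offsets = c(0L, 5L), levels = 2),
               "outside")
})

test_that("Haralick features match closed forms and the literal oracle", {
  # checkerboard-derived matrix p(0,1) = p(1,0) = 0.5
  m <- list(p = rbind(c(0, 0.5), c(0.5, 0)), levels = 2L)
  f <- glcmFeatures(m)
  expect_equal(unname(f["B_GLCM_Contrast"]), 1)
  expect_equal(unname(f["B_GLCM_IDMoment"]), 0.5)
  expect_equal(unname(f["B_GLCM_Correlation"]), -1)
  expect_equal(unname(f["B_GLCM_SumAverage"]), 1)

  # constant image: single cell, degenerate correlation convention
  mc <- list(p = rbind(c(1, 0), c(0, 0)), levels = 2L)
  fc <- glcmFeatures(mc)
  expect_equal(unname(fc["B_GLCM_Contrast"]), 0)
  expect_equal(unname(fc["B_GLCM_IDMoment"]), 1)
  expect_equal(unname(fc["B_GLCM_Correlation"]), 0)

  set.seed(32)
  for (i in 1:100) {
    L <- sample(2:6, 1)
    raw <- matrix(stats::rexp(L * L), L, L)
    p <- raw + t(raw)
    p <- p / sum(p)
    expect_equal(glcmFeatures(list(p = p, levels = L)),
                 oracleGlcmFeatures(p), tolerance = 1e-9)
  }
})

test_that("difference statistics match enumeration and closed forms", {
  expect_equal(glds(matrix(5L, 4, 4), c(0L, 1L), levels = 8),
               c(1, rep(0, 7)))
  expect_equal(glds(rbind(c(0L, 1L), c(0L, 1L)), c(0L, 1L), levels = 2),
               c(0, 1))
  set.seed(33)
  for (i in 1:30) {
    q <- matrix(sample(0:7, 100, TRUE), 10, 10)
    delta <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(0L, 2L))[[sample(4, 1)]]
    g <- glds(q, delta, levels = 8)
    expect_equal(g, oracleGlds(q, delta, 8), tolerance = 1e-12)
    expect_equal(sum(g), 1, tolerance = 1e-9)
  }
  expect_error(glds(matrix(0L, 3, 3), c(0L, 0L)), "non-zero")
  expect_error(glds(matrix(0L, 3, 3), c(0L, 5L)), "extent")
})

test_that("difference-histogram features follow their formulas", {
  f0 <- gldsFeatures(c(1, 0, 0, 0))
  expect_equal(unname(f0), c(1, 0, 1, 0, 0))   # hom, con, asm, ent, mean
  f1 <- gldsFeatures(c(0, 1, 0, 0))
  expect_equal(unname(f1["B_GLDS_Mean"]), 1)
  expect_equal(unname(f1["B_GLDS_Contrast"]), 1)
  expect_equal(unname(f1["B_GLDS_ASM"]), 1)
  expect_equal(unname(f1["B_GLDS_Entropy"]), 0)
  expect_equal(unname(f1["B_GLDS_Homogeneity"]), 0.5)
  fu <- gldsFeatures(rep(0.25, 4))
  expect_equal(unname(fu["B_GLDS_Entropy"]), log(4))
})

test_that("entropy is maximal for the uniform difference histogram", {
  set.seed(34)
  for (i in 1:20) {
    g <- stats::rexp(6)
    g <- g / sum(g)
    expect_lte(gldsFeatures(g)["B_GLDS_Entropy"], log(6) + 1e-12)
  }
})

test_that("contrast features are invariant to gray-level inversion", {
  set.seed(35)
  offsets <- rbind(c(0L, 1L), c(-1L, 0L))
  for (i in 1:20) {
    q <- matrix(sample(0:7, 144, TRUE), 12, 12)
    qi <- 7L - q
    expect_equal(
      glcmFeatures(glcm(q, offsets, 8))["B_GLCM_Contrast"],
      glcmFeatures(glcm(qi, offsets, 8))["B_GLCM_Contrast"],
      tolerance = 1e-12)
    expect_equal(
      gldsFeatures(glds(q, c(0L, 1L), 8))["B_GLDS_Contrast"],
      gldsFeatures(glds(qi, c(0L, 1L), 8))["B_GLDS_Contrast"],
      tolerance = 1e-12)
  }
})

test_that("Haar detail statistics vanish on flat input and ignore offsets", {
  expect_equal(haarFeatures(matrix(60, 16, 16)),
               c(B_haar_mean = 0, B_haar_variance = 0))
  set.seed(36)
  x <- matrix(sample(0:200, 15 * 17, TRUE), 15, 17)   # odd edges cropped
  expect_equal(haarFeatures(x), haarFeatures(x + 30))
  expect_error(haarFeatures(matrix(1, 1, 4)), "2 x 2")
})

test_that("Haar mean scales linearly with a straddling step edge", {
  step <- function(h) {
    x <- matrix(0, 16, 16)
    x[, 10:16] <- h           # edge between columns 9 and 10 straddles a block
    haarFeatures(x)["B_haar_mean"]
  }
  expect_equal(unname(step(40) / step(10)), 4, tolerance = 1e-12)
  expect_gt(step(10), 0)
})

test_that("full B vector is finite, named and deterministic on speckle", {
  nm <- c("B_GLCM_Contrast", "B_GLCM_SumAverage", "B_GLCM_SoSVariance",
          "B_GLCM_DVariance", "B_GLCM_Correlation", "B_GLCM_IDMoment",
          "B_GLDS_Homogeneity", "B_GLDS_Contrast", "B_GLDS_ASM",
          "B_GLDS_Entropy", "B_GLDS_Mean", "B_haar_mean", "B_haar_variance")
  p <- speckleParams(width = 48, height = 48)
  for (s in 1:50) {
    b <- extractBFeatures(simulateSpeckleBackground(p, seed = s))
    expect_identical(names(b), nm)
    expect_true(all(is.finite(b)))
  }
  frm <- simulateSpeckleBackground(p, seed = 1)
  expect_identical(extractBFeatures(frm), extractBFeatures(frm))
  # constant ROI degenerates per convention
  bc <- extractBFeatures(ultrasoundFrame(matrix(100L, 16, 16)))
  expect_equal(unname(bc["B_GLCM_Contrast"]), 0)
  expect_equal(unname(bc["B_GLCM_IDMoment"]), 1)
  expect_equal(unname(bc["B_GLDS_Homogeneity"]), 1)
  expect_equal(unname(bc["B_haar_mean"]), 0)
})
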