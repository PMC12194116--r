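test_that("constant frames contain no affected areas", {
  frm <- ultrasoundFrame(matrix(80L, 64, 64))
  rs <- segmentAffectedAreas(frm)
  expect_identical(regionCount(rs), 0L)
  expect_equal(extractAFeatures(frm),
               c(A_Number = 0, A_Area = 0, A_Perimeter = 0, A_Convexity = 1,
                 A_Homogeneity = 1, A_Contrast = 0, A_ASM = 1))
})

test_that("three well-separated planted discs are detected exactly", {
  centers <- rbind(c(30, 30), c(30, 95), c(95, 60))
  fx <- plantedDiscFrame(centers, radius = 10, boostSD = 5, seed = 1)
  rs <- segmentAffectedAreas(fx$frame)
  expect_identical(regionCount(rs), 3L)
  feats <- extractAFeatures(fx$frame)
  expect_equal(unname(feats["A_Number"]), 3)
  planted <- sum(fx$mask) * 0.01^2
  expect_lt(abs(feats["A_Area"] - planted), 0.15 * planted)
})

test_that("segmentation count matches ground truth on 50 seeded fixtures", {
  centers <- rbind(c(32, 32), c(32, 96), c(96, 32), c(96, 96))
  hits <- vapply(1:50, function(s) {
    fx <- plantedDiscFrame(centers, radius = 8, boostSD = 5, seed = s)
    regionCount(segmentAffectedAreas(fx$frame))
  }, integer(1))
  expect_true(all(hits == 4L))
})

test_that("connectivity controls diagonal merging", {
  # hand-built 12x12 mask: two 4x4 squares touching at one diagonal pixel
  mask <- matrix(FALSE, 12, 12)
  mask[2:5, 2:5] <- TRUE
  mask[6:9, 6:9] <- TRUE
  lab8 <- EchoDose:::labelComponents(mask, 8L)
  lab4 <- EchoDose:::labelComponents(mask, 4L)
  expect_identical(max(lab8), 1L)
  expect_identical(max(lab4), 2L)
})

test_that("component labeling agrees with a flood-fill oracle", {
  set.seed(21)
  for (i in 1:25) {
    mask <- matrix(stats::runif(20 * 20) < 0.4, 20, 20)
    for (conn in c(4L, 8L)) {
      a <- EchoDose:::labelComponents(mask, conn)
      b <- oracleLabel(mask, conn)
      expect_identical(max(a), max(b))
      # identical partition, not just identical counts
      expect_identical(length(unique(paste(a, b))) - any(!mask),
                       as.integer(max(a)))
    }
  }
})

test_that("geometric features are correct on elementary shapes", {
  expect_equal(
    geometricFeatures(new("RegionSet", labels = matrix(0L, 8, 8),
                          roi = c(1L, 8L, 1L, 8L), connectivity = 8L)),
    c(A_Number = 0, A_Area = 0, A_Perimeter = 0, A_Convexity = 1))

  # filled 10x10 square at 0.01 cm/px
  lab <- matrix(0L, 16, 16)
  lab[4:13, 4:13] <- 1L
  rs <- new("RegionSet", labels = lab, roi = c(1L, 16L, 1L, 16L),
            connectivity = 8L)
  g <- geometricFeatures(rs, spacing = 0.01)
  expect_equal(unname(g["A_Number"]), 1)
  expect_equal(unname(g["A_Area"]), 0.01)
  expect_lte(abs(g["A_Perimeter"] - 0.40), 0.10 * 0.40 + 1e-9)
  expect_gt(g["A_Convexity"], 0.95)

  # digital discs are convex within discretization tolerance
  for (r in c(5, 8, 12)) {
    d <- EchoDose:::discUnionMask(c(2 * r + 8, 2 * r + 8),
                                  cbind(r + 4, r + 4), r)
    rs <- new("RegionSet", labels = matrix(as.integer(d), nrow(d)),
              roi = c(1L, nrow(d), 1L, nrow(d)), connectivity = 8L)
    expect_gt(geometricFeatures(rs)["A_Convexity"], 0.95)
  }

  # plus-shaped cross of five 5x5 blocks is markedly non-convex
  pl <- matrix(FALSE, 19, 19)
  pl[8:12, 3:17] <- TRUE
  pl[3:17, 8:12] <- TRUE
  rs <- new("RegionSet", labels = matrix(as.integer(pl), 19),
            roi = c(1L, 19L, 1L, 19L), connectivity = 8L)
  expect_lt(geometricFeatures(rs)["A_Convexity"], 0.95)
})

test_that("region texture follows the degenerate and checkerboard conventions", {
  frm <- ultrasoundFrame(matrix(70L, 32, 32))
  rs <- segmentAffectedAreas(frm)
  expect_equal(regionTextureFeatures(frm, rs),
               c(A_Homogeneity = 1, A_Contrast = 0, A_ASM = 1))

  # 2x2 checkerboard window at 2-level quantization, horizontal offset
  q <- rbind(c(0L, 1L), c(1L, 0L))
  m <- glcm(q, offsets = c(0L, 1L), levels = 2)
  p <- m$p
  i <- row(p) - 1; j <- col(p) - 1
  expect_equal(sum((i - j)^2 * p), 1)              # contrast
  expect_equal(sum(p^2), 0.5)                      # ASM
  expect_equal(sum(p / (1 + (i - j)^2)), 0.5)      # homogeneity (IDM)
})

test_that("A features are invariant to a constant gray offset", {
  centers <- rbind(c(40, 40), c(88, 80))
  fx <- plantedDiscFrame(centers, radius = 9, boostSD = 5, seed = 2,
                         cap = 230)
  shifted <- ultrasoundFrame(pixelData(fx$frame) + 20L)
  expect_equal(extractAFeatures(fx$frame), extractAFeatures(shifted))
})

test_that("feature extraction is deterministic", {
  fx <- plantedDiscFrame(rbind(c(50, 50)), radius = 10, seed = 3)
  expect_identical(extractAFeatures(fx$frame), extractAFeatures(fx$frame))
})

test_that("out-of-bounds ROIs are rejected", {
  frm <- ultrasoundFrame(matrix(60L, 32, 32))
  expect_error(segmentAffectedAreas(frm, segmentationConfig(roi = c(1, 64, 1, 32))),
               "outside")
})

test_that("4-connectivity labeling agrees with EBImage::bwlabel", {
  skip_if_not_installed("EBImage")
  set.seed(22)
  for (i in 1:10) {
    mask <- matrix(stats::runif(18 * 18) < 0.35, 18, 18)
    a <- EchoDose:::labelComponents(mask, 4L)
    b <- EBImage::bwlabel(mask)
    expect_identical(max(a), as.integer(max(b)))
  }
})
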