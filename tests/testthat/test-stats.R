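test_that("Spearman rho handles monotone, antitone and tied data", {
  expect_equal(spearmanRho(c(1, 2, 3), c(1, 4, 9))$rho, 1)
  expect_equal(spearmanRho(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  expect_error(spearmanRho(c(1, 1, 1), c(1, 2, 3)), "constant")
  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- sample(1:8, n, TRUE)          # heavy ties
    y <- x + sample(0:4, n, TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    res <- spearmanRho(x, y)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    expect_equal(res$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("exact permutation p agrees with enumeration on tiny n", {
  res <- spearmanRho(1:3, c(2, 5, 9), exact = TRUE)
  expect_equal(res$p, 2 / 6)     # two of six permutations reach |rho| = 1
  expect_error(spearmanRho(1:9, 9:1, exact = TRUE), "n <= 8")
})

test_that("simple regression reproduces hand-computed fits", {
  ex <- simpleRegression(c(0, 1, 2), c(1, 3, 5))
  expect_equal(ex$B, 2)
  expect_equal(ex$r.squared, 1)
  expect_equal(ex$sigma, 0)

  hand <- simpleRegression(c(0, 1, 2), c(0, 1, 1))
  expect_equal(hand$B, 0.5)
  expect_equal(hand$intercept, 1 / 6, tolerance = 1e-12)
  expect_equal(hand$r.squared, 0.75)

  expect_error(simpleRegression(c(2, 2, 2), c(1, 2, 3)), "constant")

  set.seed(42)
  for (i in 1:20) {
    x <- stats::rnorm(15); y <- stats::rnorm(15)
    fit <- simpleRegression(x, y)
    expect_equal(fit$r.squared, stats::cor(x, y)^2, tolerance = 1e-12)
    expect_true(fit$ci[1] <= fit$B && fit$B <= fit$ci[2])
    expect_equal(fit$sigma,
                 sqrt(sum(stats::residuals(stats::lm(y ~ x))^2) / 13),
                 tolerance = 1e-12)
  }
})

test_that("backward elimination removes noise and keeps signal", {
  # all predictors significant: full model retained
  tab <- generateFeatureTable(500, featureGenModel(sigma = 0.3), seed = 5)
  fit <- multipleRegressionBackward(tab[1:3], tab$dose_mA)
  expect_setequal(fit$retained, c("A_Area", "A_Number", "A_Perimeter"))
  expect_length(fit$dropped, 0)

  # pRemove = 1 can never trigger a removal
  fitFull <- multipleRegressionBackward(tab[1:3], tab$dose_mA, pRemove = 1)
  expect_length(fitFull$dropped, 0)

  # single predictor reduces to the simple regression
  f1 <- multipleRegressionBackward(tab["A_Perimeter"], tab$dose_mA)
  s1 <- simpleRegression(tab$A_Perimeter, tab$dose_mA)
  expect_equal(f1$coefficients$B[2], s1$B, tolerance = 1e-12)
  expect_equal(f1$r.squared, s1$r.squared, tolerance = 1e-12)

  # under the null the noise column survives with probability p_remove,
  # so the elimination rate sits at 1 - p_remove = 0.90
  gen <- featureGenModel(sigma = 0.3)
  removed <- vapply(1:200, function(s) {
    tb <- generateFeatureTable(2000, gen, seed = 10000 + s)
    tb$noise <- withr::with_seed(20000 + s, stats::rnorm(2000))
    ft <- multipleRegressionBackward(tb[c(1:3, 5)], tb$dose_mA)
    "noise" %in% ft$dropped
  }, logical(1))
  expect_lt(abs(mean(removed) - 0.90), 0.06)

  # rank deficiency is rejected with the offending column named
  tab$dup <- tab$A_Area * 2
  expect_error(multipleRegressionBackward(tab[c("A_Area", "dup")],
                                          tab$dose_mA), "rank deficient")
})

test_that("the composite dose index is the published linear form", {
  expect_identical(muscleElectrolysisDose(0, 0, 0), 0.542)
  expect_equal(muscleElectrolysisDose(0.01, 2, 0.5), 2.1592,
               tolerance = 1e-12)
  # strictly increasing in perimeter (positive coefficient)
  d <- muscleElectrolysisDose(0.02, 1, seq(0, 1, 0.1))
  expect_true(all(diff(d) > 0))
  expect_error(muscleElectrolysisDose(Inf, 0, 0), "finite")
})

test_that("dose groups follow the low/medium/high partition", {
  g <- segmentDoseGroups(c(0, 0.5, 1.0, 1.01, 2.0, 4.0, 4.01, 6.0, 10))
  expect_equal(as.character(g),
               c("low", "low", "low", "medium", "medium", "medium",
                 "high", "high", "high"))
  expect_error(segmentDoseGroups(c(-0.1, 2)), "non-negative")
  g2 <- segmentDoseGroups(c(0.5, 5, 7), boundaries = c(1, 6))
  expect_equal(as.character(g2), c("low", "medium", "high"))
})

test_that("Kruskal-Wallis matches hand ranks and a permutation oracle", {
  kw <- kruskalWallis(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$H, 7.2)
  expect_identical(kw$df, 2L)

  expect_equal(kruskalWallis(rep(5, 9), rep(c("a", "b", "c"), each = 3))$H, 0)
  expect_error(kruskalWallis(1:4, factor(c("a", "a", "b", "b"),
                                         levels = c("a", "b", "c"))),
               "at least one")

  # invariance under strictly monotone transforms
  set.seed(43)
  v <- stats::rnorm(15)
  g <- rep(c("a", "b", "c"), each = 5)
  expect_equal(kruskalWallis(v, g)$H, kruskalWallis(exp(v), g)$H,
               tolerance = 1e-12)

  # permutation oracle on n = 12 (no ties)
  v <- c(3.1, 0.2, 5.5, 2.2, 6.1, 4.0, 7.7, 1.5, 9.2, 8.8, 2.9, 6.6)
  g <- rep(c("a", "b", "c"), each = 4)
  obs <- kruskalWallis(v, g)
  hOf <- function(gg) kruskalWallis(v, gg)$H
  set.seed(44)
  perm <- vapply(1:20000, function(i) hOf(sample(g)), numeric(1))
  pPerm <- mean(perm >= obs$H - 1e-12)
  expect_lt(abs(obs$p - pPerm), 0.05)
})

test_that("pairwise Mann-Whitney applies the Bonferroni cap", {
  v <- c(1, 2, 3, 4, 11, 12, 13, 14, 21, 22, 23, 24)
  g <- rep(c("low", "medium", "high"), each = 4)
  tab <- pairwiseMannWhitneyBonferroni(v, factor(g, levels = c("low", "medium", "high")))
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$U[tab$comparison == "low vs medium"], 0)
  expect_true(all(tab$p_adj >= tab$p - 1e-15))
  expect_true(all(tab$p_adj <= 1))
  expect_equal(tab$p_adj, pmin(1, 3 * tab$p), tolerance = 1e-12)

  same <- pairwiseMannWhitneyBonferroni(rep(7, 9),
                                        rep(c("low", "medium", "high"), 3))
  expect_true(all(same$p_adj == 1))

  # U agrees with the definition: x = [1,2], y = [3,4] gives U(x) = 0
  two <- pairwiseMannWhitneyBonferroni(c(1, 2, 3, 4, 9, 9),
                                       factor(rep(c("a", "b", "c"), each = 2)))
  expect_equal(two$U[two$comparison == "a vs b"], 0)
})

test_that("the full analysis assembles every stage coherently", {
  tab <- generateFeatureTable(60, featureGenModel(sigma = 0.5), seed = 6)
  tab$dose_mA <- pmax(0, tab$dose_mA)    # group segmentation needs >= 0
  rep <- runFullAnalysis(tab)
  expect_s4_class(rep, "StatReport")
  expect_setequal(rep@correlations$variable,
                  c("A_Area", "A_Number", "A_Perimeter"))
  expect_equal(rep@features$UZ_eDosis,
               muscleElectrolysisDose(tab$A_Area, tab$A_Number,
                                      tab$A_Perimeter), tolerance = 1e-12)
  expect_true("UZ_eDosis" %in% rep@groupTests$variable)
  expect_true(all(rep@pairwise$p_adj >= rep@pairwise$p - 1e-15))
  expect_error(runFullAnalysis(tab[, 1:3]), "dose")
})

test_that("a lone non-significant predictor is eliminated to the null model", {
  # dose ~ feature with n = 3 and p ~ 0.16: the single predictor must be
  # dropped (not spun on), leaving the intercept-only fit
  x <- c(0.012, 0.015, 0.047)
  y <- c(0, 2, 6)
  fit <- multipleRegressionBackward(data.frame(A_Area = x), y)
  expect_identical(fit$retained, character(0))
  expect_identical(fit$dropped, "A_Area")
  expect_identical(nrow(fit$coefficients), 1L)
})
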