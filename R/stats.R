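# Dose-response statistical stage: Spearman screen, per-feature OLS,
# backward-elimination multiple regression, the composite dose index, and
# nonparametric group comparison with Bonferroni-corrected post hocs.

#' Spearman rank correlation with asymptotic p-value
#'
#' Tie-corrected rank correlation (Pearson correlation of the mid-ranks)
#' with a two-tailed p-value from the t-approximation on `n - 2` degrees of
#' freedom. For `n <= 8` an exact permutation p-value is available.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @param exact use exact permutation enumeration for the p-value
#'   (only for `n <= 8`).
#' @return A list with `rho`, `p` and `n`.
#' @examples
#' spearmanRho(1:5, c(2, 1, 4, 3, 5))
#' @export
spearmanRho <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho is undefined for constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) stop("exact permutation p-value supported only for n <= 8")
    perms <- permuteAll(n)
    rhos <- apply(perms, 1L, function(pm) stats::cor(rx[pm], ry))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

# all permutations of 1..n as a matrix (n <= 8)
permuteAll <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permuteAll(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

#' Simple linear regression of a feature on dose
#'
#' Ordinary least squares `y ~ x` with the summary quantities of a
#' per-feature dose-response table: multiple R, R-squared, standard error
#' of the estimate `sqrt(RSS / (n - 2))`, the ANOVA F with `(1, n - 2)`
#' degrees of freedom and its p-value, the standardized slope (beta), the
#' raw slope B with its 95% confidence interval, and the intercept.
#'
#' @param x predictor (e.g. dose in mA); must be non-constant.
#' @param y response.
#' @return A list with elements `R`, `r.squared`, `sigma`, `F`, `p`,
#'   `beta`, `B`, `ci` (length 2), `intercept`, `n`.
#' @examples
#' simpleRegression(c(0, 1, 2), c(1, 3, 5))$B  # exact fit: slope 2
#' @export
simpleRegression <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("'x' is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  B <- unname(stats::coef(fit)[2L])
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  if (rss < 1e-12 * max(tss, 1)) rss <- 0      # numerically exact fit
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  sigma <- sqrt(rss / (n - 2))
  Fval <- if (rss == 0) Inf else ((tss - rss) / 1) / (rss / (n - 2))
  p <- if (is.infinite(Fval)) 0 else stats::pf(Fval, 1, n - 2,
                                               lower.tail = FALSE)
  ci <- if (rss == 0) c(B, B) else unname(stats::confint(fit)[2L, ])
  beta <- B * stats::sd(x) / stats::sd(y)
  list(R = sqrt(r2), r.squared = r2, sigma = sigma, F = Fval, p = p,
       beta = beta, B = B, ci = ci,
       intercept = unname(stats::coef(fit)[1L]), n = n)
}

#' Backward-elimination multiple regression
#'
#' Starts from the full model and iteratively removes the predictor with
#' the largest partial-F p-value at or above `pRemove` (for a single
#' coefficient the partial F equals the squared t, so the coefficient
#' p-value is used), refitting after each removal, until every remaining
#' predictor has `p < pRemove`. This is the classical stepwise-backward
#' procedure with probability-of-F-to-remove 0.10 as default.
#'
#' @param X numeric matrix or data.frame of predictors (named columns).
#' @param y numeric response (dose in mA).
#' @param pRemove removal threshold on the partial-F p-value (default 0.10).
#' @return A list with `retained` (predictor names), `dropped` (in removal
#'   order), `coefficients` (data.frame: B, SE, beta, t, p, ci_lower,
#'   ci_upper, including the intercept row), `R`, `r.squared`,
#'   `adj.r.squared`, `F`, `p`, `n`, and the final `model` (an `lm`).
#' @examples
#' tab <- generateFeatureTable(200, seed = 1)
#' fit <- multipleRegressionBackward(tab[1:3], tab$dose_mA)
#' fit$retained
#' @export
multipleRegressionBackward <- function(X, y, pRemove = 0.10) {
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(!nzchar(names(X))))
    stop("predictor columns must be named")
  n <- length(y)
  if (n <= ncol(X) + 1L)
    stop("need n > number of predictors + 1")
  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < ncol(X) + 1L) {
    aliased <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)] - 1L])
    stop("predictor matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  vars <- names(X)
  dropped <- character(0)
  dat <- cbind(X, .y = y)
  repeat {
    fml <- stats::reformulate(vars, response = ".y")
    fit <- stats::lm(fml, data = dat)
    ct <- summary(fit)$coefficients
    # coefficient p-values (partial F = t^2); keep names for length-1 case
    pv <- stats::setNames(ct[-1L, 4L], rownames(ct)[-1L])
    if (length(pv) == 0L || max(pv) < pRemove) break
    worst <- names(pv)[which.max(pv)]
    dropped <- c(dropped, worst)
    vars <- setdiff(vars, worst)
    if (length(vars) == 0L) {
      fit <- stats::lm(.y ~ 1, data = dat)
      break
    }
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  ci <- stats::confint(fit)
  sdy <- stats::sd(y)
  beta <- c(NA_real_, vapply(vars, function(v)
    ct[v, 1L] * stats::sd(dat[[v]]) / sdy, numeric(1)))[seq_len(nrow(ct))]
  coefTab <- data.frame(term = rownames(ct), B = ct[, 1L], SE = ct[, 2L],
                        beta = beta, t = ct[, 3L], p = ct[, 4L],
                        ci_lower = ci[, 1L], ci_upper = ci[, 2L],
                        row.names = NULL)
  fstat <- sm$fstatistic
  list(retained = vars, dropped = dropped, coefficients = coefTab,
       R = sqrt(sm$r.squared), r.squared = sm$r.squared,
       adj.r.squared = sm$adj.r.squared,
       F = if (is.null(fstat)) NA_real_ else unname(fstat[1L]),
       p = if (is.null(fstat)) NA_real_ else
         unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                          lower.tail = FALSE)),
       n = n, model = fit)
}

#' The composite electrolysis dose index
#'
#' Evaluates the linear composite index that summarizes the structural
#' ultrasound response into an estimated applied current intensity:
#' `intercept + coefArea * area + coefNumber * number +
#' coefPerimeter * perimeter`. With the default [doseModel()] this is the
#' published Muscle_Electrolysis_Dose (UZ_eDosis) index.
#'
#' @param area affected area in cm^2 (vectorized).
#' @param number number of affected areas.
#' @param perimeter summed perimeter in cm.
#' @param model a [DoseModel-class].
#' @return Estimated dose(s) in mA.
#' @examples
#' muscleElectrolysisDose(0, 0, 0)          # the intercept, 0.542 mA
#' muscleElectrolysisDose(0.01, 2, 0.5)     # 2.1592 mA
#' @export
muscleElectrolysisDose <- function(area, number, perimeter,
                                   model = doseModel()) {
  stopifnot(is(model, "DoseModel"))
  if (!all(is.finite(area), is.finite(number), is.finite(perimeter)))
    stop("all feature inputs must be finite")
  model@intercept + model@coefArea * area + model@coefNumber * number +
    model@coefPerimeter * perimeter
}

#' Assign doses to low / medium / high groups
#'
#' Partition of the dose axis into the three ranges used for threshold
#' analysis: low `[0, b1]`, medium `(b1, b2]`, high `(b2, Inf)`, with
#' default boundaries 1 and 4 mA (minimal response, progressive response,
#' plateau).
#'
#' @param doses numeric vector of doses in mA (all >= 0).
#' @param boundaries numeric(2) increasing group boundaries (default
#'   `c(1, 4)`).
#' @return Factor with levels `low`, `medium`, `high`.
#' @examples
#' segmentDoseGroups(c(0.5, 2, 6))
#' @export
segmentDoseGroups <- function(doses, boundaries = c(1, 4)) {
  if (any(is.na(doses)) || any(doses < 0))
    stop("doses must be non-negative and non-missing")
  if (length(boundaries) != 2L || diff(boundaries) <= 0)
    stop("'boundaries' must be two increasing values")
  cut(doses, breaks = c(-Inf, boundaries, Inf),
      labels = c("low", "medium", "high"), right = TRUE)
}

#' Kruskal-Wallis rank test across dose groups
#'
#' Tie-corrected Kruskal-Wallis H with `k - 1` degrees of freedom and the
#' chi-square asymptotic p-value (via [stats::kruskal.test()]). When every
#' observation is identical the rank variance is zero and `H` is defined as
#' 0 with `p = 1`.
#'
#' @param values numeric vector.
#' @param groups factor (or coercible) of group labels, >= 2 non-empty
#'   groups.
#' @return List with `H`, `df`, `p`.
#' @examples
#' kruskalWallis(1:9, rep(c("a", "b", "c"), each = 3))
#' @export
kruskalWallis <- function(values, groups) {
  if (!is.factor(groups)) groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) == 0L))
    stop("every group must contain at least one observation")
  if (length(values) != length(groups))
    stop("'values' and 'groups' must have equal length")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Pairwise Mann-Whitney tests with Bonferroni correction
#'
#' Post hoc comparison of the three dose groups: for each of the three
#' pairs, the Mann-Whitney U statistic and the two-tailed p-value from the
#' tie-corrected normal approximation (no continuity correction), with the
#' Bonferroni-adjusted p `min(1, 3 p)`. When both groups of a pair are
#' entirely tied the test is degenerate and `p = 1` is reported.
#'
#' @param values numeric vector.
#' @param groups factor with exactly 3 levels, all non-empty.
#' @return data.frame with columns `comparison`, `U`, `p`, `p_adj`.
#' @examples
#' pairwiseMannWhitneyBonferroni(c(1:4, 11:14, 21:24),
#'                               rep(c("low", "medium", "high"), each = 4))
#' @export
pairwiseMannWhitneyBonferroni <- function(values, groups) {
  if (!is.factor(groups)) groups <- factor(groups)
  if (nlevels(groups) != 3L) stop("exactly 3 groups required")
  if (any(table(groups) == 0L))
    stop("every group must contain at least one observation")
  lev <- levels(groups)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  rows <- lapply(pairs, function(pr) {
    a <- values[groups == lev[pr[1]]]
    b <- values[groups == lev[pr[2]]]
    if (length(unique(c(a, b))) == 1L) {
      U <- length(a) * length(b) / 2
      p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                correct = FALSE))
      U <- unname(wt$statistic)
      p <- wt$p.value
    }
    data.frame(comparison = paste(lev[pr[1]], "vs", lev[pr[2]]),
               U = U, p = p, p_adj = min(1, 3 * p))
  })
  do.call(rbind, rows)
}
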