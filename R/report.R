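# Assembles the full dose-response report from a per-frame feature table.

featureColumns <- function() {
  c("A_Number", "A_Area", "A_Perimeter", "A_Convexity", "A_Homogeneity",
    "A_Contrast", "A_ASM",
    "B_GLCM_Contrast", "B_GLCM_SumAverage", "B_GLCM_SoSVariance",
    "B_GLCM_DVariance", "B_GLCM_Correlation", "B_GLCM_IDMoment",
    "B_GLDS_Homogeneity", "B_GLDS_Contrast", "B_GLDS_ASM", "B_GLDS_Entropy",
    "B_GLDS_Mean", "B_haar_mean", "B_haar_variance")
}

#' Run the full dose-response analysis
#'
#' Reproduces the multi-phase statistical stage on a per-frame feature
#' table: (1) Spearman screen of every feature against dose; (2) simple OLS
#' of each screened feature on dose; (3) backward-elimination multiple
#' regression of dose on the screened features (predictors entering the
#' elimination are those with Spearman `p < 0.05`, mirroring selection by
#' significance in the prior analyses) and the composite index column
#' `UZ_eDosis` computed with the fixed published coefficients; (4) dose
#' grouping and Kruskal-Wallis tests with Bonferroni-corrected Mann-Whitney
#' post hocs for each screened feature and the composite.
#'
#' @param featureTable data.frame with a dose column (`dose_mA` or `dose`)
#'   and feature columns; any subset of the standard 20 features is
#'   accepted, and extra columns are ignored.
#' @param model the fixed [DoseModel-class] used for the composite column
#'   (default: the published coefficients).
#' @param boundaries dose-group boundaries in mA (default `c(1, 4)`).
#' @param pRemove backward-elimination removal threshold (default 0.10).
#' @param screenAlpha Spearman significance level used to admit features to
#'   the regression and group-comparison stages (default 0.05).
#' @return A [StatReport-class].
#' @examples
#' tab <- generateFeatureTable(40, seed = 1)
#' rep <- runFullAnalysis(tab)
#' rep@multiModel$retained
#' @export
runFullAnalysis <- function(featureTable, model = doseModel(),
                            boundaries = c(1, 4), pRemove = 0.10,
                            screenAlpha = 0.05) {
  featureTable <- as.data.frame(featureTable)
  doseCol <- intersect(c("dose_mA", "dose"), names(featureTable))[1]
  if (is.na(doseCol)) stop("missing dose column: 'dose_mA' (or 'dose')")
  feats <- intersect(featureColumns(), names(featureTable))
  if (!length(feats))
    stop("no recognized feature columns; expected some of: ",
         paste(featureColumns()[1:3], collapse = ", "), ", ...")
  dose <- featureTable[[doseCol]]

  # (1) Spearman screen; constant features are reported with NA
  corr <- do.call(rbind, lapply(feats, function(v) {
    res <- tryCatch(spearmanRho(dose, featureTable[[v]]),
                    error = function(e) list(rho = NA_real_, p = NA_real_))
    data.frame(variable = v, rho = res$rho, p = res$p)
  }))

  screened <- corr$variable[!is.na(corr$p) & corr$p < screenAlpha]

  # (2) per-feature simple OLS (feature regressed on dose)
  simple <- do.call(rbind, lapply(screened, function(v) {
    fit <- simpleRegression(dose, featureTable[[v]])
    data.frame(variable = v, R = fit$R, r.squared = fit$r.squared,
               std.error = fit$sigma, F = fit$F, p = fit$p,
               beta = fit$beta, B = fit$B,
               ci_lower = fit$ci[1], ci_upper = fit$ci[2])
  }))
  if (is.null(simple))
    simple <- data.frame(variable = character(0), R = numeric(0),
                         r.squared = numeric(0), std.error = numeric(0),
                         F = numeric(0), p = numeric(0), beta = numeric(0),
                         B = numeric(0), ci_lower = numeric(0),
                         ci_upper = numeric(0))

  # (3) backward elimination on the screened predictors
  preds <- as.character(screened)
  if (length(preds) >= nrow(featureTable) - 1L)
    preds <- preds[seq_len(max(1L, nrow(featureTable) - 2L))]
  if (length(preds) > 1L) {
    qrX <- qr(cbind(1, as.matrix(featureTable[preds])))
    if (qrX$rank < length(preds) + 1L) {
      keep <- sort(setdiff(qrX$pivot[seq_len(qrX$rank)], 1L)) - 1L
      dropAliased <- setdiff(preds, preds[keep])
      message("dropping aliased predictor(s) before elimination: ",
              paste(dropAliased, collapse = ", "))
      preds <- preds[keep]
    }
  }
  multi <- if (length(preds)) {
    multipleRegressionBackward(featureTable[preds], dose, pRemove = pRemove)
  } else {
    list(retained = character(0), dropped = character(0),
         coefficients = data.frame(), R = NA_real_, r.squared = NA_real_,
         adj.r.squared = NA_real_, F = NA_real_, p = NA_real_,
         n = nrow(featureTable), model = NULL)
  }
  multi$model <- NULL                 # keep the report serializable

  out <- featureTable
  out$UZ_eDosis <- if (all(c("A_Area", "A_Number", "A_Perimeter") %in%
                           names(out))) {
    muscleElectrolysisDose(out$A_Area, out$A_Number, out$A_Perimeter, model)
  } else NA_real_
  out$dose_group <- segmentDoseGroups(dose, boundaries)

  # (4) group comparison per screened variable + the composite index
  gvars <- c(as.character(screened),
             if (!all(is.na(out$UZ_eDosis))) "UZ_eDosis")
  grp <- droplevels(out$dose_group)
  kwRows <- list(); mwRows <- list()
  for (v in gvars) {
    kw <- kruskalWallis(out[[v]], grp)
    kwRows[[v]] <- data.frame(variable = v, n = nrow(out), H = kw$H,
                              df = kw$df, p = kw$p)
    if (nlevels(grp) == 3L) {
      pw <- pairwiseMannWhitneyBonferroni(out[[v]], grp)
      pw$variable <- v
      mwRows[[v]] <- pw[c("variable", "comparison", "U", "p", "p_adj")]
    }
  }
  groupTests <- if (length(kwRows)) do.call(rbind, c(kwRows,
                                                     make.row.names = FALSE))
    else data.frame(variable = character(0), n = integer(0), H = numeric(0),
                    df = integer(0), p = numeric(0))
  pairwise <- if (length(mwRows)) do.call(rbind, c(mwRows,
                                                   make.row.names = FALSE))
    else data.frame(variable = character(0), comparison = character(0),
                    U = numeric(0), p = numeric(0), p_adj = numeric(0))

  new("StatReport", correlations = corr, simpleFits = simple,
      multiModel = multi, features = out, groupTests = groupTests,
      pairwise = pairwise)
}
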