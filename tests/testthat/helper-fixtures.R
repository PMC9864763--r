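# Shared fixtures, built lazily once per test run and memoized, so the
# slower objects (parsed molecules, a small trained model) are reused
# across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

# small curated synthetic dataset (deterministic)
fx_raw <- function() fixture("raw", function() {
  generate_synthetic_sar(synthetic_sar_config(n_compounds = 250, seed = 42))
})

fx_curated <- function() fixture("curated", function() {
  curate_activity_data(fx_raw())
})

fx_datasets <- function() fixture("datasets", function() {
  encode_datasets(fx_curated()$records)
})

# a small tuned gradient-boosted regression model on ECFP4 (shared by the
# applicability and persistence tests)
fx_reg_model <- function() fixture("reg_model", function() {
  ds <- fx_datasets()$regression
  split <- stratified_split(ds$label, 0.3, seed = 5)
  tr <- split == "TRAIN"
  fb <- feature_block(ds$canonical_smiles[tr], "ECFP4")
  spec <- model_spec("GRADIENT_BOOSTED_TREES", "REGRESSION", "ECFP4",
                     budget = 2L, seed = 5L)
  list(model = tune_and_train(spec, fb$X, ds$label[tr],
                              feature_state = fb$state),
       X_train = fb$X, y_train = ds$label[tr],
       smiles_train = ds$canonical_smiles[tr],
       smiles_test = ds$canonical_smiles[!tr],
       y_test = ds$label[!tr])
})

# a small binary random forest on ECFP4
fx_bin_model <- function() fixture("bin_model", function() {
  ds <- fx_datasets()$binary
  split <- stratified_split(ds$label, 0.3, seed = 6)
  tr <- split == "TRAIN"
  fb <- feature_block(ds$canonical_smiles[tr], "ECFP4")
  spec <- model_spec("RANDOM_FOREST", "BINARY", "ECFP4",
                     budget = 2L, seed = 6L)
  list(model = tune_and_train(spec, fb$X, ds$label[tr],
                              feature_state = fb$state, rebalance = TRUE),
       X_train = fb$X, y_train = ds$label[tr],
       smiles_test = ds$canonical_smiles[!tr],
       y_test = ds$label[!tr])
})

# the four small analyzer bundles used by the workflow tests
local_analyzer_bundles <- function() {
  fixture("analyzer_bundles", function() {
    ds <- fx_datasets()
    fit_small <- function(tbl, task, alg, seed) {
      fb <- feature_block(tbl$canonical_smiles, "ECFP4")
      spec <- model_spec(alg, task, "ECFP4", budget = 1, seed = seed)
      # the tiny fixture classes trigger the (tested elsewhere) SMOTE
      # small-class warning on every fold; keep the test log clean
      suppressWarnings(
        tune_and_train(spec, fb$X, tbl$label, feature_state = fb$state,
                       rebalance = task == "MULTICLASS"))
    }
    reg <- fx_reg_model()
    dom <- fit_leverage_domain(reg$model, reg$X_train, reg$y_train,
                               n_repeats = 3, seed = 31)
    list(
      binary = fx_bin_model()$model,
      regression = reg$model,
      sirt12 = fit_small(ds$sirt12, "MULTICLASS", "RANDOM_FOREST", 32),
      sirt23 = fit_small(ds$sirt23, "MULTICLASS", "RANDOM_FOREST", 33),
      leverage_domain = dom,
      reference_library = data.frame(
        compound_id = paste0("REF", seq_len(40)),
        smiles = ds$binary$canonical_smiles[1:40],
        stringsAsFactors = FALSE)
    )
  })
}

# ---- independent metric oracles (direct formula transcription) ---------

oracle_regression <- function(y, yh, ytr) {
  n <- length(y)
  press <- sum((y - yh)^2)
  r2ext <- 1 - press / sum((y - mean(y))^2)
  qf1 <- 1 - press / sum((y - mean(ytr))^2)
  qf2 <- 1 - press / sum((y - mean(y))^2)
  qf3 <- 1 - (press / n) /
    (sum((ytr - mean(ytr))^2) / length(ytr))
  rmse <- sqrt(press / n)
  # through-origin fits via lm as an independent route
  k <- unname(stats::coef(stats::lm(y ~ 0 + yh)))
  kp <- unname(stats::coef(stats::lm(yh ~ 0 + y)))
  r2 <- stats::cor(y, yh)^2
  r0 <- 1 - sum(stats::resid(stats::lm(y ~ 0 + yh))^2) /
    sum((y - mean(y))^2)
  r0p <- 1 - sum(stats::resid(stats::lm(yh ~ 0 + y))^2) /
    sum((yh - mean(yh))^2)
  rm2 <- r2 * (1 - sqrt(max(r2 - r0, 0)))
  rm2p <- r2 * (1 - sqrt(max(r2 - r0p, 0)))
  ccc <- {
    mo <- mean(y); mp <- mean(yh)
    sxy <- sum((y - mo) * (yh - mp))
    2 * sxy / (sum((y - mo)^2) + sum((yh - mp)^2) + n * (mo - mp)^2)
  }
  list(Rext2 = r2ext, RMSEext = rmse, QF1_2 = qf1, QF2_2 = qf2,
       QF3_2 = qf3, rm2 = rm2, rm2_prime = rm2p,
       rm2_bar = (rm2 + rm2p) / 2, delta_rm2 = abs(rm2 - rm2p),
       CCC = ccc, k = k, k_prime = kp, r2 = r2, r0_2 = r0,
       r0_prime_2 = r0p)
}

oracle_classification <- function(truth, proba) {
  classes <- colnames(proba)
  pred <- classes[apply(proba, 1, which.max)]
  # macro averages run over the classes present in the truth labels
  present <- classes[classes %in% truth]
  recalls <- sapply(present, function(cl)
    sum(truth == cl & pred == cl) / sum(truth == cl))
  precisions <- sapply(present, function(cl) {
    d <- sum(pred == cl)
    if (d == 0) NaN else sum(truth == cl & pred == cl) / d
  })
  f1 <- 2 * precisions * recalls / (precisions + recalls)
  cm <- table(factor(truth, classes), factor(pred, classes))
  n <- sum(cm); tr <- sum(diag(cm))
  rs <- rowSums(cm); cs <- colSums(cm)
  mcc_den <- sqrt(n^2 - sum(cs^2)) * sqrt(n^2 - sum(rs^2))
  mcc <- if (mcc_den == 0) 0 else (tr * n - sum(rs * cs)) / mcc_den
  # one-vs-rest AUC by the rank-sum (Wilcoxon) identity
  aucs <- sapply(present, function(cl) {
    pos <- proba[truth == cl, cl]; neg <- proba[truth != cl, cl]
    if (!length(pos) || !length(neg)) return(NaN)
    (sum(rank(c(pos, neg))[seq_along(pos)]) -
       length(pos) * (length(pos) + 1) / 2) /
      (length(pos) * length(neg))
  })
  list(BA = mean(recalls), MCC = mcc,
       precision = mean(precisions[is.finite(precisions)]),
       recall = mean(recalls), F1 = mean(f1[is.finite(f1)]),
       ROC_AUC = mean(aucs[is.finite(aucs)]))
}

# EF oracle: fraction of actives strictly above the k-th ranked inactive
oracle_ef <- function(scores, active, f) {
  dec <- sort(scores[!active], decreasing = TRUE)
  if (length(dec) < 1 / f) return(NA_real_)
  k <- floor(f * length(dec))
  thr <- if (k == 0) dec[1] else dec[k]
  mean(scores[active] > thr)
}

rand_smiles <- function(n, seed) {
  set.seed(seed)
  pool <- unique(c(
    generate_decoy_pool(2 * n, seed = seed),
    generate_synthetic_sar(
      synthetic_sar_config(n_compounds = max(10, n), seed = seed))$smiles
  ))
  sample(pool, n)
}
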