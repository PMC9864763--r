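# External-validation statistics against independent oracles and their
# analytic limits.

test_that("regression report matches hand-derived example values", {
  y <- c(4, 5, 6); yh <- c(4.1, 5.0, 5.9)
  r <- regression_report(y, yh, train_labels = c(4, 5, 6))
  expect_equal(r$Rext2, 0.99)
  expect_equal(r$RMSEext, sqrt(0.02 / 3), tolerance = 1e-12)
  expect_equal(r$QF2_2, r$Rext2)
})

test_that("perfect predictions reach the upper limit of every metric", {
  set.seed(1)
  y <- rnorm(20, 6)
  r <- regression_report(y, y, train_labels = rnorm(40, 6))
  expect_equal(r$Rext2, 1); expect_equal(r$QF1_2, 1)
  expect_equal(r$QF2_2, 1); expect_equal(r$QF3_2, 1)
  expect_equal(r$CCC, 1); expect_equal(r$RMSEext, 0)
  expect_equal(r$delta_rm2, 0); expect_equal(r$rm2_bar, 1)
  expect_equal(r$k, 1); expect_equal(r$k_prime, 1)
  expect_true(r$criteria$golbraikh_tropsha$all_pass)
})

test_that("predicting the mean gives Rext2 of exactly zero", {
  set.seed(2)
  y <- rnorm(15)
  r <- regression_report(y, rep(mean(y), 15) + rnorm(15, sd = 1e-14),
                         train_labels = y)
  expect_equal(r$Rext2, 0, tolerance = 1e-6)
})

test_that("QF1 and QF2 collapse onto Rext2 when the means coincide", {
  set.seed(3)
  y <- rnorm(30, 5)
  yh <- y + rnorm(30, sd = 0.3)
  tr <- c(y, 2 * mean(y) - y)   # training mean equals the test mean
  r <- regression_report(y, yh, train_labels = tr)
  expect_equal(mean(tr), mean(y))
  expect_equal(r$QF1_2, r$Rext2, tolerance = 1e-12)
  expect_equal(r$QF2_2, r$Rext2, tolerance = 1e-12)
})

test_that("zero observed variance is reported, not silently dropped", {
  r <- regression_report(rep(5, 5), rnorm(5, 5), train_labels = rnorm(10))
  expect_true(is.nan(r$Rext2))
  expect_match(r$undefined_reason, "zero variance")
})

test_that("Golbraikh-Tropsha flags behave at their design points", {
  set.seed(4)
  y <- rnorm(25, 6, 0.8)
  gt_perfect <- golbraikh_tropsha(y, y)
  expect_equal(gt_perfect$k, 1); expect_equal(gt_perfect$k_prime, 1)
  expect_true(gt_perfect$criteria$all_pass)
  gt_double <- golbraikh_tropsha(y, 2 * y)
  expect_false(gt_double$criteria$slope_ok ||
                 gt_double$criteria$all_pass)
  expect_error(golbraikh_tropsha(y, rep(0, 25)), "zero")
})

test_that("all regression metrics track the brute-force oracle", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(3:60, 1)
    y <- rnorm(n, 6); yh <- y * runif(1, 0.5, 1.5) + rnorm(n, sd = 0.5)
    if (var(y) == 0 || var(yh) == 0) next
    tr <- rnorm(n + 5, 6)
    r <- regression_report(y, yh, tr)
    o <- oracle_regression(y, yh, tr)
    for (f in names(o)) {
      expect_equal(r[[f]], o[[f]], tolerance = 1e-10, label = f)
    }
  }
})

test_that("classification report reproduces the textbook confusion case", {
  # 8 TP, 2 FN, 7 TN, 3 FP
  truth <- rep(c("POS", "NEG"), c(10, 10))
  pred_pos <- c(rep(0.9, 8), rep(0.1, 2), rep(0.8, 3), rep(0.2, 7))
  proba <- cbind(NEG = 1 - pred_pos, POS = pred_pos)
  r <- classification_report(truth, proba, positive = "POS")
  expect_equal(r$sensitivity, 0.8)
  expect_equal(r$specificity, 0.7)
  expect_equal(r$BA, 0.75)
  expect_equal(r$MCC, 50 / sqrt(9900), tolerance = 1e-12)
})

test_that("perfect separation maximizes every classification metric", {
  truth <- rep(c("A", "B", "C"), each = 7)
  proba <- matrix(0.01, 21, 3, dimnames = list(NULL, c("A", "B", "C")))
  proba[cbind(1:21, rep(1:3, each = 7))] <- 0.98
  proba <- proba / rowSums(proba)
  r <- classification_report(truth, proba)
  expect_equal(r$BA, 1); expect_equal(r$MCC, 1)
  expect_equal(r$ROC_AUC, 1); expect_equal(r$F1, 1)
})

test_that("classification metrics track the oracle on random problems", {
  set.seed(6)
  for (i in 1:60) {
    k <- sample(2:4, 1)
    n <- sample(20:120, 1)
    classes <- LETTERS[1:k]
    truth <- sample(classes, n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    raw <- matrix(rexp(n * k), n, k, dimnames = list(NULL, classes))
    # give the true class a random boost so problems vary in difficulty
    raw[cbind(1:n, match(truth, classes))] <-
      raw[cbind(1:n, match(truth, classes))] + rexp(n)
    proba <- raw / rowSums(raw)
    r <- classification_report(truth, proba)
    o <- oracle_classification(truth, proba)
    for (f in c("BA", "MCC", "precision", "recall", "F1")) {
      expect_equal(r[[f]], o[[f]], tolerance = 1e-10, label = f)
    }
    expect_equal(r$ROC_AUC, o$ROC_AUC, tolerance = 1e-10)
  }
})

test_that("enrichment hits its limits for perfect and inverted rankings", {
  scores_perfect <- c(rep(1, 5), runif(400, 0, 0.5))
  labels <- c(rep(TRUE, 5), rep(FALSE, 400))
  expect_equal(unname(roc_enrichment(scores_perfect, labels)),
               rep(1, 4))
  scores_worst <- c(rep(-1, 5), runif(400, 0, 0.5))
  expect_equal(unname(roc_enrichment(scores_worst, labels)), rep(0, 4))
})

test_that("enrichment is monotone in the fraction and matches its oracle", {
  set.seed(7)
  for (i in 1:50) {
    n_act <- sample(5:40, 1); n_dec <- sample(300:1200, 1)
    scores <- c(rnorm(n_act, 1), rnorm(n_dec))
    labels <- rep(c(TRUE, FALSE), c(n_act, n_dec))
    ef <- roc_enrichment(scores, labels)
    ef_def <- ef[!is.na(ef)]
    expect_true(all(diff(ef_def) >= -1e-12))
    for (f in c(0.005, 0.01, 0.02, 0.05)) {
      expect_equal(unname(ef[paste0("EF_", f * 100, "pct")]),
                   oracle_ef(scores, labels, f), tolerance = 1e-12)
    }
  }
  # too few inactives for the smallest fraction
  ef <- roc_enrichment(c(1, rnorm(150)), c(TRUE, rep(FALSE, 150)))
  expect_true(is.na(ef["EF_0.5pct"]))
  expect_false(is.na(ef["EF_1pct"]))
})

test_that("random rankings recover actives at roughly the fraction", {
  set.seed(8)
  efs <- replicate(300, {
    scores <- runif(550)
    roc_enrichment(scores, rep(c(TRUE, FALSE), c(50, 500)),
                   fractions = 0.05)[[1]]
  })
  expect_lt(abs(mean(efs) - 0.05), 0.01)
})

test_that("CCC is symmetric and bounded", {
  set.seed(9)
  a <- rnorm(30); b <- a + rnorm(30)
  expect_equal(lin_ccc(a, b), lin_ccc(b, a))
  expect_lte(abs(lin_ccc(a, b)), 1)
  expect_equal(lin_ccc(a, a), 1)
})

test_that("decoy selection enforces dissimilarity and property matching", {
  actives <- fx_datasets()$binary$canonical_smiles[
    fx_datasets()$binary$label == "ACTIVE"][1:4]
  pool <- generate_decoy_pool(1200, seed = 14)
  dec <- generate_decoys(actives, pool, per_active = 5, seed = 15)
  expect_length(dec, 20)
  afp <- fingerprint_matrix(actives, "ECFP4")
  dfp <- fingerprint_matrix(dec, "ECFP4")
  sims <- sirtscreen:::tanimoto_cross(dfp, afp)
  expect_lt(max(sims), 0.3)
  # an active included in the pool can never be selected
  dec2 <- generate_decoys(actives, c(actives, pool), per_active = 5,
                          seed = 15)
  expect_false(any(actives %in% dec2))
  # chosen decoys sit closer to the actives in property space than the
  # rejected candidates do
  props <- c("MW", "logP", "HBD", "HBA", "rotB", "charge")
  pp <- as.matrix(physchem_profile(pool)[, props])
  pa <- colMeans(physchem_profile(actives)[, props])
  sdv <- apply(pp, 2, sd); sdv[sdv == 0 | !is.finite(sdv)] <- 1
  z <- scale(pp, colMeans(pp), sdv)
  za <- (pa - colMeans(pp)) / sdv
  d_all <- sqrt(colSums((t(z) - za)^2))
  picked <- pool %in% dec
  expect_lt(median(d_all[picked]), median(d_all[!picked]))
  expect_error(generate_decoys(actives, pool[1:10], per_active = 5,
                               seed = 1))
})

test_that("decoy evaluation reports full and in-domain views", {
  fx <- fx_bin_model()
  actives <- fx$smiles_test[fx$y_test == "ACTIVE"][1:3]
  pool <- generate_decoy_pool(800, seed = 16)
  dec <- generate_decoys(actives, pool, per_active = 20, seed = 17)
  ev <- evaluate_on_decoys(fx$model, actives, dec)
  expect_identical(ev$n_total, 63L)
  expect_lte(ev$n_in_domain, ev$n_total)
  expect_s3_class(ev$all$report, "classification_report")
  expect_true(all(ev$all$enrichment >= 0 & ev$all$enrichment <= 1,
                  na.rm = TRUE))
})
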