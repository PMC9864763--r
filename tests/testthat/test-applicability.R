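# Leverage applicability domain, confidence zones, similarity maps.

test_that("the leverage threshold follows h* = 3(m+1)/p", {
  expect_equal(leverage_threshold(52, 701), 3 * 53 / 701)
  expect_equal(leverage_threshold(52, 701), 0.2268, tolerance = 1e-3)
})

test_that("training leverages satisfy the hat-matrix identities", {
  fx <- fx_reg_model()
  dom <- fit_leverage_domain(fx$model, fx$X_train, fx$y_train,
                             n_repeats = 5, seed = 3)
  expect_gt(dom$h_star, 0)
  expect_true(all(dom$train_leverage >= -1e-9 &
                    dom$train_leverage <= 1 + 1e-9))
  Z <- scale(fx$X_train[, dom$features, drop = FALSE], dom$center,
             dom$scale)
  expect_equal(sum(dom$train_leverage), qr(Z)$rank, tolerance = 1e-6)
  expect_equal(dom$h_star, 3 * (dom$m + 1) / dom$p)
})

test_that("leverage of a known train row reproduces its train leverage", {
  fx <- fx_reg_model()
  dom <- fit_leverage_domain(fx$model, fx$X_train, fx$y_train,
                             n_repeats = 3, seed = 4)
  lev <- leverage_of(dom, fx$X_train[7, , drop = FALSE])
  expect_equal(lev$leverage, dom$train_leverage[7], tolerance = 1e-9)
})

test_that("centroid queries have minimal leverage, extrapolations flag out", {
  set.seed(5)
  n <- 120
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- X %*% rnorm(6) + rnorm(n, sd = 0.1)
  spec <- model_spec("GRADIENT_BOOSTED_TREES", "REGRESSION", budget = 1,
                     seed = 5)
  m <- tune_and_train(spec, X, as.numeric(y))
  dom <- fit_leverage_domain(m, X, as.numeric(y), n_repeats = 5, seed = 5)
  centroid <- matrix(colMeans(X)[dom$features], 1,
                     dimnames = list(NULL, dom$features))
  pad <- matrix(colMeans(X), 1, ncol(X), dimnames = list(NULL, colnames(X)))
  lev_c <- leverage_of(dom, pad)
  expect_lte(lev_c$leverage, min(dom$train_leverage) + 1e-9)
  far <- pad
  far[1, dom$features] <- colMeans(X)[dom$features] +
    10 * apply(X[, dom$features, drop = FALSE], 2, sd)
  lev_f <- leverage_of(dom, far)
  expect_false(lev_f$in_domain)
  expect_gt(lev_f$leverage, dom$h_star)
  # centered zero query = exactly zero leverage
  expect_equal(lev_c$leverage, 0, tolerance = 1e-9)
  expect_error(leverage_of(dom, pad[, 1:2, drop = FALSE]), "lacks")
})

test_that("most training compounds lie inside their own domain", {
  fx <- fx_reg_model()
  dom <- fit_leverage_domain(fx$model, fx$X_train, fx$y_train,
                             n_repeats = 3, seed = 6)
  expect_lt(mean(dom$train_leverage > dom$h_star), 0.15)
})

test_that("Williams data standardizes residuals against the train RMSE", {
  fx <- fx_reg_model()
  dom <- fit_leverage_domain(fx$model, fx$X_train, fx$y_train,
                             n_repeats = 3, seed = 7)
  y_pred <- predict_qsar(fx$model, fx$X_train)
  w <- williams_data(dom, fx$X_train, fx$y_train, y_pred, train_rmse = 0.5)
  expect_length(w$leverage, length(fx$y_train))
  expect_length(w$std_residual, length(fx$y_train))
  expect_identical(w$residual_limits, c(-3, 3))
  # perfect predictions give all-zero residuals
  w0 <- williams_data(dom, fx$X_train, fx$y_train, fx$y_train, 0.5)
  expect_equal(w0$std_residual, rep(0, length(fx$y_train)))
  # a planted gross outlier is the only |residual| > 3
  y_out <- fx$y_train
  y_out[3] <- y_out[3] + 10 * 0.5
  w1 <- williams_data(dom, fx$X_train, fx$y_train, y_out, 0.5)
  expect_identical(which(abs(w1$std_residual) > 3), 3L)
  expect_error(williams_data(dom, fx$X_train, fx$y_train, y_pred, 0),
               "positive")
})

test_that("confidence zones implement the indeterminate-band rules", {
  expect_false(in_confidence_zone("BINARY", cbind(A = 0.45, B = 0.55)))
  expect_true(in_confidence_zone("BINARY", cbind(A = 0.05, B = 0.95)))
  expect_false(in_confidence_zone("BINARY", cbind(A = 0.5, B = 0.5)))
  expect_true(in_confidence_zone("BINARY", cbind(A = 0.39, B = 0.61)))
  expect_false(in_confidence_zone("MULTICLASS",
                                  cbind(A = 0.45, B = 0.35, C = 0.20)))
  expect_true(in_confidence_zone("MULTICLASS",
                                 cbind(A = 0.51, B = 0.29, C = 0.20)))
  # total over a probability-simplex grid
  set.seed(8)
  for (i in 1:200) {
    p <- rexp(3); p <- p / sum(p)
    pm <- matrix(p, 1, dimnames = list(NULL, c("A", "B", "C")))
    out_b <- in_confidence_zone("BINARY", matrix(c(p[1], 1 - p[1]), 1))
    out_m <- in_confidence_zone("MULTICLASS", pm)
    expect_true(is.logical(out_b) && is.logical(out_m))
    expect_identical(out_m[[1]], max(p) > 0.5)
  }
})

test_that("similarity maps attribute prediction to pharmacophore atoms", {
  fx <- fx_bin_model()
  # an active-library molecule carrying the benzothiazole pharmacophore
  smi <- standardize_smiles("c1cc(-c2nc3ccccc3s2)ccc1OC")
  map <- similarity_map(fx$model, smi, class_of_interest = "ACTIVE")
  mol <- parse_molecules(smi)[[1]]
  expect_identical(nrow(map$atoms), mol$n_atoms)
  expect_identical(map$atoms$element, mol$elem)
  expect_true(is.finite(map$reference_prediction))
  expect_true(any(map$atoms$weight != 0))
})

test_that("similarity maps reject unsupported feature types", {
  set.seed(9)
  X <- matrix(rnorm(40 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  spec <- model_spec("KNN", "REGRESSION", "DESCRIPTORS_2D", budget = 1,
                     seed = 9)
  m <- tune_and_train(spec, X, rnorm(40))
  expect_error(similarity_map(m, "CCO"), "ECFP")
})

test_that("a constant model yields an all-zero similarity map", {
  smi <- fx_datasets()$binary$canonical_smiles[1:30]
  fb <- feature_block(smi, "ECFP4")
  spec <- model_spec("RANDOM_FOREST", "REGRESSION", "ECFP4", budget = 1,
                     seed = 10)
  m <- tune_and_train(spec, fb$X, rep(5, 30), feature_state = fb$state)
  map <- similarity_map(m, smi[1])
  expect_equal(map$atoms$weight, rep(0, nrow(map$atoms)), tolerance = 1e-9)
})

test_that("permutation importance ranks the generating feature first", {
  set.seed(11)
  X <- matrix(rnorm(150 * 5), ncol = 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- 3 * X[, 2] + rnorm(150, sd = 0.3)
  spec <- model_spec("GRADIENT_BOOSTED_TREES", "REGRESSION", budget = 2,
                     seed = 11)
  m <- tune_and_train(spec, X, y)
  imp <- permutation_importance(m, X, y, n_repeats = 10, seed = 12)
  expect_identical(names(which.max(imp)), "f2")
  expect_gt(imp["f2"], 0)
})
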