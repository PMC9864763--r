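# Model families, hyperparameter search, cross-validation statistics,
# Y-scrambling and bundle persistence.

blobs <- function(n = 200, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * 5, mean = 0), ncol = 5),
             matrix(rnorm(n / 2 * 5, mean = 4), ncol = 5))
  colnames(X) <- paste0("f", 1:5)
  list(X = X, y = rep(c("NEG", "POS"), each = n / 2))
}

test_that("every family separates two distant Gaussian blobs", {
  fams <- c("RANDOM_FOREST", "SVM", "KNN", "GRADIENT_BOOSTED_TREES",
            "NEURAL_NET")
  for (s in 1:2) {
    d <- blobs(seed = s)
    for (alg in fams) {
      spec <- model_spec(alg, "BINARY", "DESCRIPTORS_2D", budget = 6L,
                         seed = s)
      m <- tune_and_train(spec, d$X, d$y)
      expect_gte(m$cv_stats$BA_CV, 0.98)
    }
  }
})

test_that("exact linear labels give near-perfect Q2 for the main families", {
  for (alg in c("GRADIENT_BOOSTED_TREES", "KNN", "SVM")) {
    set.seed(3)
    X <- matrix(runif(300 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- 2 * X[, "a"]
    spec <- model_spec(alg, "REGRESSION", "DESCRIPTORS_2D", budget = 4L,
                       seed = 3)
    m <- tune_and_train(spec, X, y)
    expect_gte(m$cv_stats$Q2, 0.95)
  }
})

test_that("budget 1 degenerates to fitting a single configuration", {
  d <- blobs(100, seed = 2)
  spec <- model_spec("RANDOM_FOREST", "BINARY", budget = 1L, seed = 2)
  m <- tune_and_train(spec, d$X, d$y)
  expect_identical(nrow(m$search_history), 1L)
  expect_s3_class(m, "trained_model")
})

test_that("classification probabilities are proper and deterministic", {
  d <- blobs(120, seed = 4)
  for (alg in c("RANDOM_FOREST", "SVM", "KNN", "GRADIENT_BOOSTED_TREES")) {
    spec <- model_spec(alg, "BINARY", budget = 1L, seed = 4)
    m <- tune_and_train(spec, d$X, d$y)
    p <- predict_qsar(m, d$X)
    expect_identical(colnames(p), c("NEG", "POS"))
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
    expect_identical(p, predict_qsar(m, d$X))
  }
})

test_that("constant labels give constant regression predictions", {
  set.seed(6)
  X <- matrix(rnorm(50 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  spec <- model_spec("RANDOM_FOREST", "REGRESSION", budget = 1L, seed = 6)
  m <- tune_and_train(spec, X, rep(5, 50))
  expect_equal(unname(predict_qsar(m, X)), rep(5, 50), tolerance = 1e-6)
})

test_that("non-finite regression labels are rejected", {
  X <- matrix(rnorm(40), ncol = 2, dimnames = list(NULL, c("a", "b")))
  spec <- model_spec("KNN", "REGRESSION", budget = 1L, seed = 1)
  expect_error(tune_and_train(spec, X, c(rep(1, 19), NA)), "non-finite")
})

test_that("multiclass probabilities cover all classes", {
  set.seed(7)
  X <- rbind(matrix(rnorm(60 * 3), ncol = 3),
             matrix(rnorm(60 * 3, 3), ncol = 3),
             matrix(rnorm(60 * 3, -3), ncol = 3))
  colnames(X) <- c("a", "b", "c")
  y <- rep(c("X", "Y", "Z"), each = 60)
  spec <- model_spec("RANDOM_FOREST", "MULTICLASS", budget = 1L, seed = 7)
  m <- tune_and_train(spec, X, y, rebalance = TRUE)
  p <- predict_qsar(m, X)
  expect_identical(sort(colnames(p)), c("X", "Y", "Z"))
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
})

test_that("quality-gate flags are computed, not asserted", {
  fx <- fx_reg_model()
  g <- fx$model$quality_gates
  expect_type(g$R2_gt_0.6, "logical")
  expect_type(g$Q2_gt_0.5, "logical")
  expect_identical(g$R2_gt_0.6, fx$model$cv_stats$R2_train > 0.6)
  expect_identical(g$Q2_gt_0.5, fx$model$cv_stats$Q2 > 0.5)
})

test_that("Y-scrambling separates true signal from permuted labels", {
  set.seed(8)
  X <- matrix(runif(150 * 4), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- X %*% c(2, -1, 0.5, 0) + rnorm(150, sd = 0.2)
  spec <- model_spec("GRADIENT_BOOSTED_TREES", "REGRESSION", budget = 2L,
                     seed = 8)
  m <- tune_and_train(spec, X, as.numeric(y))
  sc <- y_scramble(m, X, as.numeric(y), n_reps = 8, seed = 9)
  expect_length(sc$scrambled, 8)
  expect_gte(sc$true_stat, 0.6)
  expect_lt(mean(sc$scrambled), 0.15)
  expect_gt(sc$true_stat, max(sc$scrambled))
  expect_error(y_scramble(m, X, as.numeric(y), n_reps = 0), "n_reps")
})

test_that("Y-scrambling uses a distinct permutation per repetition", {
  set.seed(10)
  X <- matrix(rnorm(60 * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(60)
  spec <- model_spec("KNN", "REGRESSION", budget = 1L, seed = 10)
  m <- tune_and_train(spec, X, y)
  # reach into the same RNG stream the op uses
  rng <- sirtscreen:::local_rng(33)
  perms <- lapply(1:6, function(i) rng$sample(60))
  expect_identical(length(unique(lapply(perms, paste, collapse = ","))), 6L)
  sc1 <- y_scramble(m, X, y, n_reps = 4, seed = 33)
  sc2 <- y_scramble(m, X, y, n_reps = 4, seed = 33)
  expect_identical(sc1$scrambled, sc2$scrambled)
})

test_that("model bundles persist and reload with identical predictions", {
  fx <- fx_reg_model()
  dir <- withr::local_tempdir()
  save_model_bundle(fx$model, file.path(dir, "reg"))
  expect_true(all(file.exists(file.path(dir, "reg",
    c("model.bin", "spec.json", "fitted_state.json", "cv_stats.json")))))
  back <- load_model_bundle(file.path(dir, "reg"))
  smi <- fx$smiles_test[1:10]
  expect_identical(predict_qsar(back, smiles = smi),
                   predict_qsar(fx$model, smiles = smi))
  meta <- jsonlite::read_json(file.path(dir, "reg", "spec.json"))
  expect_identical(meta$algorithm, "GRADIENT_BOOSTED_TREES")
  expect_identical(meta$schema_version, 1L)
  expect_error(load_model_bundle(file.path(dir, "nope")), "model.bin")
})

test_that("feature mismatch raises a named error", {
  fx <- fx_reg_model()
  X <- fx$X_train[1:3, 1:100]
  expect_error(predict_qsar(fx$model, X), "feature mismatch")
})
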