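# Model building: five algorithm families (random forest, SVM, KNN,
# gradient-boosted trees, optional single-hidden-layer neural net) for
# regression, binary and multiclass tasks, tuned by sequential model-based
# (Bayesian) optimization over five-fold cross-validation.

ALGORITHMS <- c("RANDOM_FOREST", "SVM", "KNN", "GRADIENT_BOOSTED_TREES",
                "NEURAL_NET")
TASKS <- c("REGRESSION", "BINARY", "MULTICLASS")

#' Default hyperparameter search spaces
#'
#' Conventional, fully overridable ranges: random forests with 100-1000
#' trees and depth 2-30, SVM cost/gamma log-uniform on 1e-3..1e3, KNN k
#' 1-30 with a distance-weighting switch, boosted trees with learning
#' rate 1e-3..0.3 and depth 2-12, neural net with 4-128 hidden units and
#' log-uniform weight decay.
#'
#' @param algorithm one of `ALGORITHMS`.
#' @return named list of parameter definitions
#'   (`type` int/num, `lower`, `upper`, `log`).
#' @export
default_search_space <- function(algorithm) {
  switch(match.arg(algorithm, ALGORITHMS),
    RANDOM_FOREST = list(
      num_trees = list(type = "int", lower = 100, upper = 1000),
      max_depth = list(type = "int", lower = 2, upper = 30),
      min_node = list(type = "int", lower = 1, upper = 20)
    ),
    SVM = list(
      cost = list(type = "num", lower = 1e-3, upper = 1e3, log = TRUE),
      gamma = list(type = "num", lower = 1e-3, upper = 1e3, log = TRUE)
    ),
    KNN = list(
      k = list(type = "int", lower = 1, upper = 30),
      weighted = list(type = "int", lower = 0, upper = 1)
    ),
    GRADIENT_BOOSTED_TREES = list(
      eta = list(type = "num", lower = 1e-3, upper = 0.3, log = TRUE),
      max_depth = list(type = "int", lower = 2, upper = 12),
      nrounds = list(type = "int", lower = 50, upper = 400),
      subsample = list(type = "num", lower = 0.5, upper = 1),
      colsample = list(type = "num", lower = 0.3, upper = 1)
    ),
    NEURAL_NET = list(
      size = list(type = "int", lower = 4, upper = 128),
      decay = list(type = "num", lower = 1e-4, upper = 1e-1, log = TRUE)
    )
  )
}

#' Create a model specification
#'
#' @param algorithm algorithm family.
#' @param task `"REGRESSION"`, `"BINARY"` or `"MULTICLASS"`.
#' @param feature_type feature block type the model expects.
#' @param search_space hyperparameter space (default
#'   [default_search_space()]).
#' @param budget number of configurations evaluated by the tuner.
#' @param seed integer seed.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(algorithm, task, feature_type = "ECFP4",
                       search_space = NULL, budget = 15L, seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  task <- match.arg(task, TASKS)
  feature_type <- match.arg(feature_type, FEATURE_TYPES)
  if (is.null(search_space)) search_space <- default_search_space(algorithm)
  stopifnot(budget >= 1L)
  if (algorithm == "NEURAL_NET" && !requireNamespace("nnet", quietly = TRUE)) {
    stop("the NEURAL_NET family requires the optional 'nnet' package")
  }
  structure(list(algorithm = algorithm, task = task,
                 feature_type = feature_type, search_space = search_space,
                 budget = as.integer(budget), seed = as.integer(seed)),
            class = "model_spec")
}

# ---- family fitting ----------------------------------------------------

fit_family <- function(algorithm, task, X, y, params, seed) {
  X <- as.matrix(X)
  classification <- task != "REGRESSION"
  yf <- if (classification) factor(y) else as.numeric(y)
  set.seed(seed)
  fit <- switch(algorithm,
    RANDOM_FOREST = {
      ranger::ranger(
        x = X, y = yf, num.trees = params$num_trees,
        max.depth = params$max_depth, min.node.size = params$min_node,
        probability = classification, seed = seed, num.threads = 1L
      )
    },
    SVM = {
      e1071::svm(x = X, y = yf, cost = params$cost, gamma = params$gamma,
                 probability = classification, kernel = "radial")
    },
    KNN = list(X = X, y = yf, k = params$k,
               weighted = params$weighted >= 0.5),
    GRADIENT_BOOSTED_TREES = {
      if (classification) {
        nclass <- nlevels(yf)
        lab <- as.integer(yf) - 1L
        obj <- if (nclass == 2L) "binary:logistic" else "multi:softprob"
        pars <- list(eta = params$eta, max_depth = params$max_depth,
                     subsample = params$subsample,
                     colsample_bytree = params$colsample,
                     objective = obj, nthread = 1L,
                     tree_method = "hist", max_bin = 64L)
        if (nclass > 2L) pars$num_class <- nclass
        xgboost::xgb.train(params = pars,
                           data = xgboost::xgb.DMatrix(X, label = lab),
                           nrounds = params$nrounds, verbose = 0)
      } else {
        xgboost::xgb.train(
          params = list(eta = params$eta, max_depth = params$max_depth,
                        subsample = params$subsample,
                        colsample_bytree = params$colsample,
                        objective = "reg:squarederror", nthread = 1L,
                        tree_method = "hist", max_bin = 64L),
          data = xgboost::xgb.DMatrix(X, label = as.numeric(yf)),
          nrounds = params$nrounds, verbose = 0)
      }
    },
    NEURAL_NET = {
      if (classification) {
        nnet::nnet(x = X, y = stats::model.matrix(~ yf - 1),
                   size = params$size, decay = params$decay,
                   softmax = TRUE, maxit = 200, trace = FALSE,
                   MaxNWts = 1e6)
      } else {
        ys <- scale(as.numeric(yf))
        f <- nnet::nnet(x = X, y = ys, size = params$size,
                        decay = params$decay, linout = TRUE, maxit = 200,
                        trace = FALSE, MaxNWts = 1e6)
        attr(f, "y_center") <- attr(ys, "scaled:center")
        attr(f, "y_scale") <- attr(ys, "scaled:scale")
        f
      }
    },
    stop("unknown algorithm")
  )
  list(algorithm = algorithm, task = task, fit = fit,
       classes = if (classification) levels(yf) else NULL,
       n_features = ncol(X), feature_names = colnames(X))
}

predict_family <- function(fitted, X) {
  X <- as.matrix(X)
  classification <- fitted$task != "REGRESSION"
  cls <- fitted$classes
  out <- switch(fitted$algorithm,
    RANDOM_FOREST = {
      p <- predict(fitted$fit, data = X, num.threads = 1L)$predictions
      if (classification) {
        m <- matrix(0, nrow(X), length(cls), dimnames = list(NULL, cls))
        m[, colnames(p)] <- p
        m
      } else as.numeric(p)
    },
    SVM = {
      if (classification) {
        p <- predict(fitted$fit, X, probability = TRUE)
        pr <- attr(p, "probabilities")
        m <- matrix(0, nrow(X), length(cls), dimnames = list(NULL, cls))
        m[, colnames(pr)] <- pr
        m
      } else as.numeric(predict(fitted$fit, X))
    },
    KNN = knn_predict(fitted$fit, X, classification, cls),
    GRADIENT_BOOSTED_TREES = {
      p <- predict(fitted$fit, xgboost::xgb.DMatrix(X))
      if (!classification) {
        as.numeric(p)
      } else if (length(cls) == 2L) {
        m <- cbind(1 - p, p)
        colnames(m) <- cls
        m
      } else {
        m <- matrix(p, ncol = length(cls), byrow = TRUE)
        colnames(m) <- cls
        m
      }
    },
    NEURAL_NET = {
      p <- predict(fitted$fit, X)
      if (classification) {
        colnames(p) <- sub("^yf", "", colnames(p))
        p <- p[, cls, drop = FALSE]
        sweep(p, 1L, rowSums(p), "/")
      } else {
        as.numeric(p) * attr(fitted$fit, "y_scale") +
          attr(fitted$fit, "y_center")
      }
    }
  )
  out
}

# In-package KNN with full per-class probability vectors and optional
# inverse-distance weighting.
knn_predict <- function(fit, X, classification, cls) {
  k <- min(fit$k, nrow(fit$X))
  d2 <- outer(rowSums(X^2), rowSums(fit$X^2), "+") - 2 * X %*% t(fit$X)
  d2[d2 < 0] <- 0
  if (classification) {
    out <- matrix(0, nrow(X), length(cls), dimnames = list(NULL, cls))
  } else {
    out <- numeric(nrow(X))
  }
  for (i in seq_len(nrow(X))) {
    nn <- order(d2[i, ])[seq_len(k)]
    w <- if (fit$weighted) 1 / (sqrt(d2[i, nn]) + 1e-12) else rep(1, k)
    if (classification) {
      acc <- numeric(length(cls))
      names(acc) <- cls
      for (j in seq_len(k)) {
        lab <- as.character(fit$y[nn[j]])
        acc[lab] <- acc[lab] + w[j]
      }
      out[i, ] <- acc / sum(acc)   # entries stay in [0, 1] exactly
    } else {
      out[i] <- sum(w * fit$y[nn]) / sum(w)
    }
  }
  out
}

# ---- cross-validation and scoring --------------------------------------

cv_evaluate <- function(spec, X, y, params, n_folds = 5L,
                        rebalance = FALSE, fold_seed = NULL) {
  classification <- spec$task != "REGRESSION"
  seed <- if (is.null(fold_seed)) spec$seed else fold_seed
  folds <- make_folds(y, n_folds, seed)
  oof <- if (classification) NULL else rep(NA_real_, length(y))
  oof_lab <- rep(NA_character_, length(y))
  fold_stats <- list()
  for (f in sort(unique(folds))) {
    tr <- which(folds != f); te <- which(folds == f)
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (rebalance && classification) {
      rb <- rebalance_train(Xtr, ytr, seed = seed + f)
      Xtr <- rb$X; ytr <- rb$labels
    }
    fit <- fit_family(spec$algorithm, spec$task, Xtr, ytr, params,
                      seed = seed + f)
    p <- predict_family(fit, X[te, , drop = FALSE])
    if (classification) {
      pred <- colnames(p)[max.col(p, ties.method = "first")]
      oof_lab[te] <- pred
      cm <- table(factor(y[te], fit$classes), factor(pred, fit$classes))
      fold_stats[[f]] <- c(BA = balanced_accuracy(as.character(y[te]), pred),
                           MCC = mcc_gorodkin(cm))
    } else {
      oof[te] <- p
      tss <- sum((y[te] - mean(y[te]))^2)
      fold_stats[[f]] <- c(
        R2 = if (tss == 0) 0 else 1 - sum((y[te] - p)^2) / tss,
        RMSE = sqrt(mean((y[te] - p)^2))
      )
    }
  }
  fs <- do.call(rbind, fold_stats)
  if (classification) {
    list(score = mean(fs[, "BA"]), fold_stats = fs, oof_labels = oof_lab)
  } else {
    tss <- sum((y - mean(y))^2)
    q2 <- if (tss == 0) 0 else 1 - sum((y - oof)^2) / tss
    list(score = mean(fs[, "R2"]), Q2 = q2,
         RMSE_CV = sqrt(mean((y - oof)^2)), fold_stats = fs, oof = oof)
  }
}

# ---- sequential model-based optimization -------------------------------

space_dim <- function(space) length(space)

decode_params <- function(u, space) {
  out <- list()
  for (j in seq_along(space)) {
    def <- space[[j]]
    lo <- def$lower; hi <- def$upper
    val <- if (isTRUE(def$log)) {
      exp(log(lo) + u[j] * (log(hi) - log(lo)))
    } else {
      lo + u[j] * (hi - lo)
    }
    if (def$type == "int") val <- as.integer(round(val))
    out[[names(space)[j]]] <- val
  }
  out
}

# SMBO: Latin-hypercube initialization, random-forest surrogate, expected
# improvement over random candidates.
smbo_optimize <- function(objective, space, budget, seed) {
  d <- space_dim(space)
  rng <- local_rng(seed)
  n_init <- min(budget, max(4L, ceiling(budget / 3)))
  U <- rng$run(function() lhs::randomLHS(n_init, d))
  scores <- rep(NA_real_, budget)
  configs <- vector("list", budget)
  for (i in seq_len(n_init)) {
    configs[[i]] <- decode_params(U[i, ], space)
    scores[i] <- objective(configs[[i]])
  }
  Umat <- U
  i <- n_init
  while (i < budget) {
    i <- i + 1L
    cand <- matrix(rng$runif(500 * d), ncol = d)
    ok <- is.finite(scores[seq_len(i - 1L)])
    pick_random <- sum(ok) < 3L
    if (!pick_random) {
      df <- data.frame(Umat[ok, , drop = FALSE],
                       .s = scores[seq_len(i - 1L)][ok])
      sur <- try(ranger::ranger(.s ~ ., data = df, num.trees = 200,
                                seed = seed + i, num.threads = 1L,
                                keep.inbag = TRUE), silent = TRUE)
      if (inherits(sur, "try-error")) pick_random <- TRUE
    }
    if (pick_random) {
      u <- cand[1L, ]
    } else {
      pr <- predict(sur, data.frame(cand), type = "se",
                    num.threads = 1L)
      mu <- pr$predictions; se <- pmax(pr$se, 1e-9)
      best <- max(scores[seq_len(i - 1L)], na.rm = TRUE)
      z <- (mu - best) / se
      ei <- (mu - best) * stats::pnorm(z) + se * stats::dnorm(z)
      u <- cand[which.max(ei), ]
    }
    configs[[i]] <- decode_params(u, space)
    s <- objective(configs[[i]])
    scores[i] <- if (is.finite(s)) s else NA_real_
    Umat <- rbind(Umat, u)
  }
  if (all(!is.finite(scores))) {
    # fall back to the space midpoint
    warning("hyperparameter search failed; falling back to the midpoint")
    mid <- decode_params(rep(0.5, d), space)
    return(list(best = mid, best_score = NA_real_,
                history = data.frame(score = scores)))
  }
  b <- which.max(ifelse(is.finite(scores), scores, -Inf))
  list(best = configs[[b]], best_score = scores[b],
       history = data.frame(score = scores))
}

# ---- top-level training ------------------------------------------------

#' Tune and train a model
#'
#' Sequential model-based search over the spec's hyperparameter space,
#' maximizing the mean five-fold cross-validation score (R2 for
#' regression, balanced accuracy for classification). The final model is
#' refit on the full training set with the best configuration. Internal
#' validation statistics are recorded: training R2 / RMSE and pooled
#' out-of-fold Q2 (1 - PRESS/TSS) / RMSE_CV for regression, per-fold BA
#' and MCC for classification, plus the conventional quality-gate flags
#' (R2 > 0.6, Q2 > 0.5).
#'
#' @param spec a [model_spec()].
#' @param X training feature matrix (row-aligned with `labels`).
#' @param labels training labels.
#' @param feature_state fitted feature state stored with the model so it
#'   can predict straight from SMILES.
#' @param rebalance apply SMOTE inside each training fold and to the
#'   final refit (classification only).
#' @return object of class `trained_model`.
#' @export
tune_and_train <- function(spec, X, labels, feature_state = NULL,
                           rebalance = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(labels))
  if (spec$task == "REGRESSION" && any(!is.finite(labels))) {
    stop("non-finite regression labels")
  }
  objective <- function(params) {
    out <- try(cv_evaluate(spec, X, labels, params,
                           rebalance = rebalance)$score, silent = TRUE)
    if (inherits(out, "try-error")) NA_real_ else out
  }
  opt <- smbo_optimize(objective, spec$search_space, spec$budget, spec$seed)
  cv <- cv_evaluate(spec, X, labels, opt$best, rebalance = rebalance)
  Xfit <- X; yfit <- labels
  if (rebalance && spec$task != "REGRESSION") {
    rb <- rebalance_train(X, labels, seed = spec$seed)
    Xfit <- rb$X; yfit <- rb$labels
  }
  fitted <- fit_family(spec$algorithm, spec$task, Xfit, yfit, opt$best,
                       seed = spec$seed)
  stats <- if (spec$task == "REGRESSION") {
    p_tr <- predict_family(fitted, X)
    tss <- sum((labels - mean(labels))^2)
    list(
      R2_train = if (tss == 0) 0 else
        1 - sum((labels - p_tr)^2) / tss,
      RMSE_int = sqrt(mean((labels - p_tr)^2)),
      Q2 = cv$Q2, RMSE_CV = cv$RMSE_CV,
      fold_stats = cv$fold_stats
    )
  } else {
    p_tr <- predict_family(fitted, X)
    pred_tr <- colnames(p_tr)[max.col(p_tr, ties.method = "first")]
    list(
      BA_train = balanced_accuracy(as.character(labels), pred_tr),
      BA_CV = mean(cv$fold_stats[, "BA"]),
      MCC_CV = mean(cv$fold_stats[, "MCC"]),
      fold_stats = cv$fold_stats
    )
  }
  gates <- if (spec$task == "REGRESSION") {
    list(R2_gt_0.6 = isTRUE(stats$R2_train > 0.6),
         Q2_gt_0.5 = isTRUE(stats$Q2 > 0.5))
  } else {
    list(BA_CV_gt_0.7 = isTRUE(stats$BA_CV > 0.7))
  }
  structure(list(
    spec = spec, task = spec$task, algorithm = spec$algorithm,
    best_params = opt$best, search_history = opt$history,
    cv_stats = stats, quality_gates = gates,
    fitted = fitted, classes = fitted$classes,
    feature_state = feature_state, rebalance = rebalance
  ), class = "trained_model")
}

#' Predict with a trained model
#'
#' @param model a [tune_and_train()] result.
#' @param X feature matrix matching the model's feature block, or
#' @param smiles SMILES to featurize through the stored feature state.
#' @return numeric vector (regression) or probability matrix with one
#'   column per class (rows sum to 1).
#' @export
predict_qsar <- function(model, X = NULL, smiles = NULL) {
  stopifnot(inherits(model, "trained_model"))
  if (is.null(X)) {
    if (is.null(smiles)) stop("either X or smiles must be given")
    if (is.null(model$feature_state)) {
      stop("model carries no feature state; supply X")
    }
    X <- apply_feature_state(model$feature_state, smiles)
  }
  X <- as.matrix(X)
  if (ncol(X) != model$fitted$n_features) {
    expected <- model$fitted$feature_names
    got <- colnames(X)
    stop("feature mismatch: missing [",
         paste(utils::head(setdiff(expected, got), 5L), collapse = ", "),
         "], extra [",
         paste(utils::head(setdiff(got, expected), 5L), collapse = ", "),
         "]")
  }
  predict_family(model$fitted, X)
}

#' Y-scrambling robustness check
#'
#' Refits the model class with its tuned hyperparameters on label
#' permutations and returns the distribution of the cross-validated
#' statistic (Q2 for regression, mean CV balanced accuracy for
#' classification) next to the true-label statistic. A sound model
#' scores far above its scrambled distribution.
#'
#' @param model a trained model.
#' @param X training features; `labels` training labels.
#' @param labels training labels.
#' @param n_reps permutations (default 100).
#' @param seed integer seed; every repetition uses a distinct permutation.
#' @return object of class `scramble_result` with `scrambled` (vector of
#'   statistics), `true_stat` and `statistic` name.
#' @export
y_scramble <- function(model, X, labels, n_reps = 100L, seed = 1L) {
  stopifnot(inherits(model, "trained_model"))
  if (n_reps < 1L) stop("n_reps must be >= 1")
  X <- as.matrix(X)
  rng <- local_rng(seed)
  regression <- model$task == "REGRESSION"
  stat <- function(y, fold_seed) {
    cv <- cv_evaluate(model$spec, X, y, model$best_params,
                      fold_seed = fold_seed)
    if (regression) cv$Q2 else cv$score
  }
  perms <- lapply(seq_len(n_reps), function(i) rng$sample(length(labels)))
  scrambled <- vapply(seq_len(n_reps), function(i) {
    stat(labels[perms[[i]]], fold_seed = seed + i)
  }, 0)
  true_stat <- if (regression) model$cv_stats$Q2 else model$cv_stats$BA_CV
  structure(list(scrambled = scrambled, true_stat = true_stat,
                 statistic = if (regression) "Q2" else "BA_CV",
                 n_reps = n_reps),
            class = "scramble_result")
}

# ---- persistence -------------------------------------------------------

#' Save a trained model bundle
#'
#' Writes a directory with `model.bin` (opaque fitted object),
#' `spec.json`, `fitted_state.json` and `cv_stats.json`, schema-versioned.
#'
#' @param model a trained model.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model_bundle <- function(model, dir) {
  stopifnot(inherits(model, "trained_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.bin"))
  jsonlite::write_json(
    list(schema_version = 1L, algorithm = model$algorithm,
         task = model$task, feature_type = model$spec$feature_type,
         best_params = model$best_params, classes = model$classes),
    file.path(dir, "spec.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  jsonlite::write_json(
    model$feature_state %||% list(), file.path(dir, "fitted_state.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(model$cv_stats, function(x) if (is.matrix(x)) as.data.frame(x) else x),
    file.path(dir, "cv_stats.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}

#' Load a trained model bundle
#' @param dir bundle directory written by [save_model_bundle()].
#' @return the `trained_model` object.
#' @export
load_model_bundle <- function(dir) {
  path <- file.path(dir, "model.bin")
  if (!file.exists(path)) stop("no model.bin under ", dir)
  readRDS(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
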