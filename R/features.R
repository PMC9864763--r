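# Feature blocks: fingerprints or the 2D descriptor panel together with
# the fitted preprocessing state (descriptor selection + standardization),
# fitted on training rows only so models stay portable and leakage-free.

FEATURE_TYPES <- c("MACCS", "ECFP4", "ECFP6", "DESCRIPTORS_2D")

#' Build a feature block on training compounds
#'
#' Fingerprint types are used as-is (no selection). The descriptor panel
#' runs the four-stage selection chain of [select_descriptors()] fitted on
#' the given (training) rows, then standardizes the surviving columns to
#' zero mean / unit variance. The fitted state can be applied to new
#' compounds with [apply_feature_state()].
#'
#' @param smiles training-set SMILES.
#' @param feature_type one of `"MACCS"`, `"ECFP4"`, `"ECFP6"`,
#'   `"DESCRIPTORS_2D"`.
#' @param labels training labels (required for the descriptor RFECV stage).
#' @param seed integer seed for the selection chain.
#' @param standardize_fp also z-score fingerprint bits (default FALSE;
#'   used by the leverage applicability domain).
#' @return list with `X` (feature matrix), `feature_type`, `state`
#'   (fitted selection/standardization), and `trace` (selection counts;
#'   `NULL` for fingerprints).
#' @export
feature_block <- function(smiles, feature_type, labels = NULL, seed = 1L,
                          standardize_fp = FALSE) {
  feature_type <- match.arg(feature_type, FEATURE_TYPES)
  if (feature_type != "DESCRIPTORS_2D") {
    X <- fingerprint_matrix(smiles, feature_type)
    state <- list(feature_type = feature_type, columns = colnames(X),
                  center = NULL, scale = NULL)
    return(list(X = X, feature_type = feature_type, state = state,
                trace = NULL))
  }
  if (is.null(labels)) stop("descriptor selection requires training labels")
  D <- descriptors_2d(smiles)
  sel <- select_descriptors(D, labels, seed = seed)
  Xs <- D[, sel$selected, drop = FALSE]
  ctr <- colMeans(Xs)
  scl <- apply(Xs, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  X <- scale(Xs, ctr, scl)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  state <- list(feature_type = feature_type, columns = sel$selected,
                center = as.list(ctr), scale = as.list(scl))
  list(X = X, feature_type = feature_type, state = state,
       trace = sel$trace)
}

#' Apply a fitted feature state to new compounds
#'
#' @param state the `state` element of a [feature_block()].
#' @param smiles SMILES of the query compounds.
#' @return feature matrix with exactly the training columns, transformed
#'   with the training standardization.
#' @export
apply_feature_state <- function(state, smiles) {
  if (state$feature_type != "DESCRIPTORS_2D") {
    return(fingerprint_matrix(smiles, state$feature_type))
  }
  D <- descriptors_2d(smiles)
  miss <- setdiff(unlist(state$columns), colnames(D))
  if (length(miss)) stop("missing descriptor column(s): ",
                         paste(miss, collapse = ", "))
  X <- D[, unlist(state$columns), drop = FALSE]
  X <- scale(X, unlist(state$center), unlist(state$scale))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  X
}

#' Four-stage descriptor selection chain (train rows only)
#'
#' Stage 1 drops columns that are all-NaN, contain any NaN, or are
#' constant/all-zero. Stage 2 drops low-variance columns (variance on the
#' raw scale below `var_cutoff`; an alternative order applying the cutoff
#' after standardization is available via `variance_after_standardize`,
#' where it is vacuous by construction). Stage 3 drops, for every pair
#' with |Pearson r| above `cor_cutoff`, the later column in column order.
#' Stage 4 is recursive feature elimination with 10-fold cross-validation
#' using a decision-tree estimator, stepping down by 1% of remaining
#' features (at least one) per iteration.
#'
#' @param train_matrix descriptor matrix of training compounds.
#' @param train_labels numeric (regression) or class labels.
#' @param seed integer seed controlling fold assignment.
#' @param var_cutoff variance threshold (default 0.1).
#' @param cor_cutoff correlation threshold (default 0.9).
#' @param variance_after_standardize apply the variance filter after
#'   z-scoring instead of before (default FALSE).
#' @return list with `selected` (surviving column names) and `trace`
#'   (counts surviving each stage plus per-stage dropped names).
#' @export
select_descriptors <- function(train_matrix, train_labels, seed,
                               var_cutoff = 0.1, cor_cutoff = 0.9,
                               variance_after_standardize = FALSE) {
  if (missing(seed)) stop("a selection seed is required")
  X <- as.matrix(train_matrix)
  stopifnot(nrow(X) == length(train_labels), !is.null(colnames(X)))
  n0 <- ncol(X)
  dropped <- list()
  # stage 1: NaN / constant columns
  bad <- apply(X, 2L, function(col) any(!is.finite(col))) |
    apply(X, 2L, function(col) length(unique(col)) == 1L)
  dropped$nan_or_constant <- colnames(X)[bad]
  X <- X[, !bad, drop = FALSE]
  # stage 2: variance filter
  v <- if (variance_after_standardize) {
    apply(scale(X), 2L, stats::var)
  } else {
    apply(X, 2L, stats::var)
  }
  lowvar <- v < var_cutoff
  dropped$low_variance <- colnames(X)[lowvar]
  X <- X[, !lowvar, drop = FALSE]
  # stage 3: pairwise correlation filter, keep the earlier column
  if (ncol(X) > 1L) {
    cm <- abs(stats::cor(X))
    drop <- logical(ncol(X))
    for (j in seq_len(ncol(X) - 1L)) {
      if (drop[j]) next
      hits <- which(cm[j, ] > cor_cutoff)
      drop[hits[hits > j]] <- TRUE
    }
    dropped$correlated <- colnames(X)[drop]
    X <- X[, !drop, drop = FALSE]
  } else {
    dropped$correlated <- character()
  }
  if (ncol(X) < 2L) stop("fewer than 2 descriptors survive the filters")
  # stage 4: RFE with 10-fold CV, decision-tree estimator
  rfe <- rfecv_tree(X, train_labels, seed = seed)
  dropped$rfecv <- setdiff(colnames(X), rfe$selected)
  trace <- list(
    counts = c(initial = n0,
               after_nan_constant = n0 - length(dropped$nan_or_constant),
               after_variance = n0 - length(dropped$nan_or_constant) -
                 length(dropped$low_variance),
               after_correlation = ncol(X),
               after_rfecv = length(rfe$selected)),
    dropped = dropped,
    cv_scores = rfe$cv_scores
  )
  list(selected = rfe$selected, trace = trace)
}

# Recursive feature elimination with k-fold CV and an rpart estimator.
# Features are ranked by the tree's variable importance; each iteration
# removes the lowest-ranked 1% (>= 1) of the remaining features. The
# subset size with the best mean CV score wins; ties go to fewer features.
rfecv_tree <- function(X, y, seed, n_folds = 10L) {
  classification <- !is.numeric(y)
  y_fit <- if (classification) factor(y) else y
  folds <- make_folds(y, n_folds, seed)
  score_subset <- function(cols) {
    mean(vapply(sort(unique(folds)), function(f) {
      tr <- folds != f; te <- !tr
      df_tr <- data.frame(X[tr, cols, drop = FALSE], .y = y_fit[tr],
                          check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df_tr,
                          method = if (classification) "class" else "anova",
                          control = rpart::rpart.control(cp = 0,
                                                         minsplit = 10))
      df_te <- data.frame(X[te, cols, drop = FALSE], check.names = FALSE)
      if (classification) {
        pred <- as.character(predict(fit, df_te, type = "class"))
        balanced_accuracy(as.character(y_fit[te]), pred)
      } else {
        pred <- predict(fit, df_te)
        tss <- sum((y[te] - mean(y[te]))^2)
        if (tss == 0) 0 else 1 - sum((y[te] - pred)^2) / tss
      }
    }, 0))
  }
  rank_features <- function(cols) {
    df <- data.frame(X[, cols, drop = FALSE], .y = y_fit,
                     check.names = FALSE)
    fit <- rpart::rpart(.y ~ ., data = df,
                        method = if (classification) "class" else "anova",
                        control = rpart::rpart.control(cp = 0,
                                                       minsplit = 10))
    imp <- fit$variable.importance
    scores <- stats::setNames(rep(0, length(cols)), cols)
    if (!is.null(imp)) scores[names(imp)] <- imp
    scores
  }
  cols <- colnames(X)
  history <- list()
  while (TRUE) {
    history[[length(history) + 1L]] <-
      list(cols = cols, score = score_subset(cols))
    if (length(cols) <= 2L) break
    imp <- rank_features(cols)
    step <- max(1L, floor(0.01 * length(cols)))
    cols <- setdiff(cols, names(sort(imp))[seq_len(step)])
  }
  scores <- vapply(history, `[[`, 0, "score")
  sizes <- vapply(history, function(h) length(h$cols), 0L)
  best <- which(scores == max(scores))
  best <- best[which.min(sizes[best])]
  list(selected = history[[best]]$cols,
       cv_scores = data.frame(n_features = sizes, score = scores))
}

# Stratified fold assignment (classes, or quantile bins for numeric y).
make_folds <- function(y, n_folds, seed) {
  rng <- local_rng(seed)
  strata <- if (is.numeric(y)) {
    qs <- unique(stats::quantile(y, seq(0, 1, length.out = 6L)))
    if (length(qs) < 3L) rep(1L, length(y)) else
      cut(y, qs, include.lowest = TRUE, labels = FALSE)
  } else as.integer(factor(y))
  folds <- integer(length(y))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[rng$sample(length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

balanced_accuracy <- function(truth, pred) {
  classes <- unique(truth)
  mean(vapply(classes, function(cl) {
    mean(pred[truth == cl] == cl)
  }, 0))
}
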