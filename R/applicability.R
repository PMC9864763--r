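# Prediction-confidence machinery: leverage applicability domain for
# regression models (hat-matrix distance to the training centroid over the
# important features), indeterminate probability zones for classifiers,
# atom-contribution similarity maps, and nearest-neighbor lookup.

#' Permutation feature importance
#'
#' Mean drop in score (R2 for regression, balanced accuracy for
#' classification) when one feature column is permuted, averaged over
#' `n_repeats` permutations.
#'
#' @param model a trained model.
#' @param X feature matrix; `y` the matching labels.
#' @param y labels.
#' @param n_repeats permutations per feature (default 30).
#' @param seed integer seed.
#' @return named numeric vector of mean importances (score drops).
#' @export
permutation_importance <- function(model, X, y, n_repeats = 30L, seed = 1L) {
  X <- as.matrix(X)
  rng <- local_rng(seed)
  regression <- model$task == "REGRESSION"
  score <- function(M) {
    p <- predict_qsar(model, M)
    if (regression) {
      tss <- sum((y - mean(y))^2)
      if (tss == 0) 0 else 1 - sum((y - p)^2) / tss
    } else {
      pred <- colnames(p)[max.col(p, ties.method = "first")]
      balanced_accuracy(as.character(y), pred)
    }
  }
  n <- nrow(X)
  p_base <- predict_qsar(model, X)
  score_of <- function(p) {
    if (regression) {
      tss <- sum((y - mean(y))^2)
      if (tss == 0) 0 else 1 - sum((y - p)^2) / tss
    } else {
      pred <- colnames(p)[max.col(p, ties.method = "first")]
      balanced_accuracy(as.character(y), pred)
    }
  }
  base <- score_of(p_base)
  drops <- matrix(0, n_repeats, ncol(X))
  # constant columns are invariant under permutation
  variable <- which(apply(X, 2L, function(cc) any(cc != cc[1L])))
  # Permuting one column leaves most rows unchanged; only rows whose value
  # actually changed need re-prediction, the rest reuse the base
  # predictions. Changed rows are stacked across columns per predict call.
  one_repeat <- function(r, cols) {
    perm <- rng$sample(n)
    chg <- lapply(cols, function(j) which(X[, j] != X[perm, j]))
    counts <- lengths(chg)
    groups <- split(seq_along(cols),
                    ceiling(cumsum(pmax(counts, 1L)) / 2e4))
    for (grp in groups) {
      rows <- unlist(chg[grp])
      if (length(rows) == 0L) next
      M <- X[rows, , drop = FALSE]
      pos <- 0L
      for (gi in grp) {
        if (counts[gi] == 0L) next
        M[pos + seq_len(counts[gi]), cols[gi]] <- X[perm[chg[[gi]]], cols[gi]]
        pos <- pos + counts[gi]
      }
      p <- predict_qsar(model, M)
      pos <- 0L
      for (gi in grp) {
        if (counts[gi] == 0L) { drops[r, cols[gi]] <<- 0; next }
        rows_gi <- chg[[gi]]
        if (regression) {
          pfull <- p_base
          pfull[rows_gi] <- p[pos + seq_len(counts[gi])]
        } else {
          pfull <- p_base
          pfull[rows_gi, ] <- p[pos + seq_len(counts[gi]), , drop = FALSE]
        }
        pos <- pos + counts[gi]
        drops[r, cols[gi]] <<- base - score_of(pfull)
      }
    }
  }
  # two screening repeats over all variable columns; columns whose
  # permutation never moves the score (features the model does not use
  # have exactly zero effect) are not re-permuted further
  n_screen <- min(2L, n_repeats)
  for (r in seq_len(n_screen)) one_repeat(r, variable)
  active_cols <- variable[colSums(abs(drops[seq_len(n_screen), variable,
                                            drop = FALSE])) > 0]
  if (n_repeats > n_screen) {
    for (r in (n_screen + 1L):n_repeats) one_repeat(r, active_cols)
  }
  imp <- colMeans(drops)
  # untouched columns average over the screening repeats only
  skipped <- setdiff(variable, active_cols)
  if (length(skipped)) {
    imp[skipped] <- colMeans(drops[seq_len(n_screen), skipped,
                                   drop = FALSE])
  }
  stats::setNames(imp, colnames(X))
}

#' Fit a leverage applicability domain
#'
#' Restricts the training matrix to the important features (mean
#' permutation importance > 0 by default, 30 repeats), standardizes them,
#' and precomputes the Moore-Penrose pseudo-inverse of X'X so that the
#' leverage h = x' (X'X)^-1 x of any query is cheap. The warning
#' threshold is h* = 3(m+1)/p with m retained features and p training
#' molecules.
#'
#' @param model trained regression model.
#' @param X training feature matrix; `y` training labels.
#' @param y training labels.
#' @param n_repeats permutation-importance repeats (default 30).
#' @param seed integer seed.
#' @param top_k optional: keep the top-k features by importance instead
#'   of the positive-importance rule.
#' @return object of class `leverage_domain` with the training leverages,
#'   `h_star`, the retained feature names and the fitted standardization.
#' @export
fit_leverage_domain <- function(model, X, y, n_repeats = 30L, seed = 1L,
                                top_k = NULL) {
  X <- as.matrix(X)
  imp <- permutation_importance(model, X, y, n_repeats = n_repeats,
                                seed = seed)
  keep <- if (is.null(top_k)) {
    names(imp)[imp > 0]
  } else {
    names(sort(imp, decreasing = TRUE))[seq_len(min(top_k, length(imp)))]
  }
  if (length(keep) == 0L) {
    warning("no feature had positive importance; keeping all features")
    keep <- colnames(X)
  }
  Xk <- X[, keep, drop = FALSE]
  ctr <- colMeans(Xk)
  scl <- apply(Xk, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z <- scale(Xk, ctr, scl)
  xtx_inv <- MASS::ginv(crossprod(Z))
  h_train <- rowSums((Z %*% xtx_inv) * Z)
  m <- length(keep); p <- nrow(X)
  structure(list(
    features = keep, center = ctr, scale = scl,
    xtx_inv = xtx_inv, m = m, p = p,
    h_star = leverage_threshold(m, p),
    train_leverage = h_train,
    importance = imp
  ), class = "leverage_domain")
}

#' Leverage warning threshold h* = 3(m+1)/p
#' @param m number of retained features; `p` training-set size.
#' @param p training-set size.
#' @return the threshold.
#' @export
leverage_threshold <- function(m, p) 3 * (m + 1) / p

#' Leverage of query compounds
#'
#' @param domain a [fit_leverage_domain()] result.
#' @param X query feature matrix (full feature block; the domain selects
#'   its own columns).
#' @return data.frame with `leverage` and logical `in_domain`
#'   (`leverage <= h_star`).
#' @export
leverage_of <- function(domain, X) {
  X <- as.matrix(X)
  miss <- setdiff(domain$features, colnames(X))
  if (length(miss)) stop("query lacks feature(s): ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  Z <- scale(X[, domain$features, drop = FALSE], domain$center,
             domain$scale)
  h <- rowSums((Z %*% domain$xtx_inv) * Z)
  data.frame(leverage = h, in_domain = h <= domain$h_star)
}

#' Williams plot data
#'
#' Leverages and standardized residuals (residual / training RMSE) with
#' the thresholds used for plotting: h* and +-3 standard residuals. No
#' plotting is done here.
#'
#' @param domain a leverage domain.
#' @param X feature matrix of the plotted compounds.
#' @param y_obs,y_pred observed and predicted values.
#' @param train_rmse training RMSE used to standardize residuals.
#' @return list with `leverage`, `std_residual`, `h_star`,
#'   `residual_limits`.
#' @export
williams_data <- function(domain, X, y_obs, y_pred, train_rmse) {
  stopifnot(length(y_obs) == length(y_pred))
  if (train_rmse <= 0) stop("training RMSE must be positive")
  lev <- leverage_of(domain, X)
  list(leverage = lev$leverage,
       std_residual = (y_obs - y_pred) / train_rmse,
       h_star = domain$h_star, residual_limits = c(-3, 3),
       in_domain = lev$in_domain)
}

#' Probability confidence zones
#'
#' Binary models: a prediction is unconfident when the maximum class
#' probability falls inside the indeterminate zone 0.5 +- `half_width`
#' (default 0.1). Multiclass models: confident only when the predicted
#' class has probability above `floor` (default 0.5).
#'
#' @param task `"BINARY"` or `"MULTICLASS"`.
#' @param proba probability matrix (or vector of the positive-class
#'   probability for binary).
#' @param half_width binary zone half-width.
#' @param floor multiclass confidence floor.
#' @return logical vector, `TRUE` where the prediction is confident.
#' @export
in_confidence_zone <- function(task, proba, half_width = 0.1, floor = 0.5) {
  task <- match.arg(task, c("BINARY", "MULTICLASS"))
  if (is.matrix(proba)) {
    top <- apply(proba, 1L, max)
  } else {
    top <- pmax(proba, 1 - proba)
  }
  if (task == "BINARY") {
    top < (0.5 - half_width) | top > (0.5 + half_width)
  } else {
    top > floor
  }
}

#' Atom-contribution similarity map
#'
#' For every atom, the contribution is the change in model output when
#' the fingerprint bits generated by environments containing that atom
#' are cleared: weight = f(full fingerprint) - f(fingerprint without the
#' atom's bits). Positive weights support the prediction. Only defined
#' for fingerprint-based models.
#'
#' @param model trained model on an ECFP or MACCS-free fingerprint block
#'   (ECFP4/ECFP6; MACCS keys carry no atom mapping and are rejected).
#' @param smiles single SMILES string.
#' @param class_of_interest for classifiers, the class whose probability
#'   is attributed (default: the active/predicted class, i.e. the last
#'   column).
#' @return object of class `atom_contribution_map`: data.frame of atom
#'   index, element and weight, plus the reference prediction.
#' @export
similarity_map <- function(model, smiles, class_of_interest = NULL) {
  ft <- model$spec$feature_type
  if (!ft %in% c("ECFP4", "ECFP6")) {
    stop("similarity maps require an ECFP-based model (got ", ft, ")")
  }
  mol <- parse_molecules(smiles)[[1L]]
  if (is.null(mol)) stop("unparsable SMILES")
  nbits <- model$fitted$n_features
  fp <- morgan_fingerprint(mol, radius = ECFP_RADIUS[[ft]], nbits = nbits,
                           detail = TRUE)
  out_of <- function(bits) {
    M <- matrix(bits, nrow = 1L)
    colnames(M) <- model$fitted$feature_names
    p <- predict_qsar(model, M)
    if (is.matrix(p)) {
      cls <- class_of_interest %||% colnames(p)[ncol(p)]
      p[1L, cls]
    } else p[1L]
  }
  ref <- out_of(fp$bits)
  atom_bits <- lapply(seq_len(mol$n_atoms), function(a) {
    unique(fp$env$bit[vapply(fp$env$atoms, function(s) a %in% s, TRUE)])
  })
  weights <- vapply(seq_len(mol$n_atoms), function(a) {
    if (length(atom_bits[[a]]) == 0L) return(0)
    b <- fp$bits
    b[atom_bits[[a]]] <- 0L
    ref - out_of(b)
  }, 0)
  structure(list(
    atoms = data.frame(atom = seq_len(mol$n_atoms), element = mol$elem,
                       weight = weights),
    reference_prediction = ref,
    feature_type = ft, smiles = smiles
  ), class = "atom_contribution_map")
}
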