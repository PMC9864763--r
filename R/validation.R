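# External-validation statistics for regression and classification models:
# QF2-family external determination coefficients, Roy rm2 metrics, Lin's
# concordance correlation coefficient, Golbraikh-Tropsha criteria, balanced
# accuracy / Matthews correlation / macro one-vs-rest metrics, and ROC
# early-enrichment on decoy sets.

#' Regression external-validation report
#'
#' Computes the full battery on observed/predicted pairs of an external
#' (test) set: Rext2 and RMSEext, the three QFn2 external correlation
#' coefficients (QF1 referenced to the training mean, QF2 to the test
#' mean, QF3 to the training-set variance), the Roy rm2 family
#' (rm2, rm2', their mean and absolute difference), Lin's concordance
#' correlation coefficient, and the Golbraikh-Tropsha quantities.
#' Threshold flags follow the conventional acceptance criteria:
#' mean rm2 > 0.5 and delta rm2 < 0.2; QF1/QF2/QF3 > 0.7 and CCC > 0.85.
#'
#' @param y_obs observed values of the external set.
#' @param y_pred predictions for the external set.
#' @param train_labels observed training-set values (required by QF1/QF3).
#' @return object of class `regression_report`: a list of all statistics
#'   plus a `criteria` list of logical flags.
#' @export
regression_report <- function(y_obs, y_pred, train_labels) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 3L,
            length(train_labels) >= 2L)
  n <- length(y_obs)
  n_tr <- length(train_labels)
  press <- sum((y_obs - y_pred)^2)
  tss_ext <- sum((y_obs - mean(y_obs))^2)
  tss_tr_ref <- sum((y_obs - mean(train_labels))^2)
  tss_tr <- sum((train_labels - mean(train_labels))^2)
  if (tss_ext == 0) {
    r2ext <- qf1 <- qf2 <- NaN
    reason <- "zero variance in observed values"
  } else {
    r2ext <- 1 - press / tss_ext
    qf2 <- r2ext
    qf1 <- 1 - press / tss_tr_ref
    reason <- NULL
  }
  qf3 <- if (tss_tr == 0) NaN else 1 - (press / n) / (tss_tr / n_tr)
  rmse_ext <- sqrt(press / n)
  degenerate <- stats::var(y_obs) == 0 || stats::var(y_pred) == 0 ||
    all(y_pred == 0)
  if (degenerate) {
    gt <- list(k = NaN, k_prime = NaN, r2 = NaN, r0_2 = NaN,
               r0_prime_2 = NaN,
               criteria = list(slope_ok = NA, r0_ok = NA, gap_ok = NA,
                               all_pass = NA))
    rm <- list(rm2 = NaN, rm2_prime = NaN, rm2_bar = NaN, delta_rm2 = NaN)
    if (is.null(reason)) reason <- "zero variance in predictions"
  } else {
    gt <- golbraikh_tropsha(y_obs, y_pred)
    rm <- rm2_metrics(y_obs, y_pred)
  }
  ccc <- lin_ccc(y_obs, y_pred)
  out <- list(
    n_ext = n, n_tr = n_tr,
    Rext2 = r2ext, RMSEext = rmse_ext,
    QF1_2 = qf1, QF2_2 = qf2, QF3_2 = qf3,
    rm2 = rm$rm2, rm2_prime = rm$rm2_prime, rm2_bar = rm$rm2_bar,
    delta_rm2 = rm$delta_rm2,
    CCC = ccc,
    r2 = gt$r2, r0_2 = gt$r0_2, r0_prime_2 = gt$r0_prime_2,
    k = gt$k, k_prime = gt$k_prime,
    undefined_reason = reason,
    criteria = list(
      Rext2_gt_0.6 = isTRUE(r2ext > 0.6),
      rm2_bar_gt_0.5 = isTRUE(rm$rm2_bar > 0.5),
      delta_rm2_lt_0.2 = isTRUE(rm$delta_rm2 < 0.2),
      QFn2_gt_0.7 = isTRUE(qf1 > 0.7 && qf2 > 0.7 && qf3 > 0.7),
      CCC_gt_0.85 = isTRUE(ccc > 0.85),
      golbraikh_tropsha = gt$criteria
    )
  )
  class(out) <- "regression_report"
  out
}

#' Golbraikh-Tropsha external criteria
#'
#' Through-origin regressions of predictions on observations (slope `k`)
#' and observations on predictions (slope `k'`), the corresponding
#' through-origin determination coefficients, and the three acceptance
#' criteria: (r2 - r0^2)/r2 < 0.1 or (r2 - r0'^2)/r2 < 0.1;
#' 0.85 <= k (or k') <= 1.15; and |r0^2 - r0'^2| < 0.3.
#'
#' @param y_obs,y_pred equal-length numeric vectors (n >= 3).
#' @return list with `k`, `k_prime`, `r2`, `r0_2`, `r0_prime_2`, and a
#'   `criteria` list of logical flags (`slope_ok`, `r0_ok`, `gap_ok`,
#'   `all_pass`).
#' @export
golbraikh_tropsha <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 3L)
  if (all(y_pred == 0)) stop("all predictions are zero")
  if (stats::var(y_obs) == 0 || stats::var(y_pred) == 0) {
    stop("zero variance in observations or predictions")
  }
  r2 <- stats::cor(y_obs, y_pred)^2
  # y_obs = k * y_pred through the origin
  k <- sum(y_obs * y_pred) / sum(y_pred^2)
  # y_pred = k' * y_obs through the origin
  k_prime <- sum(y_obs * y_pred) / sum(y_obs^2)
  r0_2 <- 1 - sum((y_obs - k * y_pred)^2) / sum((y_obs - mean(y_obs))^2)
  r0_prime_2 <- 1 - sum((y_pred - k_prime * y_obs)^2) /
    sum((y_pred - mean(y_pred))^2)
  slope_ok <- (k >= 0.85 && k <= 1.15) || (k_prime >= 0.85 && k_prime <= 1.15)
  r0_ok <- ((r2 - r0_2) / r2 < 0.1) || ((r2 - r0_prime_2) / r2 < 0.1)
  gap_ok <- abs(r0_2 - r0_prime_2) < 0.3
  list(k = k, k_prime = k_prime, r2 = r2, r0_2 = r0_2,
       r0_prime_2 = r0_prime_2,
       criteria = list(slope_ok = slope_ok, r0_ok = r0_ok, gap_ok = gap_ok,
                       all_pass = slope_ok && r0_ok && gap_ok))
}

# Roy rm2 metrics: rm2 = r2 * (1 - sqrt(r2 - r0^2)), with rm2' exchanging
# the axes of the through-origin fit. delta rm2 is the absolute difference.
rm2_metrics <- function(y_obs, y_pred) {
  gt <- golbraikh_tropsha(y_obs, y_pred)
  clamp0 <- function(x) max(x, 0)
  rm2 <- gt$r2 * (1 - sqrt(clamp0(gt$r2 - gt$r0_2)))
  rm2p <- gt$r2 * (1 - sqrt(clamp0(gt$r2 - gt$r0_prime_2)))
  list(rm2 = rm2, rm2_prime = rm2p, rm2_bar = (rm2 + rm2p) / 2,
       delta_rm2 = abs(rm2 - rm2p))
}

#' Lin's concordance correlation coefficient
#'
#' @param y_obs,y_pred equal-length numeric vectors.
#' @return CCC in \[-1, 1\]; symmetric in its arguments.
#' @export
lin_ccc <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 2L)
  n <- length(y_obs)
  mo <- mean(y_obs); mp <- mean(y_pred)
  2 * sum((y_obs - mo) * (y_pred - mp)) /
    (sum((y_obs - mo)^2) + sum((y_pred - mp)^2) + n * (mo - mp)^2)
}

# ---- classification ----------------------------------------------------

#' Classification external-validation report
#'
#' Confusion matrix at the probability argmax, balanced accuracy
#' (macro-averaged recall; (sensitivity + specificity)/2 for two
#' classes), the generalized (Gorodkin) Matthews correlation
#' coefficient, macro one-vs-rest ROC AUC, and macro precision /
#' recall / F1. Classes absent from `y_true` are excluded from macro
#' averages with a note.
#'
#' @param y_true true class labels.
#' @param y_proba matrix of class probabilities (rows sum to 1; column
#'   names are the class labels).
#' @param positive for two-class problems, the positive class used for
#'   ranking (defaults to the second column).
#' @return object of class `classification_report`.
#' @export
classification_report <- function(y_true, y_proba, positive = NULL) {
  y_true <- as.character(y_true)
  y_proba <- as.matrix(y_proba)
  stopifnot(nrow(y_proba) == length(y_true), !is.null(colnames(y_proba)))
  classes <- colnames(y_proba)
  stopifnot(length(unique(y_true)) >= 2L, all(y_true %in% classes))
  pred <- classes[max.col(y_proba, ties.method = "first")]
  cm <- table(factor(y_true, classes), factor(pred, classes))
  per_class <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & pred == cl)
    fn <- sum(y_true == cl & pred != cl)
    fp <- sum(y_true != cl & pred == cl)
    tn <- sum(y_true != cl & pred != cl)
    prec <- if (tp + fp == 0) NaN else tp / (tp + fp)
    rec <- if (tp + fn == 0) NaN else tp / (tp + fn)
    f1 <- if (!is.finite(prec) || !is.finite(rec) || prec + rec == 0) NaN
      else 2 * prec * rec / (prec + rec)
    list(TP = tp, FN = fn, FP = fp, TN = tn,
         precision = prec, recall = rec, F1 = f1)
  })
  names(per_class) <- classes
  present <- classes[classes %in% y_true]
  rec_v <- vapply(per_class[present], `[[`, 0, "recall")
  prec_v <- vapply(per_class[present], `[[`, 0, "precision")
  f1_v <- vapply(per_class[present], `[[`, 0, "F1")
  ba <- mean(rec_v)
  auc <- vapply(present, function(cl) {
    truth <- as.integer(y_true == cl)
    if (length(unique(truth)) < 2L) return(NaN)
    as.numeric(pROC::auc(pROC::roc(truth, y_proba[, cl], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, 0)
  macro_auc <- mean(auc[is.finite(auc)])
  out <- list(
    confusion = cm, per_class = per_class,
    BA = ba, MCC = mcc_gorodkin(cm),
    ROC_AUC = macro_auc,
    precision = mean(prec_v[is.finite(prec_v)]),
    recall = mean(rec_v[is.finite(rec_v)]),
    F1 = mean(f1_v[is.finite(f1_v)]),
    classes = classes,
    absent_classes = setdiff(classes, present)
  )
  if (length(classes) == 2L) {
    pos <- if (is.null(positive)) classes[2L] else positive
    neg <- setdiff(classes, pos)
    out$sensitivity <- per_class[[pos]]$recall
    out$specificity <- per_class[[neg]]$recall
    out$positive <- pos
  }
  class(out) <- "classification_report"
  out
}

# Generalized (Gorodkin) Matthews correlation over a k x k confusion matrix.
mcc_gorodkin <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  trace <- sum(diag(cm))
  rows <- rowSums(cm); cols <- colSums(cm)
  num <- trace * n - sum(rows * cols)
  den <- sqrt(n^2 - sum(cols^2)) * sqrt(n^2 - sum(rows^2))
  if (den == 0) return(0)
  num / den
}

#' ROC early enrichment at fixed false-positive fractions
#'
#' `EF_f` is the fraction of true actives ranked above the score at which
#' a fraction `f` of the inactives has been accepted (the true-positive
#' rate at fixed false-positive rate). Ties at the cutoff are resolved
#' pessimistically: actives scoring exactly at the threshold are counted
#' as not recovered, giving a reproducible lower bound. Under a random
#' ranking the expected EF at fraction `f` is approximately `f`.
#'
#' @param scores numeric ranking scores (higher = more active-like).
#' @param labels logical or 0/1; `TRUE`/1 marks the actives.
#' @param fractions false-positive fractions to evaluate.
#' @return named numeric vector of EF values in \[0, 1\]; fractions for
#'   which there are too few inactives are `NA`.
#' @export
roc_enrichment <- function(scores, labels,
                           fractions = c(0.005, 0.01, 0.02, 0.05)) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), any(labels), any(!labels))
  act <- scores[labels]
  dec <- sort(scores[!labels], decreasing = TRUE)
  n_dec <- length(dec)
  out <- vapply(fractions, function(f) {
    k <- floor(f * n_dec)
    if (n_dec < 1 / f) return(NA_real_)
    thr <- if (k == 0L) dec[1L] else dec[k]
    if (k == 0L) {
      # no false positives allowed: must beat the top inactive
      mean(act > thr)
    } else {
      mean(act > thr)
    }
  }, 0)
  names(out) <- paste0("EF_", fractions * 100, "pct")
  out
}

# ---- decoys ------------------------------------------------------------

#' Select property-matched, topologically dissimilar decoys
#'
#' For each active, picks from the candidate pool the compounds closest
#' in z-scored physicochemical space (MW, logP, HBD, HBA, rotatable
#' bonds, net charge) whose maximum ECFP4 Tanimoto similarity to any
#' active stays below the dissimilarity cutoff. If the constraint is
#' infeasible the cutoff is relaxed in steps of 0.05 with a warning.
#'
#' @param actives SMILES of the active molecules.
#' @param candidate_pool SMILES of candidate decoys.
#' @param per_active decoys requested per active (default 40).
#' @param seed integer seed (ties in the property distance are broken
#'   reproducibly).
#' @param tanimoto_cutoff maximum allowed similarity to any active.
#' @return character vector of decoy SMILES of length
#'   `per_active * length(actives)`.
#' @export
generate_decoys <- function(actives, candidate_pool, per_active = 40L,
                            seed, tanimoto_cutoff = 0.3) {
  if (missing(seed)) stop("a decoy-selection seed is required")
  n_req <- per_active * length(actives)
  stopifnot(length(candidate_pool) >= n_req)
  afp <- fingerprint_matrix(actives, "ECFP4")
  cfp <- fingerprint_matrix(candidate_pool, "ECFP4")
  max_sim <- apply(tanimoto_cross(cfp, afp), 1L, max)
  props <- c("MW", "logP", "HBD", "HBA", "rotB", "charge")
  pa <- as.matrix(physchem_profile(actives)[, props])
  pc <- as.matrix(physchem_profile(candidate_pool)[, props])
  mu <- colMeans(pc); sdv <- apply(pc, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  za <- scale(pa, mu, sdv); zc <- scale(pc, mu, sdv)
  cutoff <- tanimoto_cutoff
  eligible <- max_sim < cutoff
  while (sum(eligible) < n_req && cutoff < 1) {
    cutoff <- cutoff + 0.05
    warning("decoy dissimilarity constraint infeasible; relaxing the ",
            "Tanimoto cutoff to ", cutoff)
    eligible <- max_sim < cutoff
  }
  if (sum(eligible) < n_req) stop("candidate pool cannot satisfy the request")
  rng <- local_rng(seed)
  taken <- logical(length(candidate_pool))
  out <- character(0)
  for (i in seq_along(actives)) {
    d2 <- colSums((t(zc) - za[i, ])^2)
    d2[!eligible | taken] <- Inf
    jitter <- rng$runif(length(d2)) * 1e-9  # reproducible tie-break
    pick <- order(d2 + jitter)[seq_len(per_active)]
    taken[pick] <- TRUE
    out <- c(out, candidate_pool[pick])
  }
  out
}

#' Evaluate a classifier on test actives merged with decoys
#'
#' Rebuilds the virtual-screening benchmark: test-set actives plus
#' property-matched decoys labelled inactive (1:40 by construction when
#' `per_active = 40`). Returns the classification report and enrichment
#' factors computed on all predictions, and the same restricted to
#' predictions outside the indeterminate probability zone.
#'
#' @param model a trained model from [tune_and_train()].
#' @param active_smiles test-set active SMILES.
#' @param decoy_smiles decoy SMILES (labelled with the inactive class).
#' @param active_class,inactive_class label names used by the model.
#' @return list with `all` and `in_domain`, each containing `report` and
#'   `enrichment`, plus `n_total` and `n_in_domain`.
#' @export
evaluate_on_decoys <- function(model, active_smiles, decoy_smiles,
                               active_class = "ACTIVE",
                               inactive_class = "INACTIVE") {
  smiles <- c(active_smiles, decoy_smiles)
  truth <- c(rep(active_class, length(active_smiles)),
             rep(inactive_class, length(decoy_smiles)))
  proba <- predict_qsar(model, smiles = smiles)
  scores <- proba[, active_class]
  conf <- in_confidence_zone(model$task, proba)
  mk <- function(idx) {
    list(
      report = classification_report(truth[idx], proba[idx, , drop = FALSE],
                                     positive = active_class),
      enrichment = roc_enrichment(scores[idx],
                                  truth[idx] == active_class)
    )
  }
  list(all = mk(seq_along(truth)), in_domain = mk(which(conf)),
       n_total = length(truth), n_in_domain = sum(conf))
}
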