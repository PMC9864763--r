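# End-user workflows: the virtual-screening pipeline over a SMILES CSV,
# the per-compound analyzer combining all four production models, and the
# end-to-end curate/featurize/train/validate pipeline.

#' Screen a SMILES library with a binary activity model
#'
#' Reads a CSV with a `smiles` column (and optional `compound_id`),
#' standardizes each structure, predicts the active-class probability
#' with the supplied binary model, assigns the "Yes"/"No" label at the
#' 0.5 threshold and an applicability flag from the indeterminate
#' probability zone. Invalid rows go to a `*.rejects.csv` sidecar.
#' Processing is chunked so large libraries stream through.
#'
#' @param input_csv path to the screening library.
#' @param model a trained binary model (or a bundle directory path).
#' @param output_csv path for the results table.
#' @param active_class label of the active class (default "ACTIVE").
#' @param chunk_size rows per processing chunk.
#' @return the output table, invisibly.
#' @export
vs_screen <- function(input_csv, model, output_csv,
                      active_class = "ACTIVE", chunk_size = 5000L) {
  if (is.character(model)) model <- load_model_bundle(model)
  stopifnot(inherits(model, "trained_model"), model$task == "BINARY")
  hdr <- utils::read.csv(input_csv, nrows = 1L, check.names = FALSE)
  smi_col <- grep("^smiles$", names(hdr), ignore.case = TRUE, value = TRUE)
  if (length(smi_col) != 1L) {
    stop("input must have exactly one SMILES column (header 'smiles'); ",
         "found headers: ", paste(names(hdr), collapse = ", "))
  }
  id_col <- grep("^(compound_)?id$", names(hdr), ignore.case = TRUE,
                 value = TRUE)[1L]
  raw <- utils::read.csv(input_csv, check.names = FALSE,
                         stringsAsFactors = FALSE)
  n <- nrow(raw)
  ids <- if (!is.na(id_col)) as.character(raw[[id_col]]) else
    sprintf("ROW%06d", seq_len(n))
  out_rows <- list(); rej_rows <- list()
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    smi <- as.character(raw[[smi_col]][idx])
    can <- standardize_smiles(smi)
    ok <- !is.na(can)
    if (any(!ok)) {
      rej_rows[[length(rej_rows) + 1L]] <- data.frame(
        compound_id = ids[idx][!ok], smiles = smi[!ok],
        reason = "unparsable_smiles", stringsAsFactors = FALSE)
    }
    if (any(ok)) {
      proba <- predict_qsar(model, smiles = can[ok])
      p_act <- proba[, active_class]
      conf <- in_confidence_zone("BINARY", proba)
      out_rows[[length(out_rows) + 1L]] <- data.frame(
        compound_id = ids[idx][ok], canonical_smiles = can[ok],
        probability = p_act,
        label = ifelse(p_act > 0.5, "Yes", "No"),
        ad_flag = ifelse(conf, "in", "out"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(out_rows)) do.call(rbind, out_rows) else
    data.frame(compound_id = character(), canonical_smiles = character(),
               probability = numeric(), label = character(),
               ad_flag = character())
  utils::write.csv(out, output_csv, row.names = FALSE)
  rej <- if (length(rej_rows)) do.call(rbind, rej_rows) else
    data.frame(compound_id = character(), smiles = character(),
               reason = character())
  utils::write.csv(rej, paste0(sub("\\.csv$", "", output_csv),
                               ".rejects.csv"), row.names = FALSE)
  invisible(out)
}

#' Per-compound analysis with the four production models
#'
#' For each input compound: binary active probability with Yes/No label
#' and confidence-zone flag, predicted pIC50 with the leverage
#' applicability verdict, SIRT1/2 and SIRT2/3 selectivity class
#' probabilities with confidence flags, the most similar reference
#' compound (ECFP4 Tanimoto), atom-contribution maps for the binary and
#' regression models, and min-max scaled radar summary values.
#'
#' @param smiles character vector of SMILES.
#' @param bundles named list with elements `binary`, `regression`,
#'   `sirt12`, `sirt23` (trained models or bundle directories) and
#'   optionally `leverage_domain` (for the regression AD) and
#'   `reference_library` (data.frame with `compound_id`, `smiles`).
#' @param with_maps compute atom-contribution maps (default TRUE).
#' @param active_class label of the binary active class.
#' @return list of per-compound prediction records; empty input gives an
#'   empty list.
#' @export
analyze_compounds <- function(smiles, bundles, with_maps = TRUE,
                              active_class = "ACTIVE") {
  needed <- c("binary", "regression", "sirt12", "sirt23")
  missing_b <- setdiff(needed, names(bundles))
  if (length(missing_b)) {
    stop("missing model bundle(s): ", paste(missing_b, collapse = ", "))
  }
  mods <- lapply(bundles[needed], function(b) {
    if (is.character(b)) load_model_bundle(b) else b
  })
  if (length(smiles) == 0L) return(list())
  can <- standardize_smiles(smiles)
  ok <- !is.na(can)
  reflib <- bundles$reference_library
  ref_fp <- if (!is.null(reflib)) {
    fingerprint_matrix(reflib$smiles, "ECFP4")
  } else NULL
  lapply(seq_along(smiles), function(i) {
    if (!ok[i]) {
      return(list(input_smiles = smiles[i], error = "unparsable_smiles"))
    }
    s <- can[i]
    pb <- predict_qsar(mods$binary, smiles = s)
    p_act <- pb[1L, active_class]
    pr <- predict_qsar(mods$regression, smiles = s)
    p12 <- predict_qsar(mods$sirt12, smiles = s)
    p23 <- predict_qsar(mods$sirt23, smiles = s)
    lev <- if (!is.null(bundles$leverage_domain)) {
      X <- apply_feature_state(mods$regression$feature_state, s)
      leverage_of(bundles$leverage_domain, X)
    } else NULL
    nn <- if (!is.null(reflib)) {
      tanimoto_nearest(s, reflib$smiles, reflib$compound_id,
                       library_fp = ref_fp)
    } else NULL
    radar <- c(
      active_probability = unname(p_act),
      pIC50_scaled = unname(min(max((pr[1L] - 4) / 4, 0), 1)),
      sirt12_selective = unname(p12[1L, "SELECTIVE"]),
      sirt23_selective = unname(p23[1L, "SELECTIVE"])
    )
    list(
      input_smiles = smiles[i], canonical_smiles = s,
      binary = list(probability = unname(p_act),
                    label = if (p_act > 0.5) "Yes" else "No",
                    confident = unname(in_confidence_zone("BINARY", pb))),
      regression = list(
        pIC50 = unname(pr[1L]),
        leverage = if (!is.null(lev)) lev$leverage else NA_real_,
        ad_flag = if (!is.null(lev)) {
          if (lev$in_domain) "in" else "out"
        } else NA_character_
      ),
      sirt12 = list(probabilities = p12[1L, ],
                    predicted = colnames(p12)[which.max(p12[1L, ])],
                    confident = unname(in_confidence_zone("MULTICLASS", p12))),
      sirt23 = list(probabilities = p23[1L, ],
                    predicted = colnames(p23)[which.max(p23[1L, ])],
                    confident = unname(in_confidence_zone("MULTICLASS", p23))),
      nearest_reference = nn,
      radar = radar,
      maps = if (with_maps) {
        list(binary = similarity_map(mods$binary, s,
                                     class_of_interest = "ACTIVE"),
             regression = similarity_map(mods$regression, s))
      } else NULL
    )
  })
}

#' Run the full model-building pipeline on a curated record set
#'
#' Executes curate -> encode -> split -> featurize -> (rebalance) ->
#' tune/train -> internal + external validation -> decoy evaluation ->
#' applicability-domain fitting, and returns a machine-readable report
#' together with the trained bundles. Stages mirror a production QSAR
#' protocol: a binary SIRT2 activity model for screening, a pIC50
#' regression model for potency analysis, and two three-class
#' selectivity models.
#'
#' @param raw raw activity records (the ingest CSV schema), e.g. from
#'   [generate_synthetic_sar()].
#' @param seed master seed; stage seeds derive from it.
#' @param budget tuner budget per model.
#' @param feature_type feature block for all models (default ECFP4).
#' @param algorithms named list of algorithm per task (defaults:
#'   binary/selectivity random forest, regression gradient-boosted trees).
#' @param n_scramble Y-scrambling repetitions (default 20; 0 disables).
#' @param decoy_per_active decoys per active for the enrichment
#'   benchmark; `decoy_max_actives` caps the actives used.
#' @param decoy_max_actives cap on test actives entering the benchmark.
#' @param out_dir optional directory; when given, model bundles and the
#'   JSON run report are persisted there.
#' @return list with `models`, `reports`, `leverage_domain`, `report`
#'   (the run summary) and `datasets`.
#' @export
run_pipeline <- function(raw, seed = 1L, budget = 6L,
                         feature_type = "ECFP4",
                         algorithms = list(binary = "RANDOM_FOREST",
                                           regression = "GRADIENT_BOOSTED_TREES",
                                           sirt12 = "RANDOM_FOREST",
                                           sirt23 = "RANDOM_FOREST"),
                         n_scramble = 20L,
                         decoy_per_active = 40L,
                         decoy_max_actives = 10L,
                         out_dir = NULL) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    res <- try(expr, silent = TRUE)
    if (inherits(res, "try-error")) {
      stop("pipeline stage '", name, "' failed: ",
           attr(res, "condition")$message)
    }
    res
  }
  cur <- stage("curate", curate_activity_data(raw))
  ds <- stage("encode", encode_datasets(cur$records))

  fit_one <- function(tbl, task, algorithm, seed_off) {
    labels <- if (task == "REGRESSION") tbl$label else tbl$label
    split <- stratified_split(labels, 0.3, seed = seed + seed_off)
    tr <- split == "TRAIN"
    fb <- feature_block(tbl$canonical_smiles[tr], feature_type,
                        labels = labels[tr], seed = seed + seed_off)
    spec <- model_spec(algorithm, task, feature_type, budget = budget,
                       seed = seed + seed_off)
    model <- tune_and_train(spec, fb$X, labels[tr],
                            feature_state = fb$state,
                            rebalance = task != "REGRESSION")
    Xte <- apply_feature_state(fb$state, tbl$canonical_smiles[!tr])
    list(model = model, fb = fb, split = split, X_test = Xte,
         y_train = labels[tr], y_test = labels[!tr],
         smiles_train = tbl$canonical_smiles[tr],
         smiles_test = tbl$canonical_smiles[!tr])
  }

  reg <- stage("train_regression",
               fit_one(ds$regression, "REGRESSION",
                       algorithms$regression, 11L))
  bin <- stage("train_binary",
               fit_one(ds$binary, "BINARY", algorithms$binary, 12L))
  s12 <- stage("train_sirt12",
               fit_one(ds$sirt12, "MULTICLASS", algorithms$sirt12, 13L))
  s23 <- stage("train_sirt23",
               fit_one(ds$sirt23, "MULTICLASS", algorithms$sirt23, 14L))

  reg_report <- stage("validate_regression", regression_report(
    reg$y_test, predict_qsar(reg$model, reg$X_test), reg$y_train))
  clf_report <- function(m) {
    classification_report(m$y_test, predict_qsar(m$model, m$X_test))
  }
  bin_report <- stage("validate_binary", clf_report(bin))
  s12_report <- stage("validate_sirt12", clf_report(s12))
  s23_report <- stage("validate_sirt23", clf_report(s23))

  scramble <- if (n_scramble > 0L) {
    stage("y_scramble", y_scramble(
      reg$model, reg$fb$X, reg$y_train, n_reps = n_scramble,
      seed = seed + 21L))
  } else NULL

  decoy_eval <- stage("decoy_benchmark", {
    test_actives <- bin$smiles_test[bin$y_test == "ACTIVE"]
    use <- utils::head(test_actives, decoy_max_actives)
    pool <- generate_decoy_pool(50L * decoy_per_active * length(use),
                                seed = seed + 31L)
    pool <- unique(pool[is_valid_smiles(pool)])
    decoys <- generate_decoys(use, pool, per_active = decoy_per_active,
                              seed = seed + 32L)
    evaluate_on_decoys(bin$model, use, decoys)
  })

  lev <- stage("leverage_domain", fit_leverage_domain(
    reg$model, reg$fb$X, reg$y_train, seed = seed + 41L))
  test_lev <- leverage_of(lev, reg$X_test)

  report <- list(
    curation = cur$log,
    dataset_sizes = lapply(ds, nrow),
    regression = c(
      reg_report[c("Rext2", "RMSEext", "QF1_2", "QF2_2", "QF3_2",
                   "rm2_bar", "delta_rm2", "CCC")],
      list(R2_train = reg$model$cv_stats$R2_train,
           Q2 = reg$model$cv_stats$Q2,
           quality_gates = reg$model$quality_gates,
           criteria = reg_report$criteria,
           n_test_out_of_domain = sum(!test_lev$in_domain))
    ),
    binary = list(BA = bin_report$BA, MCC = bin_report$MCC,
                  ROC_AUC = bin_report$ROC_AUC, F1 = bin_report$F1),
    sirt12 = list(BA = s12_report$BA, MCC = s12_report$MCC),
    sirt23 = list(BA = s23_report$BA, MCC = s23_report$MCC),
    decoys = list(
      n_total = decoy_eval$n_total,
      n_in_domain = decoy_eval$n_in_domain,
      enrichment = as.list(decoy_eval$all$enrichment),
      enrichment_in_domain = as.list(decoy_eval$in_domain$enrichment),
      BA = decoy_eval$all$report$BA,
      BA_in_domain = decoy_eval$in_domain$report$BA
    ),
    scramble = if (!is.null(scramble)) {
      list(mean_scrambled = mean(scramble$scrambled),
           max_scrambled = max(scramble$scrambled),
           true_stat = scramble$true_stat,
           statistic = scramble$statistic)
    } else NULL,
    leverage = list(h_star = lev$h_star, m = lev$m, p = lev$p),
    seed = seed,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  artifacts <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(binary = file.path(out_dir, "binary"),
               regression = file.path(out_dir, "regression"),
               sirt12 = file.path(out_dir, "sirt12"),
               sirt23 = file.path(out_dir, "sirt23"))
    save_model_bundle(bin$model, paths[["binary"]])
    save_model_bundle(reg$model, paths[["regression"]])
    save_model_bundle(s12$model, paths[["sirt12"]])
    save_model_bundle(s23$model, paths[["sirt23"]])
    report$artifacts <- as.list(paths)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    artifacts <- paths
  }
  list(
    models = list(binary = bin$model, regression = reg$model,
                  sirt12 = s12$model, sirt23 = s23$model),
    reports = list(regression = reg_report, binary = bin_report,
                   sirt12 = s12_report, sirt23 = s23_report),
    scramble = scramble, decoy_eval = decoy_eval,
    leverage_domain = lev, report = report, datasets = ds,
    artifacts = artifacts
  )
}
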