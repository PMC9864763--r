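# Dataset curation: ingest raw structure-activity tables, standardize and
# deduplicate structures, encode activities into regression targets and
# activity / selectivity classes, split and rebalance.

ISOFORMS <- c("SIRT1", "SIRT2", "SIRT3")
RECORD_KINDS <- c("IC50", "PERCENT_INHIBITION")

#' Convert IC50 to pIC50
#'
#' `pIC50 = -log10(IC50 [mol/L])`; an IC50 of 10 uM gives 5.0.
#'
#' @param ic50_uM positive IC50 values in micromolar.
#' @return pIC50 values.
#' @export
to_pic50 <- function(ic50_uM) {
  if (any(!is.finite(ic50_uM)) || any(ic50_uM <= 0)) {
    stop("IC50 values must be finite and > 0")
  }
  -log10(ic50_uM * 1e-6)
}

#' Convert pIC50 back to IC50 in micromolar
#' @param pic50 pIC50 values.
#' @return IC50 in uM.
#' @export
from_pic50 <- function(pic50) 10^(6 - pic50)

# units accepted on input; values stored internally in uM
IC50_UNIT_FACTOR <- c(uM = 1, nM = 1e-3, M = 1e6)

#' Assign the SIRT2 activity class of a single retained record
#'
#' Encodes the study's activity rules. ACTIVE iff IC50 <= 50 uM, or
#' Inh% >= 80 at 200 uM, or Inh% >= 70 at 100 uM, or Inh% >= 60 at
#' 50-100 uM, or Inh% >= 50 below 50 uM. INACTIVE iff IC50 >= 90 uM, or
#' Inh% <= 40 assayed above 100 uM. Everything else falls in the twilight
#' zone (e.g. IC50 in 50-90 uM, Inh% 40-80 at 200 uM) and is excluded
#' from classification datasets.
#'
#' @param kind `"IC50"` or `"PERCENT_INHIBITION"` (vectorized).
#' @param value IC50 in uM, or percent inhibition.
#' @param assay_conc_uM assay concentration in uM; required for
#'   percent-inhibition records.
#' @return character vector in `c("ACTIVE", "INACTIVE", "TWILIGHT")`.
#' @export
assign_sirt2_class <- function(kind, value, assay_conc_uM = NA_real_) {
  n <- max(length(kind), length(value))
  kind <- rep_len(kind, n); value <- rep_len(value, n)
  assay_conc_uM <- rep_len(assay_conc_uM, n)
  if (!all(kind %in% RECORD_KINDS)) stop("unknown record kind")
  if (any(kind == "PERCENT_INHIBITION" & !is.finite(assay_conc_uM))) {
    stop("percent-inhibition records require an assay concentration")
  }
  out <- character(n)
  for (i in seq_len(n)) {
    if (kind[i] == "IC50") {
      out[i] <- if (value[i] <= 50) "ACTIVE"
        else if (value[i] >= 90) "INACTIVE"
        else "TWILIGHT"
    } else {
      v <- value[i]; conc <- assay_conc_uM[i]
      active <- (conc >= 200 && v >= 80) ||
        (conc >= 100 && conc < 200 && v >= 70) ||
        (conc >= 50 && conc < 100 && v >= 60) ||
        (conc < 50 && v >= 50)
      inactive <- conc > 100 && v <= 40
      out[i] <- if (active) "ACTIVE" else if (inactive) "INACTIVE"
        else "TWILIGHT"
    }
  }
  out
}

#' Assign the isoform-selectivity class
#'
#' Combines the SIRT2 activity class with the class on an off-target
#' isoform (SIRT1 or SIRT3): SELECTIVE (SIRT2 active, off-target
#' inactive), NONSELECTIVE (both active), INACTIVE (both inactive).
#' Twilight records on either isoform, and the SIRT2-inactive /
#' off-target-active combination, are EXCLUDED.
#'
#' @param sirt2_class,offtarget_class vectors of activity classes.
#' @return character vector in
#'   `c("SELECTIVE", "NONSELECTIVE", "INACTIVE", "EXCLUDED")`.
#' @export
assign_selectivity_class <- function(sirt2_class, offtarget_class) {
  n <- max(length(sirt2_class), length(offtarget_class))
  s2 <- rep_len(sirt2_class, n); off <- rep_len(offtarget_class, n)
  ifelse(s2 == "ACTIVE" & off == "INACTIVE", "SELECTIVE",
  ifelse(s2 == "ACTIVE" & off == "ACTIVE", "NONSELECTIVE",
  ifelse(s2 == "INACTIVE" & off == "INACTIVE", "INACTIVE", "EXCLUDED")))
}

#' Deduplicate activity records per compound and isoform
#'
#' Groups standardized records by (parent canonical SMILES, isoform). If a
#' group mixes IC50 and percent-inhibition records, the IC50 records take
#' precedence and the Inh% records are discarded. Among same-kind
#' duplicates the record whose value lies closest to the group mean is
#' retained; ties are broken in favor of the more potent record (smaller
#' IC50, larger Inh%).
#'
#' @param records data.frame with columns `compound_id`, `canonical_smiles`,
#'   `isoform`, `kind`, `value`, `assay_conc_uM`, `source`.
#' @return data.frame with one retained record per (compound, isoform).
#' @export
deduplicate_records <- function(records) {
  req <- c("canonical_smiles", "isoform", "kind", "value")
  stopifnot(all(req %in% names(records)))
  if (!"assay_conc_uM" %in% names(records)) records$assay_conc_uM <- NA_real_
  key <- paste(records$canonical_smiles, records$isoform, sep = "\r")
  picked <- vapply(split(seq_len(nrow(records)), key), function(idx) {
    g <- records[idx, ]
    if (any(g$kind == "IC50")) {
      idx <- idx[g$kind == "IC50"]
      g <- records[idx, ]
    }
    dev <- abs(g$value - mean(g$value))
    cand <- idx[dev == min(dev)]
    if (length(cand) > 1L) {
      vals <- records$value[cand]
      cand <- if (g$kind[1L] == "IC50") cand[which.min(vals)]
        else cand[which.max(vals)]
    }
    cand[1L]
  }, 0L)
  out <- records[sort(unname(picked)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Curate a raw activity table
#'
#' Full ingest path: validates rows, standardizes structures (salt
#' stripping, charge neutralization, canonicalization), converts IC50
#' units to uM, deduplicates per (compound, isoform) and attaches
#' activity classes. Rejected rows are returned with reason codes rather
#' than raising errors.
#'
#' @param raw data.frame with columns `compound_id`, `smiles`, `isoform`,
#'   `kind`, `value`, optional `unit` (uM/nM/M, default uM),
#'   `assay_conc_uM`, `source`.
#' @return list with `records` (curated, deduplicated, with
#'   `canonical_smiles` and `activity_class`), `rejects` (rows + `reason`),
#'   and `log` (counts per curation rule and the class histogram).
#' @export
curate_activity_data <- function(raw) {
  stopifnot(is.data.frame(raw))
  req <- c("compound_id", "smiles", "isoform", "kind", "value")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"unit" %in% names(raw)) raw$unit <- "uM"
  if (!"assay_conc_uM" %in% names(raw)) raw$assay_conc_uM <- NA_real_
  if (!"source" %in% names(raw)) raw$source <- ""
  raw$unit[is.na(raw$unit) | raw$unit == ""] <- "uM"
  n0 <- nrow(raw)
  reason <- rep(NA_character_, n0)
  bad <- function(cond, code) {
    reason[is.na(reason) & cond] <<- code
  }
  bad(!raw$isoform %in% ISOFORMS, "bad_isoform")
  bad(!raw$kind %in% RECORD_KINDS, "bad_kind")
  bad(!is.finite(raw$value) | raw$value < 0, "bad_value")
  bad(raw$kind == "IC50" & !raw$unit %in% names(IC50_UNIT_FACTOR),
      "bad_unit")
  bad(raw$kind == "PERCENT_INHIBITION" & !is.finite(raw$assay_conc_uM),
      "missing_assay_conc")
  can <- rep(NA_character_, n0)
  todo <- is.na(reason)
  can[todo] <- standardize_smiles(as.character(raw$smiles[todo]))
  bad(is.na(can), "unparsable_smiles")
  ok <- is.na(reason)
  rec <- raw[ok, , drop = FALSE]
  rec$canonical_smiles <- can[ok]
  fac <- IC50_UNIT_FACTOR[rec$unit]
  rec$value <- ifelse(rec$kind == "IC50", rec$value * fac, rec$value)
  rec$unit <- ifelse(rec$kind == "IC50", "uM", rec$unit)
  rec$assay_conc_uM <- ifelse(rec$kind == "IC50", NA_real_,
                              rec$assay_conc_uM)
  n_valid <- nrow(rec)
  rec <- deduplicate_records(rec)
  rec$activity_class <- assign_sirt2_class(rec$kind, rec$value,
                                           rec$assay_conc_uM)
  rejects <- raw[!ok, , drop = FALSE]
  rejects$reason <- reason[!ok]
  log <- list(
    n_input = n0,
    n_rejected = sum(!ok),
    reject_reasons = as.list(table(reason[!ok])),
    n_valid = n_valid,
    n_removed_duplicates = n_valid - nrow(rec),
    n_retained = nrow(rec),
    class_histogram = as.list(table(rec$activity_class))
  )
  list(records = rec, rejects = rejects, log = log)
}

#' Read a raw activity CSV and curate it
#'
#' Expects the header
#' `compound_id, smiles, isoform, kind, value, unit, assay_conc_uM, source`.
#' Rejected rows are written next to the input as `<name>.rejects.csv`
#' with reason codes; the curation log is written as `<name>.curation.json`.
#'
#' @param path input CSV path.
#' @param write_sidecars write the rejects CSV and JSON log (default TRUE).
#' @return the [curate_activity_data()] result, invisibly.
#' @export
read_activity_csv <- function(path, write_sidecars = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- curate_activity_data(raw)
  if (write_sidecars) {
    base <- sub("\\.csv$", "", path)
    utils::write.csv(out$rejects, paste0(base, ".rejects.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out$log, paste0(base, ".curation.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}

#' Build encoded datasets from curated records
#'
#' Produces the four modeling tables from one curated record set:
#' regression (pIC50 on SIRT2 IC50 records), binary SIRT2
#' active/inactive (twilight excluded), and the SIRT1/2 and SIRT2/3
#' three-class selectivity tables (EXCLUDED dropped).
#'
#' @param records curated records from [curate_activity_data()].
#' @return list of data.frames `regression`, `binary`, `sirt12`, `sirt23`,
#'   each with `canonical_smiles` and `label`.
#' @export
encode_datasets <- function(records) {
  s2 <- records[records$isoform == "SIRT2", ]
  reg <- s2[s2$kind == "IC50" & s2$value > 0, ]
  regression <- data.frame(canonical_smiles = reg$canonical_smiles,
                           label = to_pic50(reg$value),
                           stringsAsFactors = FALSE)
  bin <- s2[s2$activity_class != "TWILIGHT", ]
  binary <- data.frame(canonical_smiles = bin$canonical_smiles,
                       label = bin$activity_class,
                       stringsAsFactors = FALSE)
  sel_table <- function(off_iso) {
    off <- records[records$isoform == off_iso, ]
    common <- intersect(s2$canonical_smiles, off$canonical_smiles)
    if (!length(common)) {
      return(data.frame(canonical_smiles = character(),
                        label = character(), stringsAsFactors = FALSE))
    }
    a <- s2$activity_class[match(common, s2$canonical_smiles)]
    b <- off$activity_class[match(common, off$canonical_smiles)]
    lab <- assign_selectivity_class(a, b)
    keep <- lab != "EXCLUDED"
    data.frame(canonical_smiles = common[keep], label = lab[keep],
               stringsAsFactors = FALSE)
  }
  list(regression = regression, binary = binary,
       sirt12 = sel_table("SIRT1"), sirt23 = sel_table("SIRT3"))
}

#' Stratified train/test split
#'
#' Classification labels are stratified directly; regression labels are
#' binned into equal-frequency quantile bins (default 5) first. Per
#' stratum, the test proportion matches the requested fraction to within
#' one compound. Deterministic under a fixed seed.
#'
#' @param labels class labels or numeric regression labels.
#' @param test_fraction fraction assigned to TEST (0 < f < 1).
#' @param seed integer seed (required; no hidden global randomness).
#' @param n_bins quantile bins for numeric labels.
#' @return character vector `"TRAIN"`/`"TEST"` aligned with `labels`.
#' @export
stratified_split <- function(labels, test_fraction = 0.3, seed,
                             n_bins = 5L) {
  stopifnot(length(labels) >= 10L,
            test_fraction > 0, test_fraction < 1)
  if (missing(seed)) stop("a split seed is required")
  if (is.numeric(labels)) {
    qs <- stats::quantile(labels, probs = seq(0, 1, length.out = n_bins + 1L),
                          type = 7)
    qs <- unique(qs)
    strata <- cut(labels, breaks = qs, include.lowest = TRUE,
                  labels = FALSE)
    # merge singleton bins with their lower neighbor
    tab <- table(strata)
    while (any(tab < 2L) && length(tab) > 1L) {
      small <- as.integer(names(tab)[tab < 2L][1L])
      strata[strata == small] <- if (small > 1L) small - 1L else small + 1L
      strata <- match(strata, sort(unique(strata)))
      tab <- table(strata)
    }
  } else {
    strata <- as.character(labels)
    if (any(table(strata) < 2L)) {
      stop("every class must have at least 2 members to stratify")
    }
  }
  out <- rep("TRAIN", length(labels))
  rng <- local_rng(seed)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_test <- round(length(idx) * test_fraction)
    take <- idx[rng$sample(length(idx))][seq_len(n_test)]
    out[take] <- "TEST"
  }
  out
}

# Seeded RNG scoped away from the session RNG state.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
          assign(".Random.seed", old, envir = globalenv())
      })
      f(...)
    }
  }
  list(
    sample = with_state(sample),
    runif = with_state(stats::runif),
    rnorm = with_state(stats::rnorm),
    run = with_state(function(f, ...) f(...))
  )
}

#' SMOTE oversampling of minority classes
#'
#' Synthetic minority rows are interpolated between a minority instance
#' and one of its k nearest minority neighbors until every class reaches
#' the majority count. Only training rows may be passed in; synthetic
#' rows are flagged in the result.
#'
#' @param X numeric feature matrix (train rows only).
#' @param labels class labels aligned with the rows of `X`.
#' @param k neighbor count (default 5); reduced with a warning when a
#'   class is smaller than `k + 1`.
#' @param seed integer seed.
#' @return list with `X` (augmented matrix), `labels`, and `synthetic`
#'   (logical flag per row).
#' @export
rebalance_train <- function(X, labels, k = 5L, seed) {
  if (missing(seed)) stop("a rebalancing seed is required")
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(labels))
  labels <- as.character(labels)
  counts <- table(labels)
  target <- max(counts)
  rng <- local_rng(seed)
  add_X <- list(); add_y <- character()
  for (cls in names(counts)) {
    need <- target - counts[[cls]]
    if (need == 0L) next
    idx <- which(labels == cls)
    Xc <- X[idx, , drop = FALSE]
    if (length(idx) == 1L) {
      warning("class '", cls, "' has a single member; duplicating it")
      syn <- Xc[rep(1L, need), , drop = FALSE]
      add_X[[cls]] <- syn
      add_y <- c(add_y, rep(cls, need))
      next
    }
    kk <- k
    if (length(idx) < kk + 1L) {
      kk <- max(1L, length(idx) - 1L)
      warning("class '", cls, "' has fewer than k+1 members; using k = ", kk)
    }
    d <- as.matrix(stats::dist(Xc))
    diag(d) <- Inf
    nn <- matrix(0L, nrow(Xc), kk)
    for (r in seq_len(nrow(Xc))) nn[r, ] <- order(d[r, ])[seq_len(kk)]
    base <- rng$sample(seq_along(idx), need, replace = TRUE)
    pick <- vapply(base, function(b) nn[b, rng$sample(seq_len(kk), 1L)], 0L)
    gap <- rng$runif(need)
    syn <- Xc[base, , drop = FALSE] +
      gap * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
    add_X[[cls]] <- syn
    add_y <- c(add_y, rep(cls, need))
  }
  if (length(add_X)) {
    Xa <- do.call(rbind, add_X)
    list(X = rbind(X, Xa), labels = c(labels, add_y),
         synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nrow(Xa))))
  } else {
    list(X = X, labels = labels, synthetic = rep(FALSE, nrow(X)))
  }
}
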