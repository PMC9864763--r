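# Activity encoding, deduplication, curation, splitting and rebalancing.

test_that("pIC50 conversion and its inverse", {
  expect_equal(to_pic50(10), 5)
  expect_equal(to_pic50(100), 4)       # low end of a 4-7.96 potency range
  expect_equal(to_pic50(0.011), -log10(0.011e-6))
  expect_equal(from_pic50(to_pic50(c(0.5, 3, 80))), c(0.5, 3, 80))
  expect_error(to_pic50(0), "> 0")
  expect_error(to_pic50(-1), "> 0")
})

test_that("SIRT2 activity classes follow the IC50 rules", {
  expect_identical(assign_sirt2_class("IC50", 50), "ACTIVE")
  expect_identical(assign_sirt2_class("IC50", 0.1), "ACTIVE")
  expect_identical(assign_sirt2_class("IC50", 70), "TWILIGHT")
  expect_identical(assign_sirt2_class("IC50", 89.9), "TWILIGHT")
  expect_identical(assign_sirt2_class("IC50", 90), "INACTIVE")
  expect_identical(assign_sirt2_class("IC50", 500), "INACTIVE")
})

test_that("SIRT2 activity classes follow the Inh% rules per assay conc", {
  # active thresholds step down with assay concentration
  expect_identical(assign_sirt2_class("PERCENT_INHIBITION", 80, 200), "ACTIVE")
  expect_identical(assign_sirt2_class("PERCENT_INHIBITION", 79, 200), "TWILIGHT")
  expect_identical(assign_sirt2_class("PERCENT_INHIBITION", 70, 100), "ACTIVE")
  expect_identical(assign_sirt2_class("PERCENT_INHIBITION", 60, 75), "ACTIVE")
  expect_identical(assign_sirt2_class("PERCENT_INHIBITION", 50, 25), "ACTIVE")
  # inactive only above 100 uM
  expect_identical(assign_sirt2_class("PERCENT_INHIBITION", 40, 150), "INACTIVE")
  expect_identical(assign_sirt2_class("PERCENT_INHIBITION", 40, 100), "TWILIGHT")
  expect_identical(assign_sirt2_class("PERCENT_INHIBITION", 60, 200), "TWILIGHT")
  expect_error(assign_sirt2_class("PERCENT_INHIBITION", 50, NA),
               "assay concentration")
})

test_that("activity classification is total and exclusive on a grid", {
  ic50 <- seq(0.1, 200, by = 0.1)
  cls <- assign_sirt2_class("IC50", ic50)
  expect_true(all(cls %in% c("ACTIVE", "INACTIVE", "TWILIGHT")))
  expect_identical(cls[ic50 <= 50], rep("ACTIVE", sum(ic50 <= 50)))
  expect_identical(cls[ic50 > 50 & ic50 < 90],
                   rep("TWILIGHT", sum(ic50 > 50 & ic50 < 90)))
  expect_identical(cls[ic50 >= 90], rep("INACTIVE", sum(ic50 >= 90)))
  grid <- expand.grid(v = seq(0, 100, by = 5),
                      conc = c(10, 25, 50, 75, 100, 150, 200, 400))
  cls2 <- assign_sirt2_class("PERCENT_INHIBITION", grid$v, grid$conc)
  expect_true(all(cls2 %in% c("ACTIVE", "INACTIVE", "TWILIGHT")))
})

test_that("selectivity classes combine on-target and off-target calls", {
  expect_identical(assign_selectivity_class("ACTIVE", "INACTIVE"), "SELECTIVE")
  expect_identical(assign_selectivity_class("ACTIVE", "ACTIVE"), "NONSELECTIVE")
  expect_identical(assign_selectivity_class("INACTIVE", "INACTIVE"), "INACTIVE")
  expect_identical(assign_selectivity_class("TWILIGHT", "ACTIVE"), "EXCLUDED")
  expect_identical(assign_selectivity_class("INACTIVE", "ACTIVE"), "EXCLUDED")
  expect_identical(assign_selectivity_class("ACTIVE", "TWILIGHT"), "EXCLUDED")
})

make_records <- function(values, kinds = "IC50", conc = NA_real_,
                         smiles = "CCO", isoform = "SIRT2") {
  n <- max(length(values), length(kinds))
  data.frame(compound_id = paste0("c", seq_len(n)),
             canonical_smiles = rep_len(smiles, n),
             isoform = rep_len(isoform, n), kind = rep_len(kinds, n),
             value = rep_len(values, n),
             assay_conc_uM = rep_len(conc, n),
             source = "t", stringsAsFactors = FALSE)
}

test_that("deduplication keeps the record closest to the group mean", {
  out <- deduplicate_records(make_records(c(1, 2, 6)))
  expect_identical(nrow(out), 1L)
  expect_equal(out$value, 2)          # mean 3, |2-3| minimal
})

test_that("IC50 records take precedence over Inh% in a duplicate group", {
  rec <- rbind(make_records(10),
               make_records(90, kinds = "PERCENT_INHIBITION", conc = 200))
  out <- deduplicate_records(rec)
  expect_identical(out$kind, "IC50")
  expect_equal(out$value, 10)
})

test_that("dedup ties break toward the more potent record", {
  out <- deduplicate_records(make_records(c(2, 4)))   # both 1 from mean 3
  expect_equal(out$value, 2)                          # smaller IC50
  inh <- deduplicate_records(make_records(c(40, 60),
                                          kinds = "PERCENT_INHIBITION",
                                          conc = 200))
  expect_equal(inh$value, 60)                         # larger Inh%
})

test_that("dedup is permutation-invariant and never adds compounds", {
  rec <- rbind(make_records(c(1, 2, 6), smiles = "CCO"),
               make_records(c(5, 7), smiles = "CCN"),
               make_records(55, smiles = "CCN", isoform = "SIRT1"))
  base <- deduplicate_records(rec)
  norm <- function(d) {
    d <- d[order(d$canonical_smiles, d$isoform), ]
    rownames(d) <- NULL
    d
  }
  set.seed(9)
  for (i in 1:5) {
    perm <- deduplicate_records(rec[sample(nrow(rec)), ])
    expect_identical(norm(perm), norm(base))
  }
  expect_lte(nrow(base), nrow(rec))
  expect_identical(deduplicate_records(make_records(3)),
                   make_records(3))   # single record is its own group
})

test_that("curation validates rows, converts units and logs rejects", {
  raw <- data.frame(
    compound_id = paste0("c", 1:6),
    smiles = c("CCO", "CC(=O)[O-].[Na+]", "bad()", "CCN", "CCC", "CCCC"),
    isoform = c("SIRT2", "SIRT2", "SIRT2", "SIRTX", "SIRT2", "SIRT2"),
    kind = c("IC50", "IC50", "IC50", "IC50", "PERCENT_INHIBITION", "IC50"),
    value = c(10000, 5, 1, 1, 85, -3),
    unit = c("nM", "uM", "uM", "uM", "", "uM"),
    assay_conc_uM = c(NA, NA, NA, NA, 200, NA),
    source = "t", stringsAsFactors = FALSE)
  out <- curate_activity_data(raw)
  expect_identical(sort(out$rejects$reason),
                   sort(c("unparsable_smiles", "bad_isoform", "bad_value")))
  expect_equal(out$records$value[out$records$compound_id == "c1"], 10)
  expect_identical(out$records$canonical_smiles[
    out$records$compound_id == "c2"], standardize_smiles("CC(=O)O"))
  expect_identical(out$log$n_input, 6L)
  expect_identical(out$log$n_rejected, 3L)
  expect_error(curate_activity_data(raw[, -2]), "missing required")
})

test_that("curation CSV round trip writes sidecars", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "acts.csv")
  utils::write.csv(data.frame(
    compound_id = c("a", "b"), smiles = c("CCO", "zzz"),
    isoform = "SIRT2", kind = "IC50", value = c(1, 2), unit = "uM",
    assay_conc_uM = NA, source = "t"), path, row.names = FALSE)
  out <- read_activity_csv(path)
  expect_identical(nrow(out$records), 1L)
  expect_true(file.exists(file.path(dir, "acts.rejects.csv")))
  expect_true(file.exists(file.path(dir, "acts.curation.json")))
  rej <- utils::read.csv(file.path(dir, "acts.rejects.csv"))
  expect_identical(rej$reason, "unparsable_smiles")
})

test_that("stratified split preserves class proportions within one unit", {
  labels <- rep(c("ACTIVE", "INACTIVE"), c(60, 40))
  split <- stratified_split(labels, 0.3, seed = 1)
  expect_identical(sum(split == "TEST" & labels == "ACTIVE"), 18L)
  expect_identical(sum(split == "TEST" & labels == "INACTIVE"), 12L)
  expect_identical(split, stratified_split(labels, 0.3, seed = 1))
  expect_false(identical(split, stratified_split(labels, 0.3, seed = 2)))
  expect_identical(length(split), 100L)
  expect_error(stratified_split(labels, 0.3), "seed")
})

test_that("regression splits stratify over quantile bins", {
  set.seed(4)
  y <- runif(200, 4, 8)
  split <- stratified_split(y, 0.3, seed = 3, n_bins = 4)
  bins <- cut(y, quantile(y, seq(0, 1, 0.25)), include.lowest = TRUE)
  for (b in levels(bins)) {
    n_b <- sum(bins == b)
    n_test <- sum(bins == b & split == "TEST")
    expect_lte(abs(n_test - 0.3 * n_b), 1 + 1e-9, label = b)
  }
})

test_that("SMOTE balances all classes using only the given rows", {
  set.seed(11)
  X <- matrix(rnorm(210 * 4), ncol = 4)
  y <- rep(c("A", "B", "C"), c(120, 60, 30))
  rb <- rebalance_train(X, y, seed = 2)
  expect_identical(as.integer(table(rb$labels)), rep(120L, 3))
  expect_identical(rb$synthetic, c(rep(FALSE, 210), rep(TRUE, 150)))
  # synthetic rows interpolate within their class's bounding box
  for (cl in c("B", "C")) {
    orig <- X[y == cl, ]
    syn <- rb$X[rb$synthetic & rb$labels == cl, , drop = FALSE]
    expect_true(all(syn >= matrix(apply(orig, 2, min), nrow(syn), 4,
                                  byrow = TRUE) - 1e-9))
    expect_true(all(syn <= matrix(apply(orig, 2, max), nrow(syn), 4,
                                  byrow = TRUE) + 1e-9))
  }
  # already balanced input is unchanged
  even <- rebalance_train(X[1:60, ], rep(c("A", "B"), 30), seed = 2)
  expect_identical(nrow(even$X), 60L)
  expect_false(any(even$synthetic))
  # small classes reduce the neighbor count with a warning
  expect_warning(rebalance_train(X[1:24, ], rep(c("A", "B"), c(20, 4)),
                                 seed = 2), "fewer than k\\+1")
})
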