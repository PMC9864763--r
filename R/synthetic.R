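# Synthetic structure-activity generator. Emulates the statistical
# structure of curated sirtuin inhibition datasets: mixed IC50 / percent-
# inhibition records, roughly 2:1 active:inactive balance, three-class
# selectivity labels driven by a second, independent substructure rule,
# and a planted pharmacophore signal that potency models can recover.
# Molecules are assembled from scaffold and substituent fragment libraries
# (ring-closure digits partitioned so concatenation is always valid) and
# every emitted SMILES parses.

# scaffold templates use ring digits 1-2, substituents 3-4
SCAFFOLDS <- c(
  "c1cc(%s)ccc1%s",            # 1,4-disubstituted benzene
  "c1cc(%s)cnc1%s",            # pyridine
  "c1cc(%s)oc1%s",             # furan
  "c1cc2ccccc2c(%s)c1%s",      # naphthalene
  "C(%s)N1CCC(%s)CC1",         # piperidine
  "c1sc(%s)nc1%s",             # thiazole
  "c1cc(%s)sc1%s",             # thiophene
  "O=C(%s)Nc1ccccc1%s"         # anilide
)

SUBSTITUENTS <- c(
  "", "C", "CC", "CCC", "OC", "OCC", "Cl", "F", "Br", "N", "N(C)C",
  "C(=O)N", "C(=O)NC", "C(=O)OC", "S(=O)(=O)N", "C#N", "CO", "CCO",
  "c3ccccc3", "Cc3ccccc3", "Oc3ccccc3", "c3ccc(F)cc3", "C(F)(F)F",
  "OC(F)(F)F", "c3ccco3", "c3cccs3", "CN3CCCC3", "C3CC3"
)

# activity-driving pharmacophores (attached as an extra substituent)
PHARMACOPHORES <- c(
  "c3nc4ccccc4s3",             # 2-benzothiazolyl
  "c3nc4ccccc4o3",             # 2-benzoxazolyl
  "C(=O)Nc3ccc4ccccc4c3",      # naphthylamide
  "c3cc4ccccc4[nH]3",          # 2-indolyl
  "c3nc4ccccc4[nH]3",          # 2-benzimidazolyl
  "c3ccc4ncccc4c3"             # quinolin-3-yl
)

# independent substructure that drives off-target (SIRT1/3) inhibition
SELECTIVITY_MARKERS <- c(
  "N3CCOCC3",                  # morpholine
  "S(=O)(=O)c3ccccc3"          # phenylsulfonyl
)

# decoy candidate scaffolds: topologically distinct from the active space;
# 3-slot templates keep the combinatorial pool large (> 20k unique)
DECOY_SCAFFOLDS <- c(
  "C1CC(%s)CC(%s)C1%s",        # 1,3,5-cyclohexane
  "C1CCC(%s)C(%s)C1",          # 1,2-cyclohexane
  "C(%s)C(%s)CCC%s",           # branched chain
  "C1COC(%s)C1%s",             # tetrahydrofuran
  "C1CC(%s)NC1%s",             # pyrrolidine
  "C1CC(%s)OC(%s)C1%s",        # tetrahydropyran
  "C(%s)(%s)CC%s",             # quaternary-ish branch
  "C1CCC(C(%s)%s)CC1%s"        # cyclohexyl-methine
)

assemble_smiles <- function(template, subs) {
  n_slots <- lengths(regmatches(template, gregexpr("%s", template)))
  subs <- rep_len(subs, n_slots)
  out <- do.call(sprintf, c(list(template), as.list(subs)))
  gsub("()", "", out, fixed = TRUE)
}

#' Configuration for the synthetic structure-activity generator
#'
#' @param n_compounds number of compounds to emit.
#' @param active_fraction fraction carrying the planted pharmacophore
#'   (default 0.65, roughly the 2:1 active:inactive balance of curated
#'   sirtuin datasets).
#' @param active_mean,inactive_mean mean pIC50 of the two populations
#'   (defaults 6.0 / 3.5).
#' @param noise_sd residual pIC50 noise (default 0.35); substituent
#'   effects add structured, learnable variation on top.
#' @param active_extra_sd extra potency spread among actives
#'   (default 0.4), widening the active pIC50 distribution to ~0.7 SD.
#' @param label_noise_rate fraction of compounds whose activity status is
#'   flipped before measurement (default 0).
#' @param inh_fraction fraction of records emitted as percent inhibition
#'   at a stated assay concentration instead of IC50 (default 0.25).
#' @param offtarget_fraction fraction of compounds that also receive a
#'   record on an off-target isoform (default 0.5).
#' @param selectivity_marker_fraction fraction of compounds carrying the
#'   off-target-activity substructure (default 0.35).
#' @param seed integer seed; the whole emission is reproducible.
#' @return object of class `synthetic_sar_config`.
#' @export
synthetic_sar_config <- function(n_compounds = 1500L,
                                 active_fraction = 0.65,
                                 active_mean = 6.0,
                                 inactive_mean = 3.5,
                                 noise_sd = 0.35,
                                 active_extra_sd = 0.4,
                                 label_noise_rate = 0,
                                 inh_fraction = 0.25,
                                 offtarget_fraction = 0.5,
                                 selectivity_marker_fraction = 0.35,
                                 seed = 1L) {
  stopifnot(n_compounds >= 10L,
            active_fraction > 0, active_fraction < 1,
            inh_fraction >= 0, inh_fraction < 1,
            label_noise_rate >= 0, label_noise_rate < 1)
  structure(as.list(environment()), class = "synthetic_sar_config")
}

#' Generate a synthetic structure-activity table
#'
#' Emits raw activity records in the ingest CSV schema. Compounds are
#' assembled from scaffold/substituent libraries; carrying one of the
#' planted pharmacophore fragments shifts pIC50 from the inactive to the
#' active population. Substituents contribute fixed, seed-determined
#' potency increments so potency is partly predictable from structure
#' beyond the binary signal. A configurable share of records is emitted
#' as percent inhibition at a stated assay concentration (converted with
#' a one-site binding model), exercising the full encoding rules.
#' Off-target (SIRT1/SIRT3) records are driven by an independent
#' substructure marker, yielding selective / nonselective / inactive
#' compounds.
#'
#' @param config a [synthetic_sar_config()].
#' @return data.frame of raw activity records
#'   (`compound_id, smiles, isoform, kind, value, unit, assay_conc_uM,
#'   source`) with attribute `truth` (per-compound ground truth).
#' @export
generate_synthetic_sar <- function(config = synthetic_sar_config()) {
  stopifnot(inherits(config, "synthetic_sar_config"))
  cf <- config
  rng <- local_rng(cf$seed)
  n <- cf$n_compounds
  sub_effect <- rng$runif(length(SUBSTITUENTS), -0.45, 0.45)
  sub_effect[SUBSTITUENTS == ""] <- 0
  eff_of_sub <- function(s) sub_effect[match(s, SUBSTITUENTS)]
  pharm_effect <- rng$runif(length(PHARMACOPHORES), -0.2, 0.2)
  eff_of_pharm <- function(s) pharm_effect[match(s, PHARMACOPHORES)]
  is_active <- rng$runif(n) < cf$active_fraction
  scaf <- SCAFFOLDS[rng$sample(length(SCAFFOLDS), n, replace = TRUE)]
  s1 <- SUBSTITUENTS[rng$sample(length(SUBSTITUENTS), n, replace = TRUE)]
  s2 <- SUBSTITUENTS[rng$sample(length(SUBSTITUENTS), n, replace = TRUE)]
  pharm <- PHARMACOPHORES[rng$sample(length(PHARMACOPHORES), n,
                                     replace = TRUE)]
  has_marker <- rng$runif(n) < cf$selectivity_marker_fraction
  marker <- SELECTIVITY_MARKERS[rng$sample(length(SELECTIVITY_MARKERS), n,
                                           replace = TRUE)]
  swap <- rng$runif(n) < 0.5
  smiles <- character(n)
  for (i in seq_len(n)) {
    subs <- c(
      if (is_active[i]) pharm[i] else s1[i],
      if (has_marker[i]) marker[i] else s2[i]
    )
    if (swap[i]) subs <- rev(subs)
    smiles[i] <- assemble_smiles(scaf[i], subs)
  }
  # ground-truth potency
  flip <- rng$runif(n) < cf$label_noise_rate
  eff_active <- xor(is_active, flip)
  base <- ifelse(eff_active, cf$active_mean, cf$inactive_mean)
  spread <- ifelse(eff_active, rng$rnorm(n, 0, cf$active_extra_sd), 0) +
    ifelse(is_active, eff_of_pharm(pharm), eff_of_sub(s1)) +
    ifelse(has_marker, 0, eff_of_sub(s2))
  pic50 <- base + spread + rng$rnorm(n, 0, cf$noise_sd)
  ic50 <- from_pic50(pic50)
  # off-target potency: marker carriers mirror the SIRT2 potency,
  # the rest are clearly inactive on the off-target isoform
  off_iso <- ifelse(rng$runif(n) < 0.5, "SIRT1", "SIRT3")
  off_pic50 <- ifelse(has_marker, pic50 + rng$rnorm(n, 0, 0.3),
                      rng$rnorm(n, 3.2, 0.3))
  has_off <- rng$runif(n) < cf$offtarget_fraction
  as_inh <- rng$runif(n) < cf$inh_fraction
  conc <- ifelse(rng$runif(n) < 0.6, 200, ifelse(rng$runif(n) < 0.5, 150, 400))
  inh_at <- function(ic50_uM, conc_uM) 100 / (1 + ic50_uM / conc_uM)
  id <- sprintf("SYN%05d", seq_len(n))
  rec <- function(i, iso, p) {
    v_ic50 <- from_pic50(p)
    if (as_inh[i]) {
      data.frame(compound_id = id[i], smiles = smiles[i], isoform = iso,
                 kind = "PERCENT_INHIBITION",
                 value = round(inh_at(v_ic50, conc[i]), 1), unit = "",
                 assay_conc_uM = conc[i], source = "synthetic",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(compound_id = id[i], smiles = smiles[i], isoform = iso,
                 kind = "IC50", value = signif(v_ic50, 4), unit = "uM",
                 assay_conc_uM = NA_real_, source = "synthetic",
                 stringsAsFactors = FALSE)
    }
  }
  rows <- vector("list", n * 2L)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L; rows[[k]] <- rec(i, "SIRT2", pic50[i])
    if (has_off[i]) {
      k <- k + 1L; rows[[k]] <- rec(i, off_iso[i], off_pic50[i])
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  attr(out, "truth") <- data.frame(
    compound_id = id, smiles = smiles, planted_active = eff_active,
    has_selectivity_marker = has_marker, pic50 = pic50,
    off_pic50 = ifelse(has_off, off_pic50, NA_real_),
    off_isoform = ifelse(has_off, off_iso, NA_character_),
    stringsAsFactors = FALSE
  )
  out
}

#' Generate a decoy candidate pool
#'
#' Assembles molecules from scaffold families disjoint from the
#' active-compound libraries (saturated carbocycles, open chains,
#' aliphatic heterocycles) with substituents spanning a broad
#' physicochemical range, as raw material for property-matched decoy
#' selection.
#'
#' @param n pool size.
#' @param seed integer seed.
#' @return character vector of SMILES.
#' @export
generate_decoy_pool <- function(n, seed = 1L) {
  rng <- local_rng(seed)
  draw <- function(m) {
    scaf <- DECOY_SCAFFOLDS[rng$sample(length(DECOY_SCAFFOLDS), m,
                                       replace = TRUE)]
    s1 <- SUBSTITUENTS[rng$sample(length(SUBSTITUENTS), m, replace = TRUE)]
    s2 <- SUBSTITUENTS[rng$sample(length(SUBSTITUENTS), m, replace = TRUE)]
    s3 <- SUBSTITUENTS[rng$sample(length(SUBSTITUENTS), m, replace = TRUE)]
    vapply(seq_len(m), function(i)
      assemble_smiles(scaf[i], c(s1[i], s2[i], s3[i])), "")
  }
  out <- unique(draw(ceiling(1.5 * n)))
  tries <- 0L
  while (length(out) < n && tries < 20L) {
    out <- unique(c(out, draw(n)))
    tries <- tries + 1L
  }
  utils::head(out, n)
}
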