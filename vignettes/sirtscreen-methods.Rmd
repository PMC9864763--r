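---
title: "QSAR modelling and virtual screening for sirtuin-2 inhibitors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QSAR modelling and virtual screening for sirtuin-2 inhibitors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`sirtscreen` builds and validates quantitative structure--activity
relationship (QSAR) models for the discovery of sirtuin-2 (SIRT2)
inhibitors, and wraps them into virtual-screening and per-compound
analysis workflows. SIRT2 is an NAD^+^-dependent deacetylase; selective
SIRT2 inhibition (sparing the close homologues SIRT1 and SIRT3) is a
recurring objective in age-related-disease programs, and public
bioactivity repositories hold thousands of heterogeneous SIRT2 records —
IC50 values from different assay formats next to single-concentration
percent-inhibition measurements. The package turns such records into
four modelling tables, trains potency and selectivity models over five
algorithm families, and judges them with the full external-validation
battery that regulatory-style QSAR work expects.

This vignette documents the scientific choices: the data model and
encoding rules, the feature and selection machinery, the model-building
protocol, every validation statistic, the applicability-domain
constructions, and what the synthetic data generator does and does not
emulate.

# Curation and activity encoding

Raw records arrive as `(compound_id, smiles, isoform, kind, value,
unit, assay_conc_uM, source)`. Curation proceeds in fixed order:

1. **Row validation.** Unknown isoforms or record kinds, negative or
   non-finite values, IC50 units outside {µM, nM, M} and
   percent-inhibition records without an assay concentration are routed
   to a rejects table with machine-readable reason codes; nothing
   crashes on a bad row.
2. **Structure standardization.** Each SMILES is reduced to its largest
   contiguous fragment (salt stripping), charges are neutralized where
   chemically valid, and the canonical SMILES is taken as the compound
   key. The operation is idempotent; its output is the fixed point used
   everywhere downstream.
3. **Deduplication.** Records are grouped by (canonical SMILES,
   isoform). IC50 records outrank percent-inhibition records in a mixed
   group. Among same-kind duplicates the record closest to the group
   mean (on the IC50 scale) is kept; exact ties resolve to the more
   potent record — deterministic, and conservative for screening use.
4. **Class encoding.** A compound is *active* on SIRT2 if
   IC50 ≤ 50 µM, or Inh% ≥ 80 at 200 µM, ≥ 70 at 100–200 µM, ≥ 60 at
   50–100 µM, or ≥ 50 below 50 µM; *inactive* if IC50 ≥ 90 µM or
   Inh% ≤ 40 when assayed above 100 µM. Everything between — e.g. the
   IC50 band 50–90 µM, or 40–80 Inh% at 200 µM — is a *twilight zone*
   record: a deliberate buffer against inter-assay noise, excluded from
   classification tables. Selectivity classes combine the SIRT2 call
   with an off-target call: selective (active/inactive), nonselective
   (active/active), inactive (inactive/inactive). A SIRT2-inactive but
   off-target-active compound fits none of the three classes used here
   and is excluded; the case is rare and flagged in the curation log.

Four tables result: a pIC50 regression table (pIC50 = −log10 of the
IC50 in mol/L), a binary SIRT2 table, and SIRT1/2 and SIRT2/3
three-class selectivity tables.

**Splitting.** 70/30 train/test by stratified sampling: classes
directly, regression labels through five equal-frequency quantile bins
(the source protocol states only that the activity distributions were
maintained; equal-frequency binning is the simplest construction with
that property). Per stratum the test share is exact to one compound.
All splits require an explicit seed — the package has no hidden global
randomness.

**Rebalancing.** Classification training sets are oversampled with
SMOTE (synthetic rows interpolated between a minority instance and one
of its k = 5 minority neighbors) until all classes match the majority
count. Rebalancing happens inside each cross-validation training fold
and for the final refit, never in a validation fold or the test set;
synthetic rows carry a provenance flag so the leakage guard is
testable.

# Molecular features

* **Fingerprints.** ECFP4 and ECFP6 (extended-connectivity/Morgan,
  neighborhood radius 2 and 3) hashed to 1024 bits, and the 166 MACCS
  structural keys. The Morgan implementation is native to the package
  and tracks, for every set bit, the atom environments that generated
  it — that mapping is what makes the atom-contribution maps exact. Two
  SMILES spellings of one molecule give identical fingerprints because
  graphs are built from the canonical structure. Fingerprints enter the
  models as-is; no bit selection.
* **2D descriptors.** A fixed ~45-column panel: bulk physicochemical
  properties (MW, logP, TPSA, molar refractivity, H-bond counts),
  graph-topological indices (ring statistics, degree statistics,
  Zagreb, Randić, Wiener), and SMARTS functional-group counts. The
  panel is intentionally compact; descriptor identities are stable and
  named, and per-descriptor failures yield NaN rather than dropping a
  compound.

**Descriptor selection** (train rows only) runs a four-stage chain:
drop NaN/constant columns; drop variance < 0.1; drop one of each pair
with |Pearson r| > 0.9 (the earlier column in panel order survives —
deterministic); recursive feature elimination with 10-fold
cross-validation using an unpruned decision-tree estimator, removing 1%
of remaining features (at least one) per step, scored by balanced
accuracy (classification) or R² (regression). The variance filter runs
on the raw scale *before* standardization: a variance cut-off after
z-scoring is vacuous by construction, and 0.1 only means something on
the natural descriptor scale. The alternative order is available behind
a flag for comparability. Note that recursive elimination with a
single-tree estimator is a high-variance procedure: on planted
linear-signal fixtures it reliably removes noise columns but keeps only
the stronger three or four of five signal columns — the reference
implementation of the same procedure behaves identically, and the test
suite asserts exactly that reproducible behavior.

# Model building

Five families: random forest, SVM (RBF), k-nearest neighbors,
gradient-boosted trees, and an optional single-hidden-layer neural
network (the neural family is a Suggests-level extra; everything else,
including the acceptance battery, runs without it). Default search
spaces are conventional and fully overridable: forests 100–1000 trees,
depth 2–30, minimum node size 1–20; SVM cost and gamma log-uniform on
10^-3^–10^3^; KNN k 1–30 with a distance-weighting switch;
boosted trees with learning rate 10^-3^–0.3, depth 2–12, 50–400
rounds, row/column subsampling.

Hyperparameters are tuned by sequential model-based (Bayesian)
optimization: a Latin-hypercube initialization, a random-forest
surrogate with uncertainty estimates, and expected improvement over
random candidates, each evaluation being a five-fold cross-validation
(stratified for classification) maximizing mean R² or balanced
accuracy. A budget of one collapses to evaluating a single sampled
configuration, which the tests exploit. Failed searches fall back to
the space midpoint with a warning.

Internal validation records R²/RMSE on the training fit and the
cross-validated Q² = 1 − PRESS/TSS over pooled out-of-fold predictions
with RMSE~CV~, plus the conventional quality gates (R² > 0.6,
Q² > 0.5) as computed flags — the package reports them, it does not
assert them. **Y-scrambling** refits the tuned configuration on label
permutations (a fresh permutation per repetition) and returns the
scrambled-statistic distribution next to the true statistic; a model
whose Q² sits far above its scrambled distribution is not a chance
artifact.

# Validation battery

For observed test values $y_i$, predictions $\hat y_i$, test size
$n_{EXT}$ and training mean $\bar y_{TR}$:

* $R^2_{ext} = 1 - \sum(y_i-\hat y_i)^2 / \sum(y_i-\bar y_{EXT})^2$
  and $RMSE_{ext}$.
* The external correlation coefficients
  $Q^2_{F1}$ (reference: training mean), $Q^2_{F2}$ (test mean; equal
  to $R^2_{ext}$ by construction) and $Q^2_{F3}$ (PRESS per test
  compound over training variance per training compound).
* The Roy metrics $r^2_m = r^2(1-\sqrt{r^2-r^2_0})$ and $r'^2_m$ with
  the axes of the through-origin fit exchanged, their mean
  $\bar r^2_m$ and gap $\Delta r^2_m = |r^2_m - r'^2_m|$.
* Lin's concordance correlation coefficient (CCC), symmetric in its
  arguments.
* The Golbraikh–Tropsha criteria: through-origin slopes
  $k = \sum y\hat y/\sum \hat y^2$ and $k'$, through-origin
  determination coefficients $r^2_0$, $r'^2_0$, with pass flags for
  $(r^2-r^2_0)/r^2 < 0.1$ (either axis), $0.85 \le k \le 1.15$ (either
  slope) and $|r^2_0 - r'^2_0| < 0.3$.

Conventional acceptance thresholds ($\bar r^2_m > 0.5$,
$\Delta r^2_m < 0.2$, $Q^2_{Fn} > 0.7$, CCC > 0.85) are reported as
flags. Degenerate inputs (zero variance in observations or predictions)
produce explicit NaN with a reason string, never silent values.

Classification reports: the confusion matrix at the probability argmax,
balanced accuracy (macro-averaged recall; (sensitivity+specificity)/2
in the two-class case), the generalized (Gorodkin) Matthews correlation
over the full k×k confusion matrix, macro one-vs-rest ROC AUC, and
macro precision/recall/F1. Classes absent from the truth labels are
excluded from macro averages and recorded.

**Early enrichment.** EF at false-positive fraction $f$ is the true
positive rate at the score threshold where a fraction $f$ of the
inactives is accepted — i.e. the share of actives recovered within the
top $f$ of screened decoys, reported at 0.5%, 1%, 2% and 5%. Values lie
in [0, 1]; this is the recovered-fraction convention, not the
ratio-to-random convention. Ties at the cutoff count as *not*
recovered, a reproducible lower bound. Under random ranking the
expected EF at $f$ is ≈ $f$, which the tests verify by Monte Carlo.

**Decoy benchmark.** The virtual-screening stress test merges the test
actives with property-matched decoys at 1:40. Decoys are picked from a
candidate pool by minimizing z-scored Euclidean distance in (MW, logP,
HBD, HBA, rotatable bonds, net charge) subject to a maximum ECFP4
Tanimoto of 0.3 to any active; infeasible constraints relax the cutoff
in 0.05 steps with a warning. Reports are produced twice: on all
predictions and restricted to confident (out-of-indeterminate-zone)
predictions.

# Applicability domains

* **Leverage (regression).** The important features are those with
  mean permutation importance > 0 (30 repeats; a top-k override
  exists). The training matrix restricted to those columns is
  standardized and $h_i = x_i^\top(X^\top X)^{-}x_i$ computed through a
  Moore–Penrose pseudo-inverse, so collinear or sparse bit columns do
  not break the construction and the trace identity
  $\sum_i h_i = rank(X)$ holds on the column space. The warning
  threshold is $h^* = 3(m+1)/p$. For fingerprint models with many
  informative bits $m$ can approach or exceed $p/3$, making $h^*$ ≥ 1
  and the domain permissive — the package reports $m$, $p$ and $h^*$ so
  that this is visible. Williams-plot data (leverage vs. residuals
  standardized by training RMSE, thresholds $h^*$ and ±3) are exported
  for plotting; the package draws nothing itself.
* **Confidence zones (classification).** Binary predictions with the
  top probability inside 0.5 ± 0.1 are unconfident; multiclass
  predictions are confident only when the predicted class exceeds 0.5.
  Both constants are exposed in the API.
* **Atom-contribution maps.** For ECFP models, each atom's weight is
  the prediction difference when all bits whose generating environments
  contain that atom are cleared. Positive weight = activity-supporting.
  Atoms generating no set bit have weight exactly 0. MACCS models are
  rejected (no atom-to-key mapping exists in the fingerprint backend);
  descriptor models are rejected by design.
* **Nearest-reference lookup.** Exhaustive maximum ECFP4 Tanimoto
  against a user-supplied reference library, ties to first occurrence.

# The synthetic data generator

No public accession is bundled; instead `generate_synthetic_sar()`
emits a structure–activity table with the statistical shape of a
curated sirtuin dataset, so the whole suite is testable offline:

* Molecules assembled from eight aromatic/heteroaromatic scaffolds and
  28 substituents; ~65% of compounds carry one of six planted
  pharmacophore fragments (benzothiazole, benzoxazole, naphthylamide,
  indole, benzimidazole, quinoline) — the activity signal.
* pIC50 = 3.5 + 2.5·(pharmacophore) + substituent increments
  (fixed per library element, seed-determined) + N(0, 0.35) noise, with
  extra N(0, 0.4) spread among actives. Actives land near
  pIC50 6.0 ± 0.7. The inactive mean sits at 3.5 (IC50 ≈ 300 µM) so
  that planted inactives encode cleanly as inactive under both the IC50
  and the percent-inhibition rules: a higher inactive mean (e.g.
  pIC50 4.2 ≈ 63 µM) would park most inactives inside the 50–90 µM
  twilight band and break the class round trip by construction.
* 25% of records are emitted as Inh% at a stated concentration via a
  one-site binding transform, exercising every encoding rule; half the
  compounds get an off-target (SIRT1 or SIRT3) record whose potency is
  driven by an independent morpholine/phenylsulfonyl marker — the
  selectivity signal.
* Decoy candidate pools come from disjoint aliphatic scaffold families
  so topological dissimilarity to actives is attainable.

What it does **not** emulate: inter-laboratory assay noise structure,
activity cliffs, scaffold-hopping actives, stereochemistry, tautomer
ambiguity, or the long-tailed scaffold frequency distribution of real
repositories. Green end-to-end tests therefore demonstrate that the
machinery recovers a planted signal under controlled conditions — they
do not certify real-data performance.

# Problem sizes and numerical choices

The default end-to-end run uses 1500 synthetic compounds, a tuner
budget of 6 configurations per model, 20 Y-scrambling repetitions, and
a decoy benchmark over 10 test actives × 40 decoys selected from a
candidate pool 50× the requested decoy count — sizes chosen so the full
protocol trains four models and finishes in a few minutes on one CPU
while leaving all statistics stable. The `y_scramble()` operation
itself defaults to 100 repetitions when called directly. Morgan hashing
uses a fixed 25-bit prime modulus so all arithmetic is exact in
doubles; bit collisions at 1024 bits behave as in any hashed
fingerprint. KNN probabilities are normalized after accumulation so
they stay in [0, 1] exactly. Tie-breaks are deterministic everywhere:
correlation filter keeps the earlier column, decoy selection breaks
distance ties by a seeded jitter, nearest-neighbor lookup takes the
first occurrence. xgboost runs with the histogram tree method (64
bins), single-threaded for reproducibility.

# Known limitations

* OpenBabel's kekulized canonical form underlies graph perception;
  aromatic-flag-based invariants (as some toolkits use) would hash
  differently. Fingerprints are internally consistent but not
  bit-compatible with other software.
* The leverage domain on 1024-bit fingerprints is permissive (see
  above); descriptor models give the textbook behavior.
* Neural-network determinism is only guaranteed within a platform.
* The percent-inhibition → class rules implement the published
  thresholds verbatim; concentrations outside every rule fall to the
  twilight zone rather than inventing new thresholds.
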