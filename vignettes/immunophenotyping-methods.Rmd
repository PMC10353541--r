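---
title: "Methods: gating, controls and statistics for PBMC immunophenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gating, controls and statistics for PBMC immunophenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunogate)
```

# Scope and model

`immunogate` implements a complete desk-side counterpart of a multicolor
flow-cytometry immunophenotyping workflow for human PBMC: two declarative
antibody panels with hierarchical gate trees, the control-sample
computations that qualify such panels (titration, single-stain
compensation, interference screening), isotype-referenced gating with
activation quadrants, stimulation-index readouts, and a statistics layer
built for three-donor paired designs. Because instrument data for such
workflows are rarely shareable, the package also ships a synthetic cohort
generator with per-event ground truth; every downstream stage is tested
against that truth.

## The two panels

Panel 1 (lymphocyte panel, 12 channels) resolves B cells, total T cells,
cytotoxic T cells (CD8+/CD4−), naive cytotoxic T cells (CD45RA+), CD4 T
cells (CD4+/CD8−), regulatory T cells (CCR4+, CD25+/CD127-low) and
gamma-delta T cells, with CD25 (proliferation) and CD154
(co-stimulation) as activation markers on B, cytotoxic T and CD4 T cells.
Panel 2 (monocyte/DC/NK panel, 11 channels) splits a monocyte and a
lymphocyte scatter region, then resolves CD14+ monocytes,
pDC (CD123+), mDC (CD11c+), NK (CD56+) and NKT (CD3+CD56+) cells, with
CD54 (adhesion) and CD69 (early activation) on monocytes, pDC, mDC and NK.

Both panels are expressed in a JSON schema (`inst/extdata/panel*.json`)
read by `read_panel()`; `build_panel1()`/`build_panel2()` are just that
reader applied to the shipped schemas, so user-defined panels are
first-class. Channel/column names follow `"Marker-Fluorophore"`
(`"CD3-BV570"`), which makes the join between reagent tables and
population definitions unambiguous.

Two structural choices deserve a note:

* **Single root with branch children.** The two-region scatter split of
  panel 2 is modelled as one debris-excluding root (`main`) with two
  `scatter-region` children tagged `monocyte`/`lymphocyte`. This keeps the
  gate set a single-rooted tree; the validator requires exactly one
  live/dead exclusion gate on every root-to-leaf path (each branch carries
  its own singlet and viability gate).
* **CD127-low is a `threshold-low` gate**, i.e. at-or-below an
  isotype-referenced cutoff, not a negative gate — "lo" is a dim
  population, not an absent one.

## Gating

Gates execute top-down; every gate is inclusive except the live/dead gate,
whose members (dead cells) are removed from all downstream gating.

* **Main cells**: a percentile-trimmed rectangle on (FSC-A, SSC-A) — keep
  [p2, p99.5] per axis — plus a fixed FSC-A floor (default 20,000 a.u.)
  that removes the debris cloud. A reproducible surrogate for a hand-drawn
  region.
* **Monocyte/lymphocyte split** (panel 2): a deterministic 2-means
  location model on scaled (FSC-A, SSC-A) among main cells; the cluster
  with the larger SSC-A mean is the monocyte region. Starting centers are
  quantile-based and iteration is Lloyd's, so gating consumes no RNG.
* **Singlets**: FSC-H/FSC-A within [0.8, 1.2] (configurable). Simulated
  doublets are additive in FSC-A but sub-additive in FSC-H, so they fall
  below the window.
* **Live/dead**: the viability dye is strongly bimodal on the log scale in
  any stained sample; the cut is the geometric midpoint of a deterministic
  1-D 2-means on log intensity, computed per sample.
* **Marker thresholds**: the given quantile (default 0.995, i.e. a 0.5%
  false-positive rate) of the *condition-matched isotype control*'s
  distribution on that channel, computed among the isotype sample's live
  singlets of the gate's branch. We deliberately do **not** nest isotype
  thresholds through upstream marker gates: an isotype sample carries only
  background, so each 0.995-quantile gate would keep 0.5% of events and
  deeper parents would be empty or undefined. Activation markers without a
  tree gate (CD154, CD54) get thresholds by the same rule, keyed
  `"act:<detector>"`; where a marker appears both as a population gate and
  a quadrant axis (CD25), the two share one threshold.
* **Boundary rule**: strictly greater than the threshold is positive,
  everywhere.
* **Empty parents**: percentages are reported as 0 with an explicit
  `empty_parent` flag rather than `NA`, keeping downstream tables
  rectangular while preventing silent misreading of rare populations.

Percent-of-live uses the union of branch survivors as the denominator.
Condition matching of isotype controls (unstimulated isotypes gate
unstimulated samples, activated isotypes gate activated samples) is
enforced by the manifest pairing in `run_pipeline()`.

## Controls

* **Spillover estimation** (`estimate_spillover()`): per single-stain
  sample, events are split positive/negative against the unstained
  background at its 99.5th percentile on the primary channel (a stand-in
  for the vendor's bead classification, which is not published);
  `S[i, j] = (median_pos_j − median_neg_j) / (median_pos_i − median_neg_i)`,
  with unit diagonal and negatives clipped at 0. A sample whose positive
  fraction does not exceed the split's false-positive floor fourfold is
  reported as "no separable positive population".
* **Compensation** (`compensate()`): solves `observed = true %*% S` per
  event by a linear solve (never an explicit inverse); exact inverse of
  the simulator's forward model.
* **Stain index**: `(median(positive) − median(negative)) / (2 · rSD)`
  with `rSD = 1.4826 · MAD`. The vendor formula is unpublished; whether it
  uses SD or robust SD, mean or median, is unknown — this median/robust
  form is the package's documented, configurable choice. An unseparable
  stained sample scores 0. Optimal dilution is the stain-index argmax with
  ties broken toward the larger dilution (less antibody).
* **Interference screen**: per detector,
  `score = (median_treated − median_untreated) / rSD(untreated)` on
  unstained samples, flagged at 3 robust SDs (configurable). The published
  call for the anthracycline case is visual; 3 rSD is a conventional
  robust-outlier cutoff. FMO-based manual compensation touch-up is a
  visual step by nature and is deliberately *not* automated — no code in
  this package edits a spillover matrix after estimation.

## Readouts

gMFI is `exp(mean(log(x)))` over positive values; compensation can push a
minority of events at or below zero, and those are excluded with a count
rather than shift-transformed, because additive shifts distort fold
changes (more than half non-positive makes the gMFI undefined and
flagged). The stimulation index divides replicate means (fold change of
the replicate-averaged readout), never averages per-replicate ratios.
Whether activation gMFIs should be quadrant-restricted is ambiguous in
practice; the default uses the whole population per marker, with
`quadrant_gmfi = TRUE` as the documented alternative. Endpoints per
sample: one percent-of-live per population, plus four quadrant
percentages and two marker gMFIs per activation-flagged population
(25 endpoints for panel 1, 29 for panel 2).

## Statistics

With three donors, rank tests are powerless (`wilcoxon_min_p(3)` is 0.25)
and standard multiplicity corrections assume an independence these
endpoints do not have. The layer therefore:

1. computes the real paired t (two-sided, n−1 df) per treatment and
   endpoint, excluding endpoints with fewer than 3 complete pairs;
2. enumerates all unique treated/control label swaps over donor pairs —
   sign vectors modulo global negation, minus the identity:
   `2^(n−1) − 1`, i.e. exactly 3 at n = 3;
3. applies each flip *jointly across all endpoints of a treatment*,
   preserving the endpoint correlation structure (independent per-endpoint
   flipping is explicitly rejected);
4. pools all permuted p-values across endpoints and treatments within a
   panel into one null, and reports `perm_p = (b + 1)/(m + 1)` with `b`
   counting pooled values strictly below the real p (a non-strict variant
   is available, matching the construction in the permutation-p-value
   literature);
5. reports the "value to beat": the largest real p that still attains
   `perm_p < alpha`. Under strict counting the pass region is closed at
   that threshold; with 3 permuted values per test the minimum attainable
   `perm_p` from an unpooled test is 0.25, which is why pooling matters.

Degenerate permuted t-tests (zero variance after a flip) contribute
p = 1 and stay in the pool — dropping them would shrink `m` invisibly.
Whether pooling should cross treatments as well as endpoints is not
fully settled; the default pools both within a panel, configurable.

A caution the package's own tests quantify: the pooled null treats
correlated permuted values as independent contributions, so under
*extreme* endpoint correlation the marginal rate of `perm_p < 0.05` can
exceed the nominal level (in the degenerate limit of perfectly correlated
endpoints it approaches 1/4 at n = 3). On cohorts from this package's own
generator — where endpoint correlation is the realistic
compositional/gating structure — the empirical level stays at nominal
(the acceptance suite checks 200 null cohorts).

Negative-control reproducibility is Pearson correlation of
gate-percentage vectors across control runs with complete-linkage
clustering on the Euclidean distances between correlation rows — the
standard heat-map ordering.

# The synthetic cohort generator

The generator is the package's stated experimental world, not a tuning
dial; its defaults are fixed here once.

* **Classes and fractions.** Disjoint generator classes with constitutive
  marker profiles; panel-population fractions are unions. Panel 1 defaults
  (of live): B 10%, CD8 T 20% (8% naive), CD4 T 30% (3% Treg), gd T 3%,
  double-negative T 2%, other 35% — a typical resting PBMC draw. Panel 2:
  monocytes 20%, NK 10%, T 42%, B 10%, pDC 4%, mDC 4%, NKT 6%, other 4%.
  The pDC/mDC/NKT fractions are deliberately *inflated* relative to blood
  (where they run 0.2–1%): 0.995-quantile gating has an irreducible 0.5%
  false-positive leak from the parent gate, so precision/recall of a
  sub-1% population cannot reach the tested 0.95 at any separation; the
  defaults keep rare-population recovery measurable at desk-scale event
  counts. Set realistic fractions when the rare-population regime itself
  is under study — and expect precision, not recall, to degrade.
* **Expression.** Two-component log-normal mixtures per class and marker:
  background `lognormal(log 100, 0.5)`, positives `lognormal(log 8000,
  0.45)` — generously separated so a ground-truth oracle exists.
  Viability dye: live `log 150`, dead `log 30000`. Activation markers are
  per-event Bernoulli-positive with a baseline rate of 10% in activatable
  classes; conditions add a positive-fraction shift and a log-location
  shift (`default_activation_effects()`). Effect sizes for the positive
  controls are not published quantitatively; the defaults are chosen for
  clear separability and are fully user-configurable.
* **Structure.** Dead cells default to 25% (the 3:1 live:dead FMO
  construction), debris 5%, doublets 3% (sums of two random singlets,
  FSC-H sub-additive). One donor random effect multiplies class fractions
  (log-SD 0.15, renormalized) and shifts expression locations; isotype,
  FMO and unstained replacements carry the same donor shift so isotype
  thresholds transfer. Default 100,000 events per sample — a desk-scale
  stand-in for the 500,000-event acquisition target of the wet protocol.
* **Determinism.** Every sample draws from a substream keyed by a stable
  hash of (seed, donor, condition, replicate, stain type); fully-stained
  and isotype samples of one well share the cell draw. Cohorts are
  bit-reproducible and adding samples never perturbs existing ones.
* **Interference model.** A drug with intrinsic fluorescence adds
  `concentration × gain × lognormal loading` per event on affected
  detectors. The default gains (15,000 a.u. per mg/ml on the green/red
  detectors an anthracycline chromophore lights up) were set from the
  simulator's unstained robust SD so that, at the four printed assay
  concentrations of the doxorubicin-liposome case, the two highest flag
  and the two lowest do not — the qualitative pattern the screen exists to
  reproduce.

**What a green test does and does not establish.** The simulator has
log-normal mixtures, linear spillover, and clean bimodal viability; real
data add spectral spreading error, autofluorescence structure,
instrument drift, and gates whose populations are not well separated.
Green acceptance tests establish that the *algorithms* are correct on
their stated model, not that any particular wet-lab panel will meet the
same error bars.

# Numerical choices and edge cases

* Deterministic 2-means (quantile-seeded Lloyd) everywhere a location
  split is needed; gating never consumes RNG.
* Quantiles are type-7 (R's default) throughout.
* Ties in `select_optimal_dilution()` go to the larger dilution factor.
* `value_to_beat()` returns `NA` for "unattainable" (e.g. any pool with
  `1/(m+1) >= alpha`).
* Compensation refuses singular spillover matrices at construction
  (`spillover_matrix()` checks invertibility); estimation clips negative
  coefficients to 0.
* Zero-variance control runs make their correlations `NA` and are
  flagged; zero-variance paired differences flag the test as degenerate.
* FCS files are written as DATATYPE "D" (doubles) by default so
  write/read round-trips are bit-exact; "F" (float32) is supported for
  compatibility and reads back within 1e-6 relative error.

# Known limitations

* No spectral unmixing beyond square spillover matrices; no
  autofluorescence modelling beyond the drug-gain model.
* The FMO compensation touch-up is reported, never applied.
* Heat-map rendering is cosmetic; values are the contract, plots are not.
* The statistics layer reports the pooled permutation p as published; as
  noted above its marginal level is only guaranteed near-nominal for
  realistic (not extreme) endpoint correlation.
* Donor-specific published values (per-donor SI tables, the printed
  panel-specific values-to-beat) are functions of undeposited raw data
  and are out of reach by construction; the package reproduces the
  *machinery*, verified against synthetic ground truth.
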