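---
title: "Methods: disease-specific variant prioritization from binned epigenomic profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease-specific variant prioritization from binned epigenomic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epirisk)
```

## The problem and the model

Around 90% of GWAS index SNPs fall in introns and intergenic DNA, where a
variant's impact cannot be judged from the protein code. What *can* be
measured is the chromatin context: histone-mark and transcription-factor
ChIP-seq, DNase-seq and FAIRE-seq signal around the variant. `epirisk`
scores non-coding variants **one disease at a time**: the reported risk
variants of that disease are contrasted against matched benign controls in
a panel of epigenomic features, and a classifier trained on that contrast
assigns new variants a probability of being disease-implicated.

Two statistical obstacles shape the design:

* **Large p, small n.** A disease typically has tens to a few hundred
  reported risk variants, while the feature panel has hundreds to thousands
  of tracks. Fitting on everything overfits, so a univariate screen selects
  the informative features first.
* **Class imbalance.** Controls outnumber risk variants ten to one by
  design. A single classifier trained on the imbalanced set degenerates
  toward the majority class, so a balanced bagging ensemble is used
  instead.

The fitted object is produced by `epirisk()` and behaves like other
classed R model fits (`print`, `summary`, `predict`, `coef`, `plot`,
`residuals`).

### Step 1 — variant sets

Risk variants are GWAS index SNPs for the disease (surrogates for the
unknown functional variants). Benign controls are sampled from a
pre-filtered candidate pool so that their distance to the nearest
transcription start site (TSS) matches the risk variants' distances in
distribution, because chromatin differs strongly between promoter-proximal
and distal DNA; ten controls are drawn per risk variant
(`match_benign_tss()`). The matching mechanism is stratified sampling on a
log10 distance grid with bin edges 0, 100 bp, 1 kb, 10 kb, 100 kb, 1 Mb and
infinity: per stratum, the control count is the risk count times the ratio,
sampled without replacement; an exhausted stratum borrows from its nearest
neighbors with a warning. Stratified binning was chosen over per-variant
nearest-neighbor matching because it is the standard construction for this
kind of control set, is transparent to audit stratum by stratum, and makes
the error mode (an exhausted stratum) explicit.

A stricter alternative, `match_benign_region()`, requires every control to
lie within 10 kb (inclusive) of some risk variant. Two hygiene operations
support honest evaluation: `thin_by_proximity()` greedily keeps, in
(chromosome, position) order, only variants at least 10 kb apart — the
first variant of a close-packed run wins — and `exclude_within()` drops
test variants within 10 kb of (or identical to) a training variant.

### Step 2 — annotation

The genome is segmented into 200-bp bins. A read-representation feature is
the (input-normalized) read count of the bin containing the variant; a
peak-representation feature is the 0/1 indicator that the variant base
intersects a called peak; static genomic annotations contribute binary
element overlap or a per-base conservation score (0 where undefined).
Replicates of the same factor and cell line are merged — counts add, peak
intervals take their union — and ChIP counts are normalized against the
matched input library by subtraction after scaling the input to the ChIP
depth (`max(0, chip − input × chip_total/input_total)` per bin; open
chromatin assays have no input and are used directly). Negative differences
are floored at zero by default so that downstream t-tests act on
non-negative counts; `floor_negative = FALSE` disables this. No variance
stabilization is applied to bin counts by default. The result is an
`annotation_matrix`: variants × features with per-column metadata. All
coordinates follow the usual conventions: BED and bedGraph are 0-based
half-open on disk, variants are 1-based, strand is ignored.

### Step 3 — feature selection

Continuous columns are screened with a two-sided **Welch** t-test (risk vs
benign), binary columns with **Fisher's exact test** (two-sided: all tables
with probability at most the observed one). Welch rather than pooled
variance because the benign sample is ten times larger and counts are
heteroskedastic; for the strong effects that matter the two flavors agree.
Degenerate inputs follow fixed conventions: a constant column records p = 1
with a warning; two constant equal groups give t = 0, p = 1; constant but
different groups give p = 0.

The p-value threshold is a tuning parameter, chosen by stratified five-fold
cross-validation over a grid (default 0.01–0.20 in steps of 0.01): for
each candidate, p-values are recomputed *within each training fold* (so
held-out rows never influence selection), features below the cutoff are
kept, the ensemble is trained and the held-out fold scored by AUC; the
candidate with the largest mean fold AUC wins, ties going to the smallest
threshold. A (threshold, fold) pair that selects nothing scores AUC 0.5
with a warning. Feature selection runs once per training set, before the
ensemble — not per base learner — matching the workflow order
(selection feeds the ensemble stage).

### Step 4 — balanced bagging ensemble

With risk set P and benign set N, each of C base learners trains on
`P ∪ N_i`, where `N_i` is a with-replacement sample of |P| benign variants
— every learner sees an exactly balanced two-class set, asserted at fit
time. The default `C = ceiling(2|N|/|P|)` (20 at the 10:1 design) keeps
the union of resamples covering most of N: the expected covered fraction
at the default is `1 − (1 − 1/|N|)^(2|N|) ≈ 1 − e^{−2} ≈ 86%`. The score of
a variant is the plain average of the learners' probabilities.

Base learners:

* **tree** (default): a CART-style decision tree — Gini impurity, no depth
  cap, minimum leaf size 5, all features considered at every split, leaf
  class frequencies as probabilities. The C trees are grown in one
  `ranger` forest whose per-tree in-bag counts encode exactly the balanced
  resamples above; this is purely an implementation of the same model that
  fits the whole ensemble in one pass, and the probability average over
  stored learners is still computed explicitly (and tested against a
  per-learner oracle).
* **svm_radial**: radial-kernel SVM with Platt-style sigmoid probabilities
  calibrated on the learner's own balanced training set.
* **lasso**: L1-penalized logistic regression, penalty tuned by five-fold
  cross-validation inside each learner.

All randomness flows from one integer seed through `derive_seed()`
(a labeled deterministic hash), so a fit, a simulation or a whole pipeline
run is reproducible bit for bit; each learner's resample seed is stored in
the model.

## Evaluation protocols

`roc_auc()` computes AUC by the Mann–Whitney rank formulation (ties count
half) and sweeps ROC/PR points over unique scores, so the trapezoidal area
of the returned curve equals the rank AUC exactly. `mcc()` applies the
standard Matthews correlation formula at a probability cutoff of 0.5 — the
natural cutoff for a balanced ensemble's averaged probabilities — with the
convention that an empty margin yields 0.

`cross_validate()` runs the **entire** pipeline (screen → threshold tuning
→ selection → ensemble) inside each training fold of a stratified k-fold
split and reports per-fold AUC/MCC plus a pooled ROC over concatenated
held-out scores; both the fold-averaged and pooled AUC are reported since
either convention is defensible. `k = n` degenerates to plain leave-one-out
(singleton folds, per-fold AUC undefined and reported as `NA`, pooled
metrics intact). `independent_test()` trains once and re-scores against
`repeats` (default 10) fresh benign resamples from a pool, averaging the
AUCs. `leave_one_disease_out()` trains on all diseases of a class but one
and tests on the held-out disease.

## Factor over-representation

For disease i with `n_i` informative features out of N total, and `k_ij`
informative features of factor j, the upper binomial tail
`P(X > k_ij)` with `n_i` trials and success probability `n_i/N` scores
factor j's over-representation (`factor_overrep_pvalue()`, computed via
`pbinom` and verified against high-precision term-by-term summation). The
published formula defines the factor's feature count `m_ij` but does not
use it in the tail; because that reads like a typo, an alternative
`"m_trials"` variant (trials `m_ij`, same success probability) is provided
behind a flag, and neither is promoted as "intended". Factors with
p below the Bonferroni threshold `alpha/D` (0.05/45 at the full 45-disease
panel) count as over-represented, and `tally_overrepresentation()` counts
per factor the diseases where that happens.

## The synthetic-data generator

`simulate_dataset()` emits a complete, self-contained study:
a small two-chromosome genome (2 × 1 Mb, 200-bp bins), TSSs scattered
uniformly, risk variants and a benign candidate pool both placed at
log-uniform distances (1 bp–200 kb) from random TSSs — the *same*
placement law, so TSS-distance matching is exercised non-trivially — and a
panel of count tracks with negative-binomial noise (mean 5, size 2;
sequencing bin counts are overdispersed, and the size parameter recovers
Poisson as it grows). Planted informative features redraw the bins
containing risk variants at `mu0 × fold` (enriched) or `mu0 / fold`
(depleted), half each by default, mirroring the observed mix of enrichment
at active/open chromatin and depletion at repressive marks. `fold = 1` is
the null configuration. Peak tracks are derived by thresholding a track's
counts at its own quantile (default 0.90) and merging the surviving bin
runs, which reproduces qualitatively how peak calling coarsens a count
signal. The default study size — 100 risk variants, a 10,000-variant pool,
1000 features with 50 informative at fold 3 — is a well-powered single
disease at desk scale.

What the generator does **not** emulate: spatial autocorrelation of
chromatin signal along the genome, correlation between features (cell-type
blocks, co-binding), linkage disequilibrium among variants, and
minor-allele-frequency structure in the pool. Passing tests on this
generator therefore demonstrate the correctness and calibration of the
procedure — recovery of planted univariate shifts, chance-level behavior
on nulls, contract conformance — not performance on real epigenomes,
where feature correlation typically reduces the effective number of
independent features.

`table1_manifest_fixture()` reproduces the published feature panel's
count structure (1806 features: 1002 histone, 571 TF, 184 open chromatin,
49 RNA polymerase across eight source/category blocks) with synthetic
placeholder factor and cell-line labels; only counts and categories are
meaningful.

## Problem sizes and numerical choices in the test suite

The suite validates exact arithmetic against independent oracles
(hypergeometric enumeration for Fisher, pair counting for AUC, log-space
tail summation and an exact-rational frozen value for the binomial tail,
the closed-form confusion-matrix formula for MCC) and runs the full
pipeline at the default planted scale (1100 variants × 1000 features,
three seeds) plus a sparse-signal read-vs-peak comparison (1100 × 300,
`mu0 = 0.5`, three seeds). These sizes give stable stochastic checks in a
few minutes on one core while preserving the 10:1 imbalance, the 2×
learner rule and the nested tuning loop at full fidelity.

## Known limitations

* Feature correlation is ignored by the univariate screen; two highly
  correlated informative tracks are both selected and both vote.
* The ensemble probability is an average of heterogeneously calibrated
  base probabilities; it ranks well but is not itself a calibrated
  posterior.
* The region-matched criterion can exhaust small candidate pools near
  isolated risk variants; the TSS-matched criterion is the default for
  that reason.
* Leave-one-disease-out assumes the matched controls of each disease are
  tagged with that disease; pooling untagged controls silently weakens the
  protocol.
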