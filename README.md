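# epirisk

Disease-specific prioritization of non-coding variants from binned
epigenomic profiles.

## What it does and for whom

Most GWAS hits land in non-coding DNA. For a geneticist asking *"which of
these variants plausibly matters for **this** disease?"*, sequence alone
says little — but the chromatin around a variant (histone marks, TF
binding, open chromatin, RNA polymerase occupancy, measured by
ChIP-seq/DNase-seq/FAIRE-seq) says a lot, and it says different things for
different diseases. `epirisk` trains a per-disease classifier that
contrasts the epigenomic context of reported risk variants against matched
benign controls and scores any variant with a probability of being
disease-implicated.

The core procedure, for one disease with risk set *P* and benign set *N*
(|N| = 10|P|, TSS-distance matched):

1. **Annotate**: the genome is cut into 200-bp bins; each variant gets,
   per feature, the input-normalized read count of its bin (read
   representation) or a peak-overlap indicator (peak representation).
2. **Select**: each feature is screened with a two-sided Welch t-test
   (counts) or Fisher's exact test (peaks); features with p below a
   threshold tuned by five-fold cross-validation are kept.
3. **Ensemble**: C = ⌈2|N|/|P|⌉ base learners (decision tree by default;
   radial SVM or lasso optional) each train on *P* plus a with-replacement
   resample of |P| benign variants — exactly balanced classes. The score
   of a variant is the mean of base-learner probabilities:
   E(Y = 1 | X) = (1/C) Σᵢ pᵢ(X).

Evaluation protocols (stratified CV with the full pipeline re-run inside
each fold, repeated independent tests, leave-one-disease-out), a binomial
over-representation analysis of factors among informative features with a
Bonferroni α/D gate, and a fully synthetic data generator with planted
signal are included. Everything runs from one integer seed,
deterministically.

## Worked example

```r
library(epirisk)

# a planted synthetic study: 50 risk / 500 benign variants, 300 features,
# 25 informative at a 3-fold count shift
sim <- simulate_annotation(n_risk = 50, n_benign = 500, n_features = 300,
                           n_informative = 25, fold = 3, seed = 42)
fit <- epirisk(sim$x, sim$labels, grid = seq(0.02, 0.1, by = 0.02), seed = 42)
summary(fit)
#> Disease-specific variant prioritization model
#>   training: 50 risk / 500 benign variants
#>   features: 30 of 300 selected at p < 0.02 (CV-tuned)
#>   ensemble: 20 tree learner(s)
#>   selected: 16 enriched, 14 depleted in risk variants
#>   training-set AUC (resubstitution, optimistic): 1.000
#>
#> Top features by p-value:
#>  track_id test  statistic      p_value direction selected
#>   trk0101    t -14.936828 2.880835e-35  depleted     TRUE
#>   trk0294    t -13.271469 8.181526e-28  depleted     TRUE
#>   ...

cv <- cross_validate(sim$x, sim$labels, threshold = fit$threshold, seed = 42)
cv
#> 5-fold cross-validation: mean AUC 0.993 (sd 0.011), pooled AUC 0.993
#>   per-fold AUC: 0.998 1.000 0.999 0.991 0.975
```

The summary reads: 30 of 300 features passed the tuned p < 0.02 screen, a
balanced mix of enrichment and depletion (repressive marks around risk
variants typically show *depletion*, which count features capture and peak
features largely cannot); held-out discrimination is essentially perfect at
this planted effect size. `predict(fit, newx)` scores new variants in
[0, 1].

The track-level interface does the same from files: `read_manifest()` +
`load_tracks()` + `build_annotation_matrix()`, or `run_pipeline()` for an
end-to-end run (simulate/load → match controls → annotate → select/train →
score → evaluate → enrich) with all artifacts written as plain text.

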