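# aesubtype

Discovery of relapse-associated molecular subgroups from multi-omics tumor
profiles, and transfer of those subgroups to external single-omics cohorts.

`aesubtype` is written for cancer-genomics analysts who have per-patient
omics layers (mRNA, miRNA, lncRNA expression; DNA methylation; copy-number
scores) together with time-to-relapse follow-up — the motivating setting is
post-prostatectomy biochemical recurrence — and who want unsupervised,
survival-anchored patient subgroups rather than a supervised risk score.

## The method

The workflow is a deep-feature survival subtyping pipeline:

1. **Stack.** Each omics matrix is cleaned (median imputation, degenerate
   features dropped), min-max scaled to [0, 1] per feature, and the blocks
   are concatenated into one samples × features matrix *X*.
2. **Compress.** A three-hidden-layer autoencoder (500 → *h* → 500 hidden
   units, tanh with 50% dropout, sigmoid output, 10 epochs) is trained on
   *X* under the penalized cross-entropy objective

   L(x, x′) = logloss(x, x′) + Σᵢ ( α_w ‖Wᵢ‖₁ + α_a ‖F₁→ᵢ(x)‖₂² ),

   with α_w = 0.001 and α_a = 0.0001. The bottleneck activations are the
   *deep features*. Eight bottleneck widths
   h ∈ {50, 100, 150, 200, 250, 300, 400, 500} form the model grid.
3. **Screen.** Each deep feature enters a univariate Cox
   proportional-hazards model (Efron ties, Newton iterations); features
   with Wald p < 0.05 are retained.
4. **Cluster.** k-means (k = 2) on the retained deep features splits the
   cohort into subgroups S1/S2, oriented so S2 has the lower Kaplan–Meier
   survival (higher relapse risk).
5. **Select.** Each grid model is scored by 10-fold cross-validated
   Harrell concordance (cluster the training folds, nearest-centroid
   assignment of held-out samples, binary-label risk); the final model is
   chosen among the two highest-concordance candidates by full-cohort
   log-rank separation.
6. **Transfer.** One lasso logistic signature per omics kind (glmnet
   coordinate descent, cross-validated penalty, one-standard-error rule)
   predicts the S2 label from a single block, so external single-platform
   cohorts can be classified and validated by log-rank test and C-index.

A bundled synthetic-data generator (`generate_dataset()`,
`generate_external_cohort()`) emulates the assumed statistical structure —
block-appropriate marginals, a sparse planted two-subgroup signal, and
proportional-hazards relapse with calibrated censoring — so the entire
pipeline is testable without any external downloads. The Cox, Kaplan–Meier,
log-rank and concordance machinery is implemented from first principles and
cross-checked against independent oracles (and the `survival` package) in
the test suite.

## Worked example

```r
library(aesubtype)

ds  <- generate_dataset(synth_config(seed = 42))          # 400 patients, 5 blocks
fit <- ae_subtype(ds$omics, ds$clinical, seed = 42)       # full 8-model grid
print(fit)
#> Autoencoder multi-omics relapse subtyping
#>   400 samples, 1000 stacked features, 8 candidate models
#>   selected model_8: 235 relapse-associated deep features; CV C-index 0.647/0.045
#>   subgroups S1=254, S2=146; log-rank p = 1.05e-27
```

The fitted object reports the selected bottleneck model, how many deep
features survived Cox screening, the cross-validated concordance of the
subgroup labels (mean/SD over 10 folds; note that a *binary* label risk
score has a concordance ceiling of about 0.62 at hazard ratio 3, so 0.647
under this seed's censoring pattern is a strong signal relative to the 0.5
null), and the Kaplan–Meier log-rank separation of the recovered S1/S2
subgroups — here p ≈ 1e-27, against planted subgroups the assignment
recovers almost perfectly (adjusted Rand index 0.99 for this seed).

Transferring the mRNA signature to a fresh external cohort:

```r
ext    <- generate_external_cohort(ds$truth$mRNA, "mRNA", 150,
                                   effect_size = 1, hazard_ratio = 3, seed = 43)
labels <- predict(fit, ext$block)
table(predicted = labels, truth = ext$labels)
#>          truth
#> predicted S1 S2
#>        S1 92  2
#>        S2  3 53
validate_external(score_external(fit$signatures$mRNA, ext$block)$assignment,
                  ext$clinical, "external_mRNA")
#> <validation_report external_mRNA> n=150 (S1=94, S2=56); log-rank p=7.05e-14; C-index=0.659
```

So 145/150 external samples are classified correctly from the mRNA layer
alone, and the transferred labels separate relapse outcomes at
log-rank p ≈ 7e-14.

`summary(fit)` prints the full model-grid table (hidden sizes, penalties,
reconstruction RMSE, retained deep-feature counts, per-model mean
C-index/SD), `coef(fit)` the signature coefficients, and `plot(fit)` the
subgroup Kaplan–Meier curves. `run_full_pipeline(demo_config(out_dir))`
runs the same workflow from a config object and writes a reproducible run
directory (grid report, assignments, signatures, KM curves, manifest).

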