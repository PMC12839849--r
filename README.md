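# cmsdistill

Translate consensus molecular subtypes (CMS) of colorectal cancer into
compact, measurable prognostic signatures.

CMS classification dissects the heterogeneity of colorectal tumours into
four expression-defined subtypes (CMS1 immune, CMS2 canonical/WNT, CMS3
metabolic, CMS4 mesenchymal with poor prognosis), but it needs
transcriptome-wide profiling and delivers only a categorical label. This
package implements the full translation pipeline from subtype biology to a
deployable risk score:

1. **Functional spectra** — single-sample gene set enrichment (ssGSEA):
   for each sample, genes are ranked by expression and each gene set *S*
   scores `ES(S) = Σᵢ (P_in(i) − P_out(i))`, the integrated difference
   between the weighted in-set cumulative distribution (weights
   `|G − p + 1|^α`, α = 0.25) and the unweighted out-of-set one.
2. **Subtype embedding** — a fully connected classifier
   (input → 128 → 32 → 10 → classes, ReLU, Adam, early stopping) trained on
   the spectra against CMS labels; the K = 10 values of its last hidden
   layer per sample are the *deep features*.
3. **Signature distillation** — per deep feature, the top 10 raw features
   by |Pearson r|, re-ranked by median absolute deviation, keep 3; the
   deduplicated union is the signature. Works identically for genes and
   radiomic features.
4. **Risk model** — univariate Cox screen (Wald p < 0.05), multivariate Cox
   (Efron ties) on z-scored signature features, risk score
   `RSᵢ = Σⱼ βⱼ zᵢⱼ`, and a high/low cutoff at the maximum Youden index
   `J = sensitivity + specificity − 1` of an IPCW time-dependent ROC at the
   5-year horizon.
5. **Validation** — Kaplan–Meier curves, log-rank test, hazard ratio with
   95% CI, Harrell's C-index, 2/3/5-year AUC, waterfall plots, subtype
   enrichment of the high-risk group (hypergeometric test + odds ratio),
   immune-cell infiltration contrasts, and radiomic feature–pathway
   correlation maps.

A seeded synthetic-cohort generator (`simulate_cohort()`,
`simulate_radiomic()`) plants subtype programs, subtype-dependent hazards,
immune programs and pathway-linked radiomic features with full ground
truth, so the whole pipeline is testable end to end without any external
download.

## Worked example

```r
library(cmsdistill)

cohort <- simulate_cohort(cohort_config(seed = 42))
res <- run_distillation_pipeline(cohort, classifier = classifier_config(seed = 42))

glance(res$classifier)
#>   n_features n_classes deep_features epochs heldout_accuracy
#> 1         78         4            10     68                1

res$signature
#> <cms_signature> 18 gene feature(s)
#> # A tibble: 18 x 5
#>    feature_id deep_feature     r sign       mad
#>  1 g0129      DF1          0.690 positive 1.11
#>  2 g0177      DF1          0.705 positive 1.10
#>  3 g0120      DF1          0.692 positive 1.09
#>  # ... 15 more rows

res$report
#> <risk_report>
#>   groups: 166 high / 434 low (cutoff 0.174)
#>   log-rank p = 7.12e-21; HR = 2.75 [2.2-3.42]
#>   C-index = 0.625

res$enrichment[, c("odds_ratio", "p")]
#>   odds_ratio         p
#> 1      1305. 7.79e-105
```

Reading the output: the classifier separates the four planted subtypes
perfectly on held-out samples (the planted effect, two log-units per
program gene, is strong); all 18 distilled signature genes are planted
program genes; the risk model splits the cohort into groups whose hazards
differ by a factor of 2.75 — close to the planted hazard ratio of 2.5 for
the mesenchymal-like subtype — and the high-risk group is overwhelmingly
enriched for that subtype, which is exactly the designed behaviour.

Plots: `autoplot(res$report)` (Kaplan–Meier), `plot_waterfall(res$report)`,
and `autoplot()` on any `time_dependent_roc()` result or
`pathway_feature_correlation()` map.

## Layout

| Path | Contents |
| --- | --- |
| `R/expression.R`, `R/gene-sets.R`, `R/clinical.R`, `R/bundle.R` | readers/writers: expression TSV, GMT, clinical CSV, JSON model bundles |
| `R/simulate.R` | synthetic cohort and radiomic generators with ground truth |
| `R/spectra.R` | ssGSEA functional spectra and rank transform |
| `R/classifier.R` | subtype classifier and deep-feature extraction |
| `R/distill.R` | correlation/MAD signature distillation |
| `R/cox-risk.R`, `R/roc.R`, `R/survival-stats.R` | Cox risk model, time-dependent ROC, Youden cutoff, KM/log-rank/HR/C-index |
| `R/evaluate.R` | enrichment, group tests, immune infiltration, correlation maps |
| `vignettes/` | methods vignette: models, assumptions, design decisions |
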