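---
title: "Distilling molecular subtypes into compact prognostic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distilling molecular subtypes into compact prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmsdistill)
```

## The problem

Consensus molecular subtypes (CMS) partition colorectal tumours into four
expression-defined groups — CMS1 (immune), CMS2 (canonical/WNT), CMS3
(metabolic) and CMS4 (mesenchymal, the poor-prognosis subtype). The
classification is biologically rich but clinically awkward: it requires
transcriptome-wide profiling, and the subtype label itself is a blunt
instrument for individual risk prediction. `cmsdistill` implements a
translation pipeline that compresses subtype biology into a small panel of
directly measurable features (a couple of dozen genes, or radiomic features
from routine CT), then turns that panel into a continuous prognostic risk
score with a reproducible high/low cutoff.

The pipeline has five stages, each exposed as ordinary functions that chain
with the pipe:

1. **Functional spectra.** `ssgsea_spectra()` converts a genes × samples
   log-expression matrix into per-sample gene-set enrichment scores.
2. **Subtype embedding.** `train_classifier()` fits a fully connected
   network on the spectra against CMS labels; `extract_deep_features()`
   returns the K = 10 values of its last hidden layer per sample.
3. **Distillation.** `correlate_features()` + `select_signature()` translate
   the deep features back into raw features: per deep feature, the 10
   strongest |Pearson r| candidates, re-ranked by median absolute deviation,
   keep 3.
4. **Risk modelling.** `univariate_cox_screen()`, `fit_cox_model()`,
   `calibrate_cutoff()`: a screened multivariate Cox model whose linear
   predictor is the risk score, cut at the maximum-Youden threshold of a
   time-dependent ROC analysis.
5. **Validation.** `survival_report()` (Kaplan–Meier, log-rank, hazard
   ratio, C-index, multi-horizon AUC, waterfall), plus group-level biology:
   `subtype_enrichment()`, `immune_infiltration()`,
   `pathway_feature_correlation()`.

`run_distillation_pipeline()` wires the stages together end to end.

## The ssGSEA dialect

For each sample, genes are ranked by expression in descending order (ties
broken by the stable gene order of the matrix — `rank_transform()` always
returns a permutation of `1..G`). With the gene at descending position $p$
assigned the rank value $G - p + 1$, the enrichment score of a set $S$ is the
integrated difference of two cumulative distributions along the ranked list:

$$
\mathrm{ES}(S) \;=\; \sum_{i=1}^{G}\Bigl(P^{\mathrm{in}}_S(i) - P^{\mathrm{out}}_S(i)\Bigr),
\qquad
P^{\mathrm{in}}_S(i) = \frac{\sum_{p \le i,\, p \in S} |G-p+1|^{\alpha}}
                            {\sum_{p \in S} |G-p+1|^{\alpha}},
$$

with $P^{\mathrm{out}}_S$ the unweighted empirical CDF over out-of-set
positions. This is the integrated running-sum statistic of the
single-sample GSEA lineage (not the max-deviation statistic of classical
GSEA); the weight exponent defaults to $\alpha = 0.25$, and $\alpha = 0$
gives a rank-only score invariant to any strictly monotone transform of a
sample's values. Because each position's increment propagates to all later
positions, the sum collapses to a closed form over set members only, which
is what the implementation evaluates; the test suite certifies it against a
literal position-by-position running-sum oracle on hundreds of random
instances.

Sets lose members absent from the matrix silently (logged); a set with
fewer than 2 matched genes, or covering every gene (empty complement), is
dropped with a warning. Normalization — division of all scores by the
global max − min — is on by default for classifier input and off for
immune-infiltration scoring, where only within-sample contrasts between
groups are interpreted.

## The classifier and its deep features

The network is `input → 128 → 32 → 10 → classes` with rectified-linear
hidden units and a softmax head, trained by cross-entropy with the Adam
optimizer (mini-batches of 32, learning rate $10^{-3}$), a stratified 20%
validation split, and early stopping on validation loss with best-epoch
restore. All stochastic steps — initialization, the split, batch shuffling —
flow from one seed, and identical configurations reproduce identical
weights. Unlabelled (`NOLBL`) samples are never trained on but can still be
embedded.

Three design choices deserve explanation:

* **Output head initialized at the prior.** The softmax layer starts with
  zero weights and log-prior biases, so before any gradient step the model
  predicts the training class distribution. Combined with early stopping
  that may select this initial state, a cohort with no subtype signal
  degrades gracefully to majority-class accuracy instead of chasing noise —
  a property the null-calibration tests rely on.
* **Unweighted loss by default.** Inverse-frequency class weighting is
  available (`class_weights = "inverse_frequency"`) for severely skewed
  cohorts, but off by default: weighting moves the no-signal optimum from
  the marginal prior to the uniform distribution, which silently changes
  what "chance performance" means and complicates null calibration.
* **Deep features are the pre-rectification values** of the last hidden
  layer. Rectified activations can leave individual latent coordinates dark
  (zero for every sample) on easy problems; the linear embedding feeding
  the rectifier carries the same learned geometry, keeps all ten
  coordinates informative, and is better matched to the Pearson-correlation
  distillation that follows. Hidden biases also start slightly positive
  (0.01) so rectified units begin active.

## Distillation: correlation then variability

For each of the K deep features, candidate raw features are ranked by
absolute Pearson correlation — "positive or negative" is read as one ranking
by |r| with the sign recorded, not ten candidates per sign — and the top 10
are re-ranked by unscaled median absolute deviation
(`median(|x − median(x)|)`, no 1.4826 consistency factor: MAD is used purely
ordinally). The top 3 per deep feature are kept and the union deduplicated
by first occurrence, so a signature never exceeds 10 × 3 slots and is
usually smaller. All ties break lexicographically by feature id; features
with zero variance never enter candidacy. MAD is computed on the training
cohort only. The same surface serves gene and radiomic matrices — the
modality is just a tag on the signature.

## Risk model and cutoff

Screened features (univariate Cox Wald p < 0.05 by default; no multiplicity
correction in the screen, with BH available) enter a multivariate Cox model
fitted by partial-likelihood maximization with Efron tie handling.
Features are z-scored with training-cohort statistics that are stored on
the model, so validation cohorts are scored with frozen parameters — no
refitting leakage. The risk score is $RS_i = \sum_j \beta_j z_{ij}$.

One tie-handling subtlety surfaced during testing and is worth recording:
duplicating every record of a dataset leaves the Breslow partial likelihood
maximizer exactly unchanged (the log-likelihood doubles up to a constant),
but not the Efron maximizer — Efron's within-tie averaging deliberately
treats a block of 2d tied events differently from two independent blocks of
d. The package defaults to Efron (more accurate under heavy ties) and
exposes `ties = "breslow"`; the test suite certifies the Efron fit against
an independent dense grid search of the Efron likelihood and checks
replication invariance in its valid Breslow form.

The high/low cutoff is the maximum-Youden threshold
($J = \text{sensitivity} + \text{specificity} - 1$) of a time-dependent ROC
at a 5-year horizon (60 on the month scale used throughout; the horizon is
config-exposed and 2/3/5-year AUCs are always reported). The ROC uses the
cumulative-case / dynamic-control definition with inverse-probability-of-
censoring weights from the Kaplan–Meier estimator of the censoring
distribution, evaluated at $G(t_i^-)$ for cases; with no censoring before
the horizon it reduces exactly to the plain ROC against the event-by-horizon
indicator. Ties in J break toward the smaller threshold (the larger
high-risk group), and the boundary itself is high risk ($RS \ge c^*$).
Because J is invariant to monotone transforms of the score, rescaling all
coefficients and recomputing the cutoff reproduces the identical grouping.

## Group-level statistics

Subtype enrichment of the high-risk group collapses risk × subtype to a 2×2
table (target subtype vs rest, unlabelled samples excluded) and reports the
cross-product odds ratio — with the Haldane–Anscombe +0.5 correction when
any cell is zero — and the one-sided hypergeometric tail
$P(X \ge \text{observed})$; a two-sided option exists but enrichment is the
directional claim of interest. Continuous group contrasts use the Wilcoxon
rank-sum test (exact enumeration when both groups have ≤ 8 observations and
no ties; otherwise the tie-corrected normal approximation without
continuity correction, so that fully tied data gives p = 1). Categorical
contrasts route on the classical rule: Pearson chi-square without continuity
correction when all expected counts are ≥ 5, Fisher's exact test (2×2 only)
otherwise, with the applied rule reported. Immune infiltration scores each
of the 28 immune-cell programs by ssGSEA (unnormalized) and contrasts
high vs low per cell type with BH adjustment across the 28 tests; the
feature–pathway correlation map reports r, raw p and BH q per pair (both
raw and adjusted significance are kept, since star conventions differ
across publications).

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` generates the statistical structure the analysis
assumes, with planted ground truth for recovery testing:

* **Expression**: $x_{gj} = \text{baseline}_g + \delta\,[g \in
  \text{program}(\text{subtype}_j)] + N(0, \sigma^2)$, with per-gene
  baselines uniform on [2, 12] (log₂-like scale), four *disjoint* 100-gene
  subtype programs in a 2 000-gene background, effect δ = 2 and noise σ = 1.
  Real CMS programs overlap; disjointness is a deliberate simplification
  that makes recovery metrics unambiguous.
* **Subtypes**: multinomial with proportions (0.15, 0.45, 0.14, 0.26),
  mirroring the skewed CMS mix of labelled CRC discovery cohorts; 10% of
  labels are masked to `NOLBL` to emulate unclassifiable samples.
* **Survival**: exponential event times (baseline hazard 0.01/month) with
  per-subtype log-hazard multipliers (0, −0.2, 0, ln 2.5) — a CMS4-like
  subtype at hazard ratio 2.5 — censored by an independent Uniform(0, 240 mo)
  dropout time and a 120-month administrative horizon, yielding roughly
  half the cohort with events. Exponential rather than Weibull keeps the
  planted log-hazards analytically transparent as recovery targets.
* **Gene sets**: five program-tagging sets per subtype (size 50, exactly
  80% drawn from the program), 30 random background sets, and 28 disjoint
  immune-cell sets of 15 genes, the first two embedded in the CMS1-like
  program so immune infiltration tracks the immune subtype.
* **Radiomics**: 30 features, 5 linked per program as
  $r_{fj} = \lambda \cdot \text{activity}_{pj} + N(0, \text{sd}^2)$ with the
  pathway activity defined as the standardized mean program expression;
  λ = 1.5 and sd = 1 give linked correlations around 0.83. The remaining 10
  features are pure noise. The nominal feature→program assignment is kept in
  the truth object even at λ = 0 so null recovery is testable.

One master seed drives a hierarchy of per-component generators (expression,
survival, sets, masking, radiomics), so adding the radiomic stage never
perturbs the expression draws. Effect sizes were chosen once for
comfortable-but-not-trivial recovery and are all config-exposed.

The generator does **not** emulate real gene identities, correlated
co-expression structure, chromosomal organisation, microarray noise,
batch effects, or overlapping subtype programs. Passing recovery tests
therefore demonstrates that the pipeline's machinery is correct and
well-calibrated under its own assumptions — not that it will achieve any
particular accuracy on real cohorts, where signal is weaker and structured.

## Numerical choices and degenerate inputs

Cox fits converge at a score tolerance of 1e-10 (up to 100 iterations);
non-convergence and apparent separation (|β| diverging) are hard errors
naming the feature. Zero-variance features are flagged and excluded from
correlation candidacy, screening and Cox fitting rather than propagating
NaNs. Missing expression values are hard errors — the pipeline operates on
complete matrices, as upstream preprocessing is out of scope. Survival
times must be positive; event indicators must be exactly 0/1; all survival
inputs carry an explicit declared time unit (the generator uses months),
since cohorts in the wild mix days and months and a silent unit mismatch
would corrupt every horizon-dependent quantity.

Problem sizes in the test-suite recovery studies — 20 seeded cohorts of 600
samples × 2 000 genes for the full pipeline, 50-instance oracle batteries
for the survival statistics, 200 instances for the enrichment-score oracle —
were chosen as the smallest scales at which the planted effects are
estimated stably, and run in a few minutes on one CPU.

## Serialization

Fitted classifiers and risk models round-trip through JSON bundles
(`bundle_model()` / `save_bundle()` / `load_bundle()` / `unbundle_model()`)
with numeric arrays stored as base64-encoded IEEE doubles: lossless to the
bit while keeping stage name, seed, config hash and timestamps readable in
any text editor. A version field guards against silent format drift, and a
truncated or tampered file fails loudly at parse time.

## Known limitations

* The distillation is a ranking heuristic, not an optimisation: no sparse
  regression, stability selection or mutual-information alternative is
  provided.
* The univariate screen is uncorrected by default (matching common
  practice in signature construction); with many candidate features the
  retained set will contain false positives at the nominal rate.
* The time-dependent ROC assumes censoring independent of the risk score;
  informative censoring would bias the IPCW weights.
* No proportional-hazards diagnostics beyond the model's own fit are run,
  and no competing-risks machinery is included.
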