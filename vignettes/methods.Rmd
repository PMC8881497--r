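---
title: "Rank-pair lncRNA risk signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-pair lncRNA risk signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncPairRisk)
```

## The model

lncPairRisk builds prognostic models from *relative expression ordering*
of long noncoding RNAs rather than from their expression levels. For an
unordered gene pair (A, B) and a sample *s*, the feature is the indicator

$$S_{AB}(s) = \mathbf{1}\{x_A(s) > x_B(s)\},$$

which depends only on the within-sample ranking of the two genes. Any
strictly monotone per-sample transform of the expression vector — a
normalization change, a platform shift, a log transform — leaves every
indicator unchanged. That rank-invariance is the method's selling point:
a signature of pair indicators transfers across cohorts without
cross-sample normalization.

The pipeline narrows the candidate gene set before pairing:

1. **Immune screen.** A lncRNA is immune-related if its Pearson
   correlation with at least one immune gene satisfies `r > 0.4` at
   `p < 0.001` (signed rule; `use_abs = TRUE` switches to `|r|`).
   Correlations are computed on `log2(x + 1)` values.
2. **Differential expression.** Among immune-related lncRNAs, the
   dysregulated subset satisfies `|log2FC| > 1.5` (strict) and
   BH-adjusted `p < 0.05`, using a moderated t statistic with
   empirical-Bayes variance shrinkage (below).
3. **Pairing.** All `n(n-1)/2` unordered pairs of the dysregulated set
   are formed over tumor samples; a pair is an *effective match* only if
   its minority indicator fraction exceeds 20%, i.e. its prevalence lies
   strictly inside (0.2, 0.8). A pair that is almost always 0 or almost
   always 1 carries no usable ordering information.
4. **Selection.** A univariate Cox screen (Wald `p < 0.05`) is followed
   by stability selection: cross-validated LASSO-Cox is repeated (1000
   cycles by default, fresh stratified fold assignment each cycle) and
   pairs chosen in strictly more than `freq_threshold` cycles (default
   100, a 10% inclusion bar) enter the signature.
5. **Risk score.** A joint multivariate Cox fit over the selected
   indicators gives coefficients $\beta_i$; the per-patient risk score is
   the linear predictor $RS = \sum_i \beta_i S_i$.

Evaluation uses time-dependent ROC curves at 1/3/5 years
(cumulative-case / dynamic-control with inverse-probability-of-censoring
weights), a cutoff maximizing Youden's J on the first horizon,
Kaplan–Meier curves with the two-group log-rank test, and uni-/multi-
variate Cox models testing whether RS predicts survival independently of
clinical covariates. Downstream association statistics (chi-square,
Wilcoxon, Kruskal–Wallis, Spearman) link risk groups to clinical
features, immune-infiltration matrices, checkpoint-gene expression, and
imputed drug IC50 tables; deconvolution and IC50 imputation themselves
are out of scope and consumed as precomputed inputs.

## Moderated t and its limits

Per gene, on `log2(x + 1)`: group means, pooled residual variance $s^2$
on $d = n_1 + n_2 - 2$ degrees of freedom. The gene-wise variances are
modelled as draws from a scaled inverse chi-square prior with parameters
$(d_0, s_0^2)$, estimated by matching the mean and variance of
$\log s^2$ through digamma/trigamma identities (the trigamma inverse is
solved by Newton iteration). The posterior variance
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ yields
$t = \mathrm{log2FC} / (\tilde s \sqrt{1/n_1 + 1/n_2})$ on $d_0 + d$
degrees of freedom. Forcing $d_0 = 0$ reproduces the ordinary pooled
two-sample t exactly; $d_0 \to \infty$ replaces every variance by
$s_0^2$. Both limits are asserted in the test suite, and the default
estimator is checked against the reference empirical-Bayes
implementation in `limma` on random matrices. Trend fitting and
precision weights are deliberately not implemented; the pipeline uses
the core shrinkage only.

## Time-dependent ROC estimator

At horizon $\tau$: cases have an event by $\tau$, controls survive past
$\tau$; samples censored before $\tau$ drop out, and the remaining cases
and controls are reweighted by $1/\hat G(T^-)$ and $1/\hat G(\tau)$,
where $\hat G$ is the Kaplan–Meier estimate of the censoring
distribution. This estimator is deterministic and bandwidth-free, and
with zero censoring it reduces *exactly* to the classical binary ROC —
the AUC equals the Mann–Whitney statistic with half-credit for ties —
which is what the oracle tests exploit. The nearest-neighbour smoothed
estimator used by some published scripts is not implemented; on
moderately sized cohorts the two differ by far less than seed-to-seed
variation.

The high/low cutoff is the grid threshold maximizing TPR − FPR (Youden's
J), ties broken toward the larger cutoff so fewer patients are called
high-risk. The signature literature often labels this cutpoint step
"AIC" / "maximum inflection point" without printing a formula; the
Youden rule is the reproducible reading used here and the label is
carried in the output metadata. Scores exactly at the cutoff go to the
low-risk group (`rs > cutoff` is high).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `r_threshold`, `p_threshold` | 0.4, 0.001 | –, prob. | canonical immune-screen gates |
| `lfc_threshold`, `fdr_threshold` | 1.5, 0.05 | log2, prob. | strict DE gates |
| `min_minority_frac` | 0.2 | fraction | effective-match bar, strict |
| `cox_p` | 0.05 | prob. | univariate prognostic screen |
| `n_reps`, `n_folds` | 1000, 10 | counts | stability-selection budget |
| `freq_threshold` | 100 | count | strict 10% inclusion bar |
| `horizons` | 1, 3, 5 | years | 1 year = 365.25 days |

## What the synthetic generator emulates

`generate_cohort()` states a TCGA-like world: 414 tumor / 19 normal
samples by default; a per-sample latent immune-activity factor
$z \sim N(0,1)$ on which immune genes and immune lncRNAs load with
$\sqrt{f}$ (so any immune lncRNA–immune gene pair has population Pearson
correlation exactly $f$ = `factor_loading`, the quantity the screen
thresholds); a tumor-only mean shift of `de_log2_shift` (default 2, above
the 1.5 gate) for the dysregulated lncRNAs; exponential survival with
hazard $h_0 \exp(\sum_k \beta_k S_k)$ driven by known pair indicators;
independent Uniform(0, `censor_max`) censoring, the simplest mechanism
satisfying the IPCW assumptions; and categorical clinical covariates with
an optional knob tying stage/T/N/M to the true risk quantile so the
chi-square stage has signal. Expression is generated on the log2 scale
and exponentiated (`2^y - 1`, floored at 0) so values look FPKM-like
while the DE gates operate on the controlled scale. Members of each true
pair share a baseline mean, so true-pair prevalence sits near 0.5, inside
the informative band.

What it does **not** emulate: negative-binomial count noise and
mean-dispersion trends, batch effects, molecular subtypes, informative
censoring, or correlated noise beyond the single factor. A green
end-to-end test therefore establishes that the pipeline recovers a known
signal under its own assumptions — not that those assumptions hold in any
real cohort.

## Numerical and design choices

- **Tie handling in pairs:** $x_A = x_B$ gives indicator 0. The defining
  inequalities are strict, ties are measure-zero for continuous FPKM,
  and a deterministic rule keeps runs reproducible.
- **Effective-match filter:** the published description of this filter
  is garbled in the method family's literature; the implemented reading —
  retain when the minority fraction strictly exceeds 20% — is symmetric
  in the pair's orientation and reproduces the intended "a fixed rank
  cannot predict" exclusion.
- **Cox details:** Efron tie handling (Breslow by config); Wald 95% CIs
  as $\exp(\beta \pm 1.96\,\mathrm{se})$; CV-optimal penalty is
  `lambda.min`, not the 1-SE rule; fold assignment is stratified by event
  status so no fold is event-free in small cohorts.
- **Correlation screen scale:** raw-FPKM Pearson is unstable under heavy
  tails, so `log2(x + 1)` is the default working scale; a config switch
  restores raw values. Whether the original method family used signed or
  absolute correlation is unstated in most descriptions; the signed rule
  follows the printed inequality, `use_abs` exposes the alternative.
- **Biotype conflicts:** a gene with both protein_coding and lncRNA GTF
  records is classified mRNA (conservative), with a warning.
- **Wilcoxon:** exact enumeration for small untied samples, normal
  approximation with tie correction otherwise (the `stats::wilcox.test`
  defaults, which the test suite pins against full rank enumeration).
- **Boundary semantics** are strict everywhere the gates are printed as
  strict: `|logFC| > 1.5`, prevalence in open (0.2, 0.8), stability
  frequency `> 100`, `rs > cutoff` for high risk.

## Known limitations

- The stability loop refits `cv.glmnet` `n_reps` times; at the default
  1000 cycles this is minutes of compute on one CPU. Tests and the
  acceptance script scale down to 100 cycles with a proportional
  frequency bar (strictly > 10%), as noted where it happens.
- Ordinal encodings for clinical covariates (stage I–IV as 1–4, etc.)
  are a modelling convention, not established fact; unknown codes
  (Tx/Nx/Mx) are excluded from ordinal models but retained for
  chi-square tables.
- `independence_analysis` assumes proportional hazards for all
  covariates and does not test the assumption.
- AUC confidence bands, competing risks, calibration and nomograms are
  out of scope.
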