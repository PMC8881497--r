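# lncPairRisk

Prognostic risk modelling from **immune-related lncRNA pairs** in tumor
expression cohorts.

Expression-level prognostic signatures break when cohorts differ in
platform or normalization. lncPairRisk instead builds features from
*relative expression ordering*: for an unordered lncRNA pair (A, B) and
sample *s*, the feature is the indicator

    S_AB(s) = 1  if  x_A(s) > x_B(s),   else 0

which depends only on the within-sample rank of the two genes and is
invariant to any strictly monotone per-sample transform. The package is
aimed at computational oncologists building survival signatures from
bulk RNA-seq (TCGA-like cohorts with tumor/normal samples, survival
follow-up and clinical covariates).

## Pipeline

1. **Ingest** — expression TSV (genes × samples, FPKM-like), GTF-based
   mRNA/lncRNA split, clinical table (0-day survivors removed), immune
   gene list.
2. **Immune screen** — lncRNAs with Pearson `r > 0.4`, `p < 0.001`
   against any immune gene (on `log2(x+1)`).
3. **Differential expression** — moderated-t (empirical-Bayes variance
   shrinkage) with strict gates `|log2FC| > 1.5`, BH `FDR < 0.05`.
4. **Pairing** — all `n(n-1)/2` binary pair indicators over tumor
   samples; *effective matches* keep prevalence strictly inside
   (0.2, 0.8).
5. **Signature fit** — univariate Cox screen (`p < 0.05`), then
   stability selection: 1000 cycles of ten-fold cross-validated
   LASSO-Cox, keeping pairs selected in strictly more than 100 cycles;
   joint multivariate Cox gives coefficients β and the risk score
   `RS = Σ βᵢ Sᵢ`.
6. **Evaluation** — IPCW time-dependent ROC/AUC at 1/3/5 years,
   Youden-optimal cutoff, high/low Kaplan–Meier + log-rank,
   independence Cox models, per-covariate AUC comparison.
7. **Associations** — chi-square (clinical features), Wilcoxon /
   Kruskal–Wallis (risk-score subgroups), Spearman + Wilcoxon
   (precomputed immune-infiltration matrices), checkpoint-gene and drug
   IC50 comparisons.

A seeded synthetic-cohort generator (`generate_cohort()`) with known
ground truth (which lncRNAs are immune-related, which pairs drive
hazard, each sample's true risk score) makes the whole pipeline testable
without external data. See `vignettes/methods.Rmd` for the model,
estimator choices and the generator's scope.

## Worked example

```r
library(lncPairRisk)

# simulate a TCGA-like cohort with 3 planted prognostic pairs
paths <- stage_simulate(generator_config(
  n_tumor = 200, n_normal = 19, n_mrna = 80, n_lncrna = 120,
  n_immune_genes = 30, n_immune_lncrna = 40, n_de_lncrna = 10,
  n_true_pairs = 3, true_betas = c(1, -1, 1.2), seed = 7), "inputs")

cfg <- pipeline_config(
  expression = paths[["expression"]], gtf = paths[["gtf"]],
  clinical = paths[["clinical"]], immune_genes = paths[["immune_genes"]],
  out_dir = "run", n_reps = 100, freq_threshold = 10, seed = 7)
res <- run_pipeline(cfg)
#> immune-related lncRNAs: 40 of 120
#> dysregulated immune-related lncRNAs: 10
#> candidate pairs: 45
#> effective-match filter: kept 6 of 45 pairs
#> prognostic pairs (univariate Cox): 3
#> stability-selected pairs: 3

res$fit$model
#>              pair      beta       hr    ci_low   ci_high            p
#> 1 LNC0001|LNC0002  1.182104 3.261230 2.2564451 4.7134417 3.161882e-10
#> 2 LNC0003|LNC0004 -1.078116 0.340236 0.2355419 0.4914647 9.136175e-09
#> 3 LNC0005|LNC0006  1.187287 3.278177 2.2550914 4.7654134 4.954581e-10

round(unlist(res$manifest$auc), 3)
#> year1 year3 year5
#> 0.785 0.814 0.910
```

The three selected pairs are exactly the planted ones; the fitted
coefficients recover the simulated log-hazards (1, −1, 1.2) within
sampling error; hazard ratios are `exp(beta)`. The AUCs say the risk
score ranks patients well at all three horizons; the manifest also
records the Youden cutoff (1.182 here) and the high/low log-rank p
(1.5e-12).

Risk scores can also be computed from a published signature table
without refitting. A 15-pair bladder-cancer signature ships as a worked
example:

```r
sig <- read.delim(system.file("extdata", "signature_blca15.tsv",
                              package = "lncPairRisk"), check.names = FALSE)
model <- signature_model(sig$pair, sig$coefficient)
all(abs(exp(sig$coefficient) - sig$HR) < 0.001)   # printed HR = exp(beta)
#> [1] TRUE
```

## Command line

```sh
Rscript inst/cli/lncpairrisk.R simulate --out-dir inputs --seed 7
Rscript inst/cli/lncpairrisk.R run --expression inputs/expression.tsv \
    --gtf inputs/genes.gtf --clinical inputs/clinical.tsv \
    --immune-genes inputs/immune_genes.txt --out-dir run --seed 7
```

Subcommands `screen | pair | fit | evaluate | associate` run single
stages against an existing run directory and produce identical artifacts
to `run`.

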