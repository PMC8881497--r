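#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a TCGA bladder-cancer-like bulk RNA-seq cohort at desk
#' scale: 414 tumor and 19 normal specimens, a few hundred genes, a shared
#' latent "immune activity" factor on which immune genes and a subset of
#' lncRNAs load, a tumor-only mean shift for the dysregulated lncRNAs, and
#' an exponential proportional-hazards survival mechanism driven by known
#' pair indicators with independent uniform censoring.
#'
#' @param n_tumor,n_normal sample counts per group.
#' @param n_mrna number of coding genes (the immune genes are a subset).
#' @param n_lncrna number of lncRNA genes.
#' @param n_immune_genes number of immune-annotated coding genes.
#' @param n_immune_lncrna number of lncRNAs loading on the immune factor.
#' @param n_de_lncrna number of immune lncRNAs given a tumor-only shift
#'   (must be <= n_immune_lncrna).
#' @param de_log2_shift tumor-only mean shift in log2 units (> 1.5 so the
#'   default differential-expression gate can recover it).
#' @param factor_loading population Pearson correlation, in (0, 1], between
#'   any immune lncRNA and any immune gene (both load `sqrt(factor_loading)`
#'   on the shared latent factor).
#' @param n_true_pairs number of lncRNA pairs whose indicators drive hazard.
#' @param true_betas log-hazard coefficients, length `n_true_pairs`.
#' @param baseline_hazard events per day for a subject with risk score 0.
#' @param censor_max censoring times are Uniform(0, censor_max) days.
#' @param stage_association in `[0, 1]`; strength with which tumor stage is
#'   tied to the true risk-score quantile (0 = independent).
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_tumor = 414, n_normal = 19,
                             n_mrna = 200, n_lncrna = 300,
                             n_immune_genes = 60, n_immune_lncrna = 80,
                             n_de_lncrna = 20, de_log2_shift = 2,
                             factor_loading = 0.7,
                             n_true_pairs = 5,
                             true_betas = c(1, -1, 0.9, -0.9, 1.1),
                             baseline_hazard = 5e-4, censor_max = 3650,
                             stage_association = 0.5, seed = 1) {
  cfg <- list(n_tumor = n_tumor, n_normal = n_normal, n_mrna = n_mrna,
              n_lncrna = n_lncrna, n_immune_genes = n_immune_genes,
              n_immune_lncrna = n_immune_lncrna, n_de_lncrna = n_de_lncrna,
              de_log2_shift = de_log2_shift, factor_loading = factor_loading,
              n_true_pairs = n_true_pairs, true_betas = true_betas,
              baseline_hazard = baseline_hazard, censor_max = censor_max,
              stage_association = stage_association, seed = seed)
  counts <- c("n_tumor", "n_normal", "n_mrna", "n_lncrna", "n_immune_genes",
              "n_immune_lncrna", "n_de_lncrna", "n_true_pairs")
  for (f in counts)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1 ||
        cfg[[f]] != round(cfg[[f]]))
      stop("invalid generator_config field '", f, "': must be a count > 0")
  if (n_immune_genes > n_mrna)
    stop("invalid generator_config field 'n_immune_genes': exceeds n_mrna")
  if (n_immune_lncrna > n_lncrna)
    stop("invalid generator_config field 'n_immune_lncrna': exceeds n_lncrna")
  if (n_de_lncrna > n_immune_lncrna)
    stop("invalid generator_config field 'n_de_lncrna': exceeds n_immune_lncrna")
  if (n_true_pairs > n_de_lncrna * (n_de_lncrna - 1) / 2)
    stop("invalid generator_config field 'n_true_pairs': exceeds ",
         "n_de_lncrna choose 2")
  if (length(true_betas) != n_true_pairs)
    stop("invalid generator_config field 'true_betas': length must equal ",
         "n_true_pairs")
  if (!(factor_loading > 0 && factor_loading <= 1))
    stop("invalid generator_config field 'factor_loading': must be in (0, 1]")
  if (censor_max <= 0)
    stop("invalid generator_config field 'censor_max': must be > 0")
  if (baseline_hazard <= 0)
    stop("invalid generator_config field 'baseline_hazard': must be > 0")
  if (stage_association < 0 || stage_association > 1)
    stop("invalid generator_config field 'stage_association': must be in [0, 1]")
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic TCGA-like cohort with known ground truth
#'
#' Expression is generated on the log2 scale and exponentiated
#' (`2^y - 1`, floored at 0) so values look FPKM-like while the
#' differential-expression gates operate on the scale the generator
#' controls. Per sample, a latent immune factor `z ~ N(0, 1)` is drawn;
#' immune genes and immune lncRNAs are
#' `mu + s * (sqrt(f)*z + sqrt(1-f)*e)` with `f = factor_loading`, so the
#' population Pearson correlation between any immune lncRNA and any immune
#' gene equals `f` — the quantity the downstream correlation screen
#' thresholds.
#' Dysregulated lncRNAs receive a tumor-only `+de_log2_shift`. Survival
#' times are exponential with rate
#' `baseline_hazard * exp(sum(true_betas * S))` where `S` are the
#' rank-pair indicators of the true pairs; censoring is independent
#' Uniform(0, censor_max). The two members of each true pair share the
#' same baseline mean, so indicator prevalence is near 0.5.
#'
#' @param config a [generator_config()].
#' @return list of class `lnc_cohort`:
#'   `expr` ([expression_set]), `annotation` (gene biotype data.frame),
#'   `clinical` (data.frame), `immune_genes` (character), and `truth`
#'   (list: `immune_lncrna_ids`, `de_lncrna_ids`, `true_pairs` two-column
#'   matrix, `true_betas`, `per_sample_true_rs`).
#' @export
generate_cohort <- function(config = generator_config()) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, config)
  set.seed(config$seed)
  n_s <- config$n_tumor + config$n_normal
  sample_ids <- c(sprintf("SYN-%04d-01", seq_len(config$n_tumor)),
                  sprintf("SYN-%04d-11", seq_len(config$n_normal)))
  group <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
  is_tumor <- group == "tumor"

  mrna_ids <- sprintf("MRNA%04d", seq_len(config$n_mrna))
  lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lncrna))
  immune_genes <- mrna_ids[seq_len(config$n_immune_genes)]
  immune_lnc <- lnc_ids[seq_len(config$n_immune_lncrna)]
  de_lnc <- immune_lnc[seq_len(config$n_de_lncrna)]

  z <- stats::rnorm(n_s)                       # latent immune factor
  f <- config$factor_loading
  n_g <- config$n_mrna + config$n_lncrna
  gene_ids <- c(mrna_ids, lnc_ids)
  mu <- stats::runif(n_g, 2, 8)
  names(mu) <- gene_ids
  gene_sd <- 1.2

  # true pairs: unordered combinations of DE lncRNAs, members share mu so
  # the pair indicator has prevalence near 0.5; disjoint members when
  # possible so the indicators are independent
  if (2 * config$n_true_pairs <= config$n_de_lncrna) {
    true_pairs <- matrix(de_lnc[seq_len(2 * config$n_true_pairs)],
                         ncol = 2, byrow = TRUE)
  } else {
    combs <- utils::combn(de_lnc, 2)
    true_pairs <- t(combs[, seq_len(config$n_true_pairs), drop = FALSE])
  }
  colnames(true_pairs) <- c("lncrna_a", "lncrna_b")
  for (k in seq_len(nrow(true_pairs)))
    mu[true_pairs[k, 2]] <- mu[true_pairs[k, 1]]

  loads_factor <- gene_ids %in% c(immune_genes, immune_lnc)
  y <- matrix(stats::rnorm(n_g * n_s), n_g, n_s,
              dimnames = list(gene_ids, sample_ids))
  y[loads_factor, ] <- sqrt(f) *
    matrix(z, sum(loads_factor), n_s, byrow = TRUE) +
    sqrt(1 - f) * y[loads_factor, ]
  y <- mu + gene_sd * y
  y[de_lnc, is_tumor] <- y[de_lnc, is_tumor] + config$de_log2_shift
  vals <- pmax(2^y - 1, 0)
  expr <- expression_set(vals, group)

  # pair indicators on the FPKM-like scale over tumor samples
  tum_ids <- sample_ids[is_tumor]
  S <- vapply(seq_len(nrow(true_pairs)), function(k)
    as.numeric(vals[true_pairs[k, 1], tum_ids] >
               vals[true_pairs[k, 2], tum_ids]),
    numeric(config$n_tumor))
  true_rs <- as.vector(S %*% config$true_betas)
  names(true_rs) <- tum_ids

  rate <- config$baseline_hazard * exp(true_rs)
  t_event <- stats::rexp(config$n_tumor, rate = rate)
  t_cens <- stats::runif(config$n_tumor, 0, config$censor_max)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  clinical <- synth_clinical(tum_ids, time, event, true_rs,
                             config$stage_association)
  annotation <- data.frame(
    gene_id = gene_ids,
    biotype = rep(c("mRNA", "lncRNA"), c(config$n_mrna, config$n_lncrna)),
    stringsAsFactors = FALSE)
  truth <- list(immune_lncrna_ids = immune_lnc, de_lncrna_ids = de_lnc,
                true_pairs = true_pairs, true_betas = config$true_betas,
                per_sample_true_rs = true_rs)
  structure(list(expr = expr, annotation = annotation, clinical = clinical,
                 immune_genes = immune_genes, truth = truth,
                 config = config),
            class = "lnc_cohort")
}

# categorical clinical covariates; stage (and T/N/M, loosely) can be tied
# to the true risk-score quantile so chi-square stages have signal
synth_clinical <- function(ids, time, event, true_rs, stage_association) {
  n <- length(ids)
  q <- rank(true_rs, ties.method = "average") / (n + 1)
  mix <- function(base_probs, shift_probs, w, u) {
    # per-sample categorical draw from (1-w)*base + w*quantile-shifted probs
    vapply(seq_len(n), function(i) {
      p <- (1 - w) * base_probs + w * (base_probs * (1 - u[i]) +
                                         shift_probs * u[i])
      sample(seq_along(p), 1, prob = p)
    }, integer(1))
  }
  stage_lvl <- c("I", "II", "III", "IV")
  st <- mix(c(0.1, 0.3, 0.35, 0.25), c(0.02, 0.08, 0.4, 0.5),
            stage_association, q)
  tq <- mix(c(0.05, 0.3, 0.45, 0.2), c(0.02, 0.13, 0.45, 0.4),
            stage_association, q)
  nq <- mix(c(0.55, 0.2, 0.2, 0.05), c(0.35, 0.25, 0.3, 0.1),
            stage_association, q)
  mq <- mix(c(0.9, 0.1), c(0.75, 0.25), stage_association, q)
  nstat <- paste0("N", nq - 1)
  nstat[sample(n, max(1, round(0.05 * n)))] <- "Nx"
  mstat <- c("M0", "M1")[mq]
  mstat[sample(n, max(1, round(0.2 * n)))] <- "Mx"
  data.frame(
    sample_id = ids, time = time, event = event,
    age = round(stats::rnorm(n, 68, 10)),
    gender = sample(c("male", "female"), n, TRUE, prob = c(0.74, 0.26)),
    grade = sample(c("low", "high"), n, TRUE, prob = c(0.05, 0.95)),
    stage = stage_lvl[st],
    T = paste0("T", tq), N = nstat, M = mstat,
    stringsAsFactors = FALSE)
}

#' Write a cohort's pipeline input files
#'
#' Serializes the standard pipeline inputs: expression TSV, a minimal GTF
#' with `gene_type` attributes, clinical TSV, immune-gene list (one id per
#' line) and the ground-truth JSON.
#'
#' @param cohort an `lnc_cohort` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return Named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lnc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             gtf = file.path(dir, "genes.gtf"),
             clinical = file.path(dir, "clinical.tsv"),
             immune_genes = file.path(dir, "immune_genes.txt"),
             truth = file.path(dir, "truth.json"))
  write_expression(cohort$expr, paths["expression"])
  writeLines(minimal_gtf(cohort$annotation), paths["gtf"])
  utils::write.table(cohort$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(cohort$immune_genes, paths["immune_genes"])
  truth <- cohort$truth
  truth$true_pairs <- apply(truth$true_pairs, 1, paste, collapse = "|")
  jsonlite::write_json(truth, paths["truth"], auto_unbox = FALSE, digits = NA)
  invisible(paths)
}

minimal_gtf <- function(annotation) {
  bt <- ifelse(annotation$biotype == "mRNA", "protein_coding", "lncRNA")
  sprintf(
    'chr1\tsynthetic\tgene\t%d\t%d\t.\t+\t.\tgene_id "%s"; gene_type "%s";',
    seq_len(nrow(annotation)) * 1000L,
    seq_len(nrow(annotation)) * 1000L + 500L,
    annotation$gene_id, bt)
}
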