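#' Pipeline configuration
#'
#' Collects every input path and threshold of the workflow in one
#' validated object. Thresholds default to the canonical values of this
#' signature family: correlation screen r > 0.4 at p < 0.001, DE gates
#' |log2FC| > 1.5 and FDR < 0.05, effective-match minority fraction 0.2,
#' univariate Cox p < 0.05, 1000 LASSO cycles with ten folds and a strict
#' frequency bar of 100, ROC horizons 1/3/5 years.
#'
#' @param expression,gtf,clinical,immune_genes input file paths.
#' @param infiltration,ic50 optional precomputed matrices (TSV paths).
#' @param group_map optional sample-group sidecar (see [read_expression()]).
#' @param out_dir output directory for stage artifacts.
#' @param r_threshold,p_threshold correlation screen thresholds.
#' @param lfc_threshold,fdr_threshold differential-expression gates.
#' @param min_minority_frac effective-match bar.
#' @param cox_p univariate Cox gate.
#' @param n_reps,n_folds,freq_threshold stability-selection parameters.
#' @param horizons ROC horizons in years.
#' @param seed integer seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression = NULL, gtf = NULL, clinical = NULL,
                            immune_genes = NULL, infiltration = NULL,
                            ic50 = NULL, group_map = NULL,
                            out_dir = "lncpairrisk_run",
                            r_threshold = 0.4, p_threshold = 0.001,
                            lfc_threshold = 1.5, fdr_threshold = 0.05,
                            min_minority_frac = 0.2, cox_p = 0.05,
                            n_reps = 1000, n_folds = 10,
                            freq_threshold = 100, horizons = c(1, 3, 5),
                            seed = 1) {
  cfg <- as.list(environment())
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg)
  chk(r_threshold > -1 && r_threshold < 1, "r_threshold must be in (-1, 1)")
  for (f in c("p_threshold", "fdr_threshold", "cox_p"))
    chk(cfg[[f]] > 0 && cfg[[f]] <= 1,
        paste(f, "must be a probability in (0, 1]"))
  chk(lfc_threshold >= 0, "lfc_threshold must be >= 0")
  chk(min_minority_frac >= 0 && min_minority_frac < 0.5,
      "min_minority_frac must be in [0, 0.5)")
  chk(n_reps >= n_folds, "n_reps must be >= n_folds")
  chk(n_folds >= 2, "n_folds must be >= 2")
  chk(all(horizons > 0), "horizons must be positive")
  structure(cfg, class = "pipeline_config")
}

art <- function(config, name) file.path(config$out_dir, name)

need_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("stage ", stage, ": required upstream artifact missing: ", path)
  path
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a cohort and write its pipeline inputs
#'
#' Convenience stage wrapping [generate_cohort()] + [write_cohort()]; the
#' written files plug directly into `pipeline_config()`.
#'
#' @param gen_config a [generator_config()].
#' @param dir output directory.
#' @return named vector of written paths.
#' @export
stage_simulate <- function(gen_config = generator_config(), dir) {
  write_cohort(generate_cohort(gen_config), dir)
}

# shared ingest used by the screen stage
ingest_inputs <- function(config) {
  for (f in c("expression", "gtf", "clinical", "immune_genes"))
    if (is.null(config[[f]]))
      stop("stage ingest: config field '", f, "' is required")
  expr <- read_expression(config$expression, config$group_map)
  annot <- read_gtf_biotypes(config$gtf)
  clin <- read_clinical(config$clinical)
  immune_ids <- read_gene_list(config$immune_genes)
  parts <- split_lncrna(expr, annot)
  immune <- subset_expression(
    parts$mrna, genes = intersect(immune_ids, rownames(parts$mrna$values)))
  list(lncrna = parts$lncrna, immune = immune, clinical = clin)
}

#' Stage: correlation screen + differential expression
#'
#' Writes `immune_lncrnas.tsv` and `differential_expression.tsv` under the
#' configured output directory.
#'
#' @param config a [pipeline_config()].
#' @return invisible list `hits`, `de`, `de_ids`.
#' @export
stage_screen <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- ingest_inputs(config)
  hits <- pearson_screen(inp$lncrna, inp$immune,
                         r_threshold = config$r_threshold,
                         p_threshold = config$p_threshold)
  message("immune-related lncRNAs: ", nrow(hits), " of ",
          nrow(inp$lncrna$values))
  if (!nrow(hits)) stop("stage screen: no immune-related lncRNAs found")
  imm_lnc <- subset_expression(inp$lncrna, genes = hits$lncrna_id)
  grp <- imm_lnc$sample_group
  de <- moderated_t_de(
    subset_expression(imm_lnc, samples = grp == "tumor"),
    subset_expression(imm_lnc, samples = grp == "normal"),
    lfc_threshold = config$lfc_threshold,
    fdr_threshold = config$fdr_threshold)
  message("dysregulated immune-related lncRNAs: ", sum(de$de))
  write_tsv(hits, art(config, "immune_lncrnas.tsv"))
  write_tsv(de, art(config, "differential_expression.tsv"))
  invisible(list(hits = hits, de = de, de_ids = de$lncrna_id[de$de]))
}

#' Stage: build and filter the 0/1 pair matrix
#'
#' Reads the DE table written by [stage_screen()], restricts the
#' expression matrix to dysregulated lncRNAs over tumor samples, builds
#' all pair indicators and applies the effective-match filter. Writes
#' `pair_matrix.tsv`.
#'
#' @param config a [pipeline_config()].
#' @return invisible `pair_matrix`.
#' @export
stage_pair <- function(config) {
  de <- utils::read.delim(
    need_artifact(art(config, "differential_expression.tsv"), "pair"))
  de_ids <- de$lncrna_id[de$de]
  if (length(de_ids) < 2) stop("stage pair: < 2 dysregulated lncRNAs")
  expr <- read_expression(config$expression, config$group_map)
  de_tumor <- tumor_samples(subset_expression(expr, genes = de_ids))
  pm_all <- build_pairs(de_tumor)
  message("candidate pairs: ", nrow(pm_all$indicators))
  pm <- filter_effective(pm_all, config$min_minority_frac)
  write_pairs(pm, art(config, "pair_matrix.tsv"))
  invisible(pm)
}

#' Stage: select pairs and fit the signature
#'
#' Univariate Cox screen, repeated cross-validated LASSO-Cox stability
#' selection (seeded from `config$seed`), multivariate Cox fit and risk
#' scores. Writes `univariate_cox.tsv`, `stability_counts.tsv`,
#' `signature.tsv` and `risk_profile.tsv`.
#'
#' @param config a [pipeline_config()].
#' @return invisible list `univariate`, `stability`, `model`, `profile`.
#' @export
stage_fit <- function(config) {
  pm <- read_pairs(need_artifact(art(config, "pair_matrix.tsv"), "fit"))
  clin <- read_clinical(config$clinical)
  uni <- univariate_cox_screen(pm, clin, p_threshold = config$cox_p)
  message("prognostic pairs (univariate Cox): ", nrow(uni))
  if (!nrow(uni)) stop("stage fit: no pair passes the univariate screen")
  pm_prog <- subset_pairs(pm, uni$pair)
  stab <- lasso_stability_select(pm_prog, clin, n_reps = config$n_reps,
                                 n_folds = config$n_folds,
                                 freq_threshold = config$freq_threshold,
                                 seed = config$seed)
  message("stability-selected pairs: ", length(stab$selected))
  if (!length(stab$selected))
    stop("stage fit: stability selection chose no pairs")
  model <- fit_multivariate_cox(pm_prog, clin, stab$selected)
  profile <- risk_score(model, pm_prog)
  write_tsv(uni, art(config, "univariate_cox.tsv"))
  write_tsv(stab$counts, art(config, "stability_counts.tsv"))
  write_signature(model, art(config, "signature.tsv"))
  write_tsv(profile, art(config, "risk_profile.tsv"))
  invisible(list(univariate = uni, stability = stab, model = model,
                 profile = profile))
}

read_profile <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("risk_profile", "data.frame")
  df
}

#' Stage: evaluate the risk score
#'
#' Time-dependent ROC at every configured horizon, Youden-optimal cutoff
#' on the first horizon, risk-group assignment, KM/log-rank comparison,
#' independence Cox tables and the per-covariate AUC comparison. Writes
#' `roc_year*.tsv`, `auc_comparison.tsv`, `evaluation.json` and updates
#' `risk_profile.tsv` with groups.
#'
#' @param config a [pipeline_config()].
#' @return invisible list `rocs`, `cutoff`, `profile`, `survival`,
#'   `independence`, `auc_table`.
#' @export
stage_evaluate <- function(config) {
  profile <- read_profile(need_artifact(art(config, "risk_profile.tsv"),
                                        "evaluate"))
  clin <- read_clinical(config$clinical)
  rocs <- lapply(config$horizons, function(h)
    td_roc(profile, clin, h * DAYS_PER_YEAR))
  names(rocs) <- paste0("year", config$horizons)
  for (nm in names(rocs))
    write_tsv(with(rocs[[nm]],
                   data.frame(threshold = thresholds, tpr = tpr, fpr = fpr)),
              art(config, paste0("roc_", nm, ".tsv")))
  cut1 <- optimal_cutoff(rocs[[1]])
  profile <- assign_groups(profile, cut1)
  write_tsv(profile, art(config, "risk_profile.tsv"))
  surv_cmp <- km_logrank(profile, clin)
  indep <- independence_analysis(profile, clin)
  aucs <- compare_auc(profile, clin, config$horizons[1] * DAYS_PER_YEAR)
  write_tsv(aucs, art(config, "auc_comparison.tsv"))
  jsonlite::write_json(
    list(auc = lapply(rocs, `[[`, "auc"), cutoff = cut1$cutoff,
         cutoff_label = cut1$label, logrank_stat = surv_cmp$logrank_stat,
         logrank_p = surv_cmp$p),
    art(config, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(rocs = rocs, cutoff = cut1, profile = profile,
                 survival = surv_cmp, independence = indep,
                 auc_table = aucs))
}

#' Stage: association statistics
#'
#' Chi-square clinical associations, RS subgroup comparisons, and — when
#' the config provides matrices — infiltration, checkpoint-expression and
#' IC50 comparisons. Writes `associations_*.tsv`.
#'
#' @param config a [pipeline_config()].
#' @return invisible list of association tables.
#' @export
stage_associate <- function(config) {
  profile <- read_profile(need_artifact(art(config, "risk_profile.tsv"),
                                        "associate"))
  if (anyNA(profile$group) || !"group" %in% colnames(profile))
    stop("stage associate: run the evaluate stage first (no risk groups)")
  clin <- read_clinical(config$clinical)
  out <- list(clinical = clinical_association(profile, clin))
  write_tsv(out$clinical, art(config, "associations_clinical.tsv"))
  if (!is.null(config$infiltration)) {
    inf <- utils::read.delim(config$infiltration, check.names = FALSE)
    meth <- if ("method" %in% colnames(inf)) inf$method else NULL
    m <- as.matrix(inf[, setdiff(colnames(inf), c("cell_type", "method")),
                       drop = FALSE])
    rownames(m) <- if ("cell_type" %in% colnames(inf)) inf$cell_type
                   else rownames(inf)
    out$infiltration <- infiltration_association(profile, m, meth)
    write_tsv(out$infiltration, art(config, "associations_infiltration.tsv"))
  }
  if (!is.null(config$ic50)) {
    ic <- utils::read.delim(config$ic50, check.names = FALSE, row.names = 1)
    out$ic50 <- ic50_comparison(profile, as.matrix(ic))
    write_tsv(out$ic50, art(config, "associations_ic50.tsv"))
  }
  if (!is.null(config$expression)) {
    expr <- read_expression(config$expression, config$group_map)
    out$checkpoints <- expression_comparison(profile, expr)
    write_tsv(out$checkpoints, art(config, "associations_checkpoints.tsv"))
  }
  invisible(out)
}

#' Run the full pipeline
#'
#' Executes the stages in order — screen, pair, fit, evaluate, associate —
#' each writing its artifacts under `config$out_dir`, then writes a
#' machine-readable `manifest.json` recording the package version, seed,
#' thresholds and the per-stage selection funnel. A stage failure leaves
#' completed artifacts in place and re-raises the error with the stage
#' name.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with every stage result and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(name, f) {
    tryCatch(f(config), error = function(e)
      stop("pipeline failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE))
  }
  scr <- run_stage("screen", stage_screen)
  pm <- run_stage("pair", stage_pair)
  fit <- run_stage("fit", stage_fit)
  ev <- run_stage("evaluate", stage_evaluate)
  assoc <- run_stage("associate", stage_associate)
  manifest <- list(
    package = "lncPairRisk",
    version = as.character(utils::packageVersion("lncPairRisk")),
    seed = config$seed,
    thresholds = config[c("r_threshold", "p_threshold", "lfc_threshold",
                          "fdr_threshold", "min_minority_frac", "cox_p",
                          "n_reps", "n_folds", "freq_threshold")],
    horizons_years = config$horizons,
    funnel = list(immune_lncrna = nrow(scr$hits),
                  de_lncrna = length(scr$de_ids),
                  pairs_effective = nrow(pm$indicators),
                  pairs_prognostic = nrow(fit$univariate),
                  pairs_selected = length(fit$stability$selected)),
    auc = lapply(ev$rocs, `[[`, "auc"),
    cutoff = ev$cutoff$cutoff,
    logrank_p = ev$survival$p,
    stages = c("screen", "pair", "fit", "evaluate", "associate"))
  jsonlite::write_json(manifest, art(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(screen = scr, pairs = pm, fit = fit, evaluate = ev,
                 associations = assoc, manifest = manifest))
}
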