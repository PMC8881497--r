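#' Significance stars
#'
#' `ns` for p >= 0.05, then `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#' @param p numeric p-value(s).
#' @return character vector of stars.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = FALSE)
}

#' Chi-square association of risk group with clinical features
#'
#' One contingency table per feature (risk group x feature category),
#' Pearson chi-square without continuity correction. Features with a
#' single observed category are skipped with a warning; tables with an
#' expected count below 5 are flagged.
#'
#' @param profile a `risk_profile` with groups assigned.
#' @param clin clinical data.frame.
#' @param features feature columns to test.
#' @return data.frame `feature`, `test`, `statistic`, `df`, `p`,
#'   `low_expected` (logical).
#' @export
clinical_association <- function(profile, clin,
                                 features = c("age_group", "gender",
                                              "grade", "stage", "T", "N",
                                              "M", "event")) {
  d <- merge_profile(profile, clin)
  if (anyNA(d$group)) stop("assign risk groups first")
  d$age_group <- ifelse(encode_clinical(d, "age")$age > 65, ">65", "<=65")
  rows <- lapply(features, function(f) {
    if (!f %in% colnames(d)) return(NULL)
    v <- as.character(d[[f]])
    ok <- !is.na(v)
    if (length(unique(v[ok])) < 2) {
      warning("feature '", f, "' has a single category; skipped")
      return(NULL)
    }
    tab <- table(d$group[ok], v[ok])
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(feature = f, test = "chi-square",
               statistic = unname(ct$statistic), df = unname(ct$parameter),
               p = ct$p.value, low_expected = any(ct$expected < 5),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare risk scores across levels of a clinical feature
#'
#' Two observed levels are compared with a Wilcoxon rank-sum test; three
#' or more with Kruskal-Wallis. Small untied two-group samples use the
#' exact rank-sum distribution, larger or tied ones the normal
#' approximation with tie correction.
#'
#' @param profile a `risk_profile`.
#' @param clin clinical data.frame.
#' @param feature feature column name.
#' @return one-row data.frame `feature`, `test`, `statistic`, `p`.
#' @export
subgroup_rs_comparison <- function(profile, clin, feature) {
  d <- merge_profile(profile, clin)
  v <- as.character(d[[feature]])
  ok <- !is.na(v)
  lev <- unique(v[ok])
  if (length(lev) < 2) stop("feature '", feature, "' has < 2 levels")
  if (stats::var(d$rs[ok]) == 0) {
    warning("all risk scores identical; p = 1")
    return(data.frame(feature = feature, test = "degenerate",
                      statistic = NA_real_, p = 1))
  }
  if (length(lev) == 2) {
    ht <- stats::wilcox.test(d$rs[ok][v[ok] == lev[1]],
                             d$rs[ok][v[ok] == lev[2]])
    test <- "wilcoxon"
  } else {
    ht <- stats::kruskal.test(d$rs[ok], factor(v[ok]))
    test <- "kruskal-wallis"
  }
  data.frame(feature = feature, test = test,
             statistic = unname(ht$statistic), p = ht$p.value,
             stringsAsFactors = FALSE)
}

#' Associate immune-infiltration scores with the risk score
#'
#' Per infiltration row (a cell type as quantified by one deconvolution
#' method): Spearman correlation with RS across overlapping samples, and a
#' Wilcoxon rank-sum comparison between high- and low-risk groups. Rows
#' with p < 0.05 (Spearman) are flagged for display. Constant rows are
#' skipped with a warning.
#'
#' @param profile a `risk_profile` with groups assigned.
#' @param infiltration numeric matrix, rows = cell type entries, columns =
#'   samples; rownames like `"T cell CD8_CIBERSORT"` or supply `methods`.
#' @param methods optional character vector of method labels per row.
#' @return data.frame `cell_type`, `method`, `spearman_rho`, `p`,
#'   `wilcoxon_p`, `flagged`.
#' @export
infiltration_association <- function(profile, infiltration, methods = NULL) {
  infiltration <- as.matrix(infiltration)
  ids <- intersect(profile$sample_id, colnames(infiltration))
  if (length(ids) < 3) stop("fewer than 3 overlapping samples")
  rs <- profile$rs[match(ids, profile$sample_id)]
  grp <- profile$group[match(ids, profile$sample_id)]
  if (is.null(methods)) methods <- rep(NA_character_, nrow(infiltration))
  rows <- lapply(seq_len(nrow(infiltration)), function(i) {
    v <- infiltration[i, ids]
    if (stats::var(v) == 0) {
      warning("constant infiltration row '", rownames(infiltration)[i],
              "' skipped")
      return(NULL)
    }
    ct <- suppressWarnings(stats::cor.test(v, rs, method = "spearman"))
    wp <- if (length(unique(grp)) == 2)
      suppressWarnings(stats::wilcox.test(v[grp == "high"],
                                          v[grp == "low"]))$p.value
    else NA_real_
    data.frame(cell_type = rownames(infiltration)[i], method = methods[i],
               spearman_rho = unname(ct$estimate), p = ct$p.value,
               wilcoxon_p = wp, flagged = ct$p.value < 0.05,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default immune-checkpoint gene aliases
#'
#' Maps common figure labels to HGNC symbols: PD1 = PDCD1, PDL1 = CD274,
#' GAL9 = LGALS9, TIM-3 = HAVCR2, PD1LG2 = PDCD1LG2.
#' @export
CHECKPOINT_ALIASES <- c(CTLA4 = "CTLA4", LAG3 = "LAG3", PDL1 = "CD274",
                        PD1 = "PDCD1", TIGIT = "TIGIT", GAL9 = "LGALS9",
                        "TIM-3" = "HAVCR2", PD1LG2 = "PDCD1LG2")

#' Compare gene expression between risk groups
#'
#' Wilcoxon rank-sum test per gene (high vs low risk) with significance
#' stars and the direction of the median difference. Intended for immune
#' checkpoint genes but works for any gene list; aliases are resolved via
#' `aliases` and missing genes reported.
#'
#' @param profile a `risk_profile` with groups assigned.
#' @param expr an [expression_set] or genes x samples matrix.
#' @param genes labels to test; default the checkpoint panel.
#' @param aliases named character vector label -> rowname in `expr`.
#' @return data.frame `gene`, `symbol`, `statistic`, `p`, `stars`,
#'   `higher_in` ("high"/"low"/"none").
#' @export
expression_comparison <- function(profile, expr,
                                  genes = names(CHECKPOINT_ALIASES),
                                  aliases = CHECKPOINT_ALIASES) {
  x <- if (inherits(expr, "expression_set")) expr$values else as.matrix(expr)
  ids <- intersect(profile$sample_id, colnames(x))
  grp <- profile$group[match(ids, profile$sample_id)]
  rows <- lapply(genes, function(g) {
    sym <- if (g %in% names(aliases)) unname(aliases[g]) else g
    row <- if (sym %in% rownames(x)) sym else if (g %in% rownames(x)) g
           else NULL
    if (is.null(row)) {
      warning("gene '", g, "' (", sym, ") absent from expression matrix")
      return(data.frame(gene = g, symbol = sym, statistic = NA_real_,
                        p = NA_real_, stars = NA_character_,
                        higher_in = NA_character_))
    }
    hi <- x[row, ids][grp == "high"]; lo <- x[row, ids][grp == "low"]
    ht <- suppressWarnings(stats::wilcox.test(hi, lo))
    md <- stats::median(hi) - stats::median(lo)
    data.frame(gene = g, symbol = sym, statistic = unname(ht$statistic),
               p = ht$p.value, stars = as.character(p_stars(ht$p.value)),
               higher_in = if (md > 0) "high" else if (md < 0) "low"
                           else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare drug IC50 values between risk groups
#'
#' Wilcoxon rank-sum test per drug; the group with the lower median
#' imputed IC50 is flagged as the more chemosensitive one.
#'
#' @param profile a `risk_profile` with groups assigned.
#' @param ic50 numeric matrix, rows = drugs, columns = samples.
#' @return data.frame `drug`, `statistic`, `p`, `stars`,
#'   `more_sensitive` ("high"/"low"/"none").
#' @export
ic50_comparison <- function(profile, ic50) {
  ic50 <- as.matrix(ic50)
  ids <- intersect(profile$sample_id, colnames(ic50))
  if (!length(ids)) stop("no overlapping samples with the IC50 table")
  grp <- profile$group[match(ids, profile$sample_id)]
  rows <- lapply(rownames(ic50), function(dr) {
    hi <- ic50[dr, ids][grp == "high"]; lo <- ic50[dr, ids][grp == "low"]
    ht <- suppressWarnings(stats::wilcox.test(hi, lo))
    md <- stats::median(hi) - stats::median(lo)
    data.frame(drug = dr, statistic = unname(ht$statistic), p = ht$p.value,
               stars = as.character(p_stars(ht$p.value)),
               more_sensitive = if (md < 0) "high" else if (md > 0) "low"
                                else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
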