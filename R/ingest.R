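#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene ids and whose
#' header row holds sample ids. Duplicate gene rows are collapsed by mean.
#' Sample groups come either from an explicit map (preferred) or, as a
#' fallback, from a TCGA-style barcode suffix: sample ids ending in `-01`
#' (primary tumor) are labelled tumor, `-11` (solid tissue normal) normal.
#'
#' @param path path to the TSV file.
#' @param group_map optional: either a named character vector
#'   (sample id -> "tumor"/"normal"), a data.frame with columns `sample_id`
#'   and `group`, or a path to a two-column TSV of the same shape.
#' @return An [expression_set].
#' @export
read_expression <- function(path, group_map = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene-id column plus samples")
  gene_ids <- as.character(df[[1]])
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  mat <- df[, -1, drop = FALSE]
  for (j in seq_along(mat)) {
    v <- mat[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop("non-numeric expression value at gene '", gene_ids[bad],
           "', sample '", sample_ids[j], "'")
    }
  }
  mat <- as.matrix(mat)
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative expression value for gene '", gene_ids[neg[1, 1]], "'")
  # collapse duplicate gene rows by mean
  if (anyDuplicated(gene_ids)) {
    n_dup <- sum(duplicated(gene_ids))
    mat <- rowsum(mat, group = gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
    gene_ids <- rownames(mat)
    message("collapsed ", n_dup, " duplicate gene row(s) by mean")
  }
  rownames(mat) <- gene_ids
  colnames(mat) <- sample_ids
  expression_set(mat, infer_groups(sample_ids, group_map))
}

infer_groups <- function(sample_ids, group_map = NULL) {
  if (!is.null(group_map)) {
    if (is.character(group_map) && length(group_map) == 1 &&
        file.exists(group_map))
      group_map <- utils::read.delim(group_map, stringsAsFactors = FALSE)
    if (is.data.frame(group_map)) {
      if (!all(c("sample_id", "group") %in% colnames(group_map)))
        stop("group map needs columns 'sample_id' and 'group'")
      group_map <- stats::setNames(as.character(group_map$group),
                                   group_map$sample_id)
    }
    miss <- setdiff(sample_ids, names(group_map))
    if (length(miss))
      stop("no group label for sample(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    return(unname(group_map[sample_ids]))
  }
  # TCGA barcode fallback: -01 primary tumor, -11 solid tissue normal
  grp <- rep(NA_character_, length(sample_ids))
  grp[grepl("-01[A-Z]?$", sample_ids)] <- "tumor"
  grp[grepl("-11[A-Z]?$", sample_ids)] <- "normal"
  if (anyNA(grp))
    stop("cannot infer tumor/normal from barcode for sample(s): ",
         paste(utils::head(sample_ids[is.na(grp)], 5), collapse = ", "),
         " — provide group_map")
  grp
}

#' Default lncRNA biotype set
#'
#' Gencode dialects label long noncoding genes under several biotypes; this
#' covers the v26-era vocabulary. `protein_coding` always maps to mRNA.
#' @export
LNCRNA_BIOTYPES <- c("lncRNA", "antisense", "lincRNA", "processed_transcript",
                     "sense_intronic", "sense_overlapping")

#' Read gene biotypes from a GTF
#'
#' Parses `gene_id` / `gene_type` attributes and classifies each gene as
#' `mRNA` (protein_coding), `lncRNA` (member of `lncrna_biotypes`) or
#' `other`. A gene carrying both a protein_coding and a lncRNA record is
#' classified mRNA (conservative against calling coding genes noncoding),
#' with a warning. Records without both attributes are skipped with a
#' warning.
#'
#' @param path path to a GTF file.
#' @param lncrna_biotypes character vector of biotypes treated as lncRNA.
#' @return data.frame with columns `gene_id`, `biotype`
#'   (mRNA | lncRNA | other), one row per gene.
#' @export
read_gtf_biotypes <- function(path, lncrna_biotypes = LNCRNA_BIOTYPES) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  gene_id <- if ("gene_id" %in% colnames(md)) as.character(md$gene_id)
             else rep(NA_character_, length(gr))
  gene_type <- if ("gene_type" %in% colnames(md)) as.character(md$gene_type)
               else if ("gene_biotype" %in% colnames(md))
                 as.character(md$gene_biotype)
               else rep(NA_character_, length(gr))
  bad <- is.na(gene_id) | is.na(gene_type)
  if (any(bad))
    warning(sum(bad), " GTF record(s) without gene_id/gene_type skipped")
  gene_id <- gene_id[!bad]; gene_type <- gene_type[!bad]
  if (!length(gene_id)) stop("no genes parsed from ", path)
  class_of <- function(bt) {
    if (any(bt == "protein_coding")) "mRNA"
    else if (any(bt %in% lncrna_biotypes)) "lncRNA"
    else "other"
  }
  types <- split(gene_type, gene_id)
  conflict <- vapply(types, function(bt)
    any(bt == "protein_coding") && any(bt %in% lncrna_biotypes), logical(1))
  if (any(conflict))
    warning("gene(s) with both protein_coding and lncRNA records ",
            "classified as mRNA: ",
            paste(utils::head(names(types)[conflict], 5), collapse = ", "))
  data.frame(gene_id = names(types),
             biotype = vapply(types, class_of, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Split an expression set into mRNA and lncRNA partitions
#'
#' Genes classified `other` or absent from the annotation are dropped, with
#' a message reporting the count.
#'
#' @param expr an [expression_set].
#' @param annot data.frame from [read_gtf_biotypes()].
#' @return list with elements `mrna` and `lncrna`, both [expression_set]s,
#'   and `dropped`, the dropped gene ids.
#' @export
split_lncrna <- function(expr, annot) {
  stopifnot(inherits(expr, "expression_set"))
  cls <- stats::setNames(annot$biotype, annot$gene_id)[rownames(expr$values)]
  cls[is.na(cls)] <- "other"
  dropped <- rownames(expr$values)[cls == "other"]
  if (length(dropped))
    message("dropped ", length(dropped),
            " gene(s) that are neither mRNA nor lncRNA")
  if (!any(cls == "lncRNA")) stop("no lncRNA genes after annotation split")
  list(mrna = subset_expression(expr, genes = cls == "mRNA"),
       lncrna = subset_expression(expr, genes = cls == "lncRNA"),
       dropped = dropped)
}

#' Read and filter a clinical table
#'
#' Mandatory columns: `sample_id`, `time` (days), `event` (0/1). Rows with a
#' missing mandatory field or survival time of 0 days (or less) are removed;
#' the removal count is reported. Optional covariate columns (age, gender,
#' grade, stage, T, N, M) pass through untouched.
#'
#' @param path path to the clinical TSV.
#' @return data.frame with at least `sample_id`, `time`, `event`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("clinical table missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table")
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  keep <- !is.na(df$time) & df$time > 0 & df$event %in% c(0L, 1L)
  if (any(!keep))
    message("removed ", sum(!keep),
            " clinical row(s) with missing fields or 0-day survival")
  df[keep, , drop = FALSE]
}

#' Read an immune gene list (one id per line)
#'
#' @param path plain-text file, one gene id per line.
#' @return character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  unique(ids[nzchar(ids)])
}

#' Write an expression set to TSV
#'
#' @param expr an [expression_set].
#' @param path output path; first column `gene_id`, then one column per
#'   sample.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_set"))
  # 17 significant digits so the TSV round-trips doubles exactly
  vals <- apply(expr$values, 2, function(v) sprintf("%.17g", v))
  df <- data.frame(gene_id = rownames(expr$values), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(expr$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
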