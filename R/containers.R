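#' Expression set container
#'
#' Light container for a genes x samples expression matrix with a
#' tumor/normal label per sample. Values are FPKM-like: non-negative,
#' continuous, unlogged.
#'
#' @param values numeric matrix, rows = genes, columns = samples; dimnames
#'   required and unique.
#' @param sample_group character or factor of length `ncol(values)` with
#'   levels `"tumor"` and `"normal"`.
#' @return An object of class `expression_set`: a list with elements
#'   `values` and `sample_group` (named factor).
#' @export
expression_set <- function(values, sample_group) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression values need gene (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values)) stop("expression values contain NA")
  neg <- rownames(values)[apply(values < 0, 1, any)]
  if (length(neg))
    stop("negative expression values for gene(s): ",
         paste(utils::head(neg, 5), collapse = ", "))
  sample_group <- factor(as.character(sample_group),
                         levels = c("tumor", "normal"))
  if (length(sample_group) != ncol(values))
    stop("sample_group length (", length(sample_group),
         ") != number of samples (", ncol(values), ")")
  if (anyNA(sample_group))
    stop("every sample needs a 'tumor' or 'normal' group label")
  names(sample_group) <- colnames(values)
  structure(list(values = values, sample_group = sample_group),
            class = "expression_set")
}

#' @method print expression_set
#' @export
print.expression_set <- function(x, ...) {
  cat("<expression_set> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", sum(x$sample_group == "tumor"), " tumor / ",
      sum(x$sample_group == "normal"), " normal)\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Subset an expression set
#'
#' @param x an `expression_set`.
#' @param genes,samples character or logical/integer index; `NULL` keeps all.
#' @return An `expression_set` restricted to the requested rows/columns.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expression_set"))
  v <- x$values
  g <- x$sample_group
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    g <- g[colnames(v)]
  }
  expression_set(v, g)
}

#' Keep tumor samples only
#'
#' @param x an `expression_set`.
#' @return An `expression_set` with only the tumor columns.
#' @export
tumor_samples <- function(x) {
  stopifnot(inherits(x, "expression_set"))
  subset_expression(x, samples = names(x$sample_group)[x$sample_group == "tumor"])
}

# log2(x + 1), the working scale for correlation and DE
log2p1 <- function(x) log2(x + 1)
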