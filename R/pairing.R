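#' Build the 0/1 rank-pair indicator matrix
#'
#' For every unordered pair (A, B) of the supplied lncRNAs — taken in input
#' gene order, `n(n-1)/2` pairs in total — the per-sample indicator is 1
#' when expression(A) > expression(B) and 0 otherwise (ties give 0). The
#' indicator depends only on the within-sample ordering of the two genes,
#' so any strictly monotone per-sample transform of expression leaves the
#' matrix unchanged — the property that makes pair features platform- and
#' normalization-independent.
#'
#' @param expr [expression_set] (typically the dysregulated immune-related
#'   lncRNAs over tumor samples) or a bare genes x samples matrix.
#' @return Object of class `pair_matrix`: list with `indicators` (binary
#'   pairs x samples matrix, rownames `"A|B"`) and `pairs` (data.frame
#'   `name`, `lncrna_a`, `lncrna_b`, `prevalence`).
#' @export
build_pairs <- function(expr) {
  x <- if (inherits(expr, "expression_set")) expr$values else as.matrix(expr)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 lncRNAs to build pairs")
  idx <- utils::combn(n, 2)
  ind <- (x[idx[1, ], , drop = FALSE] > x[idx[2, ], , drop = FALSE]) * 1
  nm <- paste(rownames(x)[idx[1, ]], rownames(x)[idx[2, ]], sep = "|")
  rownames(ind) <- nm
  pairs <- data.frame(name = nm,
                      lncrna_a = rownames(x)[idx[1, ]],
                      lncrna_b = rownames(x)[idx[2, ]],
                      prevalence = rowMeans(ind),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(indicators = ind, pairs = pairs), class = "pair_matrix")
}

#' @method print pair_matrix
#' @export
print.pair_matrix <- function(x, ...) {
  cat("<pair_matrix> ", nrow(x$indicators), " pairs x ",
      ncol(x$indicators), " samples\n", sep = "")
  invisible(x)
}

#' Keep only informative ("effective match") pairs
#'
#' A pair whose indicator is almost always 0 or almost always 1 carries no
#' usable ordering information. A pair is retained iff its minority
#' fraction exceeds `min_minority_frac`, i.e. prevalence lies strictly
#' inside `(min_minority_frac, 1 - min_minority_frac)`. The rule is
#' symmetric in the pair's orientation.
#'
#' @param pm a `pair_matrix`.
#' @param min_minority_frac strict lower bound on the minority fraction;
#'   default 0.2.
#' @return Filtered `pair_matrix`; the dropped count is reported.
#' @export
filter_effective <- function(pm, min_minority_frac = 0.2) {
  stopifnot(inherits(pm, "pair_matrix"))
  prev <- pm$pairs$prevalence
  keep <- pmin(prev, 1 - prev) > min_minority_frac
  message("effective-match filter: kept ", sum(keep), " of ", length(keep),
          " pairs")
  if (!any(keep)) warning("no pairs survive the effective-match filter")
  structure(list(indicators = pm$indicators[keep, , drop = FALSE],
                 pairs = pm$pairs[keep, , drop = FALSE]),
            class = "pair_matrix")
}

#' Subset a pair matrix by pair name
#'
#' @param pm a `pair_matrix`.
#' @param names pair names to keep (order preserved).
#' @return A `pair_matrix` restricted to `names`.
#' @export
subset_pairs <- function(pm, names) {
  stopifnot(inherits(pm, "pair_matrix"))
  miss <- setdiff(names, pm$pairs$name)
  if (length(miss))
    stop("pair(s) not present: ", paste(miss, collapse = ", "))
  keep <- match(names, pm$pairs$name)
  structure(list(indicators = pm$indicators[keep, , drop = FALSE],
                 pairs = pm$pairs[keep, , drop = FALSE]),
            class = "pair_matrix")
}

#' Write / read a pair matrix as TSV
#'
#' Rows are pair names, columns tumor sample ids, cells 0/1.
#' @param pm a `pair_matrix`.
#' @param path TSV path.
#' @export
write_pairs <- function(pm, path) {
  stopifnot(inherits(pm, "pair_matrix"))
  df <- data.frame(pair = rownames(pm$indicators), pm$indicators,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ind <- as.matrix(df[, -1, drop = FALSE])
  rownames(ind) <- df[[1]]
  if (!all(ind %in% c(0, 1))) stop("pair matrix cells must be 0/1")
  ab <- do.call(rbind, strsplit(df[[1]], "|", fixed = TRUE))
  structure(list(indicators = ind,
                 pairs = data.frame(name = df[[1]], lncrna_a = ab[, 1],
                                    lncrna_b = ab[, 2],
                                    prevalence = rowMeans(ind),
                                    row.names = NULL,
                                    stringsAsFactors = FALSE)),
            class = "pair_matrix")
}
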