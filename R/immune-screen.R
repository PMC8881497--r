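#' Screen lncRNAs for correlation with immune genes
#'
#' Computes the Pearson correlation of every lncRNA against every immune
#' gene on `log2(x + 1)` values and keeps lncRNAs for which at least one
#' immune gene satisfies the correlation rule. The reported partner is the
#' immune gene with the largest correlation. P-values come from the exact
#' t transform `t = r * sqrt((n-2) / (1-r^2))` on `n - 2` degrees of
#' freedom, two-sided.
#'
#' @param lnc [expression_set] of lncRNAs.
#' @param immune [expression_set] of immune genes; must share the sample
#'   set of `lnc`.
#' @param r_threshold correlation threshold; default 0.4. The rule is the
#'   signed `r > r_threshold` by default.
#' @param p_threshold p-value threshold; default 0.001.
#' @param use_abs if `TRUE`, use `|r| > r_threshold` instead of the signed
#'   rule.
#' @param tumor_only if `TRUE`, correlate over tumor samples only; default
#'   uses all samples (the screen precedes differential expression).
#' @param log_transform compute on `log2(x + 1)` (default) or raw values.
#' @return data.frame of passing lncRNAs: `lncrna_id`,
#'   `best_partner_immune_gene`, `r`, `p`. The full lncRNA-level summary
#'   (pass or fail) is attached as attribute `"all"`.
#' @export
pearson_screen <- function(lnc, immune, r_threshold = 0.4,
                           p_threshold = 0.001, use_abs = FALSE,
                           tumor_only = FALSE, log_transform = TRUE) {
  stopifnot(inherits(lnc, "expression_set"), inherits(immune, "expression_set"))
  if (tumor_only) {
    lnc <- tumor_samples(lnc)
    immune <- tumor_samples(immune)
  }
  if (!identical(sort(colnames(lnc$values)), sort(colnames(immune$values))))
    stop("lncRNA and immune-gene matrices cover different sample sets")
  immune <- subset_expression(immune, samples = colnames(lnc$values))
  n <- ncol(lnc$values)
  if (n < 3) stop("need at least 3 samples for a correlation screen")

  xl <- if (log_transform) log2p1(t(lnc$values)) else t(lnc$values)
  xi <- if (log_transform) log2p1(t(immune$values)) else t(immune$values)
  const_l <- apply(xl, 2, stats::sd) == 0
  const_i <- apply(xi, 2, stats::sd) == 0
  if (any(const_l) || any(const_i))
    warning("skipped ", sum(const_l), " constant lncRNA(s) and ",
            sum(const_i), " constant immune gene(s)")
  xl <- xl[, !const_l, drop = FALSE]
  xi <- xi[, !const_i, drop = FALSE]
  if (!ncol(xl) || !ncol(xi))
    stop("no non-constant genes left to correlate")

  r <- stats::cor(xl, xi)                      # lncRNAs x immune genes
  crit <- if (use_abs) abs(r) else r
  best <- max.col(crit, ties.method = "first")
  best_r <- r[cbind(seq_len(nrow(r)), best)]
  best_crit <- crit[cbind(seq_len(nrow(r)), best)]
  p <- pearson_pvalue(best_r, n)
  pass <- best_crit > r_threshold & p < p_threshold
  all_df <- data.frame(lncrna_id = colnames(xl),
                       best_partner_immune_gene = colnames(xi)[best],
                       r = best_r, p = p, pass = pass,
                       row.names = NULL, stringsAsFactors = FALSE)
  out <- all_df[all_df$pass, setdiff(colnames(all_df), "pass"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- all_df
  out
}

#' Two-sided Pearson correlation p-value
#'
#' Exact t-distribution transform: `p = 2 P(T_{n-2} > |r| sqrt((n-2)/(1-r^2)))`.
#'
#' @param r correlation coefficient(s).
#' @param n sample size.
#' @return two-sided p-value(s).
#' @export
pearson_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
}

#' Moderated-t differential expression between tumor and normal
#'
#' Per gene, on `log2(x + 1)` values: group means, pooled residual
#' variance, and `log2fc = mean(tumor) - mean(normal)`. Residual variances
#' are shrunk towards a common prior by empirical Bayes: the prior degrees
#' of freedom `d0` and prior variance `s0^2` are estimated by matching
#' moments of `log(s^2)` through the digamma/trigamma relations of the
#' scaled F distribution, and the posterior variance is
#' `(d0*s0^2 + d*s^2) / (d0 + d)`. The moderated t statistic has `d0 + d`
#' degrees of freedom; p-values are BH-adjusted across genes. A gene is
#' called DE when `|log2fc| > lfc_threshold` (strict) and
#' `fdr < fdr_threshold`.
#'
#' @param tumor,normal [expression_set]s (or bare matrices) with the same
#'   genes; >= 2 samples per group.
#' @param lfc_threshold strict absolute log2-fold-change gate; default 1.5.
#' @param fdr_threshold BH-adjusted p gate; default 0.05.
#' @param prior_df optional override of the estimated prior degrees of
#'   freedom: `0` reduces to the ordinary pooled two-sample t, `Inf`
#'   replaces every variance by the prior.
#' @return data.frame, one row per gene: `lncrna_id`, `log2fc`, `t_mod`,
#'   `p`, `fdr`, `direction` ("up"/"down"), `de` (logical). Attributes
#'   `d0` and `s0_sq` hold the prior.
#' @export
moderated_t_de <- function(tumor, normal, lfc_threshold = 1.5,
                           fdr_threshold = 0.05, prior_df = NULL) {
  xt <- if (inherits(tumor, "expression_set")) tumor$values else as.matrix(tumor)
  xn <- if (inherits(normal, "expression_set")) normal$values else as.matrix(normal)
  if (!identical(rownames(xt), rownames(xn)))
    stop("tumor and normal matrices must share the same genes in order")
  n1 <- ncol(xt); n2 <- ncol(xn)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  lt <- log2p1(xt); ln <- log2p1(xn)
  m1 <- rowMeans(lt); m2 <- rowMeans(ln)
  log2fc <- m1 - m2
  d <- n1 + n2 - 2
  s2 <- (rowSums((lt - m1)^2) + rowSums((ln - m2)^2)) / d

  if (is.null(prior_df)) {
    pri <- fit_f_dist(s2, d)
  } else if (prior_df == 0) {
    pri <- list(d0 = 0, s0_sq = NA_real_)
  } else if (is.infinite(prior_df)) {
    pri <- list(d0 = Inf, s0_sq = fit_f_dist(s2, d)$s0_sq)
  } else {
    pri <- list(d0 = prior_df, s0_sq = fit_f_dist(s2, d)$s0_sq)
  }
  s2_post <- if (pri$d0 == 0) s2
             else if (is.infinite(pri$d0)) rep(pri$s0_sq, length(s2))
             else (pri$d0 * pri$s0_sq + d * s2) / (pri$d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- log2fc / se
  df_total <- min(pri$d0 + d, 1e6)             # cap for pt() stability
  p <- 2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(lncrna_id = rownames(xt), log2fc = log2fc,
                    t_mod = t_mod, p = p, fdr = fdr,
                    direction = ifelse(log2fc >= 0, "up", "down"),
                    de = abs(log2fc) > lfc_threshold & fdr < fdr_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- pri$d0
  attr(out, "s0_sq") <- pri$s0_sq
  out
}

# Moment-matching fit of the scaled-F prior for gene-wise variances:
# log(s^2) has mean log(s0^2) + digamma(d/2) - log(d/2) - digamma(d0/2) +
# log(d0/2) and excess variance trigamma(d0/2) beyond trigamma(d/2).
fit_f_dist <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s0_sq = mean(s2[ok])))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- stats::var(z) - trigamma(df / 2)
  if (!is.finite(ev) || ev <= 0)
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  d0 <- 2 * trigamma_inverse(ev)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton solve of trigamma(y) = x, x > 0 (monotone decreasing target)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}
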