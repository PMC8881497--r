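# Shared fixtures: everything is generated in code, no stored binaries.

# small cohort used by several suites (cached per test run)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(generator_config(
        n_tumor = 120, n_normal = 15, n_mrna = 60, n_lncrna = 90,
        n_immune_genes = 25, n_immune_lncrna = 30, n_de_lncrna = 10,
        n_true_pairs = 3, true_betas = c(1, -1, 1.2), seed = 42))
    cache
  }
})

# bare survival toy: exponential times, optional censoring
surv_toy <- function(n, scores, beta = 1, censor = NULL, seed = 1) {
  set.seed(seed)
  t_ev <- rexp(n, rate = 0.01 * exp(beta * scores))
  if (is.null(censor)) {
    time <- t_ev; event <- rep(1L, n)
  } else {
    t_c <- runif(n, 0, censor)
    time <- pmin(t_ev, t_c); event <- as.integer(t_ev <= t_c)
  }
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             time = time, event = event, stringsAsFactors = FALSE)
}

profile_of <- function(scores, ids = sprintf("S%03d", seq_along(scores)),
                       group = NA_character_) {
  structure(data.frame(sample_id = ids, rs = scores, group = group,
                       stringsAsFactors = FALSE),
            class = c("risk_profile", "data.frame"))
}

# brute-force Benjamini-Hochberg
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# classical (binary, uncensored) ROC AUC = Mann-Whitney with 0.5 tie credit
mw_auc <- function(status, score) {
  pos <- score[status == 1]; neg <- score[status == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# direct O/E hypergeometric log-rank statistic for two groups
logrank_brute <- function(time, event, group) {
  g <- as.integer(factor(group))  # 1/2
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# product-limit KM estimate evaluated at the event times
km_brute <- function(time, event, at) {
  s <- 1
  out <- numeric(length(at))
  for (i in seq_along(at)) {
    ts <- sort(unique(time[event == 1 & time <= at[i]]))
    s <- 1
    for (t in ts) s <- s * (1 - sum(time == t & event == 1) / sum(time >= t))
    out[i] <- s
  }
  out
}

# all permutations of 1..n as rows (recursive; for tiny n only)
all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub)))))
}

# load the bundled published 15-pair signature table
reference_signature <- function() {
  read.delim(system.file("extdata", "signature_blca15.tsv",
                         package = "lncPairRisk"),
             check.names = FALSE, stringsAsFactors = FALSE)
}
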