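grouped_profile <- function(n, frac_high = 0.5, seed = 1) {
  set.seed(seed)
  g <- rep(c("high", "low"), c(round(n * frac_high), n - round(n * frac_high)))
  profile_of(rnorm(n, ifelse(g == "high", 1, 0)),
             sprintf("S%03d", 1:n), g)
}

chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  (a * d - b * c)^2 * n / ((a + b) * (c + d) * (a + c) * (b + d))
}

test_that("chi-square association equals the closed 2x2 form", {
  # risk group x binary feature with counts (20,10 / 10,20)
  grp <- rep(c("high", "low"), each = 30)
  feat <- c(rep(c("A", "B"), c(20, 10)), rep(c("A", "B"), c(10, 20)))
  clin <- data.frame(sample_id = sprintf("S%03d", 1:60), time = 1:60,
                     event = 1L, myfeat = feat)
  pr <- profile_of(rnorm(60), clin$sample_id, grp)
  res <- clinical_association(pr, clin, features = "myfeat")
  expect_equal(res$statistic, chisq_2x2(20, 10, 10, 20), tolerance = 1e-12)
  expect_equal(res$p, pchisq(res$statistic, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("chi-square association: independence and perfect alignment", {
  set.seed(71)
  n <- 4000
  grp <- sample(c("high", "low"), n, TRUE)
  clin <- data.frame(sample_id = sprintf("S%04d", 1:n), time = 1,
                     event = 1L,
                     indep = sample(c("x", "y"), n, TRUE),
                     aligned = ifelse(grp == "high", "a", "b"),
                     solo = "only")
  pr <- profile_of(rnorm(n), clin$sample_id, grp)
  res <- clinical_association(pr, clin,
                              features = c("indep", "aligned"))
  expect_gt(res$p[res$feature == "indep"], 0.001)
  expect_lt(res$p[res$feature == "aligned"], 1e-10)
  expect_warning(clinical_association(pr, clin, features = "solo"),
                 "single category")
})

test_that("subgroup RS comparison picks the arity-appropriate test", {
  set.seed(72)
  n <- 200
  clin <- data.frame(sample_id = sprintf("S%03d", 1:n), time = 1,
                     event = 1L,
                     two = rep(c("a", "b"), n / 2),
                     three = sample(c("a", "b", "c"), n, TRUE))
  rs <- rnorm(n) + (clin$two == "b")       # +1 shift in one of two groups
  pr <- profile_of(rs, clin$sample_id)
  res2 <- subgroup_rs_comparison(pr, clin, "two")
  expect_equal(res2$test, "wilcoxon")
  expect_lt(res2$p, 0.001)
  res3 <- subgroup_rs_comparison(pr, clin, "three")
  expect_equal(res3$test, "kruskal-wallis")
  # identical subgroups sit at the null center (labels alternate a,b)
  pr0 <- profile_of(rep(rnorm(n / 2), each = 2), clin$sample_id)
  expect_gt(subgroup_rs_comparison(pr0, clin, "two")$p, 0.9)
})

test_that("Kruskal-Wallis H equals the rank-sum formula oracle", {
  rs <- c(2.1, 0.5, 3.3, 1.2, 4.8, 0.1, 2.9, 3.0, 1.7)
  lev <- rep(c("a", "b", "c"), each = 3)
  clin <- data.frame(sample_id = sprintf("S%03d", 1:9), time = 1,
                     event = 1L, f = lev)
  res <- subgroup_rs_comparison(profile_of(rs, clin$sample_id), clin, "f")
  r <- rank(rs); n <- 9
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, lev, function(x) sum(x)^2 / length(x))) - 3 * (n + 1)
  expect_equal(unname(res$statistic), h, tolerance = 1e-12)
})

test_that("Spearman association equals Pearson on ranks / closed form", {
  pr <- grouped_profile(30, seed = 4)
  set.seed(5)
  inf <- matrix(runif(60), 2, 30,
                dimnames = list(c("cellA", "cellB"), pr$sample_id))
  res <- infiltration_association(pr, inf,
                                  methods = c("CIBERSORT", "XCELL"))
  for (i in 1:2)
    expect_equal(res$spearman_rho[i],
                 cor(rank(inf[i, ]), rank(pr$rs)), tolerance = 1e-12)
  # 5-sample closed form 1 - 6*sum(d^2)/(n(n^2-1)) with one swapped rank
  pr5 <- profile_of(c(1, 2, 3, 4, 5), sprintf("P%d", 1:5),
                    rep(c("high", "low"), c(2, 3)))
  v <- c(1, 2, 3, 5, 4)
  inf5 <- matrix(v, 1, dimnames = list("cell", pr5$sample_id))
  res5 <- infiltration_association(pr5, inf5)
  d2 <- sum((rank(v) - rank(pr5$rs))^2)
  expect_equal(res5$spearman_rho, 1 - 6 * d2 / (5 * 24), tolerance = 1e-12)
  # identity gives rho 1; constant rows are skipped with a warning
  infid <- matrix(pr$rs, 1, dimnames = list("same", pr$sample_id))
  expect_equal(infiltration_association(pr, infid)$spearman_rho, 1)
  infc <- rbind(infid, const = rep(1, 30))
  expect_warning(infiltration_association(pr, infc), "constant")
  expect_error(infiltration_association(pr[1:2, ], inf), "3 overlapping")
})

test_that("checkpoint expression comparison reports direction and stars", {
  set.seed(73)
  n <- 120
  pr <- grouped_profile(n, seed = 6)
  hi <- pr$group == "high"
  x <- rbind(LGALS9 = rnorm(n, ifelse(hi, 2, 6)),    # higher in low risk
             HAVCR2 = rnorm(n, ifelse(hi, 6, 2)),    # higher in high risk
             CTLA4 = rnorm(n, 4))
  x <- pmax(x, 0)
  colnames(x) <- pr$sample_id
  res <- expression_comparison(pr, x, genes = c("GAL9", "TIM-3", "CTLA4"))
  expect_equal(res$higher_in[res$gene == "GAL9"], "low")
  expect_equal(res$stars[res$gene == "GAL9"], "***")
  expect_equal(res$higher_in[res$gene == "TIM-3"], "high")
  expect_equal(res$stars[res$gene == "CTLA4"], "ns")
  # direction flag equals the sign of the median difference
  for (i in seq_len(nrow(res))) {
    md <- median(x[res$symbol[i], hi]) - median(x[res$symbol[i], !hi])
    expect_equal(res$higher_in[i], if (md > 0) "high" else "low")
  }
  expect_warning(expression_comparison(pr, x, genes = "PD1"), "absent")
})

test_that("IC50 comparison flags the more sensitive group", {
  set.seed(74)
  n <- 100
  pr <- grouped_profile(n, seed = 8)
  hi <- pr$group == "high"
  ic <- rbind(cisplatin = rnorm(n, ifelse(hi, 2, 5)),   # high risk sensitive
              inert = rnorm(n, 4))
  colnames(ic) <- pr$sample_id
  res <- ic50_comparison(pr, ic)
  expect_equal(res$more_sensitive[res$drug == "cisplatin"], "high")
  expect_lt(res$p[res$drug == "cisplatin"], 0.001)
  expect_equal(res$stars[res$drug == "inert"], "ns")
})

test_that("small-sample Wilcoxon p equals exhaustive rank enumeration", {
  a <- c(1.2, 3.4, 0.8, 2.2)
  b <- c(4.1, 5.0, 2.9, 6.3)
  got <- wilcox.test(a, b)$p.value
  # enumerate all 8-choose-4 rank assignments
  r <- rank(c(a, b))
  obs_w <- sum(r[1:4]) - 4 * 5 / 2
  all_w <- apply(combn(8, 4), 2, function(i) sum(r[i]) - 10)
  exact_p <- mean(abs(all_w - 8) >= abs(obs_w - 8))  # center = n1*n2/2 = 8
  expect_equal(got, exact_p, tolerance = 1e-12)
  # the same route the association tests use
  pr <- profile_of(c(a, b), sprintf("S%d", 1:8),
                   rep(c("high", "low"), each = 4))
  ic <- matrix(c(a, b), 1, dimnames = list("drug", pr$sample_id))
  expect_equal(ic50_comparison(pr, ic)$p, exact_p, tolerance = 1e-12)
})

test_that("p_stars thresholds", {
  expect_equal(as.character(p_stars(c(0.2, 0.04, 0.009, 5e-4))),
               c("ns", "*", "**", "***"))
})
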