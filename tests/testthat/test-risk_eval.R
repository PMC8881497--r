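test_that("td_roc equals the binary Mann-Whitney ROC without censoring", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    scores <- round(rnorm(n), 1)             # ties likely
    clin <- surv_toy(n, scores, beta = 0.8, seed = rep)
    horizon <- unname(quantile(clin$time, 0.5))
    if (!any(clin$time <= horizon) || !any(clin$time > horizon)) next
    roc <- td_roc(profile_of(scores), clin, horizon)
    expect_equal(roc$auc,
                 mw_auc(as.integer(clin$time <= horizon), scores),
                 tolerance = 1e-12)
    # curve invariants
    expect_true(all(diff(roc$tpr) >= -1e-12))
    expect_true(all(diff(roc$fpr) >= -1e-12))
    expect_equal(c(roc$tpr[1], roc$fpr[1]), c(0, 0))
    expect_equal(c(roc$tpr[length(roc$tpr)], roc$fpr[length(roc$fpr)]),
                 c(1, 1))
  }
})

test_that("td_roc: perfect ranking gives AUC 1; null scores give ~0.5", {
  n <- 2000
  clin <- surv_toy(n, rep(0, n), beta = 0, seed = 5)
  perfect <- -clin$time                     # larger score = earlier event
  horizon <- unname(quantile(clin$time, 0.4))
  expect_equal(td_roc(profile_of(perfect), clin, horizon)$auc, 1)
  set.seed(6)
  null_sc <- rnorm(n)
  expect_lt(abs(td_roc(profile_of(null_sc), clin, horizon)$auc - 0.5), 0.03)
})

test_that("td_roc AUC is invariant under monotone score transforms and", {
  set.seed(62)
  n <- 300
  scores <- rnorm(n)
  clin <- surv_toy(n, scores, beta = 1, censor = 250, seed = 3)
  horizon <- unname(quantile(clin$time, 0.5))
  a <- td_roc(profile_of(scores), clin, horizon)$auc
  b <- td_roc(profile_of(exp(scores)), clin, horizon)$auc
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(td_roc(profile_of(scores), clin, max(clin$time) + 1),
               "horizon")
})

test_that("optimal_cutoff maximizes Youden J with the documented tie-break", {
  set.seed(63)
  scores <- c(0.1, 0.4, 0.9, 1.3, 1.8, 2.2, 2.9, 3.5)
  clin <- data.frame(sample_id = sprintf("S%03d", 1:8),
                     time = c(900, 800, 700, 650, 100, 90, 80, 70),
                     event = 1L)
  roc <- td_roc(profile_of(scores, clin$sample_id), clin, 365)
  res <- optimal_cutoff(roc)
  j <- roc$tpr - roc$fpr
  expect_equal(res$criterion, max(j))       # brute-force over the grid
  expect_true(res$cutoff %in% roc$thresholds)
  # perfectly separated: J = 1 and cutoff between the group ranges
  expect_equal(res$criterion, 1)
  expect_true(res$cutoff > 1.3 && res$cutoff <= 1.8)
  # degenerate ROC errors
  clin1 <- surv_toy(10, rep(1, 10), seed = 1)
  expect_error(optimal_cutoff(td_roc(profile_of(rep(1, 10)), clin1,
                                     median(clin1$time))),
               "identical")
})

test_that("null ROC ties break toward the largest threshold", {
  roc <- structure(list(horizon = 365,
                        thresholds = c(Inf, 3, 2, 1),
                        tpr = c(0, 0.3, 0.6, 1),
                        fpr = c(0, 0.3, 0.6, 1), auc = 0.5),
                   class = "td_roc")
  res <- optimal_cutoff(roc)
  expect_equal(res$criterion, 0)
  expect_equal(res$cutoff, Inf)
})

test_that("assign_groups: boundary goes low, partition is complete", {
  pr <- profile_of(c(0.9, 1.0, 1.0 + 1e-9, 2))
  out <- assign_groups(pr, 1.0)
  expect_equal(out$group, c("low", "low", "high", "high"))
  expect_equal(sum(table(out$group)), nrow(pr))
})

test_that("km_logrank matches the O/E hypergeometric oracle", {
  set.seed(64)
  for (rep in 1:15) {
    n <- sample(10:40, 1)
    grp <- sample(c("high", "low"), n, TRUE)
    if (length(unique(grp)) < 2) next
    time <- sample(1:50, n, TRUE)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) next
    clin <- data.frame(sample_id = sprintf("S%03d", 1:n),
                       time = time, event = event)
    pr <- profile_of(as.numeric(grp == "high"), clin$sample_id, grp)
    sc <- km_logrank(pr, clin)
    expect_equal(sc$logrank_stat, logrank_brute(time, event, grp),
                 tolerance = 1e-8)
    expect_equal(sc$p,
                 pchisq(sc$logrank_stat, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("km curves: start at 1, non-increasing, empirical when uncensored", {
  clin <- surv_toy(40, rnorm(40), seed = 7)     # no censoring
  grp <- rep(c("high", "low"), 20)
  pr <- profile_of(as.numeric(grp == "high"), clin$sample_id, grp)
  sc <- km_logrank(pr, clin)
  for (g in c("high", "low")) {
    cur <- sc$km[sc$km$group == g, ]
    expect_true(all(cur$surv <= 1 + 1e-12))
    expect_true(all(diff(cur$surv) <= 1e-12))
    tg <- clin$time[grp == g]
    emp <- vapply(cur$time, function(u) mean(tg > u), numeric(1))
    expect_equal(cur$surv, emp, tolerance = 1e-12)
    expect_equal(cur$surv, km_brute(tg, rep(1L, length(tg)), cur$time),
                 tolerance = 1e-12)
  }
  # identical data in both groups -> statistic 0, p 1
  clin2 <- rbind(clin, transform(clin, sample_id = paste0(sample_id, "b")))
  grp2 <- rep(c("high", "low"), each = 40)
  pr2 <- profile_of(as.numeric(grp2 == "high"), clin2$sample_id, grp2)
  sc2 <- km_logrank(pr2, clin2)
  expect_equal(sc2$logrank_stat, 0, tolerance = 1e-12)
  expect_equal(sc2$p, 1, tolerance = 1e-12)
})

test_that("log-rank chi-square ordering agrees with an exhaustive permutation null", {
  time <- c(3, 6, 8, 12, 15, 20)
  event <- c(1, 1, 1, 1, 1, 0)
  base_grp <- c("high", "high", "high", "low", "low", "low")
  obs <- logrank_brute(time, event, base_grp)
  combs <- combn(6, 3)
  perm_stats <- apply(combs, 2, function(i) {
    g <- rep("low", 6); g[i] <- "high"
    logrank_brute(time, event, g)
  })
  perm_p <- mean(perm_stats >= obs - 1e-12)
  chisq_p <- pchisq(obs, 1, lower.tail = FALSE)
  # both calls rank this split as unusually separated (same ordering side)
  expect_lt(perm_p, 0.5)
  expect_lt(chisq_p, 0.5)
})

test_that("independence analysis flags RS and ignores noise covariates", {
  coh <- generate_cohort(generator_config(
    n_tumor = 500, n_normal = 10, n_mrna = 30, n_lncrna = 40,
    n_immune_genes = 10, n_immune_lncrna = 12, n_de_lncrna = 6,
    n_true_pairs = 2, true_betas = c(1.2, -1), stage_association = 0,
    seed = 31))
  pr <- profile_of(coh$truth$per_sample_true_rs, coh$clinical$sample_id)
  res <- independence_analysis(pr, coh$clinical)
  expect_lt(res$univariate$p[res$univariate$covariate == "RS"], 1e-6)
  expect_lt(res$multivariate$p[res$multivariate$covariate == "RS"], 1e-6)
  noise_p <- res$multivariate$p[res$multivariate$covariate %in%
                                  c("gender", "grade")]
  expect_true(all(noise_p > 1e-4))
  # k = 1 equivalence: univariate row equals multivariate restricted to it
  one <- independence_analysis(pr, coh$clinical, covariates = character(0))
  expect_equal(one$univariate, one$multivariate, tolerance = 1e-12)
  # duplicated covariate triggers a collinearity warning
  clin_dup <- coh$clinical
  clin_dup$grade2 <- clin_dup$grade
  expect_warning(
    independence_analysis(pr, clin_dup,
                          covariates = c("grade", "grade2", "age")),
    "collinear")
})

test_that("compare_auc ranks the generating score first; rank-invariance", {
  coh <- generate_cohort(generator_config(
    n_tumor = 400, n_normal = 10, n_mrna = 30, n_lncrna = 40,
    n_immune_genes = 10, n_immune_lncrna = 12, n_de_lncrna = 6,
    n_true_pairs = 2, true_betas = c(1.5, -1.2), stage_association = 0,
    seed = 33))
  pr <- profile_of(coh$truth$per_sample_true_rs, coh$clinical$sample_id)
  tab <- suppressWarnings(compare_auc(pr, coh$clinical, 365.25))
  auc_rs <- tab$auc[tab$predictor == "RS"]
  expect_true(auc_rs > max(tab$auc[tab$predictor %in% c("gender", "grade")],
                           na.rm = TRUE))
  # AUC of a covariate equals AUC of its monotone transform
  clin2 <- coh$clinical
  clin2$age <- clin2$age * 3 + 7
  tab2 <- suppressWarnings(compare_auc(pr, clin2, 365.25))
  expect_equal(tab$auc[tab$predictor == "age"],
               tab2$auc[tab2$predictor == "age"], tolerance = 1e-12)
  # constant covariate reported as NA with warning
  clin3 <- coh$clinical
  clin3$grade <- "high"
  expect_warning(compare_auc(pr, clin3, 365.25), "constant")
})

test_that("clinical encodings follow the documented ordinal scheme", {
  clin <- data.frame(sample_id = "s", time = 1, event = 1, age = "70",
                     gender = "Male", grade = "High", stage = "iii",
                     T = "T3", N = "Nx", M = "M1")
  enc <- encode_clinical(clin)
  expect_equal(unname(unlist(enc)),
               c(70, 1, 1, 3, 3, NA, 1))
})
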