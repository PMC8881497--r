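#' Time-dependent ROC at a fixed horizon (IPCW, cumulative/dynamic)
#'
#' Cases are samples with an event by the horizon; controls are samples
#' still event-free beyond it. Samples censored before the horizon drop
#' out and the remaining cases/controls are reweighted by the inverse of
#' the Kaplan-Meier estimate of the censoring distribution (`1/G(T-)` for
#' cases, `1/G(horizon)` for controls), so the ROC is unbiased under
#' independent censoring. A sample is called test-positive at threshold
#' `c` when `rs >= c`; the threshold grid is `+Inf` followed by the unique
#' scores in descending order, so the curve runs from (0,0) to (1,1). AUC
#' is the trapezoid area. With zero censoring this reduces exactly to the
#' classical binary ROC of event-by-horizon status against the score.
#'
#' @param profile a `risk_profile` (or data.frame with `sample_id`, `rs`).
#' @param clin clinical data.frame with `sample_id`, `time`, `event`.
#' @param horizon evaluation time in days.
#' @return list of class `td_roc`: `horizon`, `thresholds`, `tpr`, `fpr`,
#'   `auc`.
#' @export
td_roc <- function(profile, clin, horizon) {
  d <- merge_profile(profile, clin)
  if (horizon <= 0 || horizon > max(d$time))
    stop("horizon must be positive and within observed follow-up")
  G <- censor_km(d$time, d$event)
  is_case <- d$event == 1 & d$time <= horizon
  is_control <- d$time > horizon
  if (!any(is_case)) stop("no cases (events by horizon)")
  if (!any(is_control)) stop("no controls (event-free beyond horizon)")
  w <- numeric(nrow(d))
  w[is_case] <- 1 / pmax(G(d$time[is_case], left = TRUE), 1e-12)
  w[is_control] <- 1 / pmax(G(horizon), 1e-12)
  thresholds <- c(Inf, sort(unique(d$rs), decreasing = TRUE))
  tpr <- fpr <- numeric(length(thresholds))
  wc <- sum(w[is_case]); wk <- sum(w[is_control])
  for (i in seq_along(thresholds)) {
    pos <- d$rs >= thresholds[i]
    tpr[i] <- sum(w[is_case & pos]) / wc
    fpr[i] <- sum(w[is_control & pos]) / wk
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(horizon = horizon, thresholds = thresholds,
                 tpr = tpr, fpr = fpr, auc = auc),
            class = "td_roc")
}

merge_profile <- function(profile, clin) {
  stopifnot(all(c("sample_id", "rs") %in% colnames(profile)),
            all(c("sample_id", "time", "event") %in% colnames(clin)))
  keep <- setdiff(colnames(clin), setdiff(colnames(profile), "sample_id"))
  d <- merge(as.data.frame(profile), clin[, keep, drop = FALSE],
             by = "sample_id")
  if (!nrow(d)) stop("no overlap between risk profile and clinical table")
  d
}

# Kaplan-Meier estimate of the censoring survival G(t) = P(C > t);
# returns a lookup closure, with left = TRUE giving the left limit G(t-)
censor_km <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  tt <- sf$time; ss <- sf$surv
  function(t, left = FALSE) {
    vapply(t, function(u) {
      i <- if (left) sum(tt < u) else sum(tt <= u)
      if (i == 0) 1 else ss[i]
    }, numeric(1))
  }
}

#' @method print td_roc
#' @export
print.td_roc <- function(x, ...) {
  cat("<td_roc> horizon ", x$horizon, " days, AUC = ",
      round(x$auc, 4), "\n", sep = "")
  invisible(x)
}

#' Optimal risk-score cutoff from a time-dependent ROC
#'
#' Maximizes Youden's J = TPR - FPR over the evaluated threshold grid;
#' ties broken toward the larger cutoff (fewer high-risk calls). This is
#' the package's reading of the "maximum inflection point" cutpoint rule
#' often labelled "AIC" in this signature literature; the label is kept in
#' the output for traceability.
#'
#' @param roc a `td_roc`.
#' @return list of class `cutoff_result`: `cutoff`, `criterion`
#'   (TPR - FPR at the cutoff), `horizon`, `label`.
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "td_roc"))
  if (length(roc$thresholds) <= 2)
    stop("degenerate ROC: all scores identical")
  j <- roc$tpr - roc$fpr
  best <- which(j == max(j))[1]       # thresholds descend: first = largest
  structure(list(cutoff = roc$thresholds[best], criterion = j[best],
                 horizon = roc$horizon,
                 label = "maximum inflection point (\"AIC\"), Youden J"),
            class = "cutoff_result")
}

#' Assign high/low risk groups
#'
#' `rs > cutoff` is high risk; `rs <= cutoff` (including the boundary) is
#' low risk.
#'
#' @param profile a `risk_profile`.
#' @param cutoff numeric cutoff or a `cutoff_result`.
#' @return The profile with its `group` column filled.
#' @export
assign_groups <- function(profile, cutoff) {
  if (inherits(cutoff, "cutoff_result")) cutoff <- cutoff$cutoff
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, !is.na(cutoff))
  profile$group <- ifelse(profile$rs > cutoff, "high", "low")
  profile
}

#' Kaplan-Meier curves and log-rank test between risk groups
#'
#' Product-limit survival curves per group and the two-group log-rank
#' chi-square statistic (O-E form with hypergeometric variance, 1 df).
#'
#' @param profile a `risk_profile` with groups assigned.
#' @param clin clinical data.frame (`sample_id`, `time`, `event`).
#' @return list of class `survival_comparison`: `group_sizes`,
#'   `logrank_stat`, `p`, `km` (data.frame `group`, `time`, `surv`).
#' @export
km_logrank <- function(profile, clin) {
  d <- merge_profile(profile, clin)
  if (anyNA(d$group)) stop("assign risk groups before km_logrank")
  if (length(unique(d$group)) < 2) stop("both risk groups must be non-empty")
  if (sum(d$event) == 0) stop("no events in either group")
  grp <- factor(d$group)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  stat <- sd_$chisq
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  km <- data.frame(
    group = rep(sub("^group=", "", names(sf$strata)),
                sf$strata),
    time = sf$time, surv = sf$surv, stringsAsFactors = FALSE)
  structure(list(group_sizes = table(grp), logrank_stat = stat, p = p,
                 km = km),
            class = "survival_comparison")
}

#' Ordinal encoding of clinical covariates for Cox/ROC models
#'
#' stage I-IV -> 1-4; T1-4 -> 1-4; N0-3 -> 0-3; M0/M1 -> 0/1; grade
#' low/high -> 0/1; gender female/male -> 0/1; age passes through as
#' years. Unknown codes (Tx/Nx/Mx or missing) become `NA` and are excluded
#' from ordinal models (they remain usable by categorical chi-square
#' tests).
#'
#' @param clin clinical data.frame.
#' @param covariates which columns to encode.
#' @return data.frame of numeric covariates, `NA` where unknown.
#' @export
encode_clinical <- function(clin,
                            covariates = c("age", "gender", "grade",
                                           "stage", "T", "N", "M")) {
  if (!length(covariates))
    return(as.data.frame(matrix(numeric(0), nrow = nrow(clin), ncol = 0)))
  enc <- list(
    age = function(v) suppressWarnings(as.numeric(v)),
    gender = function(v) c(female = 0, male = 1)[tolower(v)],
    grade = function(v) c(low = 0, high = 1)[tolower(v)],
    stage = function(v) c(I = 1, II = 2, III = 3, IV = 4)[toupper(v)],
    T = function(v) {
      x <- suppressWarnings(as.numeric(sub("^[Tt]", "", v)))
      ifelse(x %in% 1:4, x, NA_real_)
    },
    N = function(v) {
      x <- suppressWarnings(as.numeric(sub("^[Nn]", "", v)))
      ifelse(x %in% 0:3, x, NA_real_)
    },
    M = function(v) {
      x <- suppressWarnings(as.numeric(sub("^[Mm]", "", v)))
      ifelse(x %in% 0:1, x, NA_real_)
    })
  out <- lapply(covariates, function(cv) {
    if (!cv %in% colnames(clin)) return(rep(NA_real_, nrow(clin)))
    v <- clin[[cv]]
    if (is.null(enc[[cv]])) {
      # unlisted covariate: numeric if coercible, else factor codes
      num <- suppressWarnings(as.numeric(v))
      return(if (all(is.na(num) == is.na(v))) num
             else as.numeric(factor(v)))
    }
    unname(enc[[cv]](v))
  })
  names(out) <- covariates
  as.data.frame(out, check.names = FALSE)
}

#' Uni- and multivariate Cox independence analysis
#'
#' Tests whether the risk score predicts survival independently of the
#' ordinally encoded clinical covariates: one univariate Cox model per
#' covariate (and for RS), then a joint multivariate model over complete
#' cases. Collinear covariates trigger a warning with the model-matrix
#' condition number.
#'
#' @param profile a `risk_profile`.
#' @param clin clinical data.frame with survival and covariate columns.
#' @param covariates covariate names to include beside `RS`.
#' @return list with `univariate` and `multivariate` data.frames
#'   (`covariate`, `beta`, `hr`, `ci_low`, `ci_high`, `p`).
#' @export
independence_analysis <- function(profile, clin,
                                  covariates = c("age", "gender", "grade",
                                                 "stage", "T", "N", "M")) {
  d <- merge_profile(profile, clin)
  X <- encode_clinical(d, covariates)
  X$RS <- d$rs
  one_fit <- function(vars) {
    keep <- stats::complete.cases(X[vars]) & !is.na(d$time)
    xm <- as.matrix(X[keep, vars, drop = FALSE])
    if (length(vars) > 1) {
      kap <- kappa(cbind(1, scale(xm)), exact = TRUE)
      if (!is.finite(kap) || kap > 1e8)
        warning("collinear covariates (condition number ",
                format(kap, digits = 3), ")")
    }
    fit <- survival::coxph(survival::Surv(d$time[keep], d$event[keep]) ~ xm)
    beta <- unname(stats::coef(fit))
    se <- sqrt(diag(stats::vcov(fit)))
    data.frame(covariate = vars, beta = beta, hr = exp(beta),
               ci_low = exp(beta - 1.96 * se),
               ci_high = exp(beta + 1.96 * se),
               p = 2 * stats::pnorm(abs(beta) / se, lower.tail = FALSE),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  usable <- names(X)[vapply(X, function(v) sum(!is.na(v)) >= 10 &&
                              stats::var(v, na.rm = TRUE) > 0, logical(1))]
  uni <- do.call(rbind, lapply(usable, one_fit))
  multi <- one_fit(usable)
  list(univariate = uni, multivariate = multi)
}

#' Compare horizon AUCs of the risk score and clinical covariates
#'
#' Runs [td_roc()] at one horizon for the risk score and for each
#' ordinally encoded covariate; a constant or unresolvable covariate is
#' reported as `NA` with a warning.
#'
#' @param profile a `risk_profile`.
#' @param clin clinical data.frame.
#' @param horizon evaluation time in days; default one year (365.25).
#' @param covariates covariates to compare against `RS`.
#' @return data.frame `predictor`, `auc`, `n`.
#' @export
compare_auc <- function(profile, clin, horizon = 365.25,
                        covariates = c("age", "gender", "grade", "stage",
                                       "T", "N", "M")) {
  d <- merge_profile(profile, clin)
  X <- encode_clinical(d, covariates)
  X <- cbind(RS = d$rs, X)
  rows <- lapply(names(X), function(nm) {
    v <- X[[nm]]
    keep <- !is.na(v)
    if (sum(keep) < 3 || stats::var(v[keep]) == 0) {
      warning("predictor '", nm, "' constant or unresolvable; AUC = NA")
      return(data.frame(predictor = nm, auc = NA_real_, n = sum(keep)))
    }
    pr <- data.frame(sample_id = d$sample_id[keep], rs = v[keep])
    roc <- td_roc(pr, clin, horizon)
    data.frame(predictor = nm, auc = roc$auc, n = sum(keep),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Days in one year used for horizon arithmetic
#' @export
DAYS_PER_YEAR <- 365.25
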