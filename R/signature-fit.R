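#' Univariate Cox screen over pair indicators
#'
#' Fits one single-covariate Cox proportional-hazards model per pair
#' (partial likelihood, Efron ties by default) and keeps pairs whose Wald
#' p-value is below `p_threshold`. Constant pairs are skipped with a
#' warning.
#'
#' @param pm a `pair_matrix` over tumor samples.
#' @param clin clinical data.frame with `sample_id`, `time`, `event`;
#'   samples are matched by id (intersection used).
#' @param p_threshold Wald p-value gate; default 0.05.
#' @param ties ties method for the partial likelihood, `"efron"` (default)
#'   or `"breslow"`.
#' @return data.frame of passing pairs: `pair`, `beta`, `hr`, `ci_low`,
#'   `ci_high`, `p`. The full table is attached as attribute `"all"`.
#' @export
univariate_cox_screen <- function(pm, clin, p_threshold = 0.05,
                                  ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  al <- align_surv(pm, clin)
  if (sum(al$event) == 0) stop("no events in cohort; Cox screen impossible")
  rows <- lapply(rownames(al$x), function(nm) {
    s <- al$x[nm, ]
    if (stats::var(s) == 0) return(NULL)
    fit <- survival::coxph(survival::Surv(al$time, al$event) ~ s,
                           ties = ties)
    summ <- summary(fit)
    data.frame(pair = nm, beta = unname(stats::coef(fit)),
               hr = unname(summ$conf.int[1, "exp(coef)"]),
               ci_low = unname(summ$conf.int[1, "lower .95"]),
               ci_high = unname(summ$conf.int[1, "upper .95"]),
               p = unname(summ$coefficients[1, "Pr(>|z|)"]),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped) warning("skipped ", skipped, " constant pair(s)")
  all_df <- do.call(rbind, rows)
  if (is.null(all_df)) stop("no non-constant pairs to screen")
  rownames(all_df) <- NULL
  out <- all_df[all_df$p < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- all_df
  out
}

# match pair matrix columns with clinical rows; error if empty overlap
align_surv <- function(pm, clin) {
  stopifnot(inherits(pm, "pair_matrix"))
  ids <- intersect(colnames(pm$indicators), clin$sample_id)
  if (!length(ids)) stop("no overlap between pair matrix and clinical table")
  i <- match(ids, clin$sample_id)
  list(x = pm$indicators[, ids, drop = FALSE],
       time = clin$time[i], event = clin$event[i], ids = ids)
}

#' Stability selection by repeated cross-validated LASSO-Cox
#'
#' Each cycle draws a fresh fold assignment (stratified by event status so
#' no fold is event-free), runs ten-fold cross-validated LASSO-penalized
#' Cox regression, takes the nonzero-coefficient set at the CV-optimal
#' penalty (`lambda.min` by default), and increments each selected pair's
#' frequency. Pairs with frequency strictly greater than `freq_threshold`
#' form the selected set.
#'
#' @param pm a `pair_matrix` (typically the univariate-screen survivors).
#' @param clin clinical data.frame (`sample_id`, `time`, `event`).
#' @param n_reps number of LASSO cycles; default 1000.
#' @param n_folds cross-validation folds; default 10.
#' @param freq_threshold strict selection bar on frequency; default 100.
#' @param seed integer seed for the fold randomization.
#' @param lambda `"min"` (CV-deviance minimizer, default) or `"1se"`.
#' @param stratify_event stratify fold assignment by event status
#'   (default `TRUE`).
#' @return list with `counts` (data.frame `pair`, `frequency`) and
#'   `selected` (character vector of pair names).
#' @export
lasso_stability_select <- function(pm, clin, n_reps = 1000, n_folds = 10,
                                   freq_threshold = 100, seed = 1,
                                   lambda = c("min", "1se"),
                                   stratify_event = TRUE) {
  lambda <- match.arg(lambda)
  al <- align_surv(pm, clin)
  if (sum(al$event) < n_folds)
    stop("need at least n_folds events for stratified cross-validation")
  x <- t(al$x)
  y <- survival::Surv(al$time, al$event)
  freq <- stats::setNames(integer(nrow(al$x)), rownames(al$x))
  set.seed(seed)
  for (rep in seq_len(n_reps)) {
    foldid <- make_folds(al$event, n_folds, stratify_event)
    cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid)
    lam <- if (lambda == "min") cv$lambda.min else cv$lambda.1se
    b <- as.matrix(stats::coef(cv, s = lam))
    sel <- rownames(b)[b[, 1] != 0]
    freq[sel] <- freq[sel] + 1L
  }
  if (all(freq == 0))
    stop("no pair was ever selected across ", n_reps,
         " cycles; review thresholds/config")
  selected <- names(freq)[freq > freq_threshold]
  list(counts = data.frame(pair = names(freq), frequency = unname(freq),
                           stringsAsFactors = FALSE),
       selected = selected)
}

make_folds <- function(event, n_folds, stratify) {
  n <- length(event)
  foldid <- integer(n)
  if (stratify) {
    for (g in unique(event)) {
      i <- which(event == g)
      foldid[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
  } else {
    foldid <- sample(rep_len(seq_len(n_folds), n))
  }
  foldid
}

#' Fit the multivariate Cox signature model
#'
#' Joint Cox proportional-hazards fit over the selected pair indicators.
#' Reports, per pair, the coefficient beta, `HR = exp(beta)`, the Wald 95%
#' confidence limits `exp(beta -/+ 1.96 se)` and the Wald p-value — the
#' columns of the published signature-table convention (pair, coefficient,
#' HR, HR.95L, HR.95H, p-value).
#'
#' @param pm a `pair_matrix` containing at least the selected pairs.
#' @param clin clinical data.frame (`sample_id`, `time`, `event`).
#' @param selected character vector of pair names; default all pairs in
#'   `pm`.
#' @param ties ties method, `"efron"` (default) or `"breslow"`.
#' @return data.frame of class `signature_model`: `pair`, `beta`, `hr`,
#'   `ci_low`, `ci_high`, `p`; attributes `n_samples`, `n_events`, `ties`,
#'   `converged`.
#' @export
fit_multivariate_cox <- function(pm, clin, selected = pm$pairs$name,
                                 ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!length(selected)) stop("selected pair set is empty")
  pm <- subset_pairs(pm, selected)
  al <- align_surv(pm, clin)
  if (sum(al$event) <= length(selected))
    warning("fewer events (", sum(al$event), ") than pairs + 1; ",
            "estimates may be unstable")
  x <- t(al$x)
  fit <- tryCatch(
    survival::coxph(survival::Surv(al$time, al$event) ~ x, ties = ties),
    error = function(e) stop("multivariate Cox fit failed: ",
                             conditionMessage(e)))
  if (!is.null(fit$info) && isTRUE(fit$info$flag > 0))
    warning("possible separation / non-convergence in Cox fit")
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(abs(beta) > 15))
    warning("extreme coefficient(s) suggest separation")
  out <- data.frame(pair = selected, beta = beta, hr = exp(beta),
                    ci_low = exp(beta - 1.96 * se),
                    ci_high = exp(beta + 1.96 * se),
                    p = 2 * stats::pnorm(abs(beta) / se, lower.tail = FALSE),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_samples") <- length(al$ids)
  attr(out, "n_events") <- sum(al$event)
  attr(out, "ties") <- ties
  attr(out, "converged") <- fit$iter < fit$control$iter.max
  class(out) <- c("signature_model", "data.frame")
  out
}

#' Construct a signature model from known coefficients
#'
#' Builds a `signature_model` directly from pair names and coefficients —
#' for example a published signature table — so risk scores can be
#' computed without refitting.
#'
#' @param pair character vector of pair names (`"A|B"`).
#' @param beta numeric vector of Cox coefficients (log hazard ratios).
#' @return A `signature_model` data.frame with `hr = exp(beta)`.
#' @export
signature_model <- function(pair, beta) {
  stopifnot(length(pair) == length(beta), !anyDuplicated(pair))
  out <- data.frame(pair = as.character(pair), beta = as.numeric(beta),
                    hr = exp(beta), ci_low = NA_real_, ci_high = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("signature_model", "data.frame")
  out
}

#' Compute per-sample risk scores
#'
#' `RS(sample) = sum_i beta_i * S_i(sample)` over the model's pairs, with
#' `S_i` the 0/1 pair indicator — the linear predictor of the multivariate
#' Cox model.
#'
#' @param model a `signature_model`.
#' @param pm a `pair_matrix` containing every model pair.
#' @return data.frame of class `risk_profile`: `sample_id`, `rs`, `group`
#'   (NA until [assign_groups()] is applied).
#' @export
risk_score <- function(model, pm) {
  stopifnot(inherits(model, "signature_model"))
  miss <- setdiff(model$pair, pm$pairs$name)
  if (length(miss))
    stop("pair(s) missing from pair matrix: ", paste(miss, collapse = ", "))
  S <- pm$indicators[model$pair, , drop = FALSE]
  rs <- as.vector(crossprod(S, model$beta))
  if (any(!is.finite(rs))) stop("non-finite risk score produced")
  out <- data.frame(sample_id = colnames(S), rs = rs,
                    group = NA_character_, stringsAsFactors = FALSE)
  class(out) <- c("risk_profile", "data.frame")
  out
}

#' Write a signature model as a signature-table TSV
#'
#' @param model a `signature_model`.
#' @param path TSV path; columns pair, coefficient, HR, HR.95L, HR.95H,
#'   p-value.
#' @export
write_signature <- function(model, path) {
  df <- data.frame(pair = model$pair, coefficient = model$beta,
                   HR = model$hr, HR.95L = model$ci_low,
                   HR.95H = model$ci_high, `p-value` = model$p,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
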