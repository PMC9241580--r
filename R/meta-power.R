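#' Recover a log odds ratio and its SE from a printed CI
#'
#' Study-level results are usually published as an odds ratio with a 95%
#' confidence interval; pooling needs the log-scale point estimate and
#' standard error: `log_or = ln(or)`,
#' `se = (ln(ci_high) - ln(ci_low)) / (2 * 1.959964)`.
#'
#' @param or_point Odds ratio.
#' @param ci_low,ci_high 95% CI bounds (must bracket `or_point`).
#' @return List `log_or`, `se`.
#' @export
ci_to_se <- function(or_point, ci_low, ci_high) {
  if (!(ci_low > 0 && ci_low <= or_point && or_point <= ci_high)) {
    rlang::abort("require 0 < ci_low <= or_point <= ci_high")
  }
  se <- (log(ci_high) - log(ci_low)) / (2 * Z975)
  if (se == 0) rlang::warn("zero-width confidence interval: se = 0")
  list(log_or = log(or_point), se = se)
}

#' Fixed-effect meta-analysis of log odds ratios
#'
#' Inverse-variance pooling: weights `1/se^2`, pooled log OR the weighted
#' mean, pooled SE `(sum of weights)^(-1/2)`, normal CI and two-sided
#' p-value. Between-study heterogeneity is reported as Cochran's Q across
#' studies.
#'
#' @param log_or Per-study log odds ratios.
#' @param se Per-study standard errors (> 0).
#' @param labels Optional study labels.
#' @return List: `pooled` (one-row MR-estimate-style tibble,
#'   `method = "meta_fe"`), `per_study` (tibble with weights), `q_between`,
#'   `q_df`, `q_pval`.
#' @export
fixed_effect_meta <- function(log_or, se, labels = NULL) {
  if (length(log_or) == 0) rlang::abort("no studies to pool")
  stopifnot(length(se) == length(log_or), all(se > 0))
  labels <- labels %||% paste0("study_", seq_along(log_or))
  v <- 1 / se^2
  pooled_b <- sum(v * log_or) / sum(v)
  pooled_se <- 1 / sqrt(sum(v))
  q <- sum(v * (log_or - pooled_b)^2)
  q_df <- length(log_or) - 1L
  per_study <- tibble::tibble(
    study = labels, log_or = log_or, se = se,
    or = exp(log_or),
    ci_low = exp(log_or - Z975 * se),
    ci_high = exp(log_or + Z975 * se),
    weight_pct = 100 * v / sum(v)
  )
  list(
    pooled = new_mr_estimate("meta_fe", pooled_b, pooled_se,
                             k = length(log_or)),
    per_study = per_study,
    q_between = q,
    q_df = q_df,
    q_pval = if (q_df > 0) stats::pchisq(q, q_df, lower.tail = FALSE)
             else NA_real_
  )
}

#' Bonferroni significance threshold and p-value classification
#'
#' Family-wise threshold `alpha / n_tests`. A p-value below the threshold is
#' `significant`; below `alpha` but not the threshold, `suggestive`;
#' otherwise `null`.
#'
#' @param alpha Family-wise type-I error (default 0.05).
#' @param n_tests Number of outcomes tested.
#' @return The threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(n_tests >= 1)
  assert_scalar_prob(alpha, "alpha")
  alpha / n_tests
}

#' @rdname bonferroni_threshold
#' @param pvals P-values to classify.
#' @return `classify_pvalues`: character vector over
#'   `{"significant", "suggestive", "null"}`.
#' @export
classify_pvalues <- function(pvals, alpha = 0.05, n_tests) {
  thr <- bonferroni_threshold(alpha, n_tests)
  ifelse(pvals < thr, "significant",
         ifelse(pvals < alpha, "suggestive", "null"))
}

#' Analytical power for MR with a binary outcome
#'
#' Normal approximation behind the standard MR power calculators: with
#' outcome sample size `n_outcome`, case fraction `K`, exposure variance
#' explained `r2_x` and alternative odds ratio `or_alt`, the non-centrality
#' is `ncp = n_outcome * r2_x * K * (1 - K) * ln(or_alt)^2` and the
#' two-sided power at level `alpha` is
#' `Phi(sqrt(ncp) - z) + Phi(-sqrt(ncp) - z)` with `z` the upper
#' `alpha/2` normal quantile.
#'
#' @param n_outcome Total outcome sample size.
#' @param case_fraction Outcome case fraction `K` in (0, 1).
#' @param r2_x Variance of the exposure explained by the instruments,
#'   in (0, 1).
#' @param or_alt Odds ratio under the alternative.
#' @param alpha Type-I error (default 0.05).
#' @return Power in (0, 1).
#' @export
mr_power_binary <- function(n_outcome, case_fraction, r2_x, or_alt,
                            alpha = 0.05) {
  assert_scalar_prob(case_fraction, "case_fraction")
  assert_scalar_prob(alpha, "alpha")
  stopifnot(n_outcome > 0, r2_x >= 0, r2_x < 1, or_alt > 0)
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- n_outcome * r2_x * case_fraction * (1 - case_fraction) *
    log(or_alt)^2
  stats::pnorm(sqrt(ncp) - z) + stats::pnorm(-sqrt(ncp) - z)
}
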