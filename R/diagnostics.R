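#' Cochran's Q heterogeneity test
#'
#' Weighted sum of squared deviations of the per-variant Wald ratios from
#' the fixed-effect IVW estimate, with first-order weights
#' `w_j = beta_exp_j^2 / se_out_j^2`. Under homogeneity Q follows a
#' chi-square distribution with `k - 1` degrees of freedom; a p-value above
#' 0.05 is conventionally read as low heterogeneity.
#'
#' @param instrs Harmonized instruments (>= 2 rows).
#' @return List `q`, `df`, `pval`.
#' @export
cochran_q <- function(instrs) {
  instrs <- check_instruments(instrs, 2, "cochran_q")
  iw <- ivw_weights(instrs)
  theta <- sum(iw$w * iw$ratio) / sum(iw$w)
  q <- sum(iw$w * (iw$ratio - theta)^2)
  df <- nrow(instrs) - 1L
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

# LOO fixed-effect IVW estimates from weight sums; vectorised over j
loo_ivw_from_sums <- function(w, wr) {
  (sum(wr) - wr) / (sum(w) - w)
}

#' MR-PRESSO pleiotropy residual sum of squares test
#'
#' Simulation-based detection of horizontal pleiotropy.
#' * Global test: the observed residual sum of squares is
#'   `RSS = sum_j w_j (beta_out_j - theta_(-j) * beta_exp_j)^2`, where
#'   `theta_(-j)` is the leave-one-out fixed-effect IVW estimate; its null
#'   distribution is simulated by redrawing each outcome beta from
#'   `Normal(theta_(-j) * beta_exp_j, se_out_j)`. The empirical p-value uses
#'   the add-one estimator `(1 + #{RSS* >= RSS_obs}) / (n_sim + 1)` so it is
#'   never zero.
#' * Outlier test: each variant's observed RSS contribution is compared with
#'   its simulated contributions; per-variant p-values are Bonferroni
#'   corrected over k and variants below `outlier_alpha` are flagged.
#' * Distortion test (only when outliers are flagged): the relative change
#'   in the IVW estimate after removing the outliers is compared against a
#'   null of `n_removal` random equal-size removals.
#'
#' @param instrs Harmonized instruments (>= 4 rows).
#' @param n_sim Simulated datasets for the global/outlier tests
#'   (default 1000, minimum 100).
#' @param seed Integer seed, mandatory.
#' @param outlier_alpha Significance level for the Bonferroni-corrected
#'   outlier test (default 0.05).
#' @param n_removal Random removals for the distortion null (default 1000).
#' @return List: `global_rss`, `global_pval`, `outlier_pvals` (named,
#'   Bonferroni-corrected, capped at 1), `outliers` (character),
#'   `distortion_coef`, `distortion_pval` (both `NA` unless outliers were
#'   flagged), `n_sim`, `seed`.
#' @export
mr_presso <- function(instrs, n_sim = 1000, seed, outlier_alpha = 0.05,
                      n_removal = 1000) {
  if (missing(seed)) rlang::abort("mr_presso requires a `seed`")
  if (n_sim < 100) rlang::abort("mr_presso needs n_sim >= 100")
  instrs <- check_instruments(instrs, 4, "insufficient instruments for MR-PRESSO; mr_presso")
  k <- nrow(instrs)
  ids <- if ("variant_id" %in% names(instrs)) instrs$variant_id
         else as.character(seq_len(k))

  w <- instrs$beta_exp^2 / instrs$se_out^2
  ratio <- instrs$beta_out / instrs$beta_exp
  wr <- w * ratio
  theta_loo <- loo_ivw_from_sums(w, wr)
  expected <- theta_loo * instrs$beta_exp
  contrib_obs <- w * (instrs$beta_out - expected)^2
  rss_obs <- sum(contrib_obs)

  sim <- local_rng(seed, {
    # n_sim x k matrix of simulated outcome betas under the no-pleiotropy null
    bo_star <- matrix(stats::rnorm(n_sim * k, mean = rep(expected, each = n_sim),
                                   sd = rep(instrs$se_out, each = n_sim)),
                      nrow = n_sim)
    ratio_star <- sweep(bo_star, 2, instrs$beta_exp, "/")
    wr_star <- sweep(ratio_star, 2, w, "*")
    sum_w <- sum(w)
    sum_wr_star <- rowSums(wr_star)
    # theta*_(-j) for every sim and j, via the same weight-sum shortcut
    theta_loo_star <- (matrix(sum_wr_star, n_sim, k) - wr_star) /
      matrix(sum_w - w, n_sim, k, byrow = TRUE)
    resid_star <- bo_star - sweep(theta_loo_star, 2, instrs$beta_exp, "*")
    contrib_star <- sweep(resid_star^2, 2, w, "*")
    list(rss = rowSums(contrib_star), contrib = contrib_star)
  })

  global_pval <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)
  p_raw <- (1 + colSums(sweep(sim$contrib, 2, contrib_obs, ">="))) /
    (n_sim + 1)
  outlier_pvals <- pmin(1, p_raw * k)
  names(outlier_pvals) <- ids
  outliers <- ids[outlier_pvals < outlier_alpha]

  distortion_coef <- NA_real_
  distortion_pval <- NA_real_
  if (length(outliers) > 0 && length(outliers) < k - 1) {
    keep <- !ids %in% outliers
    theta_full <- sum(wr) / sum(w)
    theta_clean <- sum(wr[keep]) / sum(w[keep])
    distortion_coef <- (theta_clean - theta_full) / abs(theta_full)
    m <- sum(!keep)
    null_coefs <- local_rng(seed + 1L, {
      vapply(seq_len(n_removal), function(b) {
        drop <- sample.int(k, m)
        th <- sum(wr[-drop]) / sum(w[-drop])
        (th - theta_full) / abs(theta_full)
      }, numeric(1))
    })
    distortion_pval <- (1 + sum(abs(null_coefs) >= abs(distortion_coef))) /
      (n_removal + 1)
  }

  list(global_rss = rss_obs, global_pval = global_pval,
       outlier_pvals = outlier_pvals, outliers = outliers,
       distortion_coef = distortion_coef, distortion_pval = distortion_pval,
       n_sim = n_sim, seed = seed)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The p-value of the intercept from [mr_egger()]; a value above 0.05 is
#' conventionally read as minor pleiotropic bias.
#'
#' @param instrs Harmonized instruments (>= 3 rows).
#' @return The intercept p-value.
#' @export
egger_intercept_test <- function(instrs) {
  est <- mr_egger(instrs)
  est$pval[est$method == "egger_intercept"]
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect (multiplicative random-effects IVW, the
#' primary model) with each instrument excluded in turn; also accepts an
#' explicit single exclusion id for targeted sensitivity runs.
#'
#' @param instrs Harmonized instruments (>= 3 rows).
#' @param exclude_id If given, a single id: return just the estimate
#'   without that instrument.
#' @return Tibble with `excluded_id` plus the MR estimate columns; one row
#'   per instrument (or one row for an explicit `exclude_id`).
#' @export
leave_one_out <- function(instrs, exclude_id = NULL) {
  instrs <- check_instruments(instrs, 3, "leave_one_out")
  ids <- if ("variant_id" %in% names(instrs)) instrs$variant_id
         else as.character(seq_len(nrow(instrs)))
  run_without <- function(id) {
    est <- mr_ivw(instrs[ids != id, , drop = FALSE], "mre")
    dplyr::bind_cols(tibble::tibble(excluded_id = id), est)
  }
  if (!is.null(exclude_id)) {
    if (!exclude_id %in% ids) {
      rlang::abort(sprintf("exclude_id '%s' is not among the instruments",
                           exclude_id))
    }
    return(run_without(exclude_id))
  }
  dplyr::bind_rows(lapply(ids, run_without))
}
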