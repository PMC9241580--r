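check_instruments <- function(instrs, k_min, caller) {
  instrs <- tibble::as_tibble(instrs)
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  missing_cols <- setdiff(need, names(instrs))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("%s: instruments lack column(s) %s", caller,
                         paste(missing_cols, collapse = ", ")))
  }
  if ("status" %in% names(instrs)) instrs <- usable_instruments(instrs)
  if (nrow(instrs) < k_min) {
    rlang::abort(sprintf("%s requires at least %d instruments, got %d",
                         caller, k_min, nrow(instrs)))
  }
  if (any(instrs$se_exp <= 0) || any(instrs$se_out <= 0)) {
    rlang::abort(sprintf("%s: standard errors must be positive", caller))
  }
  instrs
}

# first-order IVW weights and per-variant Wald ratios
ivw_weights <- function(instrs) {
  list(w = instrs$beta_exp^2 / instrs$se_out^2,
       ratio = instrs$beta_out / instrs$beta_exp)
}

#' Wald ratio estimate from a single instrument
#'
#' The per-variant causal estimate: outcome effect divided by exposure
#' effect, with the first-order standard error `se_out / |beta_exp|`.
#'
#' @param instr A one-row harmonized instrument (or any list with
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`).
#' @return One-row MR estimate tibble (`method = "wald"`).
#' @export
wald_ratio <- function(instr) {
  instr <- check_instruments(instr, 1, "wald_ratio")[1, ]
  if (instr$beta_exp == 0) {
    rlang::abort("wald_ratio is undefined for beta_exp = 0")
  }
  theta <- instr$beta_out / instr$beta_exp
  se <- instr$se_out / abs(instr$beta_exp)
  new_mr_estimate("wald", theta, se, k = 1L)
}

#' Inverse-variance weighted estimate
#'
#' Precision-weighted pooling of per-variant Wald ratios with first-order
#' weights `w_j = beta_exp_j^2 / se_out_j^2` — equivalent to zero-intercept
#' weighted regression of outcome betas on exposure betas. The fixed-effect
#' standard error is `(sum w_j)^(-1/2)`; the multiplicative random-effects
#' model inflates it by `max(1, sqrt(Q / (k - 1)))` where `Q` is Cochran's
#' heterogeneity statistic.
#'
#' @param instrs Harmonized instruments (>= 2 rows; a single instrument is
#'   delegated to [wald_ratio()]).
#' @param model `"mre"` (multiplicative random effects, default) or `"fe"`.
#' @return One-row MR estimate tibble (`method = "ivw_mre"` or `"ivw_fe"`).
#' @export
mr_ivw <- function(instrs, model = c("mre", "fe")) {
  model <- match.arg(model)
  instrs <- check_instruments(instrs, 1, "mr_ivw")
  k <- nrow(instrs)
  if (k == 1) return(wald_ratio(instrs))
  if (any(instrs$beta_exp == 0)) {
    rlang::abort("mr_ivw: beta_exp = 0 gives an undefined Wald ratio")
  }
  iw <- ivw_weights(instrs)
  theta <- sum(iw$w * iw$ratio) / sum(iw$w)
  se_fe <- 1 / sqrt(sum(iw$w))
  if (model == "mre") {
    q <- sum(iw$w * (iw$ratio - theta)^2)
    se <- se_fe * max(1, sqrt(q / (k - 1)))
  } else {
    se <- se_fe
  }
  new_mr_estimate(paste0("ivw_", model), theta, se, k = k,
                  df = k - 1L)
}

# weighted interpolated median of `values` with weights `w` at probability p:
# order values, take cumulative weight midpoints, linearly interpolate
weighted_quantile_midpoint <- function(values, w, p = 0.5) {
  ord <- order(values)
  v <- values[ord]
  wn <- w[ord] / sum(w)
  s <- cumsum(wn) - wn / 2
  if (p <= s[1]) return(v[1])
  if (p >= s[length(s)]) return(v[length(v)])
  stats::approx(s, v, xout = p, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' The 50% point of the inverse-variance-weight-ordered Wald ratios,
#' consistent when at least half the total weight comes from valid
#' instruments. The standard error is a parametric bootstrap: exposure and
#' outcome betas are redrawn from normal distributions centred at the
#' observed values with their standard errors, and the SD of the replicate
#' medians is reported.
#'
#' @param instrs Harmonized instruments (>= 3 rows).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed, mandatory for reproducibility.
#' @return One-row MR estimate tibble (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(instrs, n_boot = 1000, seed) {
  if (missing(seed)) rlang::abort("mr_weighted_median requires a `seed`")
  instrs <- check_instruments(instrs, 3, "mr_weighted_median")
  iw <- ivw_weights(instrs)
  theta <- weighted_quantile_midpoint(iw$ratio, iw$w)
  k <- nrow(instrs)

  boot <- local_rng(seed, {
    vapply(seq_len(n_boot), function(b) {
      be <- stats::rnorm(k, instrs$beta_exp, instrs$se_exp)
      bo <- stats::rnorm(k, instrs$beta_out, instrs$se_out)
      wb <- be^2 / instrs$se_out^2
      weighted_quantile_midpoint(bo / be, wb)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  new_mr_estimate("weighted_median", theta, se, k = k)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with a free
#' intercept, after orienting every instrument so its exposure effect is
#' positive. Weights are `1 / se_out^2`. The slope estimates the causal
#' effect; the intercept estimates average directional pleiotropy. Standard
#' errors come from the weighted fit with the residual scale floored at 1
#' (multiplicative random-effects convention); p-values use the t
#' distribution with `k - 2` degrees of freedom.
#'
#' @param instrs Harmonized instruments (>= 3 rows).
#' @return Two-row MR estimate tibble: `egger_intercept` then `egger_slope`.
#' @export
mr_egger <- function(instrs) {
  instrs <- check_instruments(instrs, 3, "mr_egger")
  k <- nrow(instrs)
  sgn <- sign(instrs$beta_exp)
  sgn[sgn == 0] <- 1
  x <- instrs$beta_exp * sgn
  y <- instrs$beta_out * sgn
  w <- 1 / instrs$se_out^2
  fit <- stats::lm(y ~ x, weights = w)
  sigma <- summary(fit)$sigma
  # unscaled coefficient SEs straight from the weighted normal equations,
  # so an exact fit (sigma = 0) still yields finite SEs via the floor
  X <- cbind(1, x)
  se_unscaled <- sqrt(diag(solve(crossprod(X, w * X))))
  se <- se_unscaled * max(1, sigma)
  est <- stats::coef(fit)
  dplyr::bind_rows(
    new_mr_estimate("egger_intercept", est[[1]], se[[1]], k = k,
                    df = k - 2L, dist = "t"),
    new_mr_estimate("egger_slope", est[[2]], se[[2]], k = k,
                    df = k - 2L, dist = "t")
  )
}

#' Run the full estimator battery on one instrument set
#'
#' IVW in the multiplicative random-effects model (the primary estimate)
#' plus, when the instrument count permits, the weighted median and MR-Egger
#' complements. With a single instrument the Wald ratio is returned alone.
#'
#' @inheritParams mr_weighted_median
#' @return MR estimate tibble, one row per method.
#' @export
mr_all_methods <- function(instrs, n_boot = 1000, seed) {
  if (missing(seed)) rlang::abort("mr_all_methods requires a `seed`")
  instrs <- check_instruments(instrs, 1, "mr_all_methods")
  k <- nrow(instrs)
  if (k == 1) return(wald_ratio(instrs))
  out <- mr_ivw(instrs, "mre")
  if (k >= 3) {
    out <- dplyr::bind_rows(
      out,
      mr_weighted_median(instrs, n_boot = n_boot, seed = seed),
      mr_egger(instrs)
    )
  }
  out
}
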