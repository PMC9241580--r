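# shared builders for instrument tables and independent oracles

make_instruments <- function(beta_exp, beta_out, se_out,
                             se_exp = rep(1e-4, length(beta_exp)),
                             ids = sprintf("rs%03d", seq_along(beta_exp))) {
  tibble::tibble(variant_id = ids, beta_exp = beta_exp, se_exp = se_exp,
                 beta_out = beta_out, se_out = se_out)
}

random_instruments <- function(k, seed) {
  set.seed(seed)
  gamma <- runif(k, 0.05, 0.4)
  make_instruments(
    beta_exp = gamma + rnorm(k, 0, 0.01),
    beta_out = 0.1 * gamma + rnorm(k, 0, 0.02),
    se_out = runif(k, 0.01, 0.05),
    se_exp = runif(k, 0.005, 0.02)
  )
}

# independent weighted-median oracle: build the weighted empirical CDF as a
# piecewise-linear function through the cumulative-midpoint knots and invert
# it at 1/2 by root finding (vs the implementation's direct interpolation)
wm_oracle <- function(ratios, w) {
  ord <- order(ratios)
  v <- ratios[ord]
  wn <- w[ord] / sum(w)
  s <- cumsum(wn) - wn / 2
  if (0.5 <= s[1]) return(v[1])
  if (0.5 >= s[length(s)]) return(v[length(v)])
  cdf <- approxfun(v, s, ties = "ordered")
  uniroot(function(x) cdf(x) - 0.5, range(v), tol = 1e-13)$root
}

# zero-intercept WLS oracle for IVW via the closed-form normal equation
ivw_oracle <- function(instrs) {
  w <- 1 / instrs$se_out^2
  sum(w * instrs$beta_exp * instrs$beta_out) / sum(w * instrs$beta_exp^2)
}

# instrument table drawn under the exact null model for Q / MR-PRESSO:
# fixed exposure effects, outcome betas normal around theta * beta_exp
null_instruments <- function(k, theta = 0.1) {
  gamma <- seq(0.05, 0.3, length.out = k)
  se_out <- seq(0.01, 0.03, length.out = k)
  make_instruments(
    beta_exp = gamma,
    beta_out = theta * gamma + rnorm(k, 0, se_out),
    se_out = se_out
  )
}
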