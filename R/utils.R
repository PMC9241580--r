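#' @importFrom rlang %||% abort warn inform
#' @importFrom stats pnorm qnorm pchisq pt lm coef vcov rnorm runif sd
#' @importFrom utils head modifyList
NULL

# two-sided normal p-value from an estimate and its SE
z_pvalue <- function(beta, se) {
  2 * stats::pnorm(-abs(beta / se))
}

# 97.5% normal quantile used everywhere a Wald CI is formed; kept at full
# precision internally, rounding happens only at reporting
Z975 <- stats::qnorm(0.975)

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards: seeded operations never disturb (or depend
# on) global randomness.
local_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

assert_scalar_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is_scalar_number(x) || !lo_ok || !hi_ok) {
    rlang::abort(sprintf("`%s` must be a single number in %s0, 1%s, got %s",
                         name,
                         if (open_left) "(" else "[",
                         if (open_right) ")" else "]",
                         deparse(substitute(x))))
  }
  invisible(x)
}

new_mr_estimate <- function(method, beta, se, k, df = NA_integer_,
                            dist = c("normal", "t")) {
  dist <- match.arg(dist)
  if (dist == "t") {
    crit <- stats::qt(0.975, df)
    pval <- 2 * stats::pt(-abs(beta / se), df)
  } else {
    crit <- Z975
    pval <- z_pvalue(beta, se)
  }
  tibble::tibble(
    method = method,
    beta = beta,
    se = se,
    ci_low = beta - crit * se,
    ci_high = beta + crit * se,
    pval = pval,
    k = as.integer(k),
    df = as.integer(df)
  )
}
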