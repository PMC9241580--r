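test_that("Wald ratio: point estimate, SE, null case, sign invariance", {
  i1 <- make_instruments(0.1, 0.05, 0.01)
  w <- wald_ratio(i1)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.1)
  # null outcome effect: estimate 0, p = 1, CI symmetric about 0
  w0 <- wald_ratio(make_instruments(0.1, 0, 0.01))
  expect_equal(w0$beta, 0)
  expect_equal(w0$pval, 1)
  expect_equal(w0$ci_low, -w0$ci_high)
  # flipping both betas leaves the ratio unchanged
  wf <- wald_ratio(make_instruments(-0.1, -0.05, 0.01))
  expect_equal(wf$beta, w$beta)
  expect_equal(wf$se, w$se)
  expect_error(wald_ratio(make_instruments(0, 0.05, 0.01)), "beta_exp = 0")
})

test_that("IVW pools identical instruments like replicate measurements", {
  two <- make_instruments(c(0.1, 0.1), c(0.05, 0.05), c(0.01, 0.01))
  est <- mr_ivw(two, "fe")
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, wald_ratio(two[1, ])$se / sqrt(2))
})

test_that("IVW equals the zero-intercept WLS oracle", {
  three <- make_instruments(c(0.1, 0.2, 0.15), c(0.05, 0.08, 0.09),
                            c(0.01, 0.02, 0.015))
  expect_equal(mr_ivw(three, "fe")$beta, ivw_oracle(three),
               tolerance = 1e-12)
  for (s in 1:25) {
    instrs <- random_instruments(sample(3:12, 1), seed = s)
    expect_equal(mr_ivw(instrs, "fe")$beta, ivw_oracle(instrs),
                 tolerance = 1e-10)
  }
})

test_that("multiplicative random-effects SE floors at the fixed-effect SE", {
  # homogeneous data: Q < k - 1, so the floor engages
  hom <- make_instruments(c(0.1, 0.2, 0.3), c(0.05, 0.1, 0.15),
                          c(0.01, 0.01, 0.01))
  expect_equal(mr_ivw(hom, "mre")$se, mr_ivw(hom, "fe")$se)
  # heterogeneous data: the MRE SE is strictly larger
  het <- make_instruments(c(0.1, 0.2, 0.3), c(0.05, 0.2, -0.1),
                          c(0.001, 0.001, 0.001))
  expect_gt(mr_ivw(het, "mre")$se, mr_ivw(het, "fe")$se)
  expect_equal(mr_ivw(het, "mre")$beta, mr_ivw(het, "fe")$beta)
})

test_that("weighted median interpolates the weighted ratio CDF at one half", {
  # equal weights, ratios {0.2, 0.5, 0.9}: midpoints 1/6, 1/2, 5/6
  eq <- make_instruments(c(0.1, 0.1, 0.1), c(0.02, 0.05, 0.09),
                         c(0.01, 0.01, 0.01))
  expect_equal(mr_weighted_median(eq, n_boot = 50, seed = 1)$beta, 0.5)
  # all ratios equal: the median is that constant whatever the weights
  cc <- make_instruments(c(0.1, 0.2, 0.3), c(0.03, 0.06, 0.09),
                         c(0.01, 0.03, 0.02))
  expect_equal(mr_weighted_median(cc, n_boot = 50, seed = 1)$beta, 0.3)
  # arbitrary weights match the independent CDF-inversion oracle
  for (s in 1:20) {
    instrs <- random_instruments(5, seed = 100 + s)
    got <- mr_weighted_median(instrs, n_boot = 50, seed = 1)$beta
    w <- instrs$beta_exp^2 / instrs$se_out^2
    expect_equal(got, wm_oracle(instrs$beta_out / instrs$beta_exp, w),
                 tolerance = 1e-9)
  }
})

test_that("weighted median with equal weights is the unweighted median", {
  for (s in 1:5) {
    set.seed(s)
    k <- 7
    ratios <- sort(rnorm(k))
    instrs <- make_instruments(rep(0.1, k), 0.1 * ratios, rep(0.01, k))
    got <- mr_weighted_median(instrs, n_boot = 50, seed = 2)$beta
    expect_equal(got, wm_oracle(ratios, rep(1, k)))
  }
})

test_that("weighted median bootstrap SE is seed-reproducible", {
  instrs <- random_instruments(8, seed = 9)
  a <- mr_weighted_median(instrs, n_boot = 200, seed = 33)
  b <- mr_weighted_median(instrs, n_boot = 200, seed = 33)
  expect_identical(a, b)
  expect_error(mr_weighted_median(instrs, n_boot = 10), "seed")
})

test_that("Egger recovers exact linear and affine generating models", {
  gamma <- c(0.1, 0.15, 0.2, 0.3)
  lin <- make_instruments(gamma, 0.3 * gamma, rep(0.01, 4))
  est <- mr_egger(lin)
  expect_equal(est$beta[est$method == "egger_slope"], 0.3, tolerance = 1e-12)
  expect_equal(est$beta[est$method == "egger_intercept"], 0,
               tolerance = 1e-12)
  aff <- make_instruments(gamma, 0.02 + 0.3 * gamma, rep(0.01, 4))
  est2 <- mr_egger(aff)
  expect_equal(est2$beta[est2$method == "egger_slope"], 0.3,
               tolerance = 1e-10)
  expect_equal(est2$beta[est2$method == "egger_intercept"], 0.02,
               tolerance = 1e-10)
})

test_that("Egger coefficients match a weighted-least-squares oracle", {
  for (s in 1:25) {
    instrs <- random_instruments(sample(4:10, 1), seed = 200 + s)
    # orient towards positive exposure effect, as the estimator does
    sgn <- sign(instrs$beta_exp)
    x <- instrs$beta_exp * sgn
    y <- instrs$beta_out * sgn
    w <- 1 / instrs$se_out^2
    # normal-equations oracle
    sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
    sxx <- sum(w * x^2); sxy <- sum(w * x * y)
    slope <- (sw * sxy - sx * sy) / (sw * sxx - sx^2)
    intercept <- (sy - slope * sx) / sw
    est <- mr_egger(instrs)
    expect_equal(est$beta[est$method == "egger_slope"], slope,
                 tolerance = 1e-10)
    expect_equal(est$beta[est$method == "egger_intercept"], intercept,
                 tolerance = 1e-10)
  }
})

test_that("estimators are invariant to ordering and joint sign flips", {
  instrs <- random_instruments(9, seed = 77)
  perm <- instrs[sample.int(9), ]
  flip <- instrs
  idx <- c(2, 5, 7)
  flip$beta_exp[idx] <- -flip$beta_exp[idx]
  flip$beta_out[idx] <- -flip$beta_out[idx]
  for (variant in list(perm, flip)) {
    expect_equal(mr_ivw(variant, "mre")$beta, mr_ivw(instrs, "mre")$beta)
    expect_equal(mr_ivw(variant, "mre")$se, mr_ivw(instrs, "mre")$se)
    expect_equal(mr_egger(variant)$beta, mr_egger(instrs)$beta)
    expect_equal(
      mr_weighted_median(variant, n_boot = 10, seed = 4)$beta,
      mr_weighted_median(instrs, n_boot = 10, seed = 4)$beta)
  }
})

test_that("IVW with equal inputs reduces to the mean of Wald ratios", {
  instrs <- make_instruments(rep(0.2, 6), c(0.01, 0.02, 0.05, 0.03, 0.06, 0.04),
                             rep(0.02, 6))
  expect_equal(mr_ivw(instrs, "fe")$beta,
               mean(instrs$beta_out / instrs$beta_exp))
})

test_that("the method battery degrades gracefully with instrument count", {
  one <- make_instruments(0.1, 0.05, 0.01)
  expect_equal(mr_all_methods(one, seed = 1)$method, "wald")
  two <- make_instruments(c(0.1, 0.2), c(0.05, 0.1), c(0.01, 0.01))
  expect_equal(mr_all_methods(two, seed = 1)$method, "ivw_mre")
  expect_error(mr_weighted_median(two, seed = 1), "at least 3")
  expect_error(mr_egger(two), "at least 3")
})
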