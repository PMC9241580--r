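make_exposure <- function(df) {
  defaults <- tibble::tibble(
    variant_id = df$variant_id,
    chrom = df$chrom %||% "1",
    pos = df$pos %||% (seq_len(nrow(df)) * 30000000L),
    effect_allele = "A", other_allele = "G",
    eaf = df$eaf %||% 0.3,
    beta = df$beta %||% 0.1,
    se = df$se %||% 0.01,
    pval = df$pval,
    n = 10000L)
  summary_dataset(defaults, trait_name = "exposure")
}
`%||%` <- rlang::`%||%`

test_that("all-independent significant candidates pass every stage", {
  exp <- make_exposure(tibble::tibble(
    variant_id = sprintf("rs%d", 1:8), pval = 1e-9))
  sel <- select_instruments(exp, ld_table(), selection_config())
  expect_setequal(sel$instrument_ids, sprintf("rs%d", 1:8))
  expect_true(all(sel$audit$n_in == sel$audit$n_out))
})

test_that("greedy pruning keeps only the best of a correlated trio", {
  exp <- make_exposure(tibble::tibble(
    variant_id = c("rsA", "rsB", "rsC"),
    chrom = "2", pos = c(1000000L, 1050000L, 1100000L),
    pval = c(1e-10, 1e-9, 1e-8 * 0.99)))
  ld <- ld_table(tibble::tibble(id_a = c("rsA", "rsA", "rsB"),
                                id_b = c("rsB", "rsC", "rsC"),
                                r2 = 0.9))
  sel <- select_instruments(exp, ld, selection_config())
  expect_equal(sel$instrument_ids, "rsA")
})

test_that("unknown LD is conservative within the window, permissive beyond", {
  # two co-located variants with no LD entry: the weaker is pruned
  exp <- make_exposure(tibble::tibble(
    variant_id = c("rsA", "rsB"), chrom = "3",
    pos = c(1000000L, 1200000L), pval = c(1e-10, 1e-9)))
  sel <- select_instruments(exp, ld_table(), selection_config())
  expect_equal(sel$instrument_ids, "rsA")
  # same pair 20 Mb apart: both kept
  exp2 <- make_exposure(tibble::tibble(
    variant_id = c("rsA", "rsB"), chrom = "3",
    pos = c(1000000L, 21000000L), pval = c(1e-10, 1e-9)))
  sel2 <- select_instruments(exp2, ld_table(), selection_config())
  expect_setequal(sel2$instrument_ids, c("rsA", "rsB"))
})

test_that("MAF and exclusion stages remove what they should", {
  exp <- make_exposure(tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    eaf = c(0.3, 0.005, 0.996, 0.25),
    pval = c(1e-9, 1e-9, 1e-9, 1e-9)))
  sel <- select_instruments(exp, ld_table(),
                            selection_config(exclusion_ids = "rs4"))
  expect_equal(sel$instrument_ids, "rs1")
  aud <- sel$audit
  expect_equal(aud$n_out[aud$stage == "maf"], 2)
  expect_equal(aud$removed_ids[aud$stage == "exclusion"], "rs4")
})

test_that("an empty final set aborts with stage-by-stage counts", {
  exp <- make_exposure(tibble::tibble(variant_id = "rs1", pval = 1e-9))
  expect_error(
    select_instruments(exp, ld_table(),
                       selection_config(exclusion_ids = "rs1")),
    "significance 1->1")
})

test_that("selection is invariant to input row order", {
  fx <- make_example_fixture()
  cfg <- selection_config(exclusion_ids = fx$exclusions$variant_id)
  base <- sort(select_instruments(fx$exposure, fx$ld, cfg)$instrument_ids)
  for (s in 1:3) {
    set.seed(s)
    rec <- fx$exposure$records
    shuffled <- summary_dataset(rec[sample.int(nrow(rec)), ],
                                trait_name = "shuffled")
    got <- sort(select_instruments(shuffled, fx$ld, cfg)$instrument_ids)
    expect_equal(got, base)
  }
})

test_that("relaxing the significance threshold never removes eligibility", {
  fx <- make_example_fixture()
  strict <- select_instruments(fx$exposure, fx$ld,
                               selection_config(p_threshold = 1e-30))
  loose <- select_instruments(fx$exposure, fx$ld,
                              selection_config(p_threshold = 5e-8))
  # stage-1 survivors under the strict threshold survive the loose one too
  aud_strict <- strict$audit
  expect_true(all(strsplit(aud_strict$removed_ids[1], ";")[[1]] %in%
                    fx$exposure$records$variant_id))
  expect_lte(aud_strict$n_out[1], loose$audit$n_out[1])
})

test_that("variance explained follows beta^2 / (beta^2 + n se^2)", {
  expect_equal(variance_explained(0, 0.1, 1000), 0)
  expect_equal(variance_explained(1, 1, 3), 0.25)
  set.seed(11)
  for (i in 1:100) {
    beta <- rnorm(1); se <- runif(1, 0.01, 1); n <- sample(100:10000, 1)
    t <- beta / se
    expect_equal(variance_explained(beta, se, n), 1 / (1 + n / t^2))
  }
  expect_error(variance_explained(0.1, 0.01, NA), "sample size")
})

test_that("F statistic and the weak-instrument flag follow the formula", {
  expect_equal(f_statistic(0, 1000)$f, 0)
  f <- f_statistic(0.5, 4)
  expect_equal(f$f, 2)
  expect_true(f$weak)
  # a study-scale strength: R2 5.63% at N = 116,863 is far from weak
  f2 <- f_statistic(0.0563, 116863)
  expect_equal(f2$f, 0.0563 * 116861 / (1 - 0.0563), tolerance = 1e-12)
  expect_gt(f2$f, 6900)
  expect_false(f2$weak)
  expect_error(f_statistic(1, 100), "\\[0, 1\\)")
})

test_that("total R2 of identical independent instruments is additive", {
  st <- instrument_strength(
    make_exposure(tibble::tibble(variant_id = sprintf("rs%d", 1:5),
                                 pval = 1e-9)),
    sprintf("rs%d", 1:5), n = 10000)
  expect_equal(st$total_r2, 5 * st$per_snp$r2[1])
  expect_equal(st$per_snp$r2,
               rep(variance_explained(0.1, 0.01, 10000), 5))
})
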