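# minimal datasets for allele-alignment cases
one_variant_ds <- function(ea, oa, beta, eaf = 0.2, id = "rs1",
                           trait = "t", se = 0.01) {
  summary_dataset(tibble::tibble(
    variant_id = id, effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = beta, se = se, pval = 1e-9), trait_name = trait)
}

harmonize1 <- function(exp_ds, out_ds, limit = 0.42) {
  harmonize(exp_ds, out_ds, palindrome_eaf_limit = limit)
}

test_that("matching, swapped and strand-flipped allele codings align", {
  e <- one_variant_ds("A", "G", 0.1)
  cases <- list(
    # ea, oa, expected beta_out, expected flipped, status
    list("A", "G", 0.05, FALSE, "ok"),   # identical coding
    list("G", "A", -0.05, TRUE, "ok"),   # swapped order
    list("T", "C", 0.05, FALSE, "ok"),   # reverse complement
    list("C", "T", -0.05, TRUE, "ok"),   # reverse complement + swap
    list("A", "C", NA, FALSE, "dropped_missing"))  # incompatible pair
  for (cs in cases) {
    o <- one_variant_ds(cs[[1]], cs[[2]], 0.05)
    h <- harmonize1(e, o)
    expect_equal(h$status, cs[[5]], info = paste(cs[[1]], cs[[2]]))
    expect_equal(h$flipped, cs[[4]], info = paste(cs[[1]], cs[[2]]))
    if (cs[[5]] == "ok") {
      expect_equal(h$beta_out, cs[[3]], info = paste(cs[[1]], cs[[2]]))
    } else {
      expect_true(is.na(h$beta_out))
    }
  }
})

test_that("palindromic variants are resolved by EAF or dropped", {
  limit <- 0.42
  grid <- expand.grid(eaf_e = c(0.10, 0.48, 0.90),
                      eaf_o = c(0.12, 0.52, 0.88))
  for (i in seq_len(nrow(grid))) {
    ee <- grid$eaf_e[i]; eo <- grid$eaf_o[i]
    e <- one_variant_ds("A", "T", 0.1, eaf = ee)
    o <- one_variant_ds("A", "T", 0.05, eaf = eo)
    h <- harmonize1(e, o, limit)
    informative <- function(f) f < limit || f > 1 - limit
    if (!informative(ee) || !informative(eo)) {
      expect_equal(h$status, "dropped_palindromic", info = paste(ee, eo))
    } else if ((ee < limit) == (eo < limit)) {
      # same side: labelled alleles agree
      expect_equal(h$status, "ok", info = paste(ee, eo))
      expect_equal(h$beta_out, 0.05)
      expect_false(h$flipped)
    } else {
      # opposite sides: the outcome labelled the complementary allele
      expect_equal(h$status, "ok", info = paste(ee, eo))
      expect_equal(h$beta_out, -0.05)
      expect_true(h$flipped)
      expect_equal(h$eaf_out, 1 - eo)
    }
    expect_true(h$palindromic)
  }
})

test_that("palindromic variant with swapped labels uses the frequency of the
           relabelled allele", {
  e <- one_variant_ds("A", "T", 0.1, eaf = 0.10)
  o <- one_variant_ds("T", "A", 0.05, eaf = 0.88)  # same allele, other label
  h <- harmonize1(e, o)
  expect_equal(h$status, "ok")
  expect_equal(h$beta_out, -0.05)  # negated exactly once by the relabelling
  expect_equal(h$eaf_out, 0.12)
  expect_true(h$flipped)
})

test_that("palindromic variants without outcome EAF are dropped", {
  e <- one_variant_ds("C", "G", 0.1, eaf = 0.10)
  o <- one_variant_ds("C", "G", 0.05, eaf = NA)
  expect_equal(harmonize1(e, o)$status, "dropped_palindromic")
})

test_that("proxy substitution honours the r2 threshold and outcome presence", {
  fx <- make_example_fixture()
  # the two instruments absent from the outcome get their mapped proxies
  subs <- substitute_proxies(c("rs12188917", "rs6419573"), fx$proxies,
                             fx$outcome)
  expect_equal(sum(subs$substituted), 2)
  expect_setequal(subs$proxy, c("rs3091307", "rs1035127"))
  # empty missing list -> empty report
  expect_equal(nrow(substitute_proxies(character(), fx$proxies, fx$outcome)), 0)
  # proxy below the threshold is refused with a recorded reason
  weak <- tibble::tibble(original = "rs12188917", proxy = "rs3091307",
                         r2 = 0.7)
  ref <- substitute_proxies("rs12188917", weak, fx$outcome)
  expect_false(ref$substituted)
  expect_equal(ref$reason, "r2_below_threshold")
})

test_that("harmonizing a dataset against itself is the identity", {
  sim <- simulate_mr_sumstats(synthetic_truth(k = 15, seed = 5,
                                              palindromic_frac = 0.3))
  h <- harmonize(sim$exposure, sim$exposure)
  ok <- h[h$status == "ok", ]
  expect_true(all(!ok$flipped))
  expect_equal(ok$beta_out, ok$beta_exp)
  # palindromic self-pairs in the ambiguous zone may drop; none may flip
  expect_true(all(h$status %in% c("ok", "dropped_palindromic")))
})

test_that("harmonization is idempotent and preserves |beta_out|", {
  fx <- make_example_fixture()
  sel <- select_instruments(fx$exposure, fx$ld,
                            selection_config(exclusion_ids = fx$exclusions$variant_id))
  h1 <- harmonize(fx$exposure, fx$outcome, sel$instrument_ids,
                  proxies = fx$proxies)
  # exactly one negation overall: magnitudes survive
  out_in <- fx$outcome$records
  m <- match(h1$used_id[h1$status %in% c("ok", "proxied")],
             out_in$variant_id)
  expect_equal(abs(h1$beta_out[h1$status %in% c("ok", "proxied")]),
               abs(out_in$beta[m]))
  # rebuild an outcome dataset from the harmonized rows and re-harmonize
  u <- usable_instruments(h1)
  exp_rec <- fx$exposure$records[match(u$variant_id,
                                       fx$exposure$records$variant_id), ]
  out2 <- summary_dataset(tibble::tibble(
    variant_id = u$variant_id,
    effect_allele = exp_rec$effect_allele,
    other_allele = exp_rec$other_allele,
    eaf = u$eaf_out, beta = u$beta_out, se = u$se_out, pval = 0.5),
    trait_name = "rebuilt")
  h2 <- harmonize(fx$exposure, out2, u$variant_id)
  expect_true(all(h2$status == "ok"))
  expect_true(all(!h2$flipped))
  expect_equal(h2$beta_out, u$beta_out)
})
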