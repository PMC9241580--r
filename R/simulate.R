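#' Ground-truth parameters for synthetic two-sample GWAS data
#'
#' Describes the data-generating conditions for [simulate_mr_sumstats()]:
#' a true causal effect, instrument strengths, sample sizes controlling the
#' summary-statistic standard errors, and a horizontal-pleiotropy scenario.
#' Defaults emulate a large binary-trait exposure GWAS (116,863 subjects,
#' 19 instruments) paired with an even larger outcome GWAS (977,323
#' subjects) and a causal log odds ratio of 0.07 per unit exposure
#' liability.
#'
#' @param theta True causal effect, log-odds of outcome per unit exposure.
#' @param k Number of instruments.
#' @param gamma_range True per-allele exposure effects are drawn
#'   log-uniformly over this range (so a single variant can dominate, as one
#'   often does in practice).
#' @param eaf_range Effect-allele frequencies drawn uniformly over this
#'   range.
#' @param n_exp,n_out Exposure/outcome GWAS sample sizes; standard errors
#'   follow `1 / sqrt(2 p (1 - p) N)`, the standardized-trait approximation.
#' @param pleiotropy `"none"`, `"balanced"` (pleiotropic effects centred at
#'   zero) or `"directional"` (centred at `pl_mean`).
#' @param pl_mean Mean pleiotropic outcome effect under the directional
#'   scenario (log-odds).
#' @param pl_sd SD of pleiotropic effects (balanced and directional).
#' @param pl_frac Fraction of instruments that are pleiotropic
#'   (directional scenario; balanced applies to all).
#' @param palindromic_frac Fraction of variants assigned an A/T or C/G
#'   allele pair.
#' @param seed Integer seed; mandatory — all draws come from one stream and
#'   global RNG state is never touched.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(theta = 0.07, k = 19,
                            gamma_range = c(0.04, 0.35),
                            eaf_range = c(0.05, 0.95),
                            n_exp = 116863, n_out = 977323,
                            pleiotropy = c("none", "balanced", "directional"),
                            pl_mean = 0.02, pl_sd = 0.01, pl_frac = 1,
                            palindromic_frac = 0, seed) {
  if (missing(seed)) rlang::abort("synthetic_truth requires a `seed`")
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(k >= 1, pl_frac >= 0, pl_frac <= 1,
            palindromic_frac >= 0, palindromic_frac <= 1,
            n_exp > 2, n_out > 2,
            length(gamma_range) == 2, all(gamma_range > 0),
            length(eaf_range) == 2, all(eaf_range > 0), all(eaf_range < 1))
  structure(list(theta = theta, k = as.integer(k),
                 gamma_range = gamma_range, eaf_range = eaf_range,
                 n_exp = n_exp, n_out = n_out, pleiotropy = pleiotropy,
                 pl_mean = pl_mean, pl_sd = pl_sd, pl_frac = pl_frac,
                 palindromic_frac = palindromic_frac,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

NON_PALINDROMIC_PAIRS <- rbind(
  c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
  c("T", "G"), c("G", "T"), c("T", "C"), c("C", "T"))
PALINDROMIC_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Generates matched exposure and outcome summary datasets under the
#' standard instrumental-variable model: true exposure effects `gamma_j`
#' and frequencies are drawn, per-study standard errors follow
#' `1/sqrt(2 p (1-p) N)`, observed betas are normal around the truth, and
#' true outcome effects are `theta * gamma_j + alpha_j` with `alpha_j` the
#' pleiotropic contribution of the chosen scenario. Variants are placed far
#' apart on alternating chromosomes so they are exchangeable and
#' LD-independent by construction.
#'
#' @param truth A [synthetic_truth()].
#' @return List: `exposure` and `outcome` (`summary_dataset`s), and `truth`
#'   (tibble of per-variant `gamma`, `alpha`, plus the scalar parameters).
#' @export
simulate_mr_sumstats <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  k <- truth$k
  local_rng(truth$seed, {
    gamma <- exp(stats::runif(k, log(truth$gamma_range[1]),
                              log(truth$gamma_range[2])))
    eaf <- stats::runif(k, truth$eaf_range[1], truth$eaf_range[2])
    alpha <- switch(truth$pleiotropy,
      none = rep(0, k),
      balanced = stats::rnorm(k, 0, truth$pl_sd),
      directional = {
        a <- rep(0, k)
        n_pl <- round(truth$pl_frac * k)
        if (n_pl > 0) {
          idx <- sample.int(k, n_pl)
          a[idx] <- stats::rnorm(n_pl, truth$pl_mean, truth$pl_sd)
        }
        a
      })
    se_x <- 1 / sqrt(2 * eaf * (1 - eaf) * truth$n_exp)
    se_y <- 1 / sqrt(2 * eaf * (1 - eaf) * truth$n_out)
    beta_x <- stats::rnorm(k, gamma, se_x)
    gamma_out <- truth$theta * gamma + alpha
    beta_y <- stats::rnorm(k, gamma_out, se_y)

    n_pal <- round(truth$palindromic_frac * k)
    pal <- c(rep(TRUE, n_pal), rep(FALSE, k - n_pal))[sample.int(k)]
    pick_pair <- function(is_pal) {
      pool <- if (is_pal) PALINDROMIC_PAIRS else NON_PALINDROMIC_PAIRS
      pool[sample.int(nrow(pool), 1), ]
    }
    alleles <- t(vapply(pal, pick_pair, character(2)))

    ids <- sprintf("rs%07d", sample.int(9999999, k))
    chrom <- as.character(rep_len(1:22, k))
    pos <- 1e6L + 20000000L * (seq_len(k) %/% 22L) + seq_len(k)

    rec <- function(beta, se, n) tibble::tibble(
      variant_id = ids, chrom = chrom, pos = pos,
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = eaf, beta = beta, se = se,
      # strong associations underflow pnorm; floor at the smallest normal
      pval = pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin),
      n = as.integer(n))
    exposure <- summary_dataset(rec(beta_x, se_x, truth$n_exp),
                                trait_name = "synthetic_exposure",
                                validate = FALSE)
    outcome <- summary_dataset(rec(beta_y, se_y, truth$n_out),
                               trait_name = "synthetic_outcome",
                               validate = FALSE)
    list(exposure = exposure, outcome = outcome,
         truth = tibble::tibble(
           variant_id = ids, gamma = gamma, alpha = alpha,
           theta = truth$theta, pleiotropy = truth$pleiotropy,
           seed = truth$seed))
  })
}

#' Deterministic worked-example fixture
#'
#' A reproducible miniature of a complete two-sample MR input bundle, shaped
#' like a published atopic-dermatitis-on-heart-failure analysis: 21
#' genome-wide-significant exposure candidates of which one member of the
#' single LD-correlated pair (r-squared 0.5) is pruned and one
#' confounder-associated variant (rs4713555) is excluded — leaving 19
#' instruments — and an outcome dataset missing two of them (rs12188917,
#' rs6419573) but carrying valid high-LD proxies (rs3091307, rs1035127;
#' r-squared above 0.8). All values are synthetic; only the variant
#' identifiers follow their real-world counterparts.
#'
#' @param dir If given, the fixture is also written there as the TSV
#'   dialects the readers accept (`exposure.tsv`, `outcome.tsv`, `ld.tsv`,
#'   `exclusions.tsv`, `proxies.tsv`).
#' @return List: `exposure`, `outcome` (`summary_dataset`s), `ld`
#'   (`ld_table`), `exclusions`, `proxies` (tibbles), and `paths` when `dir`
#'   was given.
#' @export
make_example_fixture <- function(dir = NULL) {
  n_exp_cases <- 21399L; n_exp_controls <- 95464L
  n_out_cases <- 47309L; n_out_controls <- 930014L
  n_exp <- n_exp_cases + n_exp_controls
  n_out <- n_out_cases + n_out_controls
  theta <- log(1.07)

  ids <- c("rs61813875", "rs12730935", "rs4713555", "rs12188917",
           "rs6419573", sprintf("rs%d", 9000001:9000016))
  k <- length(ids)
  fix <- local_rng(73L, {
    gamma <- stats::runif(k, 0.05, 0.22)
    gamma[ids == "rs61813875"] <- 0.35          # dominant instrument
    gamma[ids == "rs12730935"] <- 0.08
    gamma[ids == "rs9000001"] <- 0.12           # its LD partner, smaller p
    eaf <- round(stats::runif(k, 0.08, 0.45), 3)
    # fix the LD pair's frequencies so the partner with the larger effect
    # (rs9000001) always carries the smaller p-value and survives pruning
    eaf[ids == "rs9000001"] <- 0.30
    eaf[ids == "rs12730935"] <- 0.25
    se_x <- round(1 / sqrt(2 * eaf * (1 - eaf) * n_exp), 5)
    # place the observed exposure betas at their true values (fixture is a
    # worked example, not a stochastic draw) so p-values are stable
    beta_x <- round(gamma, 4)
    alleles <- NON_PALINDROMIC_PAIRS[rep_len(seq_len(8), k), , drop = FALSE]
    chrom <- as.character(rep_len(1:21, k))
    pos <- 1000000L + 5000000L * seq_len(k)
    # rs12730935 sits 50 kb from rs9000001 on the same chromosome
    chrom[ids == "rs12730935"] <- chrom[ids == "rs9000001"]
    pos[ids == "rs12730935"] <- pos[ids == "rs9000001"] + 50000L
    noise <- stats::rnorm(k, 0, 0.3)
    list(gamma = gamma, eaf = eaf, se_x = se_x, beta_x = beta_x,
         alleles = alleles, chrom = chrom, pos = pos, noise = noise)
  })

  # with these effect sizes and frequencies every candidate clears 5e-8;
  # the strongest associations underflow, so floor at the smallest normal
  pval_x <- signif(pmax(2 * stats::pnorm(-abs(fix$beta_x / fix$se_x)),
                        .Machine$double.xmin), 3)
  exposure <- summary_dataset(
    tibble::tibble(variant_id = ids, chrom = fix$chrom, pos = fix$pos,
                   effect_allele = fix$alleles[, 1],
                   other_allele = fix$alleles[, 2],
                   eaf = fix$eaf, beta = fix$beta_x, se = fix$se_x,
                   pval = pval_x, n = n_exp),
    trait_name = "atopic_dermatitis", n_cases = n_exp_cases,
    n_controls = n_exp_controls)

  # outcome: direct associations for all but the two missing instruments,
  # plus the two proxies
  miss <- c("rs12188917", "rs6419573")
  proxies <- tibble::tibble(original = miss,
                            proxy = c("rs3091307", "rs1035127"),
                            r2 = c(0.9, 0.85))
  out_ids <- c(setdiff(ids, miss), proxies$proxy)
  m <- match(out_ids, ids)  # NA for the proxy rows
  src <- ifelse(is.na(m), match(proxies$original, ids)[match(out_ids, proxies$proxy)], m)
  eaf_o <- fix$eaf[src]
  se_y <- round(1 / sqrt(2 * eaf_o * (1 - eaf_o) * n_out), 5)
  beta_y <- round(theta * fix$gamma[src] + fix$noise[src] * se_y, 5)
  al_o <- fix$alleles[src, , drop = FALSE]
  # two direct variants are listed with swapped alleles to exercise flipping
  swap <- out_ids %in% c("rs9000003", "rs9000007")
  tmp <- al_o[swap, 1]; al_o[swap, 1] <- al_o[swap, 2]; al_o[swap, 2] <- tmp
  beta_y[swap] <- -beta_y[swap]
  eaf_o[swap] <- 1 - eaf_o[swap]
  outcome <- summary_dataset(
    tibble::tibble(variant_id = out_ids, chrom = fix$chrom[src],
                   pos = ifelse(is.na(m), fix$pos[src] + 30000L, fix$pos[src]),
                   effect_allele = al_o[, 1], other_allele = al_o[, 2],
                   eaf = eaf_o, beta = beta_y, se = se_y,
                   pval = signif(2 * stats::pnorm(-abs(beta_y / se_y)), 3),
                   n = n_out),
    trait_name = "heart_failure", n_cases = n_out_cases,
    n_controls = n_out_controls)

  ld <- ld_table(tibble::tibble(id_a = "rs9000001", id_b = "rs12730935",
                                r2 = 0.5))
  exclusions <- tibble::tibble(
    variant_id = "rs4713555",
    reason = "associated with confounders (thyroid disease, type 1 diabetes)")

  out <- list(exposure = exposure, outcome = outcome, ld = ld,
              exclusions = exclusions, proxies = proxies)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      exposure = file.path(dir, "exposure.tsv"),
      outcome = file.path(dir, "outcome.tsv"),
      ld = file.path(dir, "ld.tsv"),
      exclusions = file.path(dir, "exclusions.tsv"),
      proxies = file.path(dir, "proxies.tsv"))
    write_sumstats(exposure, paths$exposure)
    write_sumstats(outcome, paths$outcome)
    readr::write_tsv(ld$pairs, paths$ld, progress = FALSE)
    readr::write_tsv(exclusions, paths$exclusions, progress = FALSE)
    readr::write_tsv(proxies, paths$proxies, progress = FALSE)
    out$paths <- paths
  }
  out
}
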