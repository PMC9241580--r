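#' Instrument-selection configuration
#'
#' Thresholds for the four-stage instrument selection pipeline:
#' genome-wide significance, LD pruning, minor-allele-frequency filtering,
#' and confounder-association exclusion.
#'
#' @param p_threshold Significance cutoff for the SNP-exposure association
#'   (default `5e-8`, genome-wide significance).
#' @param ld_r2_max Maximum pairwise r-squared tolerated between kept
#'   instruments (default 0.001).
#' @param ld_window_kb Window, in kb, within which LD is enforced
#'   (default 10000).
#' @param maf_min Minimum minor allele frequency (default 0.01); variants
#'   with MAF at or below it are removed.
#' @param exclusion_ids Character vector of variant ids to remove at the
#'   final stage (e.g. confounder-associated instruments).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(p_threshold = 5e-8, ld_r2_max = 0.001,
                             ld_window_kb = 10000, maf_min = 0.01,
                             exclusion_ids = character()) {
  assert_scalar_prob(p_threshold, "p_threshold")
  if (!is_scalar_number(ld_r2_max) || ld_r2_max < 0 || ld_r2_max > 1) {
    rlang::abort("`ld_r2_max` must be a single number in [0, 1]")
  }
  if (!is_scalar_number(maf_min) || maf_min <= 0 || maf_min >= 0.5) {
    rlang::abort("`maf_min` must be a single number in (0, 0.5)")
  }
  structure(list(p_threshold = p_threshold, ld_r2_max = ld_r2_max,
                 ld_window_kb = ld_window_kb, maf_min = maf_min,
                 exclusion_ids = as.character(exclusion_ids)),
            class = "selection_config")
}

#' Select instruments from an exposure GWAS
#'
#' Deterministic four-stage pipeline:
#' 1. keep variants with `pval < p_threshold`;
#' 2. LD-prune greedily by ascending p-value (ties broken by variant id):
#'    a candidate is kept only if its r-squared with every already-kept
#'    variant within `ld_window_kb` (same chromosome) is below `ld_r2_max`.
#'    An unknown r-squared between co-located variants counts as failing
#'    (the later candidate is pruned — conservative); between variants on
#'    different chromosomes or farther apart than the window it counts as
#'    independent. When positions are unavailable the pair's co-location is
#'    unknowable and only LD-table entries can prune (a warning is issued);
#' 3. remove variants whose EAF-derived MAF is at or below `maf_min`
#'    (variants with missing EAF pass, with a warning);
#' 4. remove `exclusion_ids`.
#'
#' @param exposure A `summary_dataset`.
#' @param ld An [ld_table()] (may be empty).
#' @param config A [selection_config()].
#' @return List with `instrument_ids` (character, in input order) and
#'   `audit` (tibble: `stage`, `n_in`, `n_out`, `removed_ids`).
#' @export
select_instruments <- function(exposure, ld = ld_table(),
                               config = selection_config()) {
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(config, "selection_config"))
  rec <- exposure$records
  if (nrow(rec) == 0) rlang::abort("exposure dataset is empty")

  audit <- list()
  note <- function(stage, ids_in, ids_out) {
    audit[[length(audit) + 1]] <<- tibble::tibble(
      stage = stage, n_in = length(ids_in), n_out = length(ids_out),
      removed_ids = paste(sort(setdiff(ids_in, ids_out)), collapse = ";"))
  }

  all_ids <- rec$variant_id
  sig <- rec[rec$pval < config$p_threshold, ]
  note("significance", all_ids, sig$variant_id)

  kept <- ld_prune(sig, ld, config$ld_r2_max, config$ld_window_kb)
  note("ld_prune", sig$variant_id, kept)
  sig <- sig[sig$variant_id %in% kept, ]

  maf <- pmin(sig$eaf, 1 - sig$eaf)
  if (any(is.na(maf))) {
    rlang::warn(sprintf(
      "%d variant(s) have no EAF; they pass the MAF filter unchecked",
      sum(is.na(maf))))
  }
  pass_maf <- is.na(maf) | maf > config$maf_min
  note("maf", sig$variant_id, sig$variant_id[pass_maf])
  sig <- sig[pass_maf, ]

  final <- sig$variant_id[!sig$variant_id %in% config$exclusion_ids]
  note("exclusion", sig$variant_id, final)

  if (length(final) == 0) {
    aud <- dplyr::bind_rows(audit)
    rlang::abort(paste0(
      "no instruments survive selection; stage counts: ",
      paste(sprintf("%s %d->%d", aud$stage, aud$n_in, aud$n_out),
            collapse = ", ")))
  }
  list(instrument_ids = final, audit = dplyr::bind_rows(audit))
}

# Greedy LD pruning on a set of significant variants. Returns kept ids.
ld_prune <- function(records, ld, r2_max, window_kb) {
  if (nrow(records) == 0) return(character())
  ord <- order(records$pval, records$variant_id)
  rec <- records[ord, ]
  no_pos <- is.na(rec$pos) | is.na(rec$chrom)
  if (any(no_pos) && nrow(rec) > 1) {
    rlang::warn(paste("some variants lack chrom/pos; pairs without an LD-table",
                      "entry are assumed independent for them"))
  }
  kept <- integer()
  for (i in seq_len(nrow(rec))) {
    ok <- TRUE
    for (j in kept) {
      r2 <- ld_r2(ld, rec$variant_id[i], rec$variant_id[j])
      pos_known <- !is.na(rec$chrom[i]) && !is.na(rec$chrom[j]) &&
        !is.na(rec$pos[i]) && !is.na(rec$pos[j])
      colocated <- pos_known && rec$chrom[i] == rec$chrom[j] &&
        abs(rec$pos[i] - rec$pos[j]) <= window_kb * 1000
      if (is.na(r2)) {
        # unknown LD: conservative within the window, independent beyond it
        # (and independent when co-location cannot be established)
        if (colocated) { ok <- FALSE; break }
      } else if (r2 >= r2_max && (colocated || !pos_known)) {
        # a measured high r2 prunes inside the window, and also whenever
        # positions are missing so the window cannot exonerate the pair
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  ids <- rec$variant_id[kept]
  records$variant_id[records$variant_id %in% ids]
}

#' Per-variant variance explained
#'
#' Proportion of exposure variance explained by one variant, from summary
#' statistics: `R2 = beta^2 / (beta^2 + n * se^2)`, equivalently
#' `t^2 / (t^2 + n)` with `t = beta/se`.
#'
#' @param beta,se Per-allele effect and its standard error.
#' @param n Exposure GWAS sample size.
#' @return R-squared in `[0, 1)`.
#' @export
variance_explained <- function(beta, se, n) {
  if (any(is.na(n))) {
    rlang::abort("sample size `n` is required to compute variance explained")
  }
  stopifnot(all(se > 0), all(n > 0))
  beta^2 / (beta^2 + n * se^2)
}

#' Instrument-strength F-statistic
#'
#' `F = R2 * (N - 2) / (1 - R2)`. Values below 10 conventionally flag
#' weak-instrument bias.
#'
#' @param r2 Variance explained, in `[0, 1)`.
#' @param n Exposure sample size (> 2).
#' @return Named list `f` and `weak` (logical, `f < 10`).
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 < 0) || any(r2 >= 1)) {
    rlang::abort("`r2` must lie in [0, 1)")
  }
  stopifnot(all(n > 2))
  f <- r2 * (n - 2) / (1 - r2)
  list(f = f, weak = f < 10)
}

#' Instrument-strength report for a set of instruments
#'
#' Per-variant and total variance explained plus F-statistics. The total
#' assumes independent instruments (sum of per-variant R-squared).
#'
#' @param exposure A `summary_dataset`.
#' @param instrument_ids Instrument ids (subset of the exposure's variants).
#' @param n Exposure sample size; defaults to [dataset_n()].
#' @return List: `per_snp` (tibble `variant_id`, `r2`, `f`, `weak`),
#'   `total_r2`, `f_overall`, `n`.
#' @export
instrument_strength <- function(exposure, instrument_ids, n = NULL) {
  n <- n %||% dataset_n(exposure)
  if (is.na(n)) {
    rlang::abort("supply `n` (or case/control counts) to compute strength")
  }
  rec <- exposure$records
  rec <- rec[match(instrument_ids, rec$variant_id), ]
  if (any(is.na(rec$variant_id))) {
    rlang::abort("some instrument ids are not in the exposure dataset")
  }
  r2 <- variance_explained(rec$beta, rec$se, n)
  fs <- f_statistic(r2, n)
  total <- sum(r2)
  f_all <- f_statistic(total, n)
  list(per_snp = tibble::tibble(variant_id = rec$variant_id, r2 = r2,
                                f = fs$f, weak = fs$weak),
       total_r2 = total, f_overall = f_all$f, n = n)
}
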