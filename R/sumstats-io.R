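#' Canonical summary-statistics column names
#'
#' Column-name driven parsing: consortium files use arbitrary headers, so
#' [read_sumstats()] accepts a `column_map` from these canonical names to the
#' names actually present in the file.
#'
#' @format A character vector of the canonical column names.
#' @export
SUMSTATS_COLUMNS <- c("variant_id", "chrom", "pos", "effect_allele",
                      "other_allele", "eaf", "beta", "se", "pval", "n")

MANDATORY_COLUMNS <- c("variant_id", "effect_allele", "other_allele",
                       "beta", "se", "pval")

#' Construct a GWAS summary dataset
#'
#' A `summary_dataset` bundles one trait's per-variant association records
#' (a tibble with the canonical columns) with trait metadata. For binary
#' traits, `beta` is on the log-odds scale.
#'
#' @param records Tibble/data.frame with at least the mandatory canonical
#'   columns (`variant_id`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `pval`); optional `chrom`, `pos`, `eaf`, `n`.
#' @param trait_name Trait label.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param n_cases,n_controls Optional case/control counts (binary traits).
#' @param validate Drop rows violating record invariants (with a warning)?
#' @return An object of class `summary_dataset`.
#' @export
summary_dataset <- function(records, trait_name = "trait",
                            trait_type = c("binary", "quantitative"),
                            n_cases = NULL, n_controls = NULL,
                            validate = TRUE) {
  trait_type <- match.arg(trait_type)
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("summary dataset is missing mandatory column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  for (opt in setdiff(SUMSTATS_COLUMNS, names(records))) {
    records[[opt]] <- if (opt %in% c("pos", "n")) NA_integer_ else
      if (opt == "chrom") NA_character_ else NA_real_
  }
  records <- records[, SUMSTATS_COLUMNS]
  records$variant_id <- as.character(records$variant_id)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))

  if (validate) {
    records <- drop_invalid_records(records)
  }
  if (nrow(records) == 0) {
    rlang::abort("summary dataset has zero valid variant records")
  }
  if (anyDuplicated(records$variant_id)) {
    dup <- unique(records$variant_id[duplicated(records$variant_id)])
    rlang::abort(sprintf("duplicate variant_id in dataset: %s",
                         paste(utils::head(dup, 5), collapse = ", ")))
  }
  structure(
    list(trait_name = trait_name, trait_type = trait_type,
         n_cases = n_cases, n_controls = n_controls, records = records),
    class = "summary_dataset"
  )
}

# Per-record invariants: alleles single-base and distinct, se > 0,
# pval in (0, 1], eaf (if present) strictly inside (0, 1).
drop_invalid_records <- function(records) {
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  valid <- ok_allele(records$effect_allele) &
    ok_allele(records$other_allele) &
    records$effect_allele != records$other_allele &
    !is.na(records$beta) & is.finite(records$beta) &
    !is.na(records$se) & records$se > 0 &
    !is.na(records$pval) & records$pval > 0 & records$pval <= 1 &
    (is.na(records$eaf) | (records$eaf > 0 & records$eaf < 1))
  n_bad <- sum(!valid)
  if (n_bad > 0) {
    rlang::warn(sprintf(
      "dropped %d row(s) violating record invariants (ids: %s)", n_bad,
      paste(utils::head(records$variant_id[!valid], 5), collapse = ", ")))
  }
  records[valid, , drop = FALSE]
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s), %d variants\n",
              x$trait_name, x$trait_type, nrow(x$records)))
  if (!is.null(x$n_cases)) {
    cat(sprintf("  cases: %s  controls: %s\n",
                format(x$n_cases, big.mark = ","),
                format(x$n_controls, big.mark = ",")))
  }
  print(utils::head(x$records, 5))
  invisible(x)
}

#' Total sample size of a summary dataset
#'
#' Cases + controls when both are recorded, else the maximum per-variant `n`.
#'
#' @param dataset A `summary_dataset`.
#' @return Integer sample size, or `NA` if none is recorded.
#' @export
dataset_n <- function(dataset) {
  if (!is.null(dataset$n_cases) && !is.null(dataset$n_controls)) {
    return(dataset$n_cases + dataset$n_controls)
  }
  if (all(is.na(dataset$records$n))) return(NA_integer_)
  max(dataset$records$n, na.rm = TRUE)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a TSV (optionally gzip-compressed, by extension) with a header row
#' into a validated [summary_dataset()]. Parsing is column-name driven:
#' `column_map` maps canonical names (see [SUMSTATS_COLUMNS]) to the file's
#' header names, so column order never matters. Rows violating record
#' invariants (non-ACGT or identical alleles, `se <= 0`, `pval` outside
#' (0,1], `eaf` outside (0,1)) are dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @param column_map Named character vector `c(canonical = "file_name", ...)`.
#'   Canonical names already present in the header need not be mapped.
#' @inheritParams summary_dataset
#' @return A `summary_dataset`.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_name = NULL,
                          trait_type = c("binary", "quantitative"),
                          n_cases = NULL, n_controls = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) {
    rlang::abort(sprintf("summary-statistics file not found: %s", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  for (canon in names(column_map)) {
    src <- column_map[[canon]]
    if (!src %in% names(raw)) {
      rlang::abort(sprintf(
        "column_map points '%s' at '%s', which is not in the header of %s",
        canon, src, path))
    }
    names(raw)[names(raw) == src] <- canon
  }
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("%s is missing mandatory column(s): %s",
                         path, paste(missing_cols, collapse = ", ")))
  }
  records <- tibble::tibble(
    variant_id = raw$variant_id,
    chrom = if ("chrom" %in% names(raw)) raw$chrom else NA_character_,
    pos = if ("pos" %in% names(raw)) as.integer(raw$pos) else NA_integer_,
    effect_allele = raw$effect_allele,
    other_allele = raw$other_allele,
    eaf = if ("eaf" %in% names(raw)) as.numeric(raw$eaf) else NA_real_,
    beta = as.numeric(raw$beta),
    se = as.numeric(raw$se),
    pval = as.numeric(raw$pval),
    n = if ("n" %in% names(raw)) as.integer(round(as.numeric(raw$n)))
        else NA_integer_
  )
  summary_dataset(records, trait_name = trait_name %||% basename(path),
                  trait_type = trait_type,
                  n_cases = n_cases, n_controls = n_controls)
}

#' Write a summary dataset as TSV
#'
#' Writes the canonical columns with enough float precision (15 significant
#' digits) that a write/read round trip reproduces every value.
#'
#' @param dataset A `summary_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(dataset, path) {
  rec <- dataset$records
  for (col in c("eaf", "beta", "se", "pval")) {
    rec[[col]] <- formatC(rec[[col]], digits = 15, format = "g")
    rec[[col]][rec[[col]] %in% c("NA", " NA")] <- NA
  }
  readr::write_tsv(rec, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a pairwise LD table
#'
#' Three-column TSV `(id_a, id_b, r2)` with `r2` in `[0, 1]`. The returned
#' object is a symmetric lookup: query an absent pair and you get `NA`
#' ("unknown"), never an assumed 0 — downstream selection decides how to
#' treat unknowns.
#'
#' @param path Path to the LD TSV.
#' @return An object of class `ld_table`.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("LD table not found: %s", path))
  tab <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  names(tab) <- c("id_a", "id_b", "r2")
  ld_table(tab)
}

#' Construct an LD lookup from a data frame
#'
#' @param pairs Data frame with columns `id_a`, `id_b`, `r2`.
#' @return An object of class `ld_table`.
#' @export
ld_table <- function(pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- tibble::tibble(id_a = character(), id_b = character(),
                            r2 = numeric())
  }
  pairs <- tibble::as_tibble(pairs)
  if (any(is.na(pairs$r2)) || any(pairs$r2 < 0) || any(pairs$r2 > 1)) {
    rlang::abort("LD r2 values must lie in [0, 1]")
  }
  env <- new.env(parent = emptyenv())
  if (nrow(pairs) > 0) {
    keys <- pair_key(pairs$id_a, pairs$id_b)
    for (i in seq_along(keys)) assign(keys[i], pairs$r2[i], envir = env)
  }
  structure(list(pairs = pairs, index = env), class = "ld_table")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Query pairwise LD
#'
#' @param ld An `ld_table`.
#' @param id_a,id_b Variant identifiers (vectorised, recycled).
#' @return Numeric vector of r-squared values; `1` for a self pair, `NA` for
#'   an unknown pair.
#' @export
ld_r2 <- function(ld, id_a, id_b) {
  stopifnot(inherits(ld, "ld_table"))
  n <- max(length(id_a), length(id_b))
  id_a <- rep_len(id_a, n)
  id_b <- rep_len(id_b, n)
  out <- numeric(n)
  keys <- pair_key(id_a, id_b)
  for (i in seq_len(n)) {
    if (id_a[i] == id_b[i]) {
      out[i] <- 1
    } else {
      out[i] <- mget(keys[i], envir = ld$index,
                     ifnotfound = NA_real_)[[1]]
    }
  }
  out
}

#' @export
print.ld_table <- function(x, ...) {
  cat(sprintf("<ld_table> %d pair(s)\n", nrow(x$pairs)))
  invisible(x)
}

#' Read a variant exclusion list
#'
#' One- or two-column TSV (`variant_id[, reason]`), typically the output of a
#' confounder-association search (e.g. a PhenoScanner export): instruments
#' associated with potential confounders at genome-wide significance are
#' listed here and removed during selection.
#'
#' @param path Path to the exclusion TSV.
#' @return Tibble with columns `variant_id`, `reason`.
#' @export
read_exclusion_list <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("exclusion list not found: %s", path))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  out <- tibble::tibble(
    variant_id = as.character(tab[[1]]),
    reason = if (ncol(tab) >= 2) as.character(tab[[2]]) else NA_character_
  )
  out
}

#' Read a proxy-variant map
#'
#' Three-column TSV `(original, proxy, r2)` giving, for instruments absent
#' from an outcome dataset, a high-LD substitute and the pairwise r-squared.
#'
#' @param path Path to the proxy TSV.
#' @return Tibble with columns `original`, `proxy`, `r2`.
#' @export
read_proxy_map <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("proxy map not found: %s", path))
  }
  tab <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  names(tab) <- c("original", "proxy", "r2")
  if (any(tab$r2 <= 0 | tab$r2 > 1)) {
    rlang::abort("proxy r2 values must lie in (0, 1]")
  }
  tab
}

#' Write MR estimates as a results table
#'
#' Odds-ratio view of a set of MR estimates (the tabular twin of a forest
#' plot): one row per method/outcome with `or = exp(beta)` and its 95% CI.
#'
#' @param estimates Tibble of MR estimates (columns `method`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `k`, optionally `outcome`).
#' @param path Output path.
#' @param digits Decimal places for the OR and CI columns.
#' @return The written tibble, invisibly.
#' @export
write_results_table <- function(estimates, path, digits = 2) {
  estimates <- tibble::as_tibble(estimates)
  out <- tibble::tibble(
    method = if (nrow(estimates)) estimates$method else character(),
    outcome = if ("outcome" %in% names(estimates)) estimates$outcome
              else rep(NA_character_, nrow(estimates)),
    n_snps = if (nrow(estimates)) as.integer(estimates$k) else integer(),
    or = round(exp(estimates$beta), digits),
    ci_low = round(exp(estimates$ci_low), digits),
    ci_high = round(exp(estimates$ci_high), digits),
    pval = if (nrow(estimates)) signif(estimates$pval, 3) else numeric()
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}
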