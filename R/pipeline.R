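#' Read a pipeline run configuration
#'
#' YAML configuration describing one exposure, one or more outcomes, the
#' selection thresholds, auxiliary input paths, meta-analysis groups and
#' simulation parameters. Scalars omitted from the file take the package
#' defaults. See [run_mr_pipeline()] for the recognised keys.
#'
#' @param path Path to a YAML file.
#' @return The configuration as a named list (class `mr_run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  cfg$config_dir <- dirname(normalizePath(path))
  structure(cfg, class = "mr_run_config")
}

config_defaults <- function() {
  list(palindrome_eaf_limit = 0.42, proxy_r2_min = 0.8,
       n_boot = 1000, n_sim = 1000, seed = 1L,
       alpha = 0.05, n_tests = NULL, out_dir = "mr_results")
}

resolve_path <- function(p, cfg) {
  if (is.null(p)) return(NULL)
  if (file.exists(p) || is.null(cfg$config_dir)) return(p)
  file.path(cfg$config_dir, p)
}

#' Validate a pipeline configuration
#'
#' Checks, without side effects, that the configuration names existing
#' files, that outcome names are unique, that meta-analysis groups refer to
#' declared outcomes, and that numeric scalars respect their invariants.
#'
#' @param config A config list or the path to a YAML file.
#' @return Tibble of issues (`field`, `problem`); zero rows means valid.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  issues <- list()
  add <- function(field, problem) {
    issues[[length(issues) + 1]] <<- tibble::tibble(field = field,
                                                    problem = problem)
  }
  if (is.null(config$exposure$path)) {
    add("exposure.path", "missing")
  } else if (!file.exists(resolve_path(config$exposure$path, config))) {
    add("exposure.path", sprintf("file not found: %s", config$exposure$path))
  }
  if (length(config$outcomes) == 0) add("outcomes", "no outcomes declared")
  nm <- vapply(config$outcomes, function(o) o$name %||% NA_character_,
               character(1))
  if (anyNA(nm)) add("outcomes", "every outcome needs a name")
  if (anyDuplicated(nm)) {
    add("outcomes", sprintf("duplicate outcome name(s): %s",
                            paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  for (o in config$outcomes) {
    if (is.null(o$path)) {
      add(sprintf("outcomes.%s.path", o$name %||% "?"), "missing")
    } else if (!file.exists(resolve_path(o$path, config))) {
      add(sprintf("outcomes.%s.path", o$name %||% "?"),
          sprintf("file not found: %s", o$path))
    }
  }
  for (key in c("ld_path", "exclusion_path", "proxy_path")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(resolve_path(p, config))) {
      add(key, sprintf("file not found: %s", p))
    }
  }
  for (grp in names(config$meta_groups)) {
    unknown <- setdiff(unlist(config$meta_groups[[grp]]), nm)
    if (length(unknown) > 0) {
      add(sprintf("meta_groups.%s", grp),
          sprintf("unknown outcome(s): %s", paste(unknown, collapse = ", ")))
    }
  }
  sel <- config$selection
  if (!is.null(sel$p_threshold) &&
      (sel$p_threshold <= 0 || sel$p_threshold >= 1)) {
    add("selection.p_threshold", "must be in (0, 1)")
  }
  known <- c("exposure", "outcomes", "selection", "ld_path", "exclusion_path",
             "proxy_path", "meta_groups", "palindrome_eaf_limit",
             "proxy_r2_min", "n_boot", "n_sim", "seed", "alpha", "n_tests",
             "out_dir", "config_dir")
  unused <- setdiff(names(config), known)
  if (length(unused) > 0) {
    add(paste(unused, collapse = ", "), "unused key(s)")
  }
  if (length(issues) == 0) {
    return(tibble::tibble(field = character(), problem = character()))
  }
  dplyr::bind_rows(issues)
}

load_dataset_entry <- function(entry, config, default_type = "binary") {
  read_sumstats(resolve_path(entry$path, config),
                column_map = unlist(entry$column_map),
                trait_name = entry$name %||% entry$trait_name,
                trait_type = entry$trait_type %||% default_type,
                n_cases = entry$n_cases, n_controls = entry$n_controls)
}

#' Run the full two-sample MR pipeline
#'
#' Orchestrates, for each configured outcome: instrument selection from the
#' exposure GWAS, harmonization (with proxy substitution), the estimator
#' battery (multiplicative random-effects IVW as the primary estimate,
#' weighted median and MR-Egger as complements), and the diagnostics suite
#' (Cochran's Q, Egger intercept, MR-PRESSO when at least four instruments
#' remain, leave-one-out). Designated outcome groups are then pooled by
#' fixed-effect meta-analysis and every primary p-value is classified
#' against the Bonferroni threshold `alpha / n_tests`.
#'
#' Configuration keys: `exposure` (`path`, optional `column_map`,
#' `n_cases`, `n_controls`), `outcomes` (list of the same plus `name`),
#' `selection` (`p_threshold`, `ld_r2_max`, `ld_window_kb`, `maf_min`),
#' `ld_path`, `exclusion_path`, `proxy_path`, `meta_groups` (named lists of
#' outcome names), `palindrome_eaf_limit`, `proxy_r2_min`, `n_boot`,
#' `n_sim`, `seed`, `alpha`, `n_tests` (defaults to the number of
#' outcomes), `out_dir`.
#'
#' @param config A config list or the path to a YAML file.
#' @param out_dir Overrides the configured output directory.
#' @return Invisibly, the results bundle: `estimates`, `diagnostics`,
#'   `harmonization`, `audit`, `loo`, `scatter`, `meta`, `classification`,
#'   `strength`, `manifest`. All tables are also written as TSV under
#'   `out_dir`, plus `manifest.json`.
#' @export
run_mr_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  issues <- validate_run_config(config)
  issues <- issues[issues$problem != "unused key(s)", ]
  if (nrow(issues) > 0) {
    rlang::abort(paste0("invalid configuration:\n", paste(
      sprintf("- %s: %s", issues$field, issues$problem), collapse = "\n")))
  }
  defaults <- config_defaults()
  for (key in names(defaults)) {
    config[[key]] <- config[[key]] %||% defaults[[key]]
  }
  out_dir <- out_dir %||% config$out_dir
  seed <- as.integer(config$seed)

  exposure <- load_dataset_entry(config$exposure, config)
  ld <- if (!is.null(config$ld_path)) {
    read_ld_table(resolve_path(config$ld_path, config))
  } else ld_table()
  exclusions <- if (!is.null(config$exclusion_path)) {
    read_exclusion_list(resolve_path(config$exclusion_path, config))
  } else NULL
  proxies <- if (!is.null(config$proxy_path)) {
    read_proxy_map(resolve_path(config$proxy_path, config))
  } else NULL

  sel_cfg <- do.call(selection_config, c(
    config$selection %||% list(),
    list(exclusion_ids = exclusions$variant_id %||% character())))
  sel <- select_instruments(exposure, ld, sel_cfg)

  strength <- tryCatch(
    instrument_strength(exposure, sel$instrument_ids),
    error = function(e) NULL)

  estimates <- list(); diagnostics <- list(); harmonized_all <- list()
  loo_all <- list(); scatter_all <- list()
  for (oc in config$outcomes) {
    outcome <- load_dataset_entry(oc, config)
    harm <- harmonize(exposure, outcome, sel$instrument_ids,
                      proxies = proxies,
                      palindrome_eaf_limit = config$palindrome_eaf_limit,
                      proxy_r2_min = config$proxy_r2_min)
    harm$outcome <- oc$name
    harmonized_all[[oc$name]] <- harm
    usable <- usable_instruments(harm)
    k <- nrow(usable)
    if (k == 0) {
      rlang::abort(sprintf("harmonization left no usable instruments for %s",
                           oc$name))
    }
    est <- mr_all_methods(usable, n_boot = config$n_boot, seed = seed)
    est$outcome <- oc$name
    estimates[[oc$name]] <- est

    diag_row <- tibble::tibble(
      outcome = oc$name, k = k,
      q_stat = NA_real_, q_df = NA_integer_, q_pval = NA_real_,
      egger_intercept = NA_real_, egger_intercept_pval = NA_real_,
      presso_global_rss = NA_real_, presso_global_pval = NA_real_,
      presso_outliers = NA_character_, presso_distortion_pval = NA_real_,
      n_sim = NA_integer_, seed = seed)
    if (k >= 2) {
      qres <- cochran_q(usable)
      diag_row$q_stat <- qres$q
      diag_row$q_df <- qres$df
      diag_row$q_pval <- qres$pval
    }
    if (k >= 3) {
      eg <- mr_egger(usable)
      diag_row$egger_intercept <- eg$beta[eg$method == "egger_intercept"]
      diag_row$egger_intercept_pval <- eg$pval[eg$method == "egger_intercept"]
      loo <- leave_one_out(usable)
      loo$outcome <- oc$name
      loo_all[[oc$name]] <- loo
    }
    if (k >= 4) {
      pres <- mr_presso(usable, n_sim = config$n_sim, seed = seed)
      diag_row$presso_global_rss <- pres$global_rss
      diag_row$presso_global_pval <- pres$global_pval
      diag_row$presso_outliers <- paste(pres$outliers, collapse = ";")
      diag_row$presso_distortion_pval <- pres$distortion_pval
      diag_row$n_sim <- as.integer(pres$n_sim)
    }
    diagnostics[[oc$name]] <- diag_row
    scatter_all[[oc$name]] <- tibble::tibble(
      outcome = oc$name, variant_id = usable$variant_id,
      used_id = usable$used_id,
      beta_exp = usable$beta_exp, se_exp = usable$se_exp,
      beta_out = usable$beta_out, se_out = usable$se_out)
  }
  estimates <- dplyr::bind_rows(estimates)
  diagnostics <- dplyr::bind_rows(diagnostics)
  harmonized_all <- dplyr::bind_rows(harmonized_all)
  loo_all <- dplyr::bind_rows(loo_all)
  scatter_all <- dplyr::bind_rows(scatter_all)

  # meta-analysis of designated outcome groups on the primary estimates
  primary <- estimates[estimates$method %in% c("ivw_mre", "wald"), ]
  meta_rows <- list()
  for (grp in names(config$meta_groups)) {
    members <- unlist(config$meta_groups[[grp]])
    sub <- primary[primary$outcome %in% members, ]
    mt <- fixed_effect_meta(sub$beta, sub$se, labels = sub$outcome)
    meta_rows[[grp]] <- dplyr::bind_rows(
      dplyr::mutate(mt$per_study, group = grp, row = "study"),
      tibble::tibble(group = grp, row = "pooled", study = "pooled",
                     log_or = mt$pooled$beta, se = mt$pooled$se,
                     or = exp(mt$pooled$beta),
                     ci_low = exp(mt$pooled$ci_low),
                     ci_high = exp(mt$pooled$ci_high),
                     weight_pct = 100,
                     pval = mt$pooled$pval, q_between = mt$q_between,
                     q_pval = mt$q_pval))
  }
  meta <- if (length(meta_rows)) dplyr::bind_rows(meta_rows) else
    tibble::tibble()

  n_tests <- config$n_tests %||% length(config$outcomes)
  classification <- tibble::tibble(
    outcome = primary$outcome, pval = primary$pval,
    threshold = bonferroni_threshold(config$alpha, n_tests),
    class = classify_pvalues(primary$pval, config$alpha, n_tests))

  manifest <- list(
    package_version = as.character(utils::packageVersion("admr")),
    seed = seed, n_boot = config$n_boot, n_sim = config$n_sim,
    alpha = config$alpha, n_tests = n_tests,
    selection = sel_cfg[c("p_threshold", "ld_r2_max", "ld_window_kb",
                          "maf_min")],
    instruments = sel$instrument_ids,
    outcomes = vapply(config$outcomes, function(o) o$name, character(1)))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results_table(estimates, file.path(out_dir, "estimates.tsv"))
  readr::write_tsv(estimates, file.path(out_dir, "estimates_full.tsv"),
                   progress = FALSE)
  readr::write_tsv(diagnostics, file.path(out_dir, "diagnostics.tsv"),
                   progress = FALSE)
  readr::write_tsv(harmonized_all[, c("outcome", "variant_id", "used_id",
                                      "status", "flipped", "palindromic")],
                   file.path(out_dir, "harmonization.tsv"), progress = FALSE)
  readr::write_tsv(sel$audit, file.path(out_dir, "selection_audit.tsv"),
                   progress = FALSE)
  if (nrow(loo_all)) {
    readr::write_tsv(loo_all, file.path(out_dir, "leave_one_out.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(scatter_all, file.path(out_dir, "scatter.tsv"),
                   progress = FALSE)
  if (nrow(meta)) {
    readr::write_tsv(meta, file.path(out_dir, "meta.tsv"), progress = FALSE)
  }
  readr::write_tsv(classification, file.path(out_dir, "classification.tsv"),
                   progress = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(estimates = estimates, diagnostics = diagnostics,
                 harmonization = harmonized_all, audit = sel$audit,
                 loo = loo_all, scatter = scatter_all, meta = meta,
                 classification = classification, strength = strength,
                 manifest = manifest))
}
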