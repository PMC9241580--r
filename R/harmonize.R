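COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

revcomp_pair <- function(ea, oa) {
  c(unname(COMPLEMENT[ea]), unname(COMPLEMENT[oa]))
}

is_palindromic <- function(ea, oa) {
  COMPLEMENT[ea] == oa
}

# EAF is "informative" for strand resolution when it is clearly away from 0.5
eaf_side <- function(eaf, limit) {
  ifelse(is.na(eaf), NA_character_,
         ifelse(eaf < limit, "low",
                ifelse(eaf > 1 - limit, "high", "ambiguous")))
}

#' Harmonize exposure and outcome associations to a shared effect allele
#'
#' For each instrument, aligns the outcome association to the exposure's
#' effect allele. Variants absent from the outcome are substituted by their
#' proxy when the proxy map offers one at or above `proxy_r2_min`
#' (`status = "proxied"`), else dropped (`status = "dropped_missing"`).
#' Swapped or strand-flipped (reverse-complement) allele pairs are matched;
#' when the match reverses the effect allele, `beta_out` is negated exactly
#' once and `eaf_out` reflected (`flipped = TRUE`). Palindromic variants
#' (A/T, C/G) cannot be resolved from alleles and rely on allele frequency:
#' both EAFs must be informative (below `palindrome_eaf_limit` or above one
#' minus it); same side means the reported effect alleles already agree,
#' opposite sides mean they are complementary and the outcome effect is
#' flipped; an ambiguous or missing EAF drops the variant
#' (`status = "dropped_palindromic"`).
#'
#' @param exposure,outcome `summary_dataset` objects.
#' @param instrument_ids Character vector of instrument ids (must all be in
#'   `exposure`). Defaults to every exposure variant.
#' @param proxies Optional proxy map tibble (`original`, `proxy`, `r2`).
#' @param palindrome_eaf_limit Frequency limit below which an EAF is
#'   considered informative for a palindromic variant (default 0.42).
#' @param proxy_r2_min Minimum proxy r-squared (default 0.8).
#' @return Tibble with one row per instrument: `variant_id`, `used_id`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out`,
#'   `flipped`, `palindromic`, `status`, `proxy_r2`. Rows with status
#'   `ok`/`proxied` carry usable instrument data; dropped rows keep the
#'   exposure side and `NA` outcome fields.
#' @export
harmonize <- function(exposure, outcome, instrument_ids = NULL,
                      proxies = NULL, palindrome_eaf_limit = 0.42,
                      proxy_r2_min = 0.8) {
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  assert_scalar_prob(palindrome_eaf_limit, "palindrome_eaf_limit")
  exp_rec <- exposure$records
  instrument_ids <- instrument_ids %||% exp_rec$variant_id
  missing_instr <- setdiff(instrument_ids, exp_rec$variant_id)
  if (length(missing_instr) > 0) {
    rlang::abort(sprintf("instrument id(s) not in exposure dataset: %s",
                         paste(utils::head(missing_instr, 5), collapse = ", ")))
  }
  out_rec <- outcome$records
  subs <- substitute_proxies(setdiff(instrument_ids, out_rec$variant_id),
                             proxies, outcome, proxy_r2_min = proxy_r2_min)

  rows <- lapply(instrument_ids, function(id) {
    e <- exp_rec[exp_rec$variant_id == id, ]
    used_id <- id
    proxy_r2 <- NA_real_
    status <- "ok"
    if (!id %in% out_rec$variant_id) {
      hit <- subs[subs$original == id & subs$substituted, ]
      if (nrow(hit) == 1) {
        used_id <- hit$proxy
        proxy_r2 <- hit$r2
        status <- "proxied"
      } else {
        return(harmonized_row(id, id, e, NULL, FALSE, FALSE,
                              "dropped_missing", NA_real_))
      }
    }
    o <- out_rec[out_rec$variant_id == used_id, ]
    align_alleles(id, used_id, e, o, palindrome_eaf_limit, status, proxy_r2)
  })
  dplyr::bind_rows(rows)
}

harmonized_row <- function(id, used_id, e, o, flipped, palindromic, status,
                           proxy_r2) {
  tibble::tibble(
    variant_id = id,
    used_id = used_id,
    beta_exp = e$beta,
    se_exp = e$se,
    beta_out = if (is.null(o)) NA_real_ else o$beta,
    se_out = if (is.null(o)) NA_real_ else o$se,
    eaf_exp = e$eaf,
    eaf_out = if (is.null(o)) NA_real_ else o$eaf,
    flipped = flipped,
    palindromic = palindromic,
    status = status,
    proxy_r2 = proxy_r2
  )
}

align_alleles <- function(id, used_id, e, o, limit, status, proxy_r2) {
  ea_e <- e$effect_allele; oa_e <- e$other_allele
  ea_o <- o$effect_allele; oa_o <- o$other_allele
  pal <- is_palindromic(ea_e, oa_e)

  if (pal) {
    # palindromic exposure pair: alleles cannot distinguish strand, use EAF
    if (!setequal(c(ea_o, oa_o), c(ea_e, oa_e))) {
      return(harmonized_row(id, used_id, e, NULL, FALSE, TRUE,
                            "dropped_missing", proxy_r2))
    }
    # express the outcome EAF on the exposure's reported effect allele
    eaf_o_on_e <- if (ea_o == ea_e) o$eaf else 1 - o$eaf
    side_e <- eaf_side(e$eaf, limit)
    side_o <- eaf_side(eaf_o_on_e, limit)
    if (is.na(side_e) || is.na(side_o) ||
        side_e == "ambiguous" || side_o == "ambiguous") {
      return(harmonized_row(id, used_id, e, NULL, FALSE, TRUE,
                            "dropped_palindromic", proxy_r2))
    }
    beta_o_on_e <- if (ea_o == ea_e) o$beta else -o$beta
    if (side_e == side_o) {
      # frequencies agree: the labelled alleles are the same allele
      o2 <- list(beta = beta_o_on_e, se = o$se, eaf = eaf_o_on_e)
      return(harmonized_row(id, used_id, e, o2, ea_o != ea_e, TRUE, status,
                            proxy_r2))
    }
    # opposite sides: the outcome's labelled allele is the complement on the
    # other strand; flip once more
    o2 <- list(beta = -beta_o_on_e, se = o$se, eaf = 1 - eaf_o_on_e)
    return(harmonized_row(id, used_id, e, o2, ea_o == ea_e, TRUE, status,
                          proxy_r2))
  }

  rc <- revcomp_pair(ea_o, oa_o)
  if (ea_o == ea_e && oa_o == oa_e) {
    flip <- FALSE
  } else if (ea_o == oa_e && oa_o == ea_e) {
    flip <- TRUE
  } else if (rc[1] == ea_e && rc[2] == oa_e) {
    flip <- FALSE  # strand flip only
  } else if (rc[1] == oa_e && rc[2] == ea_e) {
    flip <- TRUE   # strand flip + swapped order
  } else {
    return(harmonized_row(id, used_id, e, NULL, FALSE, FALSE,
                          "dropped_missing", proxy_r2))
  }
  o2 <- list(beta = if (flip) -o$beta else o$beta,
             se = o$se,
             eaf = if (flip && !is.na(o$eaf)) 1 - o$eaf else o$eaf)
  harmonized_row(id, used_id, e, o2, flip, FALSE, status, proxy_r2)
}

#' Substitute proxies for instruments missing from an outcome dataset
#'
#' @param missing_ids Instrument ids absent from the outcome.
#' @param proxies Proxy map tibble (`original`, `proxy`, `r2`) or `NULL`.
#' @param outcome The outcome `summary_dataset` (the proxy must be present
#'   in it).
#' @param proxy_r2_min Minimum acceptable proxy r-squared (default 0.8).
#' @return Tibble `original`, `proxy`, `r2`, `substituted`, `reason` with one
#'   row per missing id.
#' @export
substitute_proxies <- function(missing_ids, proxies, outcome,
                               proxy_r2_min = 0.8) {
  if (length(missing_ids) == 0) {
    return(tibble::tibble(original = character(), proxy = character(),
                          r2 = numeric(), substituted = logical(),
                          reason = character()))
  }
  out_ids <- outcome$records$variant_id
  rows <- lapply(missing_ids, function(id) {
    entry <- if (is.null(proxies)) NULL else proxies[proxies$original == id, ]
    if (is.null(entry) || nrow(entry) == 0) {
      return(tibble::tibble(original = id, proxy = NA_character_,
                            r2 = NA_real_, substituted = FALSE,
                            reason = "no_proxy"))
    }
    entry <- entry[order(-entry$r2), ][1, ]
    if (entry$r2 < proxy_r2_min) {
      return(tibble::tibble(original = id, proxy = entry$proxy, r2 = entry$r2,
                            substituted = FALSE, reason = "r2_below_threshold"))
    }
    if (!entry$proxy %in% out_ids) {
      return(tibble::tibble(original = id, proxy = entry$proxy, r2 = entry$r2,
                            substituted = FALSE, reason = "proxy_not_in_outcome"))
    }
    tibble::tibble(original = id, proxy = entry$proxy, r2 = entry$r2,
                   substituted = TRUE, reason = NA_character_)
  })
  dplyr::bind_rows(rows)
}

#' Keep only usable harmonized instruments
#'
#' @param harmonized Output of [harmonize()].
#' @return The rows with status `ok` or `proxied`.
#' @export
usable_instruments <- function(harmonized) {
  harmonized[harmonized$status %in% c("ok", "proxied"), , drop = FALSE]
}
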