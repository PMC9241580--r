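#!/usr/bin/env Rscript
# Build the analysis inputs under results/data:
#  - the deterministic worked-example bundle (exposure candidates, outcome,
#    LD pair, confounder exclusion, proxy map), shaped like a two-sample MR
#    of atopic dermatitis on heart failure;
#  - a second, independent heart-failure-like outcome generated at the
#    smaller replication-cohort scale so the meta-analysis step has two
#    studies to pool.

suppressPackageStartupMessages(library(admr))

data_dir <- file.path("results", "data")
fx <- make_example_fixture(data_dir)

cat(sprintf("exposure candidates:   %d\n", nrow(fx$exposure$records)))
cat(sprintf("outcome associations:  %d\n", nrow(fx$outcome$records)))

# replication-style outcome: same variants (exposure allele coding), same
# generating causal effect, sample size of a 6,504-case / 387,652-control
# GWAS; proxies stand in for the two instruments the first outcome lacks
rep_n_cases <- 6504L; rep_n_controls <- 387652L
n_out <- rep_n_cases + rep_n_controls
theta <- log(1.07)
exp_rec <- fx$exposure$records
out_ids <- fx$outcome$records$variant_id
src <- match(out_ids, exp_rec$variant_id)
proxy_row <- match(out_ids, fx$proxies$proxy)
src[is.na(src)] <- match(fx$proxies$original[proxy_row[is.na(src)]],
                         exp_rec$variant_id)
e <- exp_rec[src, ]
set.seed(20220615)
se_rep <- round(1 / sqrt(2 * e$eaf * (1 - e$eaf) * n_out), 5)
beta_rep <- round(theta * e$beta + rnorm(length(out_ids), 0, se_rep), 5)
rep_out <- summary_dataset(tibble::tibble(
  variant_id = out_ids, chrom = e$chrom, pos = e$pos,
  effect_allele = e$effect_allele, other_allele = e$other_allele,
  eaf = e$eaf, beta = beta_rep, se = se_rep,
  pval = signif(pmax(2 * pnorm(-abs(beta_rep / se_rep)),
                     .Machine$double.xmin), 3),
  n = n_out),
  trait_name = "heart_failure_replication",
  n_cases = rep_n_cases, n_controls = rep_n_controls)
write_sumstats(rep_out, file.path(data_dir, "outcome_replication.tsv"))

cat(sprintf("replication outcome:   %d variants -> %s\n",
            nrow(rep_out$records),
            file.path(data_dir, "outcome_replication.tsv")))
cat("inputs written under", data_dir, "\n")
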