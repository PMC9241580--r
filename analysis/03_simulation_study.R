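#!/usr/bin/env Rscript
# Simulation study at study-scale dimensions (19 instruments, exposure
# N = 116,863, outcome N = 977,323):
#  1. parameter recovery of a causal log-OR of 0.07 with valid instruments,
#  2. behaviour under balanced and directional pleiotropy (mean pleiotropic
#     effect 0.02), contrasting IVW bias with the Egger slope and intercept.
# 200 replicates per scenario; tables under results/simulation.

suppressPackageStartupMessages(library(admr))

out_dir <- file.path("results", "simulation")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

theta <- 0.07
n_rep <- 200

run_scenario <- function(pleiotropy, seed_base) {
  reps <- lapply(seq_len(n_rep), function(s) {
    sim <- simulate_mr_sumstats(synthetic_truth(
      theta = theta, k = 19, n_exp = 116863, n_out = 977323,
      pleiotropy = pleiotropy, pl_mean = 0.02, pl_sd = 0.01, pl_frac = 1,
      seed = seed_base + s))
    h <- usable_instruments(harmonize(sim$exposure, sim$outcome))
    eg <- mr_egger(h)
    tibble::tibble(
      scenario = pleiotropy,
      ivw = mr_ivw(h, "mre")$beta,
      egger_slope = eg$beta[eg$method == "egger_slope"],
      egger_intercept = eg$beta[eg$method == "egger_intercept"],
      q_pval = cochran_q(h)$pval)
  })
  dplyr::bind_rows(reps)
}

scenarios <- dplyr::bind_rows(
  run_scenario("none", 1000),
  run_scenario("balanced", 2000),
  run_scenario("directional", 3000))

summary <- scenarios |>
  dplyr::group_by(scenario) |>
  dplyr::summarise(
    mean_ivw = mean(ivw), mc_se_ivw = sd(ivw) / sqrt(dplyr::n()),
    mean_egger_slope = mean(egger_slope),
    mean_egger_intercept = mean(egger_intercept),
    mc_se_intercept = sd(egger_intercept) / sqrt(dplyr::n()),
    q_reject_rate = mean(q_pval < 0.05))

readr::write_tsv(scenarios, file.path(out_dir, "replicates.tsv"))
readr::write_tsv(summary, file.path(out_dir, "summary.tsv"))

cat(sprintf("true causal effect: %.3f; %d replicates per scenario\n",
            theta, n_rep))
print(as.data.frame(summary), row.names = FALSE)
cat("\nreading: with valid instruments the mean IVW estimate sits within\n")
cat("Monte-Carlo error of the truth; directional pleiotropy biases IVW\n")
cat("upward while the Egger intercept absorbs the mean pleiotropic effect\n")
cat("(0.02) and the Egger slope stays closer to the truth.\n")
cat("tables written under", out_dir, "\n")
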