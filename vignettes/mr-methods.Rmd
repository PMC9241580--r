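---
title: "Methods: two-sample Mendelian randomization in admr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in admr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admr)
```

# The causal model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables for an exposure. Instrument *j* must (1) associate robustly with
the exposure, (2) be independent of confounders of the exposure–outcome
relationship, and (3) affect the outcome only through the exposure. Under
those conditions, with summary associations (γ̂ⱼ, σ_Xⱼ) for the exposure and
(Γ̂ⱼ, σ_Yⱼ) for the outcome, each ratio θ̂ⱼ = Γ̂ⱼ/γ̂ⱼ estimates the same
causal effect θ, and the estimators in this package are different ways of
pooling the ratios that fail gracefully under different violations of
assumption (3).

All effects are kept on the log-odds scale internally; odds ratios appear
only in reporting (`write_results_table()`), where `exp()` is applied last.

# Instrument selection

`select_instruments()` runs a fixed four-stage pipeline; permuting input
rows never changes the selected set.

1. **Significance**: keep `pval < p_threshold` (default 5×10⁻⁸).
2. **LD pruning**: greedy clumping in ascending p-value order (ties broken
   lexicographically by variant id, for reproducibility). A candidate is
   kept only if its r² with every already-kept variant within
   `ld_window_kb` (default 10,000 kb) is below `ld_r2_max` (default 0.001).
   The pruning literature does not fix an algorithm; p-ordered greedy
   clumping is the deterministic standard. Missing information is treated
   conservatively: an unknown r² between co-located variants fails the test
   (the weaker variant is pruned), while variants on different chromosomes
   or beyond the window are accepted as independent. A *measured* r² above
   the threshold also prunes when positions are missing, since the window
   cannot exonerate the pair.
3. **MAF**: drop variants whose EAF-derived minor allele frequency is at or
   below `maf_min` (default 0.01). Variants with no EAF pass with a
   warning — a frequency filter should not silently delete instruments the
   user asserted.
4. **Exclusion**: remove ids on the confounder-association list. This list
   replaces a live database lookup (e.g. a PhenoScanner export) so runs are
   reproducible offline.

Instrument strength uses the summary-statistic approximation
R²ⱼ = γ̂ⱼ²/(γ̂ⱼ² + N σ_Xⱼ²), equivalently t²/(t² + N), summed across
independent instruments, and F = R²(N−2)/(1−R²) with the conventional
F < 10 weak-instrument flag.

# Harmonization

`harmonize()` aligns every instrument's outcome association to the
exposure's effect allele. Allele pairs matching directly or after reverse
complement are aligned mechanically; when the match reverses the effect
allele, the outcome beta is negated exactly once and the EAF reflected.

Palindromic variants (A/T, C/G) carry no strand information in their
alleles, so frequency decides. An EAF is *informative* when it is below
`palindrome_eaf_limit` (default 0.42, common practice) or above one minus
it. If both EAFs are informative and on the same side, the labelled alleles
already agree; on opposite sides, the outcome labelled the complementary
allele and the effect is flipped. If either EAF is missing or falls in the
ambiguous middle zone, the variant is dropped (`dropped_palindromic`) —
safety over instrument count. We resolve the opposite-side case by flipping
rather than dropping because the frequencies identify the allele exactly as
reliably as in the same-side case; only the ambiguous zone is genuinely
uninformative.

Instruments absent from the outcome are replaced by proxies from a
user-supplied map when the proxy's r² is at least `proxy_r2_min` (default
0.8). The proxy's own outcome association is used unchanged — no effect
rescaling — which matches standard practice for high-LD proxies.

# Estimators

* **IVW** uses first-order weights wⱼ = γ̂ⱼ²/σ_Yⱼ² (exposure-side noise
  ignored in the weight), the form implemented by the standard MR software;
  it equals zero-intercept weighted least squares of Γ̂ on γ̂. The primary
  model is multiplicative random effects: SE inflated by
  max(1, √(Q/(k−1))). The floor at 1 means homogeneous data fall back to
  the fixed-effect SE; the p-value is normal.
* **Weighted median**: Wald ratios are ordered, cumulative weight midpoints
  sⱼ = Σᵢ₍ᵢ₎₌₁ʲ⁻¹ wᵢ' + wⱼ'/2 computed, and the estimate is the linear
  interpolation of the ordered ratios at s = 0.5. It is consistent while at
  least half the weight comes from valid instruments. The SE is a
  parametric bootstrap (default `n_boot = 1000`): exposure and outcome
  betas are redrawn around their observed values with their SEs. The seed
  is a mandatory argument; there is no hidden global RNG state.
* **MR-Egger**: instruments are oriented so γ̂ⱼ > 0, then Γ̂ⱼ is regressed
  on γ̂ⱼ with weights 1/σ_Yⱼ² and a free intercept. The intercept estimates
  the average directional pleiotropic effect; the slope is the causal
  estimate under the InSIDE assumption. Coefficient SEs come from the
  weighted normal equations with the residual scale floored at 1
  (computed directly from the design matrix, so an exact fit with zero
  residuals still yields finite SEs), and p-values use the t distribution
  with k−2 degrees of freedom.

With one instrument the battery degrades to the Wald ratio; the weighted
median and Egger require k ≥ 3.

# Diagnostics

* **Cochran's Q** = Σ wⱼ(θ̂ⱼ − θ̂_IVW)², chi-square with k−1 df under
  homogeneity. Q scales as 1/c² when all σ_Y are multiplied by c.
* **MR-PRESSO**. The observed residual sum of squares uses leave-one-out
  IVW predictions, RSS = Σⱼ wⱼ(Γ̂ⱼ − θ̂₍₋ⱼ₎γ̂ⱼ)²; its null distribution is
  simulated by redrawing Γ̂ⱼ* ~ N(θ̂₍₋ⱼ₎γ̂ⱼ, σ_Yⱼ) (default
  `n_sim = 1000`). Empirical p-values use the add-one estimator
  (1 + #{RSS* ≥ RSS})/(n_sim + 1) so they are never exactly zero. The
  per-variant outlier test compares each observed RSS contribution with its
  simulated distribution, Bonferroni-corrected over k; the distortion test
  (run only when outliers are flagged) compares the estimate shift after
  outlier removal against 1,000 random equal-size removals. A known
  numerical behaviour: with few instruments (around k = 10) the global test
  is slightly conservative, because the simulation centres inherit the
  estimation noise of the observed leave-one-out estimates; calibration is
  accurate at the instrument counts typical of well-powered exposures
  (k ≈ 19: measured type-I error 4.8–5.6% at the 5% level).
* **Leave-one-out** re-estimates the primary model with each instrument
  excluded, and also accepts a single named exclusion for targeted
  sensitivity analyses (e.g. removing a variant that dominates both the
  exposure and outcome associations).

# Meta-analysis, multiple testing, power

Study-level log odds ratios are pooled by fixed-effect inverse-variance
weighting; `ci_to_se()` reconstructs the SE from a printed 95% CI as
(ln hi − ln lo)/(2 × 1.959964) — the multiplier is kept at full precision
internally, and rounding happens only at reporting. Fixed-effect pooling is
the default because with two studies whose between-study Q is below its
degrees of freedom (verified for the worked example, Q = 0.78 on 1 df), a
DerSimonian–Laird random-effects model collapses to the fixed-effect
answer anyway.

Family-wise control uses the Bonferroni threshold α/n_tests — 0.05/9 ≈
0.0056 for a nine-outcome cardiovascular family — with a three-way
classification: significant (below the threshold), suggestive (below α but
not the threshold), null.

Analytical power for a binary outcome uses the normal approximation behind
the standard MR power calculators: ncp = N·R²·K(1−K)·ln(OR)², power =
Φ(√ncp − z₀.₉₇₅) + Φ(−√ncp − z₀.₉₇₅). It is an approximation — the test
suite checks it against a simulated score test under the linearised risk
model it assumes; real logistic non-linearity shifts power by well under a
percentage point at the effect sizes relevant here.

# The synthetic generator

`simulate_mr_sumstats()` draws true instrument effects γⱼ log-uniformly
over `gamma_range` (default 0.04–0.35 log-odds, so a single variant can
dominate, as one often does in real exposure GWAS), effect-allele
frequencies uniformly (default 0.05–0.95), and sets standard errors by the
standardized-trait approximation σ = 1/√(2p(1−p)N). Observed betas are
normal around the truth; outcome means are θγⱼ plus a pleiotropy term that
is zero (`none`), centred at zero (`balanced`), or centred at `pl_mean`
for a `pl_frac` subset (`directional`). One integer seed drives a single
local RNG stream; the caller's RNG state is untouched.

Defaults mirror a large binary-exposure design: k = 19 instruments,
exposure N = 116,863, outcome N = 977,323, causal effect θ = 0.07
log-odds, directional pleiotropy mean 0.02 with SD 0.01 — the SD chosen so
pleiotropic effects are clearly non-zero yet small against the instrument
effects, which is the regime where Egger's intercept is informative.

What the generator does *not* emulate: linkage between instruments (all
variants are generated independent, so LD pruning is exercised only by the
deterministic fixture), sample overlap between exposure and outcome
studies, winner's-curse selection of instruments, allele-frequency
mismatch between studies, and case-control ascertainment effects on SEs.
Passing recovery tests therefore show the estimators are correct under the
model they assume, not that real consortium data meet that model.

`make_example_fixture()` complements the stochastic generator with a fully
deterministic worked example: 21 genome-wide-significant candidates, one
LD-linked pair (r² = 0.5) whose weaker member is pruned, one
confounder-associated exclusion, and two instruments missing from the
outcome with valid proxies (r² 0.9 and 0.85), yielding 19 instruments with
2 proxy substitutions. Variant identifiers follow their real-world
counterparts; all numeric values are synthetic, with observed exposure
betas placed at their generating values so the example is stable to the
digit across platforms.

# Numerical choices and degenerate inputs

* P-values from extreme z-scores are floored at the smallest positive
  normal double in the generator, since a literal 0 violates the record
  invariant p ∈ (0, 1].
* Summary tables are written with 15 significant digits so a write/read
  round trip is lossless to at least 12.
* A zero exposure beta makes the Wald ratio undefined and is an error, not
  an NA; IVW refuses such instruments for the same reason.
* Ties in the LD-pruning p-value order are broken by variant id;
  `weighted_median` interpolation clamps to the extreme ratios when 0.5
  falls outside the first/last midpoint.
* An unwritable output path, a missing mandatory column (named in the
  error), or a dataset with zero valid rows abort immediately; invalid
  *rows* are dropped with a logged count instead, because real consortium
  files contain sentinel rows and the instrument list is checked again
  downstream.

# Problem sizes used in the shipped experiments

The simulation study and test suite use 200 replicates per scenario for
recovery experiments, 10,000 draws for chi-square moment checks, 500 null
replicates (n_sim = 300) for MR-PRESSO calibration, and 10,000 replicates
for the power oracle — sizes at which Monte-Carlo error is a few percent
of the quantities checked, which matches the tolerances asserted.

# Known limitations

* First-order weights throughout; no NOME/I²_GX correction, no
  second-order or exact weights.
* No Steiger directionality filtering, mode-based estimators, MR-RAPS, or
  multivariable MR.
* LD pruning consumes a user-supplied r² table; the package never computes
  LD from genotypes.
* The Egger SE floor (residual scale at 1) makes its intervals
  conservative for strongly under-dispersed data.
* MR-PRESSO's global test is mildly conservative at small instrument
  counts (see above).
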