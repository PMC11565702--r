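---
title: "Methods: two-sample Mendelian randomization with mediation in mrchain"
author: "mrchain authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization with mediation in mrchain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrchain)
```

# The problem

Observational correlations between an exposure (say, hypothyroidism) and an
outcome (osteoporosis) are confounded. Two-sample Mendelian randomization
(MR) instruments the exposure with genetic variants: because alleles are
assigned at conception, a variant that (1) associates with the exposure,
(2) is independent of confounders, and (3) affects the outcome only through
the exposure identifies a causal effect from summary statistics alone. The
"two-sample" design takes SNP-exposure and SNP-outcome associations from
separate GWAS cohorts, so only per-variant effect sizes, standard errors,
alleles and frequencies are needed.

`mrchain` implements the full analysis chain on that summary-level
substrate: instrument selection, allele harmonization, five causal
estimators with heterogeneity/pleiotropy diagnostics and outlier
correction, multivariable MR, and a two-step mediation decomposition with
a false-discovery-rate screen over many candidate mediators — plus a
simulator that generates the whole data structure with known ground truth,
so every claim the package makes is testable without downloading any GWAS.

# Instrument selection

Three filters, applied in order by `selectInstruments()`:

* **Relevance.** Genome-wide significance, strict `p < 5e-8`.
* **Independence.** Greedy LD clumping: repeatedly take the
  smallest-p remaining variant as an index and discard variants on the
  same chromosome within 10,000 kb whose r² with it exceeds 0.001.
  P-value ties break lexicographically by variant id, making the result
  independent of input row order. LD is an explicit input (`LdInfo`):
  either a pairwise r² table/matrix or a declared "independent" mode for
  pre-pruned panels, in which only exact positional duplicates are
  removed. Pairs inside a window with unknown r² are treated as linked by
  default (conservative), or raise an error on request.
* **Strength.** Per-variant F-statistic `F = beta^2 / se^2`, keeping
  `F > 10` (strict), the conventional weak-instrument cutoff.

Stage counts are recorded so attrition is always reportable.

# Harmonization

`harmonize()` aligns outcome effects onto the exposure's effect-allele
frame: swapped allele pairs flip the outcome beta's sign and complement
its allele frequency; irreconcilable pairs are dropped as `mismatch`.
Palindromic variants (A/T, C/G) are ambiguous across strands; the default
drops them outright. An opt-in relaxation keeps palindromes whose allele
frequencies on both sides are informative (farther than
`palindromicEafWindow = 0.08` from 0.5) and uses frequency concordance to
orient them. Complement-base ("strand rescue") matching is deliberately
not attempted: it cannot be distinguished from a genuine mismatch without
strand annotations. Every removal lands in a drop log with its reason,
and retained + dropped always partitions the variant intersection.

# Estimators

All effects are carried on the log odds-ratio scale; odds ratios appear
only at reporting. Confidence intervals and p-values are normal-theory at
95% throughout. For variant *j* with exposure effect $\hat\beta_{Xj}$
(SE $\sigma_{Xj}$) and outcome effect $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$):

* **Wald ratio** $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with
  first-order SE $\sigma_{Yj}/|\hat\beta_{Xj}|$.
* **IVW** fixed effects is the weighted regression of outcome on exposure
  effects through the origin with weights $w_j = \sigma_{Yj}^{-2}$:
  $\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
  \hat\beta_{Xj}^2$, $\mathrm{se} = (\sum w_j \hat\beta_{Xj}^2)^{-1/2}$ —
  algebraically the inverse-variance-weighted mean of Wald ratios. The
  random-effects variant inflates the SE by
  $\sqrt{\max(Q/(n-1),\,1)}$ (multiplicative overdispersion floored at
  one, the dominant convention in two-sample MR software; the floor means
  random-effects SEs never fall below fixed). The `auto` model implements
  the heterogeneity-gated rule: run Cochran's Q first and use random
  effects when its p < 0.05, fixed otherwise; the branch taken is always
  recorded.
* **MR-Egger** regresses outcome on exposure effects *with* an intercept
  (same weights), after orienting each variant so
  $\hat\beta_{Xj} \ge 0$. The slope estimates the causal effect even
  under directional pleiotropy (given InSIDE); the intercept, its SE and
  normal p are the directional-pleiotropy test. Egger SEs use the same
  multiplicative dispersion floored at one.
* **Weighted median**: order the Wald ratios, place each at standardized
  cumulative weight $p_j = (S_j - w_j/2)/\sum w$ (first-order inverse
  ratio variances as weights), and interpolate linearly to weight 0.5.
  Consistent when valid instruments carry half the weight.
* **Weighted mode**: normal-kernel weighted density over the ratios with
  bandwidth $\varphi \cdot 0.9\,\mathrm{mad}(\hat\theta_j)\,n^{-1/5}$
  (default $\varphi = 1$; `sd` fallback when the MAD degenerates),
  argmax on a fixed 10,000-point grid spanning the ratio range ± 3
  bandwidths. Consistent when the largest cluster of instruments is
  valid.

Weighted median/mode SEs come from a seeded parametric bootstrap (default
1,000 replicates) that redraws each effect pair from its normal sampling
distribution; the bootstrap reuses the exact kernel rule via a
1,024-point FFT density per replicate, while the point estimate always
uses the exact dense grid. Seeds are mandatory arguments (default 0), so
every number the package emits is reproducible bit-for-bit.

# Diagnostics

* **Cochran's Q** over Wald ratios with first-order weights
  $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$, chi-square on $n-1$ df. Under
  the null the conditional distribution is exactly chi-square because the
  outcome noise is Gaussian with known SE; the test suite verifies the
  distributional law by simulation.
* **Egger intercept** test (above), exposed as `pleiotropyTest()`.
* **Leave-one-out**: the gated IVW excluding each variant in turn, with a
  flag when an exclusion reverses the inferred direction.
* **Funnel data**: ratios against precisions with IVW/Egger reference
  lines, for any plotting layer (no figures are rendered here).
* **MR-PRESSO**: the observed residual sum of squares around
  leave-one-out IVW slopes is compared with `nSim` parametric replicates
  simulated under those slopes. The global p is the exceedance fraction;
  per-variant exceedances give outlier p-values, Bonferroni-adjusted,
  flagged below `outlierAlpha = 0.05`; the corrected estimate is exactly
  the gated IVW on the non-flagged set. The distortion test compares the
  observed raw-vs-corrected shift with shifts from removing random
  subsets of the same size (two-sided on the absolute shift) — the
  published method bootstraps outlier-set deviations instead, but the
  random-subset null answers the same question with fewer moving parts
  and is what is documented and tested here. All p-values use the
  (count+1)/(nSim+1) permutation convention so they stay in (0, 1], and
  simulation draws are made in variant-id order, making results invariant
  to input row order. Note the smallest attainable adjusted outlier p is
  `n/(nSim+1)`: `nSim` must be large enough for the threshold to be
  reachable (the default 1,000 suffices for panels up to ~50
  instruments).

# Multivariable MR

`assembleMvmr()` takes the union of genome-wide-significant variants
across exposures, clumps jointly (index p = minimum across exposures),
requires completeness in all exposures and the outcome, and aligns
everything to the first exposure's allele frame. `mvmrIVW()` is weighted
least squares of outcome effects on the exposure-effect matrix without
intercept (weights $\sigma_{Yj}^{-2}$); each coefficient is an exposure's
direct effect conditional on the others. SEs come from
$(X^\top W X)^{-1}$ with no dispersion scaling by default (a Q-based
multiplicative option exists); a single-exposure model therefore
reproduces fixed-effects IVW exactly, which the tests assert to 1e-12.
Exact collinearity raises an error naming the offending columns; a
warning fires when any exposure's marginal mean F drops below 10
(conditional instrument-strength statistics are out of scope).

# Two-step mediation

With total effect TE (exposure→outcome), step-1 effect β₁
(exposure→mediator, exposure's instruments) and step-2 effect β₂
(mediator→outcome, the mediator's own instruments):

$$IE = \beta_1\beta_2,\qquad DE = TE - IE,\qquad
\text{proportion mediated} = IE/TE.$$

Uncertainty is first-order delta method with the three estimates treated
as independent — they come from non-overlapping two-sample analyses — and
without the second-order $\sigma_1^2\sigma_2^2$ term (the classical
product-of-coefficients form):
$\mathrm{se}(IE)^2 = \beta_2^2\sigma_1^2 + \beta_1^2\sigma_2^2$ and
$\mathrm{se}(IE/TE)^2 = \mathrm{se}(IE)^2/TE^2 + IE^2\,
\sigma_{TE}^2/TE^4$. A zero TE leaves the proportion undefined: the
package raises a classed warning and returns IE and DE with `NA`
proportion fields, because a hard error would discard the still-valid
decomposition.

`screenMediators()` applies the two steps to a panel: step 1 is tested
across all mediators with Benjamini–Hochberg adjustment (q < α to
proceed, α = 0.05 by default); step 2 uses the mediator's own instruments
at unadjusted p < α, matching the common practice of FDR-correcting the
wide first step and reporting the narrow second step plainly. Both
thresholds are configurable. The total effect used in the proportion is
the univariable gated IVW by default (a supplied estimate — e.g. an
MVMR-adjusted one — can be passed instead).

# The simulator

`simulateUnivariable()`, `simulateMediationChain()`,
`simulateMetabolitePanel()` and `simulateMvmr()` generate the full
summary-statistics structure with known truth. Per variant: maf ~
U(0.05, 0.5); true effect γ ~ N(0.065, 0.015²); SEs follow
$1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$, coupling frequency, sample
size and power with a single parameter per study. Default sample sizes
are 405,357 (exposure), 399,054 (outcome) and 115,078 (mediator panel) —
large-biobank binary-trait and NMR-metabolite scales. The effect
distribution is calibrated so that a 100-instrument set pools to roughly
0.007 log-OR precision on the exposure→mediator step, the precision scale
at which published metabolite-mediation analyses operate; instruments are
then comfortably strong (F in the hundreds). The default causal effect
is ln(1.092) ≈ 0.088, and the default mediation chain
(β₁, β₂, DE) = (−0.02, −0.12, 0.086) implies IE = 0.0024, TE = 0.0884
and a mediated proportion of ≈ 2.7% — a small protective lipid-mediator
pathway inside a modest harmful total effect, the regime these analyses
genuinely face.

Pleiotropy regimes: `balanced` (zero-mean direct effects → heterogeneity
without bias), `directional` (non-zero mean → biases IVW while InSIDE
holds, so Egger's intercept recovers the mean), `correlated` (direct
effects proportional to instrument strength → violates InSIDE). Outliers
add a shift of `outlierMag` outcome-SEs to chosen variants. Optional LD
blocks exist solely to exercise clumping. Everything is deterministic in
the config seed, down to the bytes of the written TSVs.

**What the simulator does not emulate** — and hence what passing tests do
not establish about real data: sample overlap between the two GWAS,
LD-induced correlation between instruments surviving real clumping,
allele-frequency mismatch and strand error between cohorts, non-Gaussian
effect-size distributions, winner's curse in instrument discovery, and
population stratification. Results on real summary statistics inherit
those caveats.

# Numerical choices and degenerate inputs

* p-values are clamped to `(.Machine$double.xmin, 1]` so extreme
  instruments cannot emit an invalid 0.
* Summary-statistic TSVs serialize doubles with 17 significant digits:
  write → read → write is byte-identical and read-after-write reproduces
  every field exactly.
* A zero SNP-exposure effect makes the Wald ratio undefined and raises a
  classed error (`mrchain_degenerate_instrument`); estimators guard their
  minimum instrument counts (IVW 2, Egger/median/mode 3, MR-PRESSO 4)
  with `mrchain_insufficient_instruments` so callers can fall back to the
  Wald ratio deliberately, as the mediator screen does.
* A degenerate MAD in the mode bandwidth falls back to the SD, then to a
  small positive constant.
* Greedy-clump ties are broken by variant id; the weighted-median
  interpolation is deterministic by construction.

# Problem sizes used in the test suite

The distributional suites run at the scale the analyses themselves use:
500 replicates for type-I error, coverage, contamination-bias, MVMR
recovery and mediation recovery (100 instruments each); 100 replicates
for MR-PRESSO detection at 30 instruments with 1,000 simulations per
test; a 249-mediator null panel for the FDR screen. The whole suite runs
in well under a minute on one core.

# Known limitations

* First-order ratio weights ignore exposure-side sampling error (the
  NOME approximation); fine for strong instruments, anticonservative for
  weak ones — which is why the F > 10 gate and the weak-instrument
  warnings exist.
* MR-Egger inference here is normal-theory; exact-t intervals differ
  slightly at very small instrument counts.
* No MR-RAPS, contamination mixture, Steiger filtering, radial MR, or
  multi-mediator joint decomposition: one mediator per row, by design.
* LD is consumed, never estimated: clumping fidelity is bounded by the
  supplied r² table.
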