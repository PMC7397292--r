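---
title: "Two-sample Mendelian randomization with mrpipe: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model and its assumptions

Mendelian randomization treats genetic variants as instrumental variables
for an exposure $X$ (here: serum testosterone) on an outcome $Y$ (a disease,
on the log-odds scale). Writing $\gamma_j$ for variant $j$'s true effect on
the exposure and $\Gamma_j$ for its true effect on the outcome, a variant is
a *valid* instrument when it (i) affects the exposure ($\gamma_j \neq 0$),
(ii) shares no confounder with the outcome, and (iii) affects the outcome
only through the exposure. Under validity, $\Gamma_j = \theta\,\gamma_j$
with $\theta$ the causal effect, and every ratio
$\Gamma_j/\gamma_j$ identifies $\theta$.

In the two-sample design, $\hat\beta_{Xj} \approx \gamma_j$ and
$\hat\beta_{Yj} \approx \Gamma_j$ come from *different* GWAS, so their
errors are independent — which is what makes summary-level estimation with
per-variant SEs tractable. The package is unit-agnostic in the exposure:
estimates are "per unit of genetically predicted exposure", whatever unit
the exposure GWAS used (log- or SD-scaled testosterone behave identically up
to a scale factor that the user must track in labels).

A violation of (iii) — horizontal pleiotropy — adds a direct effect
$\alpha_j$: $\Gamma_j = \theta\gamma_j + \alpha_j$. The sensitivity
analyses below target exactly this.

## Estimators

**Wald ratio** (`ratio_estimate`). $\hat\theta_j =
\hat\beta_{Yj}/\hat\beta_{Xj}$. The default first-order delta-method SE,
$\mathrm{se}(\hat\beta_{Yj})/|\hat\beta_{Xj}|$, conditions on the observed
exposure association; the second-order option adds the exposure-side term
$\sqrt{\mathrm{se}_{Yj}^2/\hat\beta_{Xj}^2 +
\hat\beta_{Yj}^2\mathrm{se}_{Xj}^2/\hat\beta_{Xj}^4}$ and is never smaller.
First order is the default because it is the convention in summary-data MR
reporting; the flag records which was used.

**IVW** (`ivw_estimate`). The inverse-variance-weighted mean of the ratios
with weights $w_j = \hat\beta_{Xj}^2/\mathrm{se}_{Yj}^2$, equal (exactly,
and tested to $10^{-10}$) to weighted regression of $\hat\beta_Y$ on
$\hat\beta_X$ through the origin. Fixed effects is the default;
`effects_model = "random"` applies the multiplicative overdispersion factor
$\max\!\big(1, \sqrt{Q/(J-1)}\big)$, $Q = \sum_j w_j(\hat\theta_j -
\hat\theta)^2$, which inflates but never deflates the SE. With $J = 1$ the
IVW is definitionally the Wald ratio, which is how the pipeline handles
single-variant instruments.

**Correlation-aware IVW** (`ivw_correlated`, opt-in). When instrument
variants are in residual LD the outcome betas are correlated; generalized
least squares with $\Omega_{jk} = r_{jk}\mathrm{se}_{Yj}\mathrm{se}_{Yk}$
gives $\hat\theta = (\beta_X^\top\Omega^{-1}\beta_Y)/
(\beta_X^\top\Omega^{-1}\beta_X)$ and SE
$(\beta_X^\top\Omega^{-1}\beta_X)^{-1/2}$. It is never applied silently —
whether the original analyses modeled LD is typically unknowable from
reports, so the pipeline treats pruning as the LD control and exposes GLS as
an explicit choice. A `ridge` fraction regularizes near-singular $\Omega$
(duplicate variants); the error message suggests it.

**Weighted median** (`weighted_median`). Sort the ratios, accumulate
normalized weights to midpoints $s_j = \sum_{k\le j} w_k - w_j/2$, and
interpolate linearly at $s = 0.5$. The estimator is consistent whenever
valid instruments carry at least half the weight — i.e. up to 50% of the
instrument may be pleiotropic. The SE is the standard deviation of the
estimate over a parametric bootstrap that redraws
$\hat\beta_{Xj} \sim N(\hat\beta_{Xj}, \mathrm{se}_{Xj})$ and
$\hat\beta_{Yj} \sim N(\hat\beta_{Yj}, \mathrm{se}_{Yj})$. Two design
choices here: the bootstrap **requires an explicit seed** (silent
nondeterminism in a reported SE is worse than a mandatory argument), and
outcome-side perturbations are drawn in **antithetic pairs** ($+z$ and
$-z$), which reduces bootstrap variance and makes the SE exactly invariant
under a global sign flip of the outcome — so the package's sign-symmetry
property holds to machine precision rather than stochastically. Default
`n_boot = 1000` keeps the SE's own Monte-Carlo error near 2%.

**MR-Egger** (`egger_regression`). Orient every variant so
$\hat\beta_{Xj} \ge 0$ (flip both betas; this is the exposure-increasing
allele convention under which "directional" pleiotropy is defined), then fit
weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$ *with* intercept,
weights $1/\mathrm{se}_{Yj}^2$. The slope is the pleiotropy-adjusted causal
estimate; the intercept is the average directional pleiotropic effect per
variant and its test is the package's pleiotropy diagnostic. SEs carry the
same $\max(1, \sqrt{RSS/(J-2)})$ overdispersion guard as random-effects
IVW. P-values use the standard normal by default — matching the common
two-sided normal reporting convention — with `p_reference = "t"` switching
to the $t_{J-2}$ reference for small instruments. Constraining the
intercept to zero and disabling the overdispersion guard reproduces
fixed-effects IVW exactly, a cross-check in the test suite.

All methods report $\hat\theta$, its SE, the 95% CI using the exact normal
quantile $z_{0.975} = 1.959964$ (not 1.96), the two-sided p, and the odds
scale as the exact exponential of the log scale. Display formatting rounds
OR and estimate (se) to 3 decimals and floors p-values that would round to
0.000 at "<0.001".

## Instrument construction

`stepwise_select` implements greedy p-value-ranked LD pruning: select the
smallest-p remaining candidate, discard every remaining candidate with
$r^2$ *strictly greater than* the threshold against it (default 0.40; pairs
at exactly the threshold are retained, the literal reading of "in LD,
$r^2 > 0.40$"), repeat. Ties on p-value are broken by lexicographic rsid so
the output is invariant to input order — determinism the tests rely on. LD
is stored as signed $r$ (the GLS estimator needs the sign); pruning squares
it. The packaged 20-variant *SHBG* table is already mutually independent at
this threshold, so selection there exercises only the ranking; synthetic
block designs (`simulate_ld_candidates`) provide nontrivial ground truth —
one survivor per block, verified against a brute-force reimplementation on
100 random instances.

Single-variant instruments (the *JMJD1C* locus) bypass selection: the
pipeline accepts a pre-specified variant and, with one variant, reports the
IVW/ratio only — the weighted median needs $\ge 3$ ratios to be a
meaningful sensitivity analysis and Egger needs $\ge 3$ points to fit two
parameters with a residual df, so both are skipped with a logged note.

## Harmonization

Variants are matched by rsid, not position: outcome GWAS are rsid-keyed and
the instrument tables print positions without a stated genome build, so
positions are carried as metadata only (no liftover). Outcome records are
re-oriented to the exposure's effect allele: identical alleles pass
through, swapped alleles flip the outcome beta's sign, strand-complement
(and swapped-complement) alleles are complemented first. Palindromic
variants (A/T, C/G) are dropped by default — their strand is ambiguous, and
allele-frequency-based resolution is not attempted because the packaged
instrument tables carry no frequencies; `palindromic_policy = "keep"`
assumes both studies report the same strand. Everything dropped is logged
with a reason (`unmatched`, `palindromic`, `allele_mismatch`); an instrument
that loses all variants is an error, not an empty result. Harmonization is
idempotent and invariant to arbitrary allele re-coding of the outcome
table, both asserted as properties in the tests.

## The synthetic-data generator

`simulate_two_sample` draws summary statistics directly at the summary
level: MAF $p_j \sim U(0.05, 0.5)$, exposure effects
$\gamma_j$ uniform in magnitude with random sign, and

$$\hat\beta_{Xj} \sim N\!\big(\gamma_j,\ 1/\sqrt{2p_j(1-p_j)n_X}\big),\quad
\hat\beta_{Yj} \sim N\!\big(\theta\gamma_j + \mathrm{sign}(\gamma_j)\,\alpha_j,\
 1/\sqrt{2p_j(1-p_j)n_Y}\big),$$

independently (two-sample design, no overlap). Pleiotropy $\alpha_j$ is
zero for valid variants and Normal(`pleiotropy_mean`, `pleiotropy_sd`) for
an `invalid_fraction` share, with `balanced` forcing mean zero. Two
deliberate conventions:

* $\alpha_j$ acts **per exposure-increasing allele** — directional
  pleiotropy is only a meaningful notion relative to a fixed exposure
  orientation; tying it to the arbitrary allele coding would let the
  orientation step average it away by construction.
* Effects are simulated at the summary level, not from individual
  genotypes, and outcome betas are treated as log-odds without case/control
  sampling: the estimators consume only `(beta, se)` pairs, the SE formulas
  absorb the scale, and summary-level simulation keeps the full property
  suite inside seconds.

Defaults mirror the setting the packaged fixtures come from: an exposure
GWAS of $n_X = 3225$ (the size of the cohort behind the testosterone
instruments), outcome GWAS of $n_Y = 3\times10^5$ (the order of the cited
disease GWAS), and $|\gamma| \in (0.033, 0.181)$, the magnitude range of
the packaged instrument betas. Alleles are drawn from the non-palindromic
pairs so the default harmonization policy keeps every simulated variant.

What the generator does **not** emulate: LD between instrument variants
(exposure LD enters only through `simulate_ld_candidates`' block designs
for pruning tests), winner's-curse selection of instruments, sample overlap
between the two GWAS, MAF-dependent effect sizes, and real case/control
imbalance. Passing recovery tests therefore demonstrate estimator
correctness under the stated model, not robustness to those real-data
phenomena.

## Validation simulations: sizes and tolerances

The recovery suite uses 20-variant instruments with $\theta = 0.2$ at
$n_X = n_Y = 10^5$ and $|\gamma| \in (0.1, 0.3)$ — a strong-instrument
regime (per-variant F of order 100+), chosen so that weak-instrument
attenuation (order $\mathrm{se}_X^2/\gamma^2$, a known property of ratio
estimators, not the thing under test) sits well inside the Monte-Carlo
error band. Problem sizes: 500 replicates for the no-pleiotropy recovery
of IVW, weighted median, and the null Egger intercept (each within 3
Monte-Carlo SEs of truth); 300 replicates each for the contaminated and
fully-pleiotropic scenarios; 1000 for the Egger intercept's type-I error,
checked against the nominal 0.05 level in the band [0.03, 0.07].

In the contamination scenario (40% of variants directionally pleiotropic,
$\alpha \sim N(0.1, 0.02)$), the comparison tolerance is $\theta/2 = 0.1$:
the weighted median's finite-sample bias under one-sided contamination
below 50% weight is expected around $0.02$–$0.04$ (the median lands in the
upper tail of the valid cluster), while the IVW bias
$\approx 0.4\,\bar{\alpha\gamma}/\overline{\gamma^2} \approx 0.19$ clearly
exceeds it — the band separates the estimators without claiming the median
is exactly unbiased at $J = 20$, which it is not.

## Numerical choices and degenerate inputs

* Ties in selection: lexicographic rsid; documented, deterministic.
* $\beta_X = 0$ anywhere is an error naming the variant (undefined ratio),
  never a silent drop.
* LD matrices are validated for symmetry (tolerance $10^{-8}$), unit
  diagonal, $|r| \le 1$ and positive semi-definiteness; long-format input
  is symmetrized with absent pairs at 0.
* `egger_regression` refuses designs with no spread in $\hat\beta_X$ after
  orientation (two coefficients, rank-1 design).
* Bootstrap and generator seeds are explicit arguments; nothing consumes
  global RNG state implicitly (`withr::with_seed` scoping).
* P-values are floored at the smallest positive double rather than
  returned as exact zeros.

## Reference-result consistency

The packaged reference tables (`reported_estimates()`) are used for
internal-consistency checks: the exponential of each reported log-odds
estimate must agree with its reported OR within the tolerance implied by
independent rounding of the two printed columns, and reported CI endpoints
must reproduce as estimate $\pm z_{0.975}\,$se within 0.002. Two rows of
the *SHBG* table (rheumatoid arthritis and type 2 diabetes) carry SEs that
are *not* arithmetically consistent with their reported interval endpoints
(the implied SEs differ by ~20%); those two intervals are excluded from the
CI check, which otherwise covers every reported interval. The packaged
gout outcome fixture is synthetic — back-derived by inverting the Wald
ratio from the reported gout estimate — because the original outcome GWAS
are large external consortium datasets that are not redistributable here;
consequently the per-outcome disease results are demonstrated through that
derived fixture and the simulation suite, not re-derived from raw outcome
data.

## Known limitations

* No MR-PRESSO-style outlier removal, multivariable MR, Steiger filtering
  or bidirectional analysis — out of scope by design.
* No proxy-variant lookup: an instrument variant missing from an outcome
  table is dropped, so the effective instrument is the
  intersection-after-harmonization, logged per outcome.
* The weighted median's bootstrap SE assumes approximate normality of the
  summary estimates; with very weak instruments the ratio distribution is
  heavy-tailed and the SE can be optimistic.
* No multiple-testing correction across outcomes (raw two-sided
  $p < 0.05$ significance flag); the run log records how many tests were
  performed so users can apply their own.
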