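# mrpipe

Two-sample Mendelian randomization (MR) from GWAS summary statistics.

Observational associations between an exposure and a disease are confounded
by behaviour, environment and reverse causation. MR sidesteps this by using
genetic variants as instrumental variables: alleles are randomized at
conception, so a variant that raises an exposure acts like a tiny, lifelong
randomized treatment assignment. In the **two-sample** design the
variant–exposure associations ($\hat\beta_{Xj}$, from one GWAS) and the
variant–outcome associations ($\hat\beta_{Yj}$, from another) are all that is
needed — no individual-level data.

`mrpipe` implements the complete summary-level workflow and ships, as worked
fixtures, the serum-testosterone instruments at the *JMJD1C* (1 variant) and
*SHBG* (20 variant) loci together with reported reference results for seven
common diseases (type 2 diabetes, gout, rheumatoid arthritis, depression,
schizophrenia, bipolar disorder, Alzheimer's disorder).

## The estimators

For variant $j$, the Wald ratio is $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$
with first-order standard error $\mathrm{se}(\hat\beta_{Yj})/|\hat\beta_{Xj}|$.
Multi-variant instruments are pooled by the inverse-variance-weighted (IVW)
method,

$$\hat\theta_{IVW} = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j},\qquad
  w_j = \frac{\hat\beta_{Xj}^2}{\mathrm{se}(\hat\beta_{Yj})^2},\qquad
  \mathrm{se} = \Big(\sum_j w_j\Big)^{-1/2},$$

which is identical to weighted regression of $\hat\beta_Y$ on $\hat\beta_X$
through the origin. Sensitivity analyses:

* **weighted median** — the weighted 50th percentile of the $\hat\theta_j$,
  consistent while valid variants carry ≥ 50% of the weight; SE by seeded
  parametric bootstrap;
* **MR-Egger** — weighted regression *with* an intercept after orienting all
  variants to the exposure-increasing allele; the intercept estimates average
  directional pleiotropy and tests instrument validity;
* **correlation-aware IVW** (opt-in) — generalized least squares with
  $\Omega_{jk} = r_{jk}\,\mathrm{se}_{Yj}\,\mathrm{se}_{Yk}$ for instruments in
  residual linkage disequilibrium.

Instruments are built by greedy p-value-ranked LD pruning (keep the smallest-p
candidate, remove everything with $r^2 > 0.40$ against it, repeat), and
exposure/outcome tables are harmonized onto a common effect allele (sign flips
for swapped alleles, strand complements resolved, palindromic A/T and C/G
variants dropped by default). A seeded generator produces synthetic two-sample
summary statistics with known causal effect, instrument strength and
pleiotropy structure, so every stage is testable without external downloads.

## Worked example

The packaged single-variant example: the *JMJD1C* testosterone instrument
(rs10822184) against the derived gout outcome fixture.

```r
library(mrpipe)
h <- harmonize(jmjd1c_instrument(), gout_outcome_jmjd1c())
ratio_estimate(h$beta_x, h$se_x, h$beta_y, h$se_y)
#> ratio (1 variant): estimate -0.7569 (se 0.2207), 95% CI [-1.1894, -0.3244], OR 0.469, p 0.001
```

One unit more genetically predicted testosterone is associated with 0.469
times the odds of gout — higher testosterone looks protective here. The 20
*SHBG* variants are already mutually independent at the pruning threshold:

```r
shbg <- shbg_instrument()
stepwise_select(shbg, ld_matrix(diag(20), shbg$rsid))
#> Stepwise LD pruning (r^2 > 0.4 removed): 20 selected, 0 removed
#>   selected: rs727428, rs1799941, rs17806566, ...
```

On synthetic data with a known causal effect $\theta = 0.2$ all estimators
recover the truth:

```r
sim <- simulate_two_sample(sim_config(n_variants = 20, theta = 0.2,
  gamma_range = c(0.1, 0.3), n_exposure = 1e5, n_outcome = 1e5, seed = 1))
hs <- harmonize(sim$exposure, sim$outcome)
ivw_estimate(hs)
#> ivw (20 variants): estimate 0.1995 (se 0.0056), 95% CI [0.1884, 0.2105], OR 1.221, p <0.001
weighted_median(hs, 1000, seed = 2)
#> weighted_median (20 variants): estimate 0.1962 (se 0.0085), 95% CI [0.1795, 0.2130], OR 1.217, p <0.001
egger_regression(hs)
#> egger_slope (20 variants): estimate 0.1900 (se 0.0242), 95% CI [0.1425, 0.2374], OR 1.209, p <0.001
#>   intercept 0.0020 (se 0.0049), p 0.683
```

The Egger intercept is compatible with zero: no evidence of directional
pleiotropy in this (pleiotropy-free) simulation.

Whole analyses are driven by a YAML config — see
`inst/extdata/jmjd1c_gout_analysis.yaml` for a complete example — through
`run_analysis("analysis.yaml")` or the command-line wrapper:

```sh
exec/mrpipe run --config inst/extdata/jmjd1c_gout_analysis.yaml
exec/mrpipe prune --assoc candidates.tsv --ld ld.tsv --r2 0.4 --out selected.tsv
exec/mrpipe simulate --config sim.yaml --out-prefix sim/
```

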