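---
title: "Modelling subnational contraceptive supply shares: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling subnational contraceptive supply shares: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements, the
choices that were genuinely open, and what the synthetic-data experiments
do and do not demonstrate.

## The estimation problem

Household surveys such as the DHS record, for users of each modern
contraceptive method, whether the supply source was public or private.
At admin-1 level these proportions are sparse — a region may have between
one and nine surveys over thirty years, some region–method series have no
observations at all, and per-cell sample sizes can be a few dozen women —
yet programme planning needs annual, region- and method-specific estimates
with honest uncertainty, including projections beyond the latest survey.
The public and private shares are complementary (`phi_public +
phi_private = 1`), so the model works on the logit of the public share and
the private side is reported as its mirror image.

## Process model

Each region gets its own cubic B-spline basis over the year grid
(default 1990–2030) with interior knots every 5 years, laid out so that
**one knot coincides with the region's most recent survey year**. The
spline coefficient anchored there is the proxy-intercept `alpha[p, m]`:
because the basis functions at any year sum to one, shifting `alpha`
shifts the whole trajectory, and the coefficient's value is the
spline's level around the best-observed part of the series. All other
coefficients are reconstructed outward from the anchor by first-order
random-walk increments, `beta[k+1] = beta[k] + delta[k]`, with
`delta ~ N(0, sigma_delta^2)` and a half-Normal(sd 2) hyperprior on
`sigma_delta`. Mean-zero increments are the penalty: where data end, the
expected trajectory holds its level.

Intercepts are pooled twice, and both levels are multivariate across the
M = 5 methods: country intercepts around global method means
(`Sigma_theta`) and region intercepts around their country's
(`Sigma_alpha`), with `IW(I_M, M + 1)` priors whose implied marginal
correlations are uniform on (−1, 1). This is where the borrowing happens:
a region with no data for one method is informed by its country's level
for that method and, through the covariance, by its own levels of the
other methods.

The data model is `z ~ N(psi, se_z^2)` with `z` the logit of the squeezed
observed share and `se_z` the delta-method transform of the reported
design-based standard error. Observation noise is therefore *heteroskedastic
and known*, which is what lets the model smooth through noisy points while
adhering to precise ones.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `spline_degree` | 3 | – | cubic is the standard penalized-spline choice for smooth demographic trajectories |
| `knot_spacing_years` | 5 | years | roughly the between-survey gap; finer spacing adds coefficients the data cannot separate |
| `year_start`–`year_end` | 1990–2030 | years | spans all survey years plus a projection horizon |
| `n_iter`, `burn_in`, `thin` | 80000, 10000, 35 | iterations | the fitting protocol; yields 2000 retained samples per chain, enough for stable 95% interval endpoints given the strong autocorrelation of the increment-scale parameter |
| `n_chains` | 4 | – | chain count is an open choice; four overdispersed chains drawn from the prior support split-R-hat diagnostics |
| `min_sector_n` | 10 | women | observations where neither sector reaches 10 respondents are dominated by noise |
| `test_cutoff_year` | 2015 | year | "beyond 2015" is read strictly: 2015 surveys train, later ones validate |

## Design choices where the design was open

**Anchored-coefficient index.** A coefficient-to-knot association is
needed to say which coefficient "sits at" the last survey year; we use the
coefficient whose Greville abscissa (mean of its supporting knots) is
nearest that year. For the uniform interior grids built here this is also
the coefficient with maximal basis value at the anchor year (a property
the test suite checks).

**Sum-to-zero constraint.** The usual identifiability constraint on
spline coefficients is not imposed: in the (alpha, delta)
parameterization beta is fully determined — alpha is identified by the
partition of unity and the increments by coefficient differences — and an
additional hard constraint would contradict the outward recursion. The
test suite instead verifies identifiability directly (the conjugate toy
posterior and simulation-based calibration).

**When projections become flat.** With a degree-d basis, coefficients
below the anchor keep support for d more knot intervals past the anchor
year, so the fitted trend continues to evolve smoothly for up to
`d * spacing` years after the last survey before reaching an exactly
constant steady state. This is a feature, not a defect — a trend observed
up to the last survey is damped out rather than truncated — and it is how
the package states its steady-state checks: the zero-increment plug-in
surface is exactly constant (to 1e-6 and indeed machine precision) from
knot `k* + d` on, and the posterior-median share trajectory is constant
there to Monte-Carlo tolerance (1e-2).

**Boundary squeezing.** The squeeze `(y(N-1)+1/2)/N` is applied to every
observation (not only exact 0/1), with `N` the method-level total
`n_public + n_private`. It is monotone for fixed N and converges to the
identity, so orderings are preserved and large samples are essentially
untouched.

**Multiple observations in one region–method–year** (two surveys in one
year) are passed through unmodified; both rows enter the likelihood with
their own standard errors.

**Comparator variants.** The alternatives are reconstructions from their
structural descriptions: `zero_covariance` replaces both intercept
covariances with diagonal matrices (independent per-method half-Normal
sd-2 scale priors); `multivariate_delta` moves the inverse-Wishart
covariance onto the per-knot increment vectors across methods and uses
independent intercept priors; `fully_multivariate` does both;
`shrinkage` keeps the multivariate intercepts but gives every
(region, method) series its own increment scale under a common
half-Normal hyper-scale.

## Computation

Models are expressed in the BUGS language and sampled with JAGS (Gibbs
sampling) through `rjags`; the package generates the model code per
variant, including degenerate configurations in which selected nodes
(covariances, increments, intercept hyperparameters) are pinned to fixed
values — that is how the conjugate normal–normal closed form is checked
end to end through the sampler. Chains are seeded deterministically from
the run seed, making draw files bit-for-bit reproducible. Convergence is
monitored with split rank-normalized R-hat (flag at 1.05) and an
autocorrelation-based effective sample size using Geyer's initial
monotone positive-sequence truncation; constant chains are reported as
R-hat 1 / ESS 0 with a zero-variance flag rather than NaN. The
increment-scale `sigma_delta` is the slowest-mixing parameter (a classic
scale/coefficient funnel); the long default protocol exists because of
it, and `diagnose_fit()` makes the flags visible at reduced settings.

The R-side log-posterior (`log_prior()`, `log_likelihood()`) mirrors the
JAGS model with hand-coded multivariate-normal and inverse-Wishart log
densities; the test suite pins it against independent closed-form
factorizations, and the sampler against the conjugate oracle, so the two
representations cannot drift apart silently.

## What the synthetic generator emulates — and what it does not

The generator forward-simulates the full process model: hierarchy (default
4 countries with 3–6 admin-1 regions, five methods), 3–6 surveys per
country at irregular 3–7-year gaps in 1990–2021, per-cell totals uniform
on 10–300 women, and truth hyperparameters chosen to look like the real
monitoring setting: global method means scattered around logit(0.75)
(public-sector dominance at the reported levels), exchangeable
cross-method intercept correlations of 0.7 (the middle of the reported
subnational range), intercept sds of 0.5 (country) and 0.4 (region), and
increment sd 0.15 per 5-year knot interval.

Survey noise is binomial with a design effect of 1.5 applied as an
*effective-sample-size reduction*: the observed share is
`Binomial(n_eff, phi)/n_eff` with `n_eff = n_total/deff^2`, and the
reported SE is the binomial SE at `n_eff`. This keeps the reported
standard errors consistent with the noise actually simulated — the
property real design-based (Taylor-linearized) SEs have. Inflating the SE
label without inflating the noise would make every correctly specified
model over-cover by construction and would invalidate calibration
experiments.

Not emulated: spatially structured (CAR-type) truth surfaces, cluster-level
microdata and survey weights, SE imputation for legacy surveys, and
multi-source error models. Passing tests on this generator therefore show
that the *inference machinery* is correct and calibrated under the model's
own assumptions with realistic sparsity and noise; they do not certify the
model against real-data features such as spatial confounding or
systematically mis-reported standard errors.

## Experimental results the package computes

All problem sizes below were chosen so the whole suite runs on a single
core in well under half an hour; they are stated here so the experiments
are interpretable.

* **Conjugate oracle**: one region/method, increments pinned, fixed unit
  prior variance, one observation — the sampled posterior matches
  N(0.32, 0.447²) within Monte-Carlo error at 2000 retained draws.
* **Simulation-based calibration**: 200 replicates of a 2-country ×
  3-region × 2-method design with truth drawn from the prior and data from
  the data model; rank statistics of global mean, intercept and increment
  scale are uniform (chi-square p-values well above 0.01). Draws are
  thinned to ~100 near-independent samples per fit because autocorrelated
  draws distort rank histograms.
* **Calibration of predictive coverage**: 20 generator replicates of the
  default scenario, fit on pre-2016 surveys at reduced settings
  (2000/600/2, 2 chains), pooling ~650–750 held-out rows: 95% predictive
  coverage ≈ 96, 80% coverage ≈ 82.
* **Correlation recovery**: 10 countries × 5 regions × 3 surveys with two
  methods and true intercept correlation 0.7. The posterior mean
  correlation comes out around 0.42–0.58 across realizations: with
  logit-scale observation noise comparable to the cross-region signal
  (effective samples of a few dozen women per cell), the posterior
  correctly shrinks a weakly identified correlation toward its uniform
  prior. Long-run checks (80k iterations) and the SBC results confirm
  this is the genuine posterior, not a mixing artifact. Recovery to
  within ±0.1 of the truth requires either larger samples per cell or
  more regions than this deliberately sparse setting provides.

## Known limitations

* The increment scale mixes slowly in Gibbs sampling; reduced-setting
  fits flag it, and headline analyses should use the full protocol.
* Correlation parameters are weakly identified at DHS subnational sample
  sizes (see above); report their posterior intervals, not just means.
* The Normal logit-scale likelihood is an approximation that degrades for
  cells with very few users even after squeezing.
* Projections are steady-state by construction: they carry the last
  observed level (after the d-knot damping window) with growing
  uncertainty, and cannot anticipate policy-driven trend breaks.
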