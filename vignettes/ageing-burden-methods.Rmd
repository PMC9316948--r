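---
title: "Methods behind the ageing-burden metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the ageing-burden metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ageburden)
```

This vignette is the package's own account of its models and the choices
made where the design was genuinely open. It states no empirical result
that the test suite or acceptance script does not itself compute.

## The abridged life table

`build_lifetable()` converts age-specific all-cause mortality rates `mx`
on an abridged grid (default 5-year bands, open 95+ group) into the
standard columns `qx, lx, dx, Lx, Tx, ex`. Two within-interval
assumptions are offered:

- **midpoint** (`ax = n/2`, `qx = n·mx / (1 + (n − ax)·mx)`): the common
  abridged-table default for adult ages, and the package default.
- **exponential** (`qx = 1 − e^{−n·mx}`, `Lx = dx/mx`): exact under a
  piecewise-constant hazard. We ship it because it makes two classes of
  checks sharp: constant-hazard closed forms (`ex = 1/μ`,
  `20q70 = 1 − e^{−20μ}`) hold to machine precision, and a
  discrete-event cohort microsimulation with the same piecewise-constant
  hazard is a *model-identical* oracle, so agreement can be demanded
  within Monte-Carlo error rather than within a fudge band. The midpoint
  rule deliberately differs from that oracle's model by O((n·mx)²), which
  is why the microsimulation acceptance check runs under the exponential
  rule.

The open interval is always closed with `Lx = lx/mx` (so `ex = 1/mx`
there). No smoothing or graduation is applied — input rates are final.
Off-grid ages are an error, never interpolated: windowed probabilities
such as 20q70 therefore require 70 and 90 on the grid, which the default
grid provides. Which `ax` standard the large international studies use
for their published LE-70 is not documented at this level of detail; we
do not claim to reproduce it, only to satisfy the life-table identities
and the oracle.

## Comorbidity adjustment and the Sullivan method

Per-sequela burden is `prevalence × disability weight`. Because people
carry multiple conditions, naive summation overstates disability.
`comorbidity_adjust()` assumes **independent comorbidity** within an age
group/sex stratum: a person carries condition *i* with probability
`p_i` independently, and the combined disability of a set `S` is
multiplicative, `1 − Π_{i∈S}(1 − dw_i)`.

The attribution of combined disability back to individual conditions is
not dictated by the multiplicative model; we attribute **proportionally
to disability weight** among co-occurring conditions. This is the
simplest rule that (a) is exhaustive (per-cause shares sum exactly to the
combined disability), (b) leaves a single condition's burden unchanged,
and (c) makes a zero-weight condition exactly inert. The analytic mode
enumerates all `2^k` sets (capped at k = 20); the microsimulation mode
draws Bernoulli condition profiles and reports Monte-Carlo standard
errors as attributes, so "agreement within 3 SE" tests are honest.

`hale_sullivan()` then computes `HALE(x) = Σ_{a≥x} L_a(1 − yld_a)/l_x`:
life-table person-years discounted by the fraction of each year lived in
ill health. Two limits pin the implementation: zero YLD rates give
`HALE = LE` identically, and a constant rate `d` factors out to
`(1 − d)·LE`. The ill-health fraction is `pyih() = (LE − HALE)/LE`,
computed exactly; rounding (half-up, 2 decimals, matching published
tables) is applied only at the reporting layer via `round_half_up()`.
Whether the upstream studies aggregate per-draw YLD rates before or after
the Sullivan sum is unstated there; this package applies any draw logic
via `propagate()`, draw-wise by construction.

## Decomposition of Δ20q70

The change in 20q70 between two periods is attributed to causes by
**symmetric stepwise replacement** (the Das Gupta / Andreev–Shkolnikov
family): switch one cause's rates from period 1 to period 2 at a time,
record the induced change in 20q70, and average over replacement
orderings. Every single ordering telescopes to the total change, so the
averaged contributions are exactly additive — the residual is zero by
construction when all `k!` orderings are enumerated (done for k ≤ 6) and
small for the seeded Monte-Carlo sample of orderings used beyond.

We chose replacement over an age-decomposition scheme (Arriaga) because
the target functional is a survival-ratio window probability, not a life
expectancy, and replacement applies to any functional of the rate
surface. The upstream studies do not name their algorithm; only
additivity, antisymmetry and sign behaviour are testable claims, and the
suite tests exactly those.

## Comparative risk

For categorical exposures with prevalences `p` and relative risks `rr`
(TMREL category at `rr = 1`):

- `PAF = (Σp·rr − 1)/(Σp·rr)` — the proportional burden reduction if
  everyone moved to the TMREL.
- `SEV = Σp·(rr − 1)/(rr_max − 1)` — 0 when all exposure is at TMREL, 1
  when all is at maximum risk. This is the paper-level contract; the
  upstream machinery has risk-specific refinements (and continuous
  ensemble exposure distributions) that are deliberately out of scope —
  continuous risks must be discretised by the caller.
- `ARC = ln(final/initial)/years`, which telescopes across sub-periods
  when weighted by their lengths.

Risk overlap/mediation across multiple risks is not modelled;
attributable burdens are reported per risk without joint deduplication.

## Epidemiological transition curves

`fit_expected_curve()` regresses `log(metric + 1e-7)` on an intercept
plus a cubic B-spline in SDI or HAQ, by ordinary least squares. The
offset keeps zero metrics finite; predictions are back-transformed and
clamped at zero. Default: 4 interior knots at the 0.2/0.4/0.6/0.8
covariate quantiles (the knot count is not stated upstream; 4 is enough
for the smooth monotone shapes involved while keeping the fit stable at
a few hundred observations). The upstream meta-regression tool also
trims outliers and applies priors; neither is reproduced — the stated
model contract is "intercept + cubic spline, fit in log space with the
offset", and that is what is implemented and tested (constant-metric
recovery, exact recovery of log-linear curves, 2% RMSE recovery under
multiplicative noise at n = 6000, zero mean log-residual).

Observed-to-expected ratios are `(obs + offset)/(exp + offset)`; values
above 1 mean the location outperforms the level expected for its stage
of development. Out-of-range covariates warn and flag rather than error,
because scoring new locations slightly outside the fitted range is
routine.

## The data coverage index

`dci_by_cause()` is the percentage of countries with **any** input-data
indicator for a cause/risk in a (period, age-restriction) slice;
`dci_by_country()` is its transpose; `dci_gap()` is the all-ages minus
70+ difference, positive where older-age data are scarcer. "Any input
data" counts a single indicator anywhere in the slice — temporal
weighting within a period is not defined upstream and is not invented
here. Denominators are the full country (or entity) axis of the matrix,
so an entity absent from a slice scores 0, not NA.

## Uncertainty

Draw sets hold per-draw values; the point estimate is the **draw mean**
(the convention implied by published point estimates lying inside their
intervals). `propagate()` applies any deterministic stage function
draw-wise — never to means first; the suite verifies the classic
Jensen-gap example (`mean(x²) ≠ mean(x)²`). `ui95()` takes empirical
2.5/97.5 percentiles with linear interpolation between order statistics
(quantile type 7 — the rule consistent with the worked interval for
draws 1…1000). One subtlety: monotone transforms map interval endpoints
through *exactly* only when the percentiles land on order statistics;
with interpolation the commutation is approximate, and the tests state
it that way.

## The synthetic world

`sim_config()` defines the stated world the suite runs in:

- **Mortality**: Gompertz, `mx(a) = α·e^{βa}` with α = 4e-5, β = 0.09 —
  adult rates ≈ 0.02 at 70 rising to ≈ 0.2 at 95, the magnitude range of
  contemporary elderly populations. A location's SDI scales mortality by
  the stored invertible link `e^{λ(0.5 − SDI)}` (λ = 1.2), sexes by
  1.12/0.89, and calendar time by `e^{−0.008·years}` (slow secular
  decline).
- **Causes**: four level-2-like causes (cardio-, cancer-, neuro-,
  injury-like) with Dirichlet-drawn fractions (concentration 4/3/2/1)
  tilted over time by per-cause rates (−1.2%, +0.4%, +0.6%, −0.4%/yr,
  renormalised) so decompositions see the mixed-sign pattern of real
  cause trends while cause closure stays exact.
- **Disability**: per-cause prevalence linear in age
  (`intercept + slope·a`, clamped), weights 0.10–0.35, yielding a 70+
  ill-health fraction around 0.17 — the right order of magnitude for
  elderly populations, chosen once for realism, not tuned to any test.
- **Risks**: two categorical risks with known relative risks; exposure
  drifts toward the TMREL at 2%/yr so SEV falls and its annualised rate
  of change is negative, as with most real risk exposures.
- **Coverage**: independent Bernoulli(1 − sparsity) indicators.
- **Seeding**: one root seed; every stream derives a child seed from a
  documented string-hash counter (`child_seed()`), so adding a stratum
  never perturbs another and identical configs are bit-identical.

What it does **not** emulate: real per-country magnitudes, population
counts and migration, cause-list depth, non-independent comorbidity,
continuous risk exposure, reporting-driven coverage patterns, or any
pandemic shock. A green test therefore establishes that the *estimators*
are correct on a world whose truth is known — not that real-world
estimates would be reproduced.

The standard life-expectancy table bundled for YLL computations
(`standard_life_expectancy()`) is likewise a synthetic stand-in built
from a low-mortality Gompertz schedule (e₀ ≈ 85); supply the official
reference standard for real analyses.

## Numerical choices and degenerate inputs

- Life-table `qx` is clipped at 1; `mx ≤ 0` errors naming the age group.
- `pyih()` errors on `LE = 0` or `HALE > LE` rather than clamping.
- Rank-deficient spline fits (duplicate covariate values) use the
  pivoted-QR least-squares solution with aliased coefficients zeroed; at
  a duplicated covariate the prediction is the log-space mean of its
  observations.
- SEV errors on all-null risks ("undefined for null risk") instead of
  returning 0/0.
- Decomposition beyond 6 causes samples 500 orderings under a fixed
  seed; the residual is reported, not hidden.

## Known limitations

- Period life tables only; no cohort tables, projection, or parametric
  mortality-law fitting.
- The decomposition's equivalence to the (unnamed) upstream algorithm
  cannot be asserted, only its additivity and sign behaviour.
- Sex-specific transition fits are the caller's loop; the model object
  itself is sex-agnostic.
- Attributable burdens ignore mediation between risks.
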