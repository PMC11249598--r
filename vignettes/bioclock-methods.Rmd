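---
title: "Methods: residual-life biological age and its estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residual-life biological age and its estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioclock)
```

## The estimand

`bioclock` treats biological age as a population-referenced summary of
remaining lifespan. Writing `T` for age at death and `X` for a vector of
markers measured at study entry, the mean residual life of a subject alive at
age `t` is `mrl(t | x) = E(T − t | T > t, X = x)`; the reference population
has `mrl(t)`. Subject `i`, aged `c_i` with markers `x_i`, has biological age
`b_i` when

`mrl(c_i | x_i) = mrl(b_i)`.

The median residual life (`medrl(t)`: the `m` solving
`S(t + m) = S(t) / 2`) defines the same construction and is supported
everywhere the mean is; for the laws considered here the two differ by well
under 15% at adult ages, and the median avoids a tail integral, so it is the
default in simulation code paths. The mean is the natural choice when an
external life table already publishes life expectancies.

Everything downstream follows from this definition: step 1 estimates
`mrl(c | x)` by survival regression on the **chronological-age timescale**
(the natural scale for cohort data, where subjects enter at different ages),
and step 2 inverts the reference `mrl(·)` curve.

## Survival models

**Gompertz AFT (the primary fitter).** Adult human mortality is described
well by the Gompertz law `h0(t) = a·exp(b·t)`. Under the accelerated failure
time assumption, markers rescale age itself:
`S(t | x) = S0(t·θ)` with `θ = exp(β' x)` — an individual aging rate, the
quantitative version of a faster- or slower-ticking clock. The family is
closed under this rescaling: the conditional law is Gompertz `(aθ, bθ)`,
which gives closed forms for the conditional cumulative hazard, its inverse,
and hence the median residual life — no root finding anywhere in the
prediction path.

The fitter maximizes the delayed-entry log-likelihood

`Σ_i δ_i log h(t_i | x_i) − [H(t_i | x_i) − H(c_i | x_i)]`,

in which each subject contributes hazard mass only over the observed window
`(c_i, t_i]` — exactly the conditioning that left truncation (people dead
before their would-be entry age are never sampled) requires. Optimization is
BFGS with an analytic gradient on `(log a, log b, β)` — the log scale
enforces positivity and conditions the problem, since typical values like
`a = exp(−9)` are four orders of magnitude below `b`. Starting values come
from a marginal Gompertz fit ignoring covariates, itself started at
`a = exp(−9)`, `b = 0.085`; Newton steps then polish the optimum until the
gradient norm drops below `1e-5` (cap 500 BFGS iterations, 25 Newton steps).
This is a numerically delicate model: failures to converge, or a singular
observed information matrix, raise an error carrying diagnostics — they are
never silently imputed, and the experiment driver counts and excludes them.

Two numerical guards matter in practice. First, the hazard-mass difference
is evaluated as `(a/b)·e^v·expm1(u − v)` (with `u = bθt`, `v = bθc`) rather
than `(a/b)(e^u − e^v)`: the naive difference cancels catastrophically as
`b → 0` and opens a spurious unbounded likelihood direction along
`a → ∞, b → 0`. Second, exponents are bounded (`u ≤ 690`,
`log(a/b) + v ≤ 700`) so the optimizer sees a large finite penalty instead
of overflow. Survival is always computed as `exp(−H)` on the log scale, so
extreme ages underflow cleanly to zero.

**Cox on age (PH comparator).** The semiparametric proportional hazards
model on the age axis with delayed entry (risk sets contain subject `j` at
event age `t` iff `c_j < t ≤ t_j`), fitted by `survival::coxph`. Ties are
handled by Breslow throughout: simulated event times are continuous, so ties
are measure-zero, and the Breslow baseline cumulative hazard doubles as the
estimate of `H0`. Its conditional survival
`exp(−Ĥ0(t)·e^{β̂'x})` is a step function whose support ends at the last
observed age. When a subject's survival cannot halve within that support,
the prediction is **not extrapolated**: the subject is flagged (or, when
called directly, an "insufficient tail support" error is raised). This is a
real failure mode of semiparametric two-step prediction on cohorts with a
bounded age range, and hiding it would misrepresent the method.

**GrimAge-style comparator.** A Cox model on the time-on-study scale with
entry age and the markers as covariates, followed by the affine map
`B = age_mean + age_sd·(lp − lp_mean)/lp_sd` using training-set moments.
The published recipe leaves one point open: whether the linear predictor is
standardized before or after removing its age term. Here the **full** linear
predictor, age term included, is rescaled — this matches the description of
the transformation as mapping the Cox score onto the training cohort's age
distribution, and it reproduces the training age mean and SD exactly by
construction. No residual-life interpretation exists for this predictor, so
its `residual_life_hat` is `NA` and it needs no life table.

## Life tables and inversion

Tables live on a regular age grid, default `[0, 120]` years in steps of
0.05 — fine enough that residual-life inversion is accurate to about 0.01
years while tables stay small. Construction routes:

* **parametric**: baseline survival, or the marginal
  `E_Z[S(t | lp = Z)]` with `Z ~ N(0, σ_lp²)` integrated by 40-node
  Gauss–Hermite quadrature (markers enter only through the scalar linear
  predictor, so univariate quadrature suffices);
* **empirical**: delayed-entry Kaplan–Meier on a cohort, survival set to 1
  below the earliest entry age, with a warning when the curve never reaches
  half its maximum (the bounded-age-range failure mode again). No tail
  extension is applied by default: silently extrapolating an undefined tail
  would hide exactly the problem the flagging is designed to surface;
* **file**: `survival`, `lx` (normalized by the first value) or `qx`
  (accumulated as `Π(1 − qx)`) columns, optionally stratified (e.g. by sex).

Mean residual life integrates the survival curve by the trapezoidal rule
(O(h²), verified against the memoryless closed form), and requires the
relative tail mass at the grid end to be below `1e-6`. Median residual life
finds the half-survival crossing by linear interpolation between grid
neighbors. Inversion to biological age takes the **first downward crossing**
of the tabulated residual-life curve through the requested value — real
tables can wiggle non-monotonically at the ragged tail, and the first
crossing resolves that deterministically; a constant curve (memoryless
population) is rejected as non-invertible. Out-of-range predictions are
flagged `NA`, never clipped to the table bounds: clipping would pile mass at
the boundary ages and silently distort calibration. With sex-stratified
tables each subject inverts against their own stratum, so equal residual
life maps to a higher biological age in the longer-lived stratum.

## The simulator

The generator mirrors a prospective cohort design. Two markers
`X1, X2 ~ N(0, 1)` constant over life; entry age `C ~ U(20, 80)`; age at
death by inversion sampling, `t = H0^{-1}(−log U / θ)` under PH and
`t = H0^{-1}(−log U)/θ` under AFT; draws with `T < C` discarded (left
truncation) until the target retained size is reached, with the discard
count reported; administrative censoring at `C + 20` years. Baselines:
Gompertz `a = exp(−9)`, `b = 0.085`; Weibull in the rate parameterization
`h0 = λνt^{ν−1}` with `λ = 34^{−10}`, `ν = 8` — used verbatim even though
the exponent 10 next to shape 8 looks like it may have been meant as
`34^{−ν}`; as printed it yields a median lifespan near 78.4 years, which is
in the realistic range. Effect sizes: `β = (0.3, 0.3)` for Gompertz-PH,
`(0.05, 0.05)` for Gompertz-AFT, `(0.35, 0.35)` for Weibull-PH (PH and AFT
coefficients live on different scales; these produce comparable lifespan
distributions). The Weibull is the one family that is simultaneously PH and
AFT (`β_AFT = β_PH / ν`), which the tests exploit as an exact cross-check.

`n_obs` counts **retained** subjects: it is the analyzable sample size, and
the discarded draws are reported separately as attrition. The true
biological age of each retained subject is computed from the generating
law's closed-form median residual life and inverted against the **marginal**
population table (the population the cohort is actually sampled from) by
default; the baseline table is available because the truth construction can
be read either way. Subjects whose true residual life exceeds the range the
table spans — extreme decelerated agers, roughly one per 10⁵ draws — get
`NA` truth and are excluded from error summaries with a count, consistent
with the flag-don't-clip rule.

Reproducibility: one root seed spawns per-replicate child seeds by the
counter scheme `child_seed(root, i) = (root + 1000003·i) mod (2³¹ − 1)`, and
every draw function restores the caller's RNG state.

What the simulator does **not** emulate: markers that drift with age (real
omics markers do; constant markers match the age-adjustment convention of
mortality-trained clocks), competing risks, informative censoring, reporting
error in life tables, and cohort-vs-period table discrepancies. Passing
tests therefore demonstrate correctness of the machinery under the stated
design, not robustness to these real-data features.

## Evaluation metrics

* **RMSE** against the simulator's true biological ages; flagged subjects
  must be excluded explicitly by the caller.
* **Uno's C**: IPCW concordance with weights `1/Ĝ(T_i−)²`, `Ĝ` the
  Kaplan–Meier of the censoring distribution on time-on-study (entry is
  time 0 on that scale, so no delayed entry enters the censoring model).
  Score ties count ½. The truncation time `τ` defaults to the largest event
  time with `Ĝ(τ) ≥ 0.1`, which caps the weights; the standard error is the
  first-order jackknife (influence-function) estimate for a ratio
  U-statistic. With no censoring the estimator reduces exactly to
  Harrell's C.
* **Calibration**: each predicted biological age implies a 5-year mortality
  probability `1 − S_pop(b̂ + 5)/S_pop(b̂)` in the reference table; subjects
  are split into 5 equally sized groups by that probability (sizes differing
  by at most one), and the group mean is compared with the Kaplan–Meier
  complement at the horizon — raw death fractions would be biased by
  censoring inside the horizon.
* **Δ association**: the age acceleration is the OLS residual of `b̂` on
  `c`, computed on the sample being reported (not with a regression frozen
  on training data — the definition is per-sample), standardized to unit SD,
  and entered in a Cox model on time-on-study adjusted for chronological age
  and stratum. Any affine recalibration of `b̂` in `c` leaves Δ unchanged.

## Problem sizes

The test suite exercises parameter recovery at `n_obs` up to 10,000,
confidence-interval coverage over 100 replicates at `n = 5,000`, and the
predictor-comparison experiment at 20 replicates per cell with test sets of
5,000 — sizes chosen so the full suite completes in well under a minute per
file while keeping Monte-Carlo noise far below the effect sizes being
checked. The experiment driver accepts the full grid
(`n_obs ∈ {500, …, 10000}`, `n_sim = 200`) for larger runs.

## Known limitations

Lifespan only, not healthspan: the reference tables are mortality tables.
The two-parameter Gompertz baseline ignores late-life mortality
deceleration, if present. Choosing a reference population is a modelling
decision the framework makes explicit — changing the table changes every
biological age, by design. Penalized fitting for high-dimensional markers
and time-varying markers are out of scope.
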