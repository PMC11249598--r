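# bioclock

Biological age prediction from time-to-event data.

## The problem

Biological age clocks promise a single number summarizing how far along the
lifespan a person is, beyond what the calendar says. Most mortality-trained
clocks, however, are built from Cox proportional hazards regressions plus an
ad hoc rescaling of the linear predictor to the age scale, which leaves the
quantity they predict undefined: there is no measurable estimand a prediction
of "biological age 57" can be checked against.

`bioclock` implements an operationalization that fixes the estimand through
residual life. Person *i*, alive at chronological age *c* with markers *x*,
has biological age *b* if

```
mrl(c | x) = mrl(b)
```

where `mrl(t | x) = E(T − t | T > t, X = x)` is their model-based mean
residual life and `mrl(t)` is the mean residual life of a reference
population, read off a life table. (The median residual life, `medrl(t)`:
the *m* with `S(t + m) = S(t)/2`, is supported throughout and is the faster
default in simulation work.) A biological age of 57 then means: *the same
remaining-lifespan outlook as an average 57-year-old in the reference
population* — a statement that can be scored for discrimination and
calibration.

Prediction is two-step:

1. **Fit** an accelerated failure time (AFT) model with chronological age as
   the timescale on left-truncated, right-censored cohort data and predict
   each subject's conditional residual life. The workhorse is a Gompertz AFT
   model — adult mortality hazard `h0(t) = a·exp(b·t)`, covariates acting as
   `S(t | x) = S0(t · e^{β'x})` — so `e^{β'x}` is an individual aging rate:
   a clock ticking faster or slower than the reference. The Gompertz family
   is closed under this time rescaling: the conditional law is Gompertz
   `(a·θ, b·θ)`, and residual life has a closed form.
2. **Invert** a reference life table: find the age whose tabulated residual
   life equals the prediction. Tables can be built from a parametric law,
   estimated from the cohort itself by delayed-entry Kaplan–Meier, or read
   from national-statistics files (`survival`, `lx` or `qx` columns),
   optionally stratified by sex.

Two comparators are included: a semiparametric Cox model on the age timescale
(same two-step route via the Breslow baseline) and a GrimAge-style predictor
(Cox on time-on-study, linear predictor affinely rescaled to the training
cohort's age mean and SD). A cohort simulator with known true biological
ages, and evaluation metrics — RMSE against truth, Uno's IPCW concordance,
life-table calibration, age-acceleration (Δ) hazard ratios — complete the
toolkit.

## Worked example

```r
library(bioclock)

# a prospective cohort: entry ages U(20, 80), Gompertz-AFT mortality,
# left truncation, 20-year administrative censoring
cfg    <- sim_config("gompertz_aft", n_obs = 5000, seed = 42)
cohort <- draw_cohort(cfg)
cohort
#> Simulated cohort (gompertz_aft, seed 42): 5000 retained, 1264 discarded (T < C)
#> Cohort: 5000 subjects, 1865 events (37.3%), 2 marker(s)
#>   entry age 20.0-80.0 y, exit age 21.5-99.9 y

fit <- fit_gompertz_aft(cohort$data)
fit
#> Gompertz AFT fit (age timescale, delayed entry)
#>   a = 0.0001412, b = 0.08351; loglik = -7620.84 (n = 5000, events = 1865)
#>   beta (SE): 0.0469 (0.0034), 0.0502 (0.0034)

# reference table: the population the cohort is sampled from
ref   <- true_lifetable(cfg, mode = "marginal")
test  <- draw_cohort(sim_config("gompertz_aft", n_obs = 5000, seed = 43))
preds <- predict_bioage(fit, ref, test$data, kind = "median")
preds
#> Biological age predictions (gompertz_aft_fit, residual-life kind: median)
#>   n = 5000, flagged out-of-range: 0
#>   bioage: mean 45.3 y (sd 16.9); delta sd 5.52 y

b_true <- true_bioage(test, ref)
ok <- !preds$flag
rmse(preds$bioage_hat[ok], b_true[ok])
#> RMSE vs true biological age: 0.55 years
uno_concordance(test$data, preds$bioage_hat)$c_index
#> Uno concordance: 0.808 (se 0.005)
```

The fit recovers the generating coefficients `β = (0.05, 0.05)` and baseline
slope `b = 0.085` within one standard error; the resulting biological ages
sit about half a year from the latent truth, and rank mortality better than
chronological age alone.

A command-line wrapper (`inst/scripts/bioclock`) exposes the same pipeline as
`simulate`, `lifetable`, `fit`, `predict`, `evaluate` and `experiment`
subcommands; every run writes its resolved configuration and seed next to its
outputs.

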