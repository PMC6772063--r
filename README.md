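# scedmed

Mediation analysis for single-case experimental designs (SCEDs).

In an SCED, one participant is measured repeatedly — typically daily — across
treatment phases (e.g. baseline B, intervention C, follow-up D). Clinical
researchers often want to know not only *whether* an intervention worked for
this client but *through what mechanism*: did therapy improve coping skills,
which in turn reduced anxiety? Group-level mediation machinery (regressions of
Y on X and M across subjects) does not apply to a single subject's time
series. `scedmed` implements a joint-significance framework for exactly this
setting, aimed at clinical researchers and methodologists analysing daily
self-report data from n-of-1 treatment studies.

## The framework

With the phase change as the manipulated independent variable X, a single
mediator M and an outcome Y, the classical single-mediator model

```
Y = i1 + cX            (total effect)
M = i2 + aX            (a path)
Y = i3 + c'X + bM      (b path, direct effect c')
```

is re-expressed with SCED equivalents per path:

- **a path (phase → mediator)** — Tau-U nonoverlap between phases
  (`tau = S / n_pairs`, with S the number of positive minus negative pairwise
  differences; optionally corrected for the earlier phase's own trend by
  subtracting its within-phase S), plus the immediate level-change and
  trend-change coefficients of a piecewise (segmented) OLS regression.
- **b path (mediator → outcome)** — cross-lagged Pearson correlations at lags
  −L..0 (negative lag = mediator leads), with significance from Monte-Carlo
  AR(1) surrogate series that match each series' lag-1 autocorrelation, and a
  max-statistic adjustment across lags.
- **c path (phase → outcome)** — reported for completeness; a significant
  total effect is *not* required for mediation.

Evidence is combined by joint significance: the verdict is
`consistent_with_mediation` only when the a- and b-path tests are both
significant (each gated on the hypothesized direction of improvement) and the
timing of changes does not contradict temporal precedence of the mediator.
No numeric indirect effect `a*b` is estimated — no agreed method exists for
SCEDs — so the output is structured evidence, not an effect size.

## Worked example

```r
library(scedmed)

# a synthetic client: coping (mediator) jumps by 3 points when phase C
# starts and drives anxiety (outcome) down 2 days later (b = -0.6)
cfg <- synth_config(phase_lengths = c(26, 32), a_level = 3, b = -0.6, lag = 2,
                    phi_m = 0.3, phi_y = 0.3, sd_m = 1, sd_y = 1,
                    outcome_base = c(7, 0))
ds <- generate_sced(cfg, seed = 2026)
ds
#> <sced_dataset> 58 days, phases B (26 obs, 26 complete), C (32 obs, 32 complete)
#>   hypothesized improvement: mediator up, outcome down

tau_between(ds$mediator$value[1:26], ds$mediator$value[27:58],
            phases = c("B", "C"))
#> <tau_u> between_level B vs C: Tau = 0.964, p = 3.62e-10, 90% CI [0.711, 1.000]

fit_piecewise(ds$mediator)
#> <piecewise_fit>
#>         term estimate     se t_value  p_value
#>    Intercept   1.6106 0.3300    4.88 9.76e-06
#>        Time1   0.0914 0.0226    4.04 1.71e-04
#>        Phase   2.6875 0.4600    5.84 3.05e-07
#>  Phase_time2  -0.1393 0.0281   -4.97 7.21e-06
#> R-squared = 0.802, model p = 5.81e-19 (df = 54)

mediation_report(ds, reps = 5000, seed = 2026)
#> <mediation_evidence>
#>   a path: significant
#>   b path: significant
#>   c path: significant
#>   temporal precedence: supported
#>   specificity: mediator change at the boundary is immediate (level jump), ...
#>   verdict: consistent_with_mediation
```

Reading the numbers: Tau-U = 0.964 means 96% net nonoverlap — nearly every
phase-C coping score exceeds every phase-B score. The piecewise fit estimates
the coping level at day 1 (1.61), the phase-B trend per day (0.09), an
immediate jump of 2.69 points at the first day of phase C, and a slope change
of −0.14/day thereafter. The b path is carried by negative-lag correlations
(e.g. r = −0.73 at lag −2, adjusted p = 0.0002 with 5000 surrogates): higher
coping predicts lower anxiety days later, with the mediator leading, so the
joint verdict is consistent with mediation.

Real data come in the same way via `read_sced_csv()` (long-format CSV: day,
phase, mediator, outcome), and `inst/cli/scedmed.R` wraps the whole pipeline
for shell use (`analyze`, `simulate` subcommands).

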