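---
title: "Testing mediators of intervention outcomes in single-case designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing mediators of intervention outcomes in single-case designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scedmed)
```

## The problem

Single-case experimental designs (SCEDs) measure one participant repeatedly
across treatment phases; the phase change is the manipulated independent
variable. Mediation questions — does the treatment change a mechanism
variable M, which in turn changes the outcome Y? — are usually answered with
between-subject regressions that have no analogue for a single subject's
time series. `scedmed` combines three univariate/bivariate SCED methods into
a joint-significance framework: the treatment→mediator (a) and
treatment→outcome (c) paths are tested with Tau-U nonoverlap statistics and
piecewise phase regression, the mediator→outcome (b) path is proxied by
cross-lagged correlations, and the verdict additionally requires temporal
precedence of the mediator's change. Three caveats frame everything below:
the b-path proxy is a correlation, not a partial regression coefficient
controlling for phase; no numeric indirect effect a·b is estimated (no
accepted way to do so exists for SCEDs); and a cross-lagged correlation can
never by itself establish causal direction.

## Data model

A `sced_series` is one variable's daily scores: an integer study day
(strictly increasing, calendar gaps allowed), a phase label per day (phases
must be contiguous blocks), optional scale bounds, and `NA` for missed
reports. A `sced_dataset` pairs the mediator and outcome series on one time
index and records the *hypothesized direction of improvement* per variable
(+1 = higher is better, −1 = lower is better); every significance gate in
the framework is one-sided in effect because results opposite to the
declared direction never count as support.

Two missing-data policies are provided. `"listwise"` removes any day with
either score missing and re-indexes days consecutively, reproducing the
common practice of deleting missing daily reports; it distorts calendar
timing, which matters for lagged analyses. `"calendar"` (the default) keeps
the calendar and lets each lagged comparison skip incomplete pairs. Both are
exposed because neither is uniformly right; analysts comparing with older
listwise-based results need the first, analysts who care about timing should
prefer the second.

## Tau-U

For an earlier phase with scores $a_1..a_{n_A}$ and a later phase
$b_1..b_{n_B}$, every one of the $n_A n_B$ pairwise differences
$b_j - a_i$ is classified as positive, negative or tied, and
$S = P - N$. The between-phase level statistic is
$\tau = S / (n_A n_B)$: the net proportion of nonoverlapping pairs, $+1$
when the later phase completely dominates. Within one phase the same count
over the $n(n-1)/2$ forward-in-time pairs measures monotone trend. Ties
contribute 0 to $S$ but stay in the denominator.

When the earlier phase already trends toward improvement, the between-phase
statistic partly reflects that pre-existing trend; the corrected variant
subtracts the earlier phase's trend numerator, $S_{corr} = S_{between} -
S_{trend}(a)$, keeping the denominator $n_A n_B$. (Variants in the
literature enlarge the denominator instead; the simple subtraction is used
here and reported alongside, never instead of, the uncorrected value.) The
a-/c-path evaluators run the corrected comparison only when the earlier
phase's trend is itself significant.

Inference uses the normal approximation to the null distribution of $S$.
Between phases, $S = 2U - n_A n_B$ for the Mann-Whitney $U$, so
$\mathrm{Var}(S) = n_A n_B (n_A + n_B + 1)/3$; the implementation is tested
to agree with `wilcox.test(..., exact = FALSE, correct = FALSE)` to 1e-12.
Within phases the Kendall variance $n(n-1)(2n+5)/18$ applies. Confidence
intervals (default level 0.90, matching common reporting practice for these
statistics) are $\tau \pm z \cdot \mathrm{SD}(S)/n_{pairs}$, truncated to
$[-1, 1]$ at the boundaries. Two approximations are documented limitations:
no tie correction is applied to the variances, and the corrected statistic's
variance is taken as the sum of the between- and trend-components' variances,
ignoring their covariance (they share the earlier phase's scores). Both
matter little at the 26–32 observations per phase this package targets, but
p-values for heavily tied, very short phases are approximate.

## Piecewise phase regression

One OLS fit with $2k$ columns for $k$ phases: an intercept, time re-centred
at the first observation (so the intercept is the estimated level on day 1),
and per later phase $j$ a step indicator (1 from the first observation of
phase $j$ onward — cumulatively, through all subsequent phases) and an
interaction $(t - t_{first,j})$ from that day onward. Under this coding each
indicator coefficient is the *immediacy* estimate: the gap at the boundary
between the previous segment's extrapolated line and the new segment's line;
each interaction coefficient is the slope change at that boundary. The
within-phase time is re-zeroed at the *first observation of the new phase*
(not the last of the previous one) precisely so that the indicator reads as
this gap; `predict_segments()` reconstructs the per-phase lines and verifies
the identity. An algebraic consequence, used as a test invariant: the joint
fit reproduces exactly the per-phase simple regression lines.

Inference is classical OLS (homoskedastic, independent errors), with
two-sided t-tests, $R^2$ and the model F-test, and no multiplicity
adjustment across terms. Daily data are autocorrelated, so these p-values
are anticonservative — under AR(1) errors with $\phi = 0.3$ each term's
nominal 5% test rejects at roughly 10–15% two-sided. This is a deliberate
fidelity choice: the framework mirrors how these analyses are actually run
and reported in the SCED literature; an autocorrelation-robust variant is
out of scope, and the operating-characteristics section below quantifies the
consequence rather than hiding it. In listwise mode the compressed index is
used as the time variable; in calendar mode real study days are used and
missing days simply drop rows.

Degenerate inputs: a constant series fits with all non-intercept estimates 0
and $R^2$/model-p reported as `NA` (zero total variance); noiseless
piecewise-linear series are recovered with zero residuals (tested to 1e-9);
rank deficiency (e.g. a phase observed on a single day) errors out naming
the problem rather than silently dropping terms.

## Cross-lagged correlations

The lag convention follows the mediator-leads reading: lag $-k$ pairs the
outcome on day $t$ with the mediator on day $t-k$, so negative lags are the
mediation-relevant ones and temporal precedence reads directly off them.
Lags $-5..+5$ are computed by default (five is the customary window in
single-case cross-lag software); pairing is by calendar day, with pairs
skipped when either side is missing, and lags with fewer than 5 usable pairs
or zero variance are reported as not evaluable rather than failing the run.

Significance respects autocorrelation by simulation. A lag-1 autocorrelation
$\hat\phi$ is estimated for each series from consecutive-day complete pairs
(clamped to $|\hat\phi| \le 0.95$; set to 0 when fewer than 3 such pairs
exist), and `reps` independent pairs of stationary Gaussian AR(1) surrogates
with matching lengths, $\hat\phi$s and missingness patterns are generated.
The per-lag two-sided p-value is $(b + 1)/(reps + 1)$ where $b$ counts
surrogates with $|r|$ at least the observed $|r|$ — the add-one form keeps
p-values strictly positive and valid. Because 11 lags are examined, a
max-statistic family-wise adjustment is also reported: the observed $|r|$ is
compared against the null distribution of $\max_{lags} |r|$; the b-path
evaluator uses these adjusted p-values, and $p_{adj} \ge p$ always. With
$\hat\phi = 0$ and long series the surrogate p converges to the classical
t-based Pearson p (tested at n = 500 within 0.02). Determinism: a fixed seed
gives bit-identical p-values; the generator state is saved and restored so
package calls do not disturb the caller's RNG.

## The mediation decision rule

The a path is *significant* when at least one of its tests — between-phase
Tau-U, its baseline-corrected variant (when triggered), piecewise level
change, piecewise trend change — has $p < \alpha$ *and* an effect sign
matching the declared direction of improvement. The tests are treated as
disjunctive lines of evidence and deliberately not multiplicity-adjusted:
each answers a different question (overall level shift vs. immediate jump
vs. slope change), and the report lists every test so stricter users can
demand a conjunction. The cost is an inflated family-wise a-path rate,
quantified below. The c path uses identical machinery on the outcome and is
reported only. The b path is significant when any lag $\le 0$ has adjusted
$p < \alpha$ with the correlation sign implied by the two directions of
improvement (e.g. coping up, anxiety down ⇒ negative r expected).

Temporal precedence is `supported` when the mediator changes at the boundary
while the outcome's change is gradual rather than immediate (significant
trend-change but no significant direction-consistent immediate level change),
or when a strictly negative lag is significant; support only at lag 0, or
leading lags non-contiguous with 0, downgrade to `supported_with_caveats`;
no mediator-side support gives `not_supported`. The verdict is
`consistent_with_mediation` iff a and b are both significant and precedence
is not contradicted; `no_evidence` when either path fails; `inconclusive`
when a path could not be evaluated (e.g. phases too short for the lag
window) or joint significance holds but precedence is contradicted. The
wording "consistent with" is deliberate: a correlational b-path proxy cannot
demonstrate mediation, only fail to falsify it.

## The synthetic generator

`generate_sced()` produces the study conditions the analyses target: default
phase lengths 26/32/14 (a month-scale B/C/D design), bounded ordinal-like
scores, an immediate level shift and/or slope change in the mediator at the
onset of the second phase, a linear lagged effect $Y_t = \mu_Y + s_Y t + b
M_{t-\ell} + \varepsilon_t$, stationary AR(1) innovations in both series
(default $\phi = 0.3$, a typical daily self-report autocorrelation), MCAR
missingness (the case-study-scale default rate used in tests is 14.5%,
`round(rate·n)` days removed, never leaving a phase under 3 complete days),
optional treatment withdrawal in the final phase (level effect removed,
trend effect reversed), and optional discretization to the 0/2/4/6/8 grid
(off by default because it breaks exact-recovery identities). The mediator
process is extended $\ell$ days before day 1 so the lagged term is defined
from the first day. The noiseless trajectories are stored as ground truth
and are reproducible from the configuration alone — a tested identity.

What it does *not* emulate, and what passing tests therefore do not show:
missingness that depends on the scores themselves (a client too anxious to
report is MNAR — generating it would wrongly imply the analyses handle it),
non-Gaussian or heteroskedastic innovations, floor/ceiling censoring
dynamics, and multi-participant designs. Conclusions from the simulation
suite are about the framework's behaviour under its stated model, not about
robustness to these violations.

## Operating characteristics and sizes

Simulation sizes were chosen to keep Monte-Carlo error small relative to the
quantities checked: 1000 replicates for null rates (binomial SE ≈ 0.007 at
rate 0.05), 200 per cell for the 3×3 power grid (SE ≤ 0.035), 500 surrogate
pairs per b-path test inside replicated simulations and 5000 for one-shot
analyses. Under the complete null (no a or b effect, $\phi = 0.3$, phases
26/32): the b path holds ≈0.025 (the max-statistic adjustment is slightly
conservative), the joint verdict fires in ≈0.002 of replicates — the
intersection of two gates is far below $\alpha$ — but the a path's
unadjusted disjunction rejects in ≈0.19 (≈0.07 even with independent
errors). Users who want a calibrated a path should apply a Bonferroni
correction across its listed tests or demand a conjunction; the default
mirrors the disjunctive-evidence reading and relies on the joint rule for
error control. Verdict power rises monotonically in both effect sizes and
reaches ≈0.99 at a strong scenario (level shift 3 SDs of innovation noise,
b = −0.6, lag 2).

## Known limitations

- The b-path proxy ignores the phase variable; a phase-driven common trend
  in both series can masquerade as a mediator→outcome association.
- Tau-U and piecewise p-values assume independent errors; with daily data
  they are anticonservative in proportion to the autocorrelation.
- Listwise compression changes what "lag k" means in calendar time.
- No indirect-effect magnitude, no c′ path, no multi-participant pooling,
  no imputation: all out of scope by design.
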