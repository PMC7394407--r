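---
title: "Quantifying postural adaptation to continuous support-surface translations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying postural adaptation to continuous support-surface translations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturadapt)
```

## The measurement problem

When a person stands on a platform that translates sinusoidally in the
antero-posterior (AP) direction, the balancing response is not stationary:
over the first perturbation cycles the oscillation amplitude of the head and
pelvis drifts toward a steady state. The speed and direction of that drift —
the *adaptation* of the balancing behaviour — depend on vision (eyes open or
closed, or engaged by a reading task) and on the translation frequency. The
standard protocol this package analyzes uses sinusoidal translations of
10 cm peak-to-peak at 0.18 Hz (LF, 27 cycles, one cycle every 5.6 s) or
0.56 Hz (HF, 31 cycles, one every 1.8 s), with markers sampled at 140 Hz
and at least 5 s of quiet stance before the first cycle. Analyses truncate
both frequencies to the first 27 cycles so conditions are comparable.

`posturadapt` turns a three-trace recording (platform, head, pelvis AP
displacement) into:

1. **cycle windows** — one per platform period, delimited by positive-going
   crossings of the platform's post-onset midline;
2. **per-cycle metrics** — peak-to-peak (PP) displacement `max - min` and
   mean AP position (referenced to cycle 1) for each body segment;
3. **adaptation fits** — the three-parameter exponential
   `y = A + B e^{-C t}` fitted to each per-cycle series;
4. **coordination** — the lag-0 cross-correlation between the within-cycle
   head and pelvis traces, its course across cycles, and its regression on
   head PP.

## The adaptation model

Per-cycle series are fitted by least squares with

$$y_n = A + B\,e^{-C\,(n-1)}, \qquad n = 1, 2, \dots$$

where $A$ is the steady-state value (asymptote), $I = A + B$ the model value
at the first cycle (intercept), and $C$ the rate per cycle. Two conventions
matter and are easy to get wrong:

* **The first cycle sits at $t = 0$.** Only then does the intercept obey the
  exact identity $I = A + B$, which the derived indices rely on. Fitting
  with the first cycle at $t = 1$ would silently redefine $I$ as
  $A + B e^{-C}$.
* **The time constant is reported positive**: $\tau = 1/|C|$, in cycles,
  and $\tau_\text{seconds} = \tau \times (1/f)$ (5.6 s per cycle at LF,
  1.8 s at HF). A time constant measures elapsed time and carries no
  direction; the *direction* of adaptation is carried entirely by the sign
  of $B$, equivalently by the **adaptation index**

$$\mathrm{AI} = \frac{A - I}{A + I} \in (-1, 1),$$

negative when the amplitude shrinks across the trial (decaying envelope;
AI is about $-0.3$ when the asymptote is half the intercept), positive when
it grows, near zero when adaptation is negligible.

Goodness of fit is the Pearson correlation $R$ between observed and fitted
values with a two-tailed p-value on $n - 2$ degrees of freedom. Because the
curve is itself fitted to the series, this p-value is optimistic under a
null of no structure (numerically, pure-noise series are "significant" at
the 5% level in roughly 15% of cases); it is reported descriptively, and no
fit is discarded because of it — summaries retain all fits, including
non-significant ones, as the protocol prescribes.

### Numerical choices

Fitting uses damped (Levenberg–Marquardt) least squares with a multi-start
grid: $C_0 \in \{1, 1/2, 1/4, 1/8\}$ crossed with both signs of
$B_0 = y_1 - A_0$, where $A_0$ is the mean of the last five cycles. The
multi-start guards against the local-minimum fragility of single-start
spreadsheet solvers on noisy series. The rate is bounded so
$\tau \in [0.2,\ 3 n]$ cycles; a fit on a bound, or with
$|B| < 0.02\,|A|$, is flagged *degenerate*: at the data's resolution it is
indistinguishable from a constant, and its nominal time constant is
unreliable — exactly the caveat that applies to real eyes-open trials,
where adaptation is small. Degenerate fits are kept, flagged, in all
downstream tables. Convergence tolerances are $10^{-15}$ on the objective
and parameters; a zero-variance series falls back to the constant model.

### Steady state and averaging

Cycles 15–27 operationalize the steady state, justified by $3\tau < 15$
cycles for the fitted time constants. Repeated trials of a condition are
averaged **per cycle, before fitting** (PP and position element-wise;
correlation coefficients through the Fisher z-transform), not by averaging
fitted parameters.

## Cycle segmentation

The protocol's quiet pre-period makes onset detection simple: the first
sample deviating from the baseline mean by more than $k$ baseline SDs
(default $k = 5$, with a floor of $10^{-6}$ cm for noiseless traces),
backtracked to the last sample still at baseline level. Cycle boundaries
are then the positive-going crossings of the post-onset platform midline
(the mean of the post-onset trace, robust to baseline offset), with a
hysteresis band of 5% of the platform PP so that sensor noise cannot
produce spurious boundaries. The platform stops *at* the midline after the
last cycle, so the final cycle is closed from the nominal period when a
full period of samples remains past the last crossing; genuinely partial
trailing cycles are discarded, never extrapolated. PP is computed on the
raw trace by default; a zero-phase Butterworth low-pass
(`per_cycle_metrics(..., lowpass = )`) is available for noisy real
recordings, because wide-band noise inflates the raw `max - min` of a
window by the expected range of the noise.

## Coordination

The per-cycle coordination measure is the Pearson correlation of the
within-cycle head and pelvis traces — the lag-0 normalized
cross-covariance. Mean-centering within the cycle is forced by the
interpretation of the sign (without it the coefficient is not bounded in
$[-1, 1]$); no further detrending is applied, the cycle being short
relative to positional drift. Group summaries average Fisher-z values and
back-transform. The course of the coefficient across cycles is fitted with
the same exponential model as the PP series, and the cycle means of the
coefficient are regressed (OLS) on the cycle means of head PP, reported as
slope, intercept, $R^2$ and the slope's two-tailed p-value.

## What the synthetic generator emulates

No raw recordings are distributed with the protocol, so the package ships a
generator whose *parameters are the ground truth* of validation studies.
Each segment trace is

$$x(t) = M(t) + \frac{G(n(t))}{2\sqrt{2}}\,o(t) + \varepsilon(t)$$

* $G(n) = A + (I - A)e^{-(n-1)/\tau}$ is the per-cycle PP envelope,
  piecewise-constant within cycles — the simplest model consistent with a
  per-cycle PP analysis. With no noise and full coordination the measured
  PP equals $G(n)$ up to sampling discretization
  ($2a(1 - \cos(\pi f/f_s)) \approx 10^{-4}$ cm at protocol settings).
* $o(t)$ mixes a sinusoid *shared* between head and pelvis with a
  *segment-specific* unit-variance band-limited Gaussian sway process
  (AR(1), ~2 Hz bandwidth): with shared-variance fraction $\lambda$, the
  expected per-cycle lag-0 correlation is $\lambda$ (attenuated
  analytically by measurement noise — see `expected_cc()`). $\lambda$ may
  itself follow an exponential course across cycles so the coordination
  analysis has a recoverable target. Sway is band-limited because
  uncoordinated postural motion lives below a few Hz; wide-band sway would
  make the per-cycle PP an extreme-value statistic of the noise rather
  than a measure of the oscillation.
* $M(t)$ is the mean position: zero by default, since mean positions vary
  little across cycles in this protocol, with an optional linear drift for
  exercising the position metrics.
* $\varepsilon(t)$ is white Gaussian measurement noise, by default 5% of
  the segment's asymptote.

Default envelope parameters per condition (`condition_defaults()`) follow
the group means reported for this protocol where such means are printed —
e.g. pelvis time constants at LF of 1.47 (EO), 3.16 (EO-TP), 3.02 (EO-TG)
and 3.47 (EC) cycles; head 1.84 cycles with EO at LF; head AI of $-0.16$
with EC at HF; pelvis AI of 0.078/0.09 for the reading tasks at LF —
while the remaining values (amplitude levels per condition, HF head time
constants of ~2–2.5 cycles, coordination levels high at LF and low at HF
with a ~4-cycle course) were chosen once from the protocol's qualitative
description and frozen. Per-subject variability is emulated with
log-normal multipliers on each envelope parameter (log-SD 0.15 by
default).

### What passing tests do and do not show

The generator reproduces the *statistical structure the analysis assumes*:
sinusoidal platform motion, exponential PP envelopes, controllable
coordination, stationary mean position. It deliberately does not model
inverted-pendulum biomechanics, muscle activity, or sensory feedback, so
recovery results validate the *pipeline*, not any claim about human
physiology. Two properties of the synthetic conditions deserve emphasis:

* **Raw PP is biased upward by measurement noise.** `max - min` over a
  ~780-sample window includes the range of the noise (~3 cm for white
  noise of SD 0.5 cm). The asymptote and intercept inherit this common
  offset, the adaptation index is attenuated, and the time constant is
  essentially unaffected. This is a property of the PP statistic itself,
  not of the implementation; the optional low-pass removes most of it.
* **Single-trial time constants are noisy.** At realistic coordination and
  noise levels, the per-fit relative error of $\hat\tau$ has a median
  around 30% at the per-cycle-series level and more at trace level —
  consonant with real cohorts, where the between-subject SD of $\tau$ is
  of the order of its mean. The estimator is median-unbiased: across
  replicates the *median estimate* lands within a few percent of the true
  time constant, which is what the package's validation asserts. Cohort
  claims should rest on condition-level medians and on structure (e.g.
  rapid EO vs slow EC adaptation), not on individual fits.

## Problem sizes used in validation

The test suite fits noiseless series across a parameter grid to $10^{-6}$
relative error; recovers the reported time constants and adaptation
indices as medians over a few hundred simulated 27-cycle series at 5%
noise; verifies coordination fidelity over 100 generator seeds (tolerance
0.02 on the mean coefficient); checks type-I error of the implemented
tests (one-sample t, paired t, Spearman, regression slope) within
3.5–6.5% at $\alpha = 0.05$ over 1000 null replicates each; and runs the
full pipeline on small cohorts (2–4 subjects, 1–2 conditions) for
determinism, cardinality and structure checks. These sizes were chosen so
the whole suite completes in well under a minute while keeping Monte-Carlo
error far from each tolerance.

## A worked example

```{r example, eval = FALSE}
library(posturadapt)

# one eyes-closed LF trial with known envelopes
cfg <- synth_config(
  frequency = 0.18,
  head = pp_envelope(A = 10.8, I = 7.2, tau = 3.5),
  pelvis = pp_envelope(A = 9.5, I = 7.5, tau = 3.47),
  coordination = cc_course(A = 0.95, I = 0.86, tau = 2),
  visual_condition = "EC", seed = 1)
rec <- generate_trial(cfg)

a <- analyze_cycles(rec, segments = c("head", "pelvis"))
fit <- fit_adaptation(a$head$pp, frequency = 0.18)
fit
steady_state(a$head)

ccs <- cc_per_cycle(rec, a$windows)
fit_cc_course(ccs)
cc_vs_pp_regression(ccs, a$head)
```

For cohort-scale work, `pipeline_config()` + `run_pipeline()` orchestrate
generation (or reading of trial TSVs), segmentation, averaging, fitting and
condition-level summaries, and `recovery_report()` joins the estimates to
the generator's ground truth.

## Known limitations

* The package consumes one pre-combined AP trace per segment; reducing
  multiple physical head markers to one trace is the caller's concern.
* Only the AP component is analyzed; medio-lateral and vertical motion,
  and within-cycle events other than boundary crossings, are out of scope.
* Repeated-measures ANOVA machinery is intentionally not included; the
  tidy long-format outputs are designed to feed any statistics package.
* The exponential model is a single-process description; series with
  two-phase dynamics or near-zero amplitude change yield degenerate or
  unreliable time constants, and are flagged rather than excluded.
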