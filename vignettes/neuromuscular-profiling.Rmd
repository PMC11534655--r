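---
title: "Profiling neuromuscular performance from IMTP force and crank torque"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling neuromuscular performance from IMTP force and crank torque}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crankforce)
```

## The measurement problem

Sprint-cycling coaches and researchers characterise an athlete's
neuromuscular capacity with two families of tests. On the force plate, the
isometric mid-thigh pull (IMTP) yields a force–time curve from which peak
force (PF) and the rate of force development (RFD) are extracted. On the
bicycle, short maximal sprints against different resistances yield crank
torque, cadence and power per pedal stroke, from which one derives observed
peaks (peak power output PPO, peak cadence, peak torque), the rate of torque
development (RTD) of early downstrokes, and the torque–cadence (T–C) and
power–cadence (P–C) profiles with their theoretical parameters: maximal
torque $T_0$, maximal cadence $RPM_{max}$, peak power $P_{max}$ and optimal
cadence $RPM_{opt}$.

`crankforce` implements this full measurement chain — signal in, statistics
out — together with a synthetic-data generator whose ground truth is known
exactly, so every stage can be tested for parameter recovery without access
to raw participant data.

## IMTP analysis

The force signal is used raw; no filtering is applied at any stage, so every
metric is defined directly on the sampled record.

**Onset.** The field's verbal rule is "the last peak/trough before the
signal deflects away from baseline noise", usually applied by eye.
`detect_onset()` operationalises it in two steps: the signal is declared to
have deflected at the first sample exceeding the baseline mean plus `k_sd`
(default 3) baseline standard deviations while staying above threshold for
at least 10 ms; the onset is then backtracked to the last local extremum of
the raw signal within `extremum_lookback_s` (default 50 ms) before that
crossing. The extremum rule is weak on the left and strict on the right
(`x[i] >= x[i-1] & x[i] > x[i+1]` for a peak, mirrored for a trough), so the
final sample of a flat stretch counts but the first sample of a plateau does
not — this makes a noiseless flat-then-rise corner its own onset. If the
supplied baseline window turns out to contain the start of the rise (its
second half drifts above its first half beyond sampling error), the window
is shrunk with a warning before detection.

**Metrics.** With onset $t_0$ and the raw maximum $F_{pk}$ at $t_{pk}$:

* net peak force: $PF = F_{pk} - \bar F_{baseline}$. The baseline mean is
  the quiet-standing force, which embodies the participant's body weight on
  the plate; subtracting it keeps the units coherent (N − N). Ties in the
  maximum break to the earliest sample.
* banded RFD: $(F(t_0 + \Delta) - F(t_0)) / \Delta$ for $\Delta$ = 100 and
  200 ms, with the band endpoint snapped to the nearest sample on the grid
  and the elapsed time taken as the actual grid time spanned.
* average RFD: $(F(t_{pk}) - F(t_0)) / (t_{pk} - t_0)$.
* peak RFD: the fastest slope over any 20-ms window, advanced one sample at
  a time; this equals an exhaustive scan by construction, and the test suite
  asserts that equality against an independently coded brute-force scan.

Any uniform sampling rate is accepted; band and window lengths are converted
to whole samples by rounding. Per field convention, RFD variables are taken
from the short explosive (≈1 s) trials and PF from the long maximal (≈5 s)
trials; `aggregate_best_trials()` averages the best three trials of a set,
ranking the maximal set by PF and the explosive set by peak RFD. The
ranking rule for "best" trials is configurable because conventions differ
between laboratories.

## Sprint-cycling analysis

**Segmentation.** Crank torque rises and falls once per downstroke.
`segment_downstrokes()` finds candidate lobes at local maxima and places a
boundary at the trough between two maxima whenever the trough falls below
`trough_frac` (default 0.3) of the smaller adjacent peak; shallower dips are
treated as one lobe. Each segment keeps 250 ms of context on both sides and
a 30-ms pre-lobe trough window that serves as the torque-onset baseline.

**RTD.** The IMTP machinery is reused verbatim with torque in place of
force. RTD is defined on the hardest stationary sprint (0.6 Nm·kg⁻¹), as
the mean over downstrokes 2 and 3 — the first stroke is contaminated by the
standardised starting position, later strokes by rising cadence. Banded RTD
may extend past the lobe into the following trough (the band is a fixed
time, not a fraction of the stroke); average and peak RTD are confined to
the lobe so a following downstroke cannot leak in. Torque onset uses the
local pre-lobe trough as baseline rather than absolute zero; this choice is
exposed through the segment's `baseline_window_s`.

**Profiles.** Per-stroke mean torque is regressed linearly on cadence
(ordinary least squares); $T_0$ is the y-intercept and $RPM_{max} = -b_0 /
b_1$ the x-intercept, both extrapolated beyond the observed range by
design. Power is fitted with the zero-intercept cubic $P(c) = a_1 c + a_2
c^2 + a_3 c^3$, which satisfies $P(0) = 0$ exactly for every fit. The apex
is the admissible root of $P'(c) = 0$ inside $(0,\ 1.2\,c_{obs,max})$ with
the greater fitted power; when the cubic coefficient is numerically
negligible the stationary point $-a_1 / (2 a_2)$ of the quadratic is used
instead, because the general root formula divides by $3 a_3$ and is
unstable there. Only acceleration-phase strokes (up to each sprint's
maximum-cadence stroke) enter the profile fits, to avoid fatigue-phase
contamination. The reported $r^2$ for the P–C fit is centred (about the
mean power), not the uncentred statistic `lm()` reports for zero-intercept
models, so it is comparable across the two fits.

For a *linear* torque–cadence truth the induced power curve is the parabola
$P(c) = \frac{2\pi}{60} T_0\, c\, (1 - c/RPM_{max})$, with closed-form apex

$$RPM_{opt} = RPM_{max}/2, \qquad
P_{max} = \pi\, T_0\, RPM_{max} / 120 .$$

This is the package's standing oracle: the cubic fitted to noiseless linear
sessions must reproduce it, and the test suite asserts recovery to within
0.5%.

## Training-response statistics

Pre/post responses are summarised with:

* percent change, by default $100(\bar x_{post} - \bar x_{pre}) /
  \bar x_{pre}$ (ratio of means). The per-participant alternative (mean of
  individual percent changes) is available via
  `percent_change_by_participant()` and the `pct_convention` setting,
  because published tables mix the two conventions.
* bias-corrected Hedge's g, treating pre and post as two groups of size $n$
  with pooled SD $s_p$ and correction $J = 1 - 3/(4(n_1+n_2-2) - 1)$, with
  the normal-approximation interval $g \pm z_{0.975}\sqrt{(n_1+n_2)/(n_1
  n_2) + g^2 / (2(n_1+n_2))}$. This two-group convention (rather than a
  repeated-measures d) is the one that reproduces published tables in this
  literature.
* magnitude labels on half-open bins with lower-edge inclusion — effect
  sizes: trivial [0, 0.2), small [0.2, 0.6), moderate [0.6, 1.2), large
  [1.2, 2.0), very large [2.0, 4.0), extremely large [4.0, ∞); correlations
  (Hopkins-modified Cohen): trivial [0, 0.1), small [0.1, 0.3), moderate
  [0.3, 0.5), large [0.5, 0.7), very large [0.7, 0.9), almost perfect
  [0.9, 1]. The quoted verbal scales leave gaps at the bin edges (e.g.
  "<0.2" then "0.21–0.60"); lower-edge inclusion makes the mapping
  deterministic and monotone.
* Pearson correlations with two-tailed p from the t transform on $n-2$
  degrees of freedom, and `change_correlation_matrix()` correlating
  per-participant relative changes between metric pairs.
* a paired t comparison (`paired_comparison()`) as the pre/post inference
  utility. A mixed-effects model with gender and timepoint fixed effects is
  what a full study analysis would use; the paired t is a deliberately
  simple, documented stand-in for this package's scope, and its p-values
  are labelled as such in the summary table.

No multiple-testing correction is applied, matching practice in this
literature.

## The synthetic-data generator

The generator exists so that every downstream stage has a recoverable ground
truth.

**IMTP trials.** Force is a quiet-standing baseline plus a logistic rise
rescaled to be exactly zero before the true onset and to asymptote at
`pf_true`, plus Gaussian white noise (no drift — the analyser must tolerate
raw noise, and white noise exercises exactly that). Defaults: sampling
1000 Hz; onset 1 s into the record; rise midpoint 50 ms after onset; rise
rate 60 s⁻¹; noise SD 20 N; baseline force 820 N. The 50-ms midpoint makes
the signal leave the noise band within a few milliseconds of true onset, as
a well-performed maximal-intent pull does; a substantially later midpoint
would make the stored onset unrecoverable by *any* detector, because the
signal would still be inside the noise band at the true onset.

**Sprint sessions.** The torque–cadence truth is linear with known
`t0_true` and `rpmmax_true` (so the P–C apex is analytically known, giving a
free oracle for the cubic fit). Five conditions reproduce the standard
protocol: stationary starts at 0.2/0.4/0.6 Nm·kg⁻¹ and rolling starts
(~80 rpm lead-in) at 0.0/0.2 Nm·kg⁻¹. Per-stroke cadence approaches each
condition's steady state — where rider torque balances the brake torque —
as a saturating exponential with a 3-stroke time constant, so higher
resistance saturates at lower cadence. Four strokes per sprint give ~20
profile points per session, the typical modelling count for this protocol.
Per-stroke mean torque is the linear truth plus Gaussian noise
(SD 4 Nm, chosen so the synthetic torque–cadence fit quality, $r^2 \approx
0.98$, matches what this protocol typically achieves); power is torque
times angular velocity; the 256-Hz trace is one half-sine lobe per
downstroke occupying 75% of its half-revolution, scaled so the sampled lobe
mean equals the stroke's mean torque exactly.

**Cohorts.** `generate_cohort()` draws paired pre/post metric tables under
two pairing models. The default draws pre and post independently, which is
the null model matching the two-independent-group effect-size convention
above — under it the 95% interval excludes zero in ≈5% of null cohorts, and
the test suite checks that calibration over 1000 simulated cohorts of
n = 14. The additive model adds per-participant changes (optionally
correlated across metrics) to the pre values and is the right model for
studying correlations between individual changes. `simulate_study()`
assembles a full signal-level cohort (10 IMTP trials and 5 sprints per
participant-timepoint) with multiplicative training responses whose
defaults emulate a strength-trained novice cohort: +13% peak-force ability,
+10% torque-cadence intercept, +0.8% maximal cadence.

**What the generator does not emulate.** Fatigue across strokes and
sprints, left/right asymmetry, flywheel inertia dynamics, signal drift, and
correlated torque/power measurement error. The last point matters when
judging fit quality: because synthetic power is derived exactly from noisy
torque, the synthetic P–C scatter is larger relative to its T–C scatter
than in real crank data, where the P–C relationship is typically tighter
($r^2 \approx 0.997$) than the package's synthetic sessions achieve
(≈0.87). Passing recovery tests therefore demonstrates correctness of the
estimators under white noise, not robustness to structured artefacts of
real instrumentation.

## Numerical choices and known limitations

* Band endpoints and window lengths snap to the nearest sample; all slopes
  use the actual grid time spanned.
* Ties in maxima break to the earliest sample, making every pipeline output
  order-stable and reruns bit-identical.
* The unfiltered sample maximum is a biased estimator of plateau force
  under noise: over $n$ plateau samples of white noise with SD $\sigma$ its
  expectation sits $\approx \sigma\sqrt{2\ln n}$ above the true plateau —
  about $3.2\sigma$ for the ~850-sample plateau of a 1-s pull at 1000 Hz.
  This is a property of the field's PF definition itself (raw maximum, no
  filtering), not of the implementation; net PF on noisy trials should be
  read with that bias in mind, and between-condition comparisons at equal
  noise and duration are unaffected.
* Banded RTD on fast strokes can span past the lobe peak (the 200-ms point
  may land in the following trough); the value is still reported, as the
  definition is a fixed time band, but `rtd_avg`/`rtd_peak` are confined to
  the lobe.
* Stochastic test sizes — 50 seeded trials/sessions for recovery medians,
  1000 cohorts for interval calibration, a 14-participant simulated cohort
  for the end-to-end run — were chosen to make Monte-Carlo error small
  relative to the tolerances asserted.

## A minimal session in code

```{r example}
# a noiseless sprint session recovers its truth exactly
sess <- generate_sprint_session(
  cycling_ground_truth(t0_true = 165, rpmmax_true = 232,
                       torque_noise_sd = 0), seed = 1)
profile_session(sess)$metrics[, c("t0_nm", "rpmmax_rpm", "pmax_w",
                                  "rpmopt_rpm")]
pi * 165 * 232 / 120   # analytic peak power of the linear truth
```
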