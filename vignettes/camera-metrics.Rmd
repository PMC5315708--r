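---
title: "Camera metrics for endoscope control: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera metrics for endoscope control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scopemetrics)
```

## The problem

In robot-assisted minimally invasive surgery (RAMIS) the operating surgeon
controls both the instruments and the endoscope from the same console, so how
often, how long, and how densely a surgeon repositions the camera is a
measurable technical skill. `scopemetrics` turns time-stamped trial telemetry
(3-D positions of hand controllers, instrument tips, and endoscope, plus
discrete console events) into three *camera metrics* and three conventional
efficiency metrics, and provides the statistical machinery to test whether
those metrics separate surgeons of known different experience — construct
validity — across a battery of exercises.

Per trial, with camera movement episodes $\{(s_j, e_j)\}_{j=1..N}$ and
completion time $T$:

* **CFrq** $= N / T$ — camera movements per second over the exercise.
* **CDur** $= \frac{1}{N}\sum_j (e_j - s_j)$ — mean movement duration (s).
* **CInt** $= \frac{1}{N-1}\sum_j (s_{j+1} - e_j)$ — mean viewpoint-hold gap
  between movements (s).
* **CompTime** $= T$ — last sample time minus first (s).
* **EOM** — summed Euclidean polyline length of every instrument-tip
  trajectory (m).
* **MWR** — a workspace radius: per hand, distances from the centroid of its
  sampled positions; by default 85% of the larger of the two maximum-distance
  radii (m).

## Episode segmentation

When the platform records camera events, each `camera_start` is paired with
the next `camera_stop`; these markers are treated as ground truth. Protocol
violations degrade gracefully: a stop with no open episode is skipped, an
unclosed start is clamped to the trial end, both with structured warnings.

For recordings without camera events, `episodes_from_kinematics()` detects
movement from the endoscope positions: speed by centered finite differences
(edge replication at the two boundary samples, avoiding the half-sample bias
of one-sided differences), a moving-average smoother, a speed threshold,
then a merge rule and a minimum-length rule. Defaults — threshold 2 mm/s,
minimum episode 0.1 s, merge gap 0.2 s, window 5 samples — describe
plausible console dynamics and are all configurable, because no platform
standard exists. The detector is an approximation: its boundaries are
blurred by roughly `smoothing_window / sample_rate` seconds, and true
pauses shorter than the merge gap are (intentionally) fused. The event path
therefore takes precedence whenever events exist; the kinematic path is
opt-in (`use_kinematics` in the pipeline config).

## Design choices in the metrics

* **CInt is the end-to-start gap**, not the start-to-start period: "time
  between movements" reads as time during which the endoscope is *not*
  moving, and the period would double-count durations already captured by
  CDur. `convention = "start_to_start"` is available for sensitivity
  analysis.
* **Zero-episode trials yield missing CDur/CInt**, not zero. A zero would
  fake instantaneous movements and drag group means down precisely in the
  novice group, where trials without any camera movement actually occur.
  Missing values are excluded pairwise downstream, and every reported
  statistic carries its effective n.
* **MWR ships in two modes** because "85% of the larger radius" is genuinely
  ambiguous: `scaled_max` (the literal reading, 0.85 times the larger
  maximum-distance radius) is the default; `percentile` (85% as a
  sample-coverage radius) is the alternative. The mode used is an explicit
  argument and recorded in the pipeline config hash. Note the maximum of
  noisy distances grows with the number of samples, so `scaled_max` values
  are comparable only at a common sampling rate.
* **EOM sums all instrument streams present** and does not exclude clutched
  segments: instruments are stationary while clutched, so the contribution
  is ≈ 0.
* **MWR uses the hand controllers (masters)**, not instrument tips — it
  measures the surgeon's hand workspace.

## The construct-validity analysis

Group comparisons use the pooled-variance Student t test (two-sided,
df $= n_1 + n_2 - 2$) as the default, with Welch available by flag. Pearson
correlations carry the usual $t = r\sqrt{(n-2)/(1-r^2)}$ significance test.
Degenerate inputs (a group with fewer than two values, zero pooled variance,
a constant correlation target) are *flagged*, never raised, so they
propagate as missing cells in the report tables.

No multiple-testing correction is applied — each table cell is a single
unadjusted test, the convention for these construct-validity tables — and
the total comparison count is written into `summary.json` so users can apply
their own.

To compare metrics *across* exercises with wildly different scales, the
per-exercise group means of the two contrasted groups are min–max normalized
**together** (shared minimum and maximum per metric):
$x_i^n = (x_i - x_{\min}) / (x_{\max} - x_{\min})$. Normalizing each group
separately would force both onto $[0,1]$ and erase the very between-group
difference being measured. The discrimination score is then
$d = |\mu_1 - \mu_2|$, the absolute difference of the groups' mean
normalized values across exercises; per-exercise absolute differences are
retained for dispersion (the reported SD) and for metric-vs-metric t tests,
**paired by exercise** since the same exercises underlie every metric (an
unpaired variant exists). Min–max normalization makes the ranking exactly
invariant to affine rescaling of any metric's raw units, and the output
invariant to exercise order — both asserted in the test suite.

One caveat worth knowing: correlations here are against *raw* completion
time, so CFrq typically correlates negatively with time (frequent movers
finish faster). Published tables sometimes print a time-derived score in
which the sign convention is reversed; the package does not force either
sign.

## The synthetic cohort generator

No public corpus of console telemetry with experience labels exists, so the
package ships a generator whose defaults encode the study conditions the
analysis expects: three experience groups of 18 new / 8 intermediate / 13
experienced surgeons, 25 exercises, one trial per surgeon per exercise,
50 Hz kinematics.

Camera behaviour is an **alternating renewal process**: viewpoint-hold gaps
$\sim \Gamma(2, \text{mean} = \texttt{target\_cint})$ alternate with
movements $\sim \Gamma(2, \text{mean} = \texttt{target\_cdur})$, giving a
long-run movement rate of $1/(\texttt{target\_cint} + \texttt{target\_cdur})$
with independently tunable frequency, duration, and interval. Shape 2 gives
the mild right skew seen in real timing data (SD ≈ 70% of the mean).
Completion times are lognormal. An episode whose movement would straddle the
end of the trial is dropped entirely rather than clipped: a trial ends with
instrument action, not mid-camera-move, and clipping would bias mean
durations downward by a term of order $E[\text{dur}]/n_{\text{cycles}}$,
which matters for parameter-recovery checks.

Default group targets (difficulty 1): new surgeons 0.04 movements/s
(cint 23.6 s, cdur 1.4 s), intermediates 0.11 /s, experienced 0.14 /s
(cint 6.4 s, cdur 0.8 s); completion times 240/170/140 s. These sit at the
scales published for simulator cohorts of this composition. Group standard
deviations at realistic size require **between-surgeon heterogeneity** on
top of within-trial renewal noise, so each trial draws lognormal skill
multipliers for pacing (CV 0.75/0.45/0.35 by group) and movement duration
(CV 0.30/0.25/0.25); without them group SDs come out several times too
small. Exercises get a difficulty multiplier (default an even spread over
0.6–1.6) scaling pacing, durations, and completion time, which is what
gives the cross-exercise spread that min–max normalization needs.

Kinematics are synthesized to be **sampling-rate-stable**: the endoscope
integrates a constant speed along a random per-episode heading; instrument
tips move at constant speed along a slowly wandering (≈ 1 s smoothed)
heading, so EOM ≈ path\_speed × CompTime at any rate rather than growing
like a random-walk's sampled path; hands are i.i.d. Gaussian about fixed
centroids. The surrogate overall score — explicitly *not* any vendor's
proprietary composite — averages $100(1 - \text{minmax})$ of completion
time and EOM within each exercise, anchoring 100 at the fastest/most
economical trial and 0 at the slowest/least.

What the generator does **not** emulate: task content (rings, needles,
pegs), learning across consecutive exercises, exercise-specific null
effects (every exercise discriminates by construction, whereas trivially
easy real exercises may not), clutch-phase kinematics, endoscope
orientation, and any within-surgeon correlation structure beyond that
induced by shared group parameters. Passing calibration tests therefore
demonstrates that the *pipeline* is correct and well-calibrated under these
conditions, not that real cohorts will show the same effect sizes.

## Verification strategy and numerical choices

* Metric arithmetic is pinned to hand-computable fixtures (e.g. episodes
  {(1,2), (4,6), (9,9.5)} in a 10 s trial give CFrq 0.3, CDur 7/6,
  CInt 2.5) and closed forms (circle chord sums for EOM; antipodal point
  sets for MWR, which make the centroid exact).
* The normalization → discrimination pipeline reproduces a worked
  three-exercise example ($d = 0.5$) exactly, in exact floating point.
* Analytic p-values are checked against 10^5-replicate brute-force
  *resimulation* oracles (draw fresh null datasets, recompute the statistic
  from its definition, count exceedances), which agree at Monte-Carlo
  resolution (3 SEs). Data-permutation oracles are also checked, but at a
  looser absolute tolerance: the randomization distribution of the t
  statistic differs from the t reference by a systematic $O(1/n)$ term at
  small n — with 3 observations per group the exact permutation p cannot go
  below 0.1 — so Monte-Carlo-resolution agreement with a permutation oracle
  is not a meaningful requirement there.
* Null calibration: with identical group profiles, the empirical rate of
  p < 0.05 per comparison family (metric × group pair) over 100 seeded
  cohorts of 39 surgeons × 5 exercises must stay inside the 99% binomial
  band around 0.05.
* Parameter recovery uses long homogeneous trials (mean 2000 s, ≈ 330
  renewal cycles): the mean of the observed gaps in a fixed window
  under-estimates the generating mean by a term of order
  $\mathrm{CV}^2/n_{\text{cycles}}$ (the straddling-interval effect), so
  the horizon is chosen long enough that this known bias sits well below
  the 3-standard-error resolution of a 50-seed Monte-Carlo mean. Recovery
  of CFrq against the renewal identity $1/(\text{cint}+\text{cdur})$ is
  only meaningful for homogeneous profiles: with between-surgeon
  heterogeneity $E[1/X] > 1/E[X]$ biases mean CFrq upward by ≈ CV².
* Simulation-heavy tests run at 2–4 Hz sampling — camera metrics derive
  from events and are rate-independent, and the generator's kinematics are
  rate-stable by design — while fixture-level tests run at 50 Hz.
* End-to-end determinism is asserted byte-for-byte: one seed drives a
  per-trial seed table, so cohort, metrics.csv, and every report CSV are
  identical across reruns.

## Known limitations

* The kinematic episode detector has no hysteresis; speeds hovering at the
  threshold can fragment (mitigated, but not eliminated, by the merge rule).
* `scaled_max` MWR depends on the number of samples (a maximum over noisy
  distances); compare trials only at a common sampling rate, or use the
  percentile mode.
* The sampling rate of real recordings is platform-dependent; the on-disk
  format requires it in `meta.json` but the package imposes no value.
* Student's t on lognormal-ish metrics is adequate at these group sizes but
  not exact; the Welch flag is the first thing to try for robustness.
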