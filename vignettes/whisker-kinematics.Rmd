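---
title: "Quantifying whisking behaviour: model, metrics and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying whisking behaviour: model, metrics and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whiskerkin)
```

## The problem

Mice sweep their facial whiskers back and forth at 12–25 Hz ("whisking")
and modulate that rhythm with exquisite precision: on contacting an object
they increase whisk amplitude and left–right asymmetry while bunching the
whiskers (lower spread) and slowing both the protraction (forward) and
retraction (backward) strokes. Whisker kinematics extracted from
high-speed video are therefore a sensitive, fully quantitative readout of
exploratory behaviour, fine motor control and attention — sensitive enough
to phenotype subtle mutants such as the reelin-deficient Reeler mouse,
whose grossly ataxic gait coexists with remarkably normal whisking.

`whiskerkin` implements the full analysis chain for such experiments:

1. per-clip kinematic metrics from tracker-style per-frame whisker-angle
   tables;
2. clip quality control, pre-contact/during-contact (PC/DC) sectioning and
   PC−DC differencing for object-exploration clips, nose-to-object
   distance, and arena zone occupancy;
3. the inference layer: per-metric random-intercept linear mixed models
   with Kenward-Roger F-tests, MANOVA with partial eta-squared effect-size
   bands, Tukey post hoc contrasts, and Pearson χ² tests on zone timings;
4. a synthetic cohort generator with the same statistical structure, so
   every stage is testable without video.

## The per-clip metrics

All angles are in degrees; larger angles mean more protracted (forward)
whiskers. A tracker detects 2–12 whiskers per frame (typically 5–6 per
side); the *side mean* is the arithmetic mean angle of one side's tracked
whiskers in a frame. With left/right side-mean series $L_t, R_t$ and
individual whisker angles $\theta_{t,w}$:

| metric | definition |
|---|---|
| mean angular position | $\tfrac12(\bar L + \bar R)$ |
| amplitude | $2\sqrt2 \cdot \mathrm{SD}(\{L_t\} \cup \{R_t\})$ |
| asymmetry | $\lvert \bar L - \bar R \rvert$ |
| spread | per-frame SD of $\theta_{t,w}$ within a side, averaged over frames, then sides |
| protraction speed | mean of positive first differences of the side mean, × fps, averaged over sides |
| retraction speed | mean magnitude of the negative differences, likewise |
| locomotion speed | mean centroid step length × fps ÷ px/mm (mm/s) |

For a pure sinusoid of peak-to-peak $A$, $\mathrm{SD} = (A/2)/\sqrt2$, so
the $2\sqrt2\cdot\mathrm{SD}$ estimator returns exactly $A$; and the mean
absolute angular velocity is $2Af$ — the closed forms the recovery tests
lean on. All SDs use the $n-1$ denominator; the spread estimator is a
plain sample SD over $\approx 6$ whiskers and therefore carries the
finite-sample shrinkage $c_4(n)$ (`c4_factor()`), which the tests account
for rather than "correct".

Two definitions in the source protocol are ambiguous and were resolved as
follows, both config-visible:

* **Asymmetry** ("difference in whisker angles between the left and right
  sides") is computed as the absolute difference of the clip-level side
  means, not frame-wise differencing — frame-wise absolute differences
  inflate under phase jitter between the sides.
* **Amplitude** is the one metric exempted from side-averaging; the two
  sides' per-frame means are pooled into a single SD, which equals the
  per-side value for symmetric whisking.

Retraction speed is reported as a positive magnitude so that "retraction
speed decreased" is monotone in the reported number. No temporal smoothing
is applied before differencing (none is described in the protocol).

## Segmentation and QC

Object-exploration clips are sectioned at the annotated contact frame:
PC = frames $[0, c)$, DC = $[c, \text{end})$. Both segments must
**strictly** exceed 0.2 s — at 500 fps that means at least 101 frames
each; a 100-frame segment (exactly 0.200 s) is rejected. PC−DC
differencing is implemented literally as stated (PC minus DC), which means
metrics that *rise* during contact (amplitude, asymmetry) produce
*negative* deltas; the protocol's accompanying intuition ("increases
during contact as positive") contradicts its own formula, and we follow
the formula while documenting the discrepancy here.

Automatable inclusion criteria: both whisker sides visible (≥ 1 tracked
whisker per side) in at least 90% of frames, and per-frame whisker counts
within the tracker's 2–12 band. The "level head" criterion needs manual 3D
review and is only honoured as a metadata pass-through. Zone occupancy
(middle / near-wall / around-object) is computed geometrically from the
centroid track with a 5 cm wall margin and a 5 cm object zone — the
original timings were scored manually, so these radii are package choices,
exposed in the arena config and recorded in output metadata.

## The generative model

The simulator is a phase-jittered sinusoid with additive per-whisker
offsets — the simplest process in which every metric above maps to one
closed-form parameter:

$$\theta^{\text{side}}_{t,w} = S \pm \tfrac\delta2
  + \tfrac A2 \sin\!\big(2\pi f t + \phi_0 + J_t\big) + c_w + \varepsilon_{t,w}$$

* $S$ — setpoint (default 100°), plus a per-mouse random intercept
  (SD 3°) shared across that mouse's clips;
* $A$ — peak-to-peak amplitude, 40°;
* $\delta$ — left-minus-right setpoint offset, 2°: left gets $+\delta/2$,
  right $-\delta/2$;
* $f$ — whisk frequency, drawn uniformly from the murine 12–25 Hz band;
* $J_t$ — Brownian phase drift (0.1 rad/√s): cycle-to-cycle frequency
  wander that leaves the velocity field smooth. (White per-frame phase
  noise would add ~10³ °/s of spurious velocity at 500 fps and drown the
  speed metrics.)
* $c_w$ — fixed per-clip whisker offsets, SD $\sigma_w = 5$°, centred
  within each side so that the side mean is exactly $S \pm \delta/2$:
  asymmetry is governed by $\delta$ alone and spread by $\sigma_w$ alone;
* $\varepsilon$ — per-frame tracking noise, SD 1°.

Clips are 1.6 s at 500 fps. The body centroid follows a smoothed-heading
random walk at the session's locomotion speed (150 mm/s baseline) with
billiard reflection at the walls of the 30 × 50 cm arena; the nose sits
35 mm ahead of the centroid, and for contact clips the path is shifted so
the nose grazes the object at the contact frame.

**Contact modulation.** From the contact frame on: $A \times 1.3$,
$\delta + 4°$, $\sigma_w \times 0.5$, $f \times 0.6$ (phase-continuous),
locomotion × 0.5. Because mean absolute angular velocity is $2Af$,
realising "amplitude up, speeds down" requires
$k_A k_f = 1.3 \times 0.6 = 0.78 < 1$.

**Habituation.** Sessions OF → H1 → H5 receive additive shifts
(setpoint −1.5°, −2.0°; spread −1.0°, −1.5°; locomotion −30, −50 mm/s),
with extra H5 decrements for Reeler animals (−1.0°, −0.5°, −10 mm/s) —
the genotype × session interaction. Magnitudes were chosen once to mirror
the reported qualitative picture: decreases of "a couple of degrees" in
angular position over habituation, strong enough that the multivariate
habituation effect lands in the large η²p band, while the genotype main
effect stays modest.

Cohorts default to the study design: 9 + 9 mice, two sexes, four ordinal
age bins spanning 2–8 months (four bins are implied by the reported age
numerator df of 3), three interneuron-reporter lines, 1–9 clips per mouse
per session.

**What the generator does *not* emulate** — and hence what passing
recovery tests do and do not show: real whisking has asymmetric
protraction/retraction waveforms, bout structure (whisking starts and
stops), amplitude–frequency covariation, head rotations that leak into
measured angles, tracking dropouts and mislabelled whiskers. Passing tests
show the *estimators and inference machinery* are correct under a process
with the right first- and second-order structure; they cannot certify
behaviour of the metrics under systematic tracking artefacts.

## Inference layer

Each clip contributes one observation; clips of one animal are not
independent, so every univariate model is
`metric ~ fixed effects + (1 | mouse_id)`, fitted by **REML** (the only
mode offered for models feeding Kenward-Roger tests). F-tests on fixed
effects use the Kenward-Roger small-sample approximation; the fractional
denominator df land between (number of animals − rank) and (number of
clips − rank). In a balanced between-mouse design KR reproduces the exact
mouse-level ANOVA — df2 = n(mice) − parameters — and it does so for *any*
variance ratio, including a singular zero mouse-variance fit; KR is an
exactness-preserving adjustment, not an interpolation in the estimated
variance ratio.

The MANOVA uses the Pillai trace with approximate F; partial eta-squared
is Pillai$/s$ with $s = \min(\text{df}_h, p)$, banded lower-inclusively at
0.01 (small), 0.06 (medium), 0.14 (large). Classical MANOVA has no random
effect, so the "mouse as random effect" phrasing of the source analysis
cannot be reproduced exactly with unknown software; we run the MANOVA at
clip level with the animal recorded, and offer a conservative mouse-mean
aggregation mode (`manova_aggregate: mouse`).

Post hoc pairwise session contrasts use estimated marginal means with
**Tukey** adjustment (the standard default for all-pairs families;
switchable to none/Bonferroni) and Kenward-Roger df, since the original
adjustment is unstated. Zone timings come as percentages of session time
(one overhead video per session); the Pearson χ² test is applied to the
percentage table exactly as in the original procedure, with an explicit
warning that percentages are not counts, and accepts count tables when
available. Residual normality is reported (Shapiro-Wilk + QQ straightness)
but never gates the pipeline. No multiple-testing correction is applied
across the seven univariate models, matching the original analysis.

## Numerical choices

* Frames are 0-based everywhere; time of frame $k$ is $k/\text{fps}$ s.
* Angles cross every interface in degrees; radians never do.
* The ">0.2 s" rule is a strict inequality evaluated in frames.
* Spectral frequency estimates take the periodogram argmax after mean
  removal, refined by quadratic interpolation of log-power across the peak
  bin (sub-bin resolution for near-sinusoidal traces); a peak/median power
  ratio below 15 flags the estimate unreliable (white noise reaches ~10).
* A side with no positive (negative) velocities yields a missing
  protraction (retraction) speed plus a flag — missing, never zero.
* Degenerate inputs: constant responses produce a flagged boundary fit
  with undefined F-tests; aliased fixed effects error naming the terms;
  single-frame segments error.
* Determinism: every stochastic routine takes a seed and restores the
  caller's RNG state; identical seeds give bit-identical output.

## Problem sizes in the test-suite

The suite validates statistical calibration by simulation at sizes chosen
to keep the full run around a minute: type-I error of the genotype KR test
from 500 replicates of the 9 + 9 × 5-clip null design (metric-level
generator); habituation-shift recovery, CI coverage and post hoc ordering
from 200 replicates; contact-effect directions from 200 simulated contact
clips; spread/c4 recovery from 100 clips. Trace-level pipeline tests use
small cohorts (3–4 mice per genotype, 0.3–1.6 s clips).

## Limitations

* Contact frames are annotations (simulator or metadata); no contact
  detection from whisker shape is attempted.
* Only a single mouse-level random intercept is supported — no crossed or
  nested structures, no random slopes, no Bayesian estimation.
* Whisk-cycle structure beyond the sign-of-velocity rule (bout
  segmentation, phase estimation) is out of scope.
* The zone geometry automates what was manually scored; absolute zone
  percentages depend on the configured margins.
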