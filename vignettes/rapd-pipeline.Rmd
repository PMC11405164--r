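---
title: "Quantifying relative afferent pupillary defect from binocular pupillometry"
author: "pupilrapd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying relative afferent pupillary defect from binocular pupillometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilrapd)
```

## The problem

A relative afferent pupillary defect (RAPD) is an interocular asymmetry in
the afferent drive to the pupillary light reflex and a hallmark of
unilateral optic neuropathy. Clinically it is elicited with the swinging
flashlight test: the two eyes are stimulated alternately and the examiner
judges which eye produces the weaker direct constriction. That judgement is
subjective; automated binocular pupillometry replaces it with a measured
ratio. `pupilrapd` implements the complete computational chain for such a
device — stimulus timeline, trace cleaning, reflex extraction, efferent
screening, RAPD scoring and diagnostic-accuracy evaluation — together with
a physiologically structured simulator that provides ground truth for
end-to-end validation.

## Stimulation protocol

`default_timeline()` encodes the automated swinging-flashlight sequence:
5 s of darkness for dark adaptation, a 1 s binocular conditioning pulse
followed by 3 s of darkness, then three cycles of monocular stimulation in
which each pulse is 1 s of 125 lux followed by 3 s of darkness, the left
eye always first — 33 s in total, sampled at the eye tracker's 90 Hz.

```{r}
tl <- default_timeline()
tl
```

The published description of the cycle order is compatible with either
per-cycle alternation (L, R, L, R, L, R) or a blocked order
(L, L, L, R, R, R). We default to alternation — the swinging-flashlight
convention — and expose `cycle_order = "blocked"`; total duration and all
derived quantities are identical either way. Time is measured in seconds
from recording start, intervals are half-open `[start, end)`, and sample
`i` (0-based) covers time `i / rate`. No extra darkness is inserted between
the left- and right-eye profiles.

## Preprocessing

Raw tracker output contains blink dropouts and spurious extreme diameters.
The cleaning chain is:

1. **Diameter cutoffs** (`flag_artifacts()`): samples below 1 mm or above
   9 mm are physiologically implausible (blinks, partial lid closure, large
   eye movements) and are marked missing, per eye independently.
2. **Gap interpolation** (`interpolate_gaps()`): interior missing runs of
   at most 90 samples (1 s at 90 Hz) are bridged by shape-preserving
   piecewise cubic Hermite (PCHIP) interpolation through the surrounding
   valid samples. PCHIP reproduces its knots exactly, is exact on linear
   segments and never overshoots a monotone bracket — the property that
   makes it safe inside a constriction flank. Leading and trailing runs
   have no bracketing knot on one side and are filled by nearest-valid
   constant extension rather than extrapolation, which could fabricate
   trends. Any longer run fails the quality gate: the trace is returned
   untouched, flagged for a repeat measurement. The 90-sample limit is a
   hard threshold; exactly 90 missing samples still pass.
3. **Smoothing** (`smooth_trace()`): a 100-sample running mean. We use a
   centred (zero-phase) window so reflex timing is unbiased; the window is
   truncated symmetrically at the trace edges. With an even window the
   extra sample is taken on the causal side.

The device's published description lists smoothing before cutoff exclusion
and interpolation. A running mean applied across a blink spike smears the
artifact into its neighbours before the cutoffs can catch it, so the
package default is cutoffs → interpolation → smoothing; the literal
published order remains available as `published_order = TRUE` in
`preprocess_trace()`. On an artifact-free trace the two pipelines coincide
with plain smoothing.

## Reflex extraction and the RAPD score

For every light pulse and each responding eye, `measure_epoch()` takes the
baseline as the mean diameter over a 0.5 s baseline window and the trough
as the minimum over a 2.5 s response window starting at pulse onset, and
reports the constriction as a percentage of baseline. The trough operator
(rather than the value at light-off) is the standard pupillary-reflex
amplitude and is robust to latency variation. A 2.5 s response window
always contains the trough of a reflex with typical (~0.25 s) latency.
Negative constrictions (net dilation) are floored at zero — keeping the
downstream ratio defined — and recorded via the `dilated` flag.

Two baseline conventions are implemented. The pipeline default anchors
every pulse's baseline to the *dark-adapted state* (the end of the initial
5 s dark epoch), which is the quantity the constriction percentages are
defined against. The alternative (`baseline_mode = "preceding"`) re-reads
the baseline from the dark epoch immediately before each pulse; it tracks
slow drift but, with only 3 s of darkness between pulses and redilation
time constants around 1.5 s, that window still contains residual
constriction from the previous pulse, which biases interocular ratios away
from unity. The adaptation anchor avoids this entirely.

One further numerical detail: the zero-phase smoother draws on samples up
to half a window (~0.56 s at the defaults) *ahead* of each output sample,
so the last half-window of a dark epoch on the smoothed trace already
carries stimulus-locked constriction. The pipeline therefore backs the
baseline window off the pulse onset by the filter half-width
(`baseline_margin_s`, default derived from the smoothing window). Without
the margin, recovered interocular ratios err by several percent at strong
defects.

Per (stimulated eye, responding eye) pair the three per-cycle percentages
are averaged (`aggregate = "median"` is available for robustness). Direct
responses have stimulated = responding eye; consensual responses are the
fellow eye's. The binocular conditioning pulse serves light adaptation and
is excluded from scoring.

**Efferent screen.** An afferent (optic-nerve) defect weakens *both*
pupils' responses when the affected eye is stimulated; an efferent (motor)
defect weakens *one pupil* regardless of stimulation side. Because the
RAPD ratio is only meaningful for afferent asymmetry,
`detect_efferent_defect()` compares the two pupils' constrictions within
each stimulation side and raises a flag only when the same pupil is the
weaker responder on both sides with both within-side ratios above 1.25.
The 1.25 default sits above the noise-level asymmetry of healthy pupils
yet well below the twofold asymmetry of a clear motor defect; the rule is
invariant to uniform scaling of all responses, and a non-reactive pupil
(zero constriction) always trips it. The published device screens for
efferent defects without stating its criterion, so this rule is the
package's documented surrogate. Flagged recordings are not scored.

**Score.** The two-tailed score is the ratio of right- to left-eye mean
direct constriction (OD/OS). The one-tailed score folds it about unity —
stronger eye over weaker eye — so it is always ≥ 1, with the weaker eye
reported separately; this makes the score distribution one-tailed and the
classifier threshold one-sided. (The alternative convention, affected over
non-affected, cannot be "always greater than unity" and is not used.) When
the clinically affected eye and the measured weaker eye could disagree,
the measured weaker eye defines the denominator.

## Diagnostic evaluation

`roc_curve()` sweeps thresholds over the distinct observed scores (plus
infinite sentinels) with the rule *score ≥ threshold → RAPD-positive*;
higher scores are always worse. `auroc()` integrates the polyline by
trapezoids, which equals the rank (pair-counting) estimator exactly — a
dual-route identity the test suite asserts to 1e-12 and cross-checks
against an independent ROC implementation. `youden_cutoff()` maximizes
J = sensitivity + specificity − 1, breaking ties toward the smallest
threshold (higher sensitivity), since a missed RAPD is clinically costlier
than a false positive; the tie rule is configurable.
`classification_metrics()` reports sensitivity, specificity, accuracy and
precision as percentages and the Matthews correlation coefficient; any
zero-denominator metric is 0 by convention and flagged.

Two confirmatory re-analyses are provided. `stratify_by_grade()` splits
cases into mild (Bell grades 1–2) and ≥ moderate (grades ≥ 3), pairing
each stratum with a seeded random control subsample of matching size
(without replacement). `reorganize_low_scores()` addresses clinical
over-diagnosis: physiological pupillomotor asymmetry of up to ~20% exists
in healthy individuals, so cases scoring at or below the 25th percentile
of the case cohort (linear-interpolation quantile, type 7) are shuffled
with the seeded generator and half (rounding down) are relabelled as
controls; "equally distributed" is implemented as this half-split rather
than per-record coin flips. `evaluate_cohort()` assembles the standard
four-row report: overall, mild, ≥ moderate, reorganized.

## The simulator

`simulate_subject()` generates binocular traces with the statistical
structure the analysis assumes:

* **Reflex kernel** (`plr_kernel()`): zero during the latency, a
  saturating exponential rise with time constant `tau_constrict_s` while
  the drive lasts (pulse + latency), then exponential redilation with
  `tau_redilate_s`; continuous everywhere.
* **Gain model**: pupil diameter is
  `baseline × (1 − afferent × efferent × A0 × drive)`, where the drive at
  any instant is the largest of the active per-pulse kernels and the
  binocular pulse contributes the larger of the two afferent gains. The
  multiplicative form gives the score a closed-form ground truth,
  `1/afferent_gain` of the affected eye — a saturating nonlinearity would
  break that testability. The max-combination rule only matters where
  kernels overlap (residual redilation into the next pulse).
* **Nuisances**: a bilateral hippus sinusoid (0.1 mm, 0.2 Hz, seeded
  random phase), independent Gaussian sensor noise (SD 0.05 mm),
  bilateral Poisson blink dropouts (0.1 Hz, 0.2 s) mirroring tracker
  behaviour, and optional extreme-value spikes (0.5/9.5 mm) to exercise
  the cutoff filter.

Defaults: dark-adapted diameter 6 mm; maximal constriction fraction
A0 = 0.38, matching the mean direct constriction of healthy controls at
this stimulus intensity; latency 0.25 s; time constants 0.35 s and 1.5 s.

`simulate_cohort()` draws labelled cohorts (defaults 77 cases, 77
controls, mirroring the study design). Cases receive one affected eye
(uniform) with an afferent gain from a severity band — mild: gain in
[0.55, 0.85]; ≥ moderate: [0.2, 0.55]; mixing 50:27 — so implied true
scores span ~1.2–5. No quantitative Bell-grade-to-gain calibration exists,
so these bands are the package's own construction, chosen to place mild
cases near the physiological boundary and moderate ones clearly beyond it.
Controls carry only physiological asymmetry: interocular gain ratio
uniform in [1, 1.2]. Nuisance parameters are jittered per subject
(baseline 5.5–6.5 mm, A0 ≈ N(0.38, 0.03), latency 0.2–0.3 s). Everything
derives from one master seed.

**What the simulator does and does not emulate.** It reproduces the
protocol timing, reflex kinetics, gain structure, hippus, dropout and
noise characteristics the analysis chain relies on — so passing tests
demonstrate that the chain recovers known ground truth under realistic
signal structure. It does not emulate gaze-dependent measurement error,
fatigue or adaptation drift across the recording, inter-subject kinetic
correlations, light-intensity dose–response, or the clinical-grading noise
of real cohorts; simulated case/control separation is therefore cleaner
than clinical data, and simulated diagnostic accuracy characterizes the
pipeline, not the device's clinical performance.

## Validation set-up

The test suite checks every operation against independent oracles
(brute-force pair counting for AUROC, an explicit sliding-mean loop for
the smoother, closed forms for the kernel and metrics) and asserts the
pipeline-level properties: noiseless score recovery within 2% of
`1/gain` over gains 0.3–0.9; median relative score error under 10% across
200 subjects at default noise; one-tailedness of every emitted score over
a 500-subject noisy cohort; zero efferent false flags over 100 noiseless
afferent deficits; and reallocation seed stability (AUROC range across 20
seeds below 5 percentage points on a 77 + 77 cohort). The bundled
acceptance script recomputes the same quantities from scratch at those
problem sizes.

## Known limitations

* The efferent-screen criterion and threshold are surrogates; a device
  with a stated criterion should override `efferent_ratio`.
* Constriction flooring at 0 means a paradoxically dilating eye yields an
  unscorable (not negative) result.
* The quality gate is binary and global per eye; partial recordings are
  never salvaged.
* Latency, peak velocity, redilation dynamics and post-illumination
  responses are out of scope.
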