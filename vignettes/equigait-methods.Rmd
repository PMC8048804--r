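---
title: "Quantifying equine forelimb lameness on the treadmill: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying equine forelimb lameness on the treadmill: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equigait)
```

## The problem

When a horse is lame on one forelimb it redistributes load and retimes its
footfalls. At the trot these adaptations are well characterised — the lame
limb's peak vertical force and vertical impulse drop sharply, and the head
"nods" once per stride — but at the walk, a four-beat gait with alternating
bipedal and tripedal support and no suspension, the changes are subtler and
spread across many temporal, kinetic and kinematic variables.

`equigait` implements a complete analysis pipeline for treadmill recordings
of this kind: per-limb vertical ground reaction force (GRFz) traces sampled
at 512 Hz and 3-D optical motion-capture (OMC) marker trajectories at
256 Hz, collected in ~20 s trials at the horse's preferred belt speed
(walk ≈ 1.57–1.79 m/s, trot ≈ 3.78–3.94 m/s). Because raw recordings of
this kind are rarely public, the package also contains a synthetic trial
generator that emulates the study design closely enough that every stage of
the pipeline — event detection, stride parameter extraction, per-horse
discrimination, mixed-model inference — is testable end to end against
known ground truth.

## Gait events and stride segmentation

Hoof-on and hoof-off are detected from each limb's force trace alone. After
subtracting the swing-phase baseline (the median of sub-threshold samples),
above-threshold runs (default 50 N, with a 200 N minimum-peak requirement
that rejects noise excursions) are candidate stances. Within each
candidate, a least-squares line through the rising flank between 20% and
80% of the first local force maximum is extrapolated to the zero baseline
to give hoof-on; the falling flank of the last maximum gives hoof-off
symmetrically. Events are therefore real-valued times that may fall between
samples — important because the 512 Hz sampling quantum (≈2 ms) is of the
same order as some of the temporal effects of interest. Stances shorter
than 100 ms are discarded, and overlapping detections resolve in favour of
the stronger stance. All thresholds are `eq_config()` keys.

Strides run from each left-fore hoof-on to the next. Within a stride the
pipeline computes stride duration (SD), absolute and relative stance
durations per limb (StD_abs, StD_rel — the duty factor), the ipsilateral
step duration StpDi (hind hoof-on to the following same-side fore hoof-on),
the contralateral step duration StpDc (fore hoof-on to the following
contralateral fore hoof-on; half a stride in an evenly timed walk), and the
diagonal dissociation TAP, defined here as the fore-minus-hind contact time
within a diagonal pair so that landing forelimb-first is negative. Support
phases are labelled by the instantaneous set of limbs in stance; the sound
walk cycles through eight phases (tripedal and bipedal alternating), and
the labelled intervals tile each stride exactly.

## Kinetics

Forces are normalised to body mass. At walk the two largest local maxima of
the 30 Hz zero-lag-smoothed curve give the two force peaks in stance order,
with the minimum between them as the dip; at trot there is a single peak.
Peak values and times are refined by a quadratic fit over ±8 samples of the
raw trace around the located maximum. The vertical impulse Iz is the
trapezoidal integral of normalised force over the stance window clipped at
the sub-sample event times. Loading and unloading rates are least-squares
chord slopes over the 20–80% rising and falling flanks, and the first-peak
time t_Fz_peak1 is expressed as a percentage of stance (the relative-timing
reading of the reported peak-delay effect; the stride-relative reading is
recoverable from StD_rel).

## Upper-body symmetry and limb kinematics

Vertical displacement of the poll and withers is modelled (and extracted)
per stride. Each stride is split into two half-cycles at the two forelimb
hoof-on events; within the stride the two half-cycle minima and the two
intervening maxima (one wrapping the stride boundary) define

* `MinDiff` — right-half minimum minus left-half minimum,
* `RUD` — difference of the two upward ranges (minimum to following
  maximum),
* `RDD` — difference of the two downward ranges,
* `ROMz` — global range of motion.

The exact upward/downward pairing conventions follow common usage in the
equine movement-symmetry literature and are isolated in
`vertical_symmetry()` so an alternative convention is a one-function
substitution. Upper-body signals are low-passed at 8 Hz (zero lag) before
extremum extraction and each extremum is refined by a local quadratic fit;
without this, the max/min of a noisy sampled signal is biased outward by
the measurement noise, which distorts range-of-motion ratios by about a
percentage point at the 1 mm noise level.

Limb kinematics use a minimal marker set per limb (hoof, fetlock,
carpus/tarsus, upper-limb pivot). The protraction/retraction angle is the
signed sagittal angle of the pivot-to-hoof segment from the vertical
(cranial positive); fetlock hyperextension is 180° minus the vertex angle
at the fetlock marker, maximised over stance; stance length StL is the
cranio-caudal hoof travel between the interpolated event positions;
and Prot_speed is the maximal resultant hoof speed during swing from
central differences at the marker rate, unsmoothed (a config key can
enable filtering).

## Centre of force and centre of mass

The trunk centre of mass is proxied as `w·sternum + (1−w)·L3` with
`w = 0.6` toward the sternum; the full segmental model behind this style of
proxy is not reproduced here, and `w` is an exposed, documented
approximation. The centre of force is the force-weighted mean of the hoof
ground positions over the four limbs, computed at the force rate after
linear resampling of the marker data; it is undefined during trot
suspension and always lies in the convex hull of the supporting hooves.
Per stride the pipeline reports COM translation ranges per axis and, for
each body side, the maximal cranial COF−COM displacement during the
transition from tripedal support into that side's ipsilateral bipedal
support (walk phases 1→2 on the left, 5→6 on the right), with the side
windows defined by the phase labels rather than fixed stride percentages so
they track timing changes under lameness. The side asymmetry
(lame-side maximum minus sound-side maximum) is this package's numeric
operationalisation of an effect that has so far been described only by
visual inspection of the butterfly-shaped COF−COM path; it has no
published reference value.

## Discrimination and inference

For every horse × variable, stride-level baseline and lame values are
classified by the cutoff (midpoints of sorted pooled values, both
directions) that maximises Youden's J = sensitivity + specificity − 1,
with ties broken toward the pooled median and then toward direction
"greater". The search is exhaustive-equivalent (property-tested against a
brute-force oracle and against pROC). Group-level summaries are medians of
per-horse sensitivity, specificity and J, ranked by median J — the tabular
equivalent of the dot heat maps used to visualise individual compensation
strategies. Right-side inductions are mirrored: signed symmetry indices are
negated and limb-suffixed variables are relabelled to roles (lame, contra,
ipsi, diag).

Group comparison fits, per variable and gait separately,

```
value ~ condition + (1 | horse)
```

by REML with a Satterthwaite p-value for the condition effect (lme4 /
lmerTest). Least-square means of the two conditions are the fixed-effect
predictions — identical to `emmeans` output for this one-factor design,
which a unit test verifies. Percent change is computed from the LS means.
p-values are Bonferroni-adjusted with m = the number of variables actually
modelled within the gait; significance is 0.05. Horses lacking one
condition are excluded from that model; singular fits fall back to a
flagged pooled comparison.

## The synthetic generator

The generator is first-class, tested code, not a fixture. Its defaults are
the study conditions: 10 horses, 20 s trials, 512/256 Hz, walk speeds
1.57–1.79 m/s with stride durations 1.18–1.32 s (≈14–16 usable strides,
matching the reported 14.6 average), trot speeds 3.78–3.94 m/s with stride
durations 0.74–0.82 s (≈23–26 strides, matching the reported average of
24). Body mass is drawn from 470–620 kg.

**Force waveforms.** Walk stances are continuously differentiable
piecewise-quadratic curves through (0,0), (t_peak1, peak1), (t_dip, dip),
(t_peak2, peak2), (1,0): parabolic caps of half-width 5% of stance around
the peaks and dip, joined by common tangent lines. This family was chosen
over a monotone cubic spline for two numerical reasons: the flanks are
exactly straight (measured GRFz curves rise almost linearly, and the
chord-intersection event detector is then unbiased), and the peaks are
exactly parabolic so quadratic peak refinement is exact rather than
shape-dependent. Trot stances are `peak·sin(πs)^q` with default
`q = 1.15`, near which the least-squares 20–80% chord extrapolates to the
true onset with sub-millisecond bias. Default amplitudes (walk fore
6.3/4.5/6.6 N/kg, trot fore 11 N/kg, hind scaled ×0.8) are stand-ins for
unavailable reference tables and are finally calibrated by a global factor
so that the summed per-stride vertical impulse equals `g·SD` exactly —
over whole steady-state strides the mean total normalised force is
9.81 N/kg.

**Footfalls.** Walk uses the lateral sequence (relative to the left fore:
LF 0, RH 0.25, RF 0.5, LH 0.75) with duty factor 0.625, which produces the
eight-phase support sequence at 12.5% each in the ideal case; trot uses
diagonal pairs at phases 0 and 0.5 with duty 0.45 and configurable
diagonal dissociation.

**Upper body and limbs.** Landmark heights follow
`mean + a2·sin(4πt/SD + φ2) + a1·sin(2πt/SD + φ1)`: a symmetric
twice-per-stride harmonic plus a once-per-stride asymmetry that is zero at
baseline. Phases are φ2 = π/2, φ1 = 0, which places one minimum inside
each half-cycle and makes MinDiff first-order in a1. Hooves track the belt
exactly during stance (so StL = belt speed × stance duration) and swing
forward along a `sin^p` speed profile with a `sin²` height bump; the
fetlock hyperextension angle is driven proportional to the limb's
normalised force (default gain 3° per N/kg), so its maximum is the gain
times the peak force.

**Noise model.** Additive Gaussian measurement noise (defaults:
0.05 N/kg on forces, clamped non-negative; 1 mm on markers) plus
multiplicative stride-to-stride jitter with CV 2% applied to stride
duration, duty factor, loading amplitude, the stance shape's internal
timing/shape parameters and the upper-body amplitudes. The jitter CV is
deliberately applied to *all* timing/shape parameters: leaving any of them
deterministic makes the corresponding extracted variable discriminate
perfectly (J = 1) for arbitrarily small effects, which no real recording
would show.

## Lameness effect profiles

A `lameness_profile()` is a set of multiplicative factors on *extracted*
parameters, keyed by limb role relative to the lame limb, plus additive
head/withers asymmetry injections, a diagonal-dissociation shift and COM
amplitude factors. The `walk_moderate` and `trot_moderate` presets encode
the group-level percentage changes reported for moderate sole-pressure
forelimb lameness (for example lame-fore Iz ×0.949 at walk and ×0.857 at
trot, lame-fore peak force ×0.823 at trot, first-peak delay ×1.084 at walk,
contralateral loading rate ×1.165, head ROMz ×1.505 at trot).

The generator *inverts the extraction relation* so the targets are met on
the extracted scale: the walk dip is solved (1-D root find) so the stance
integral hits the Iz target after the peak and duration targets are
applied; the trot exponent q is solved likewise; the swing-profile exponent
is solved for the Prot_speed target; the fetlock gain for the A_fetlock
target; the stance-window position for the protraction target; and the
once-per-stride poll amplitude for a trot ROMz target. Where the geometry
is over-determined (protraction, retraction and slip-free stance length
share two degrees of freedom) protraction and StL are honoured exactly and
retraction is emergent — the reported walk values are mutually consistent
with slip-free geometry to within 0.1%, so the emergent retraction change
lands on the reported −2.6% almost exactly.

Effects reported only directionally (walk stance-duration reductions,
ipsilateral-hind impulse reduction, contralateral peak increases at walk,
the trot impulse redistribution to the contralateral fore and diagonal
hind, COM translation changes, the walk head-nod amplitude) are encoded
with small fixed values chosen once to respect total weight support
(Σ Iz ≈ g·SD under lameness to within ~2%) and the reported directions:
e.g. walk ipsilateral-hind Iz ×0.98, contralateral fore peaks ×1.02, poll
a1 injection 8 mm and withers 2 mm at walk, trot contralateral-fore Iz
×1.07 with ipsilateral hind ×0.98 and diagonal hind ×1.03. They are
documented here precisely because they are choices, not reported numbers.

## What passing tests do and do not show

The generator reproduces the *parametric structure* of lame treadmill
locomotion — waveform shapes, footfall timing, symmetry indices, effect
sizes, stride-to-stride variability and sensor noise — and the end-to-end
test suite verifies that the pipeline recovers the encoded group effects to
within a percentage point (walk, with noise) or 1.5 points (trot) at the
study's cohort size, that event detection matches ground truth to ≤2 ms,
and that identity-profile cohorts produce null-level discrimination
(median optimal-cutoff J ≤ 0.25, which for ~24 strides per condition is
the null median of the equivalent two-sample KS statistic) and ≤5%
Bonferroni-significant variables. None of this shows that the pipeline
handles features absent from the generator: soft-tissue marker artefacts,
belt-speed drift, partial occlusions, non-stationary lameness within a
trial, or waveform shapes outside the two parametric families. Curve
shapes are deliberately not claimed to be subject-faithful.

## Numerical choices and degenerate inputs

* Real-valued event times; all durations from events, never sample
  indices.
* Walk stances with fewer than two local maxima are flagged monophasic
  (second peak and dip missing) rather than dropped silently.
* Stride windows with a missing or duplicated limb event are excluded.
* Monotone half-cycles (no interior extremum) flag the symmetry record.
* COF frames with zero total force are missing, not zero.
* Collinear fetlock markers give 0° hyperextension; coincident markers are
  an error.
* Ties in the Youden search break toward the pooled median, then toward
  direction "greater"; left wins exact ties in induction-side selection.
* The problem sizes used in the test suite (cohorts of 10 horses with 15
  walk / 20 trot strides per condition; 20 identity-profile cohorts with
  force-only extraction for the null checks) match the study scale while
  keeping the default run reproducible in a few minutes.

## Known limitations

The COM proxy ignores limb segments; the COF asymmetry metric is this
package's own operationalisation without a published reference value; the
marker set is minimal (no pelvis/croup symmetry); horizontal forces are
not modelled (the instrumented treadmill measures only GRFz); and
stride-level mixed models assume independent stride residuals within
horse × condition, ignoring serial correlation along a trial.
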