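---
title: "Breath-by-breath monitoring of acute pulmonary edema: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath-by-breath monitoring of acute pulmonary edema: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathEIT)
```

## The problem

Acute pulmonary edema develops over seconds to minutes. Three bedside
modalities can follow it breath by breath: electrical impedance
tomography (EIT), which images regional ventilation as cross-sectional
impedance change; volumetric capnography (VCap), which plots expired
CO~2~ tension against expired volume; and spirometry, which yields
global respiratory mechanics. `breathEIT` implements the complete
analysis chain for synchronized recordings of all three in a
mechanically ventilated, prone subject — segmentation, synchronization,
per-breath feature extraction, and per-breath statistical comparison to
baseline — together with a parametric cohort simulator that generates
full virtual experiments with known ground truth.

The experiment the simulator emulates is an edemagenic challenge in
anesthetized sheep: volume-controlled ventilation at 10 mL/kg and 10
breaths/min with zero PEEP, EIT at 47 frames/s on a 32 x 32 grid,
airway signals at 100 Hz, a 10-s apnea for retrospective
synchronization, 60 s of baseline, a 60-s intravenous injection
starting at t = 0, and continued recording afterwards. Statistics
compare each post-start breath (one every 6 s, 21 in the 0–120 s
window) against the pooled baseline breaths.

## EIT variables

All impedance quantities are in arbitrary units (AU) on the global
lung-region signal, the per-frame sum of pixel values inside the lung
mask. Per breath:

* **EELI** — the global signal at the start-of-inspiration frame; the
  impedance of the chest before the breath, a surrogate for functional
  residual capacity.
* **TIV** — the rise of the global signal from start to end of
  inspiration; a surrogate for tidal volume.
* **CoV~VD~, CoV~RL~** — the impedance-weighted centroid of the tidal
  image (the end-inspiratory minus start-inspiratory frame difference,
  negative pixels clipped to zero), expressed as a percentage of the
  lung-region bounding extent: 0% most ventral (or subject's right),
  100% most dorsal (or left). The extent is the mask's bounding box,
  not the full image, so the centroid is a property of the lung region.
  A single-row extent maps to 50% rather than dividing by zero.
* **Silent spaces** — mask pixels whose tidal impedance change is
  *strictly* below 10% of the maximum over the mask. They are split at
  the horizontal plane through the CoV~VD~ height: dorsal pixels form
  the non-dependent silent space (NSS), ventral pixels (and pixels
  exactly on the plane) the dependent silent space (DSS) — the animal
  is prone, so ventral is dependent. Both are percentages of the total
  lung pixel count. The split rule at the CoV plane is the only choice
  consistent with the centroid definition; the threshold uses the
  strict global pixel maximum (a robust percentile is a possible
  alternative, flagged for sensitivity analysis).
* **Band fractions** ΔZ~V~, ΔZ~CV~, ΔZ~CD~, ΔZ~D~ — the
  ventro-dorsal extent is cut into four equal-width bands; each value is
  the band's share of total clipped tidal impedance change (pixels are
  assigned to the band containing their center). The four values sum to
  100%.

Two design choices deserve emphasis. Negative tidal-image pixels are
clipped before all ventilation measures because out-of-phase pixels
would otherwise corrupt centroids; TIV itself is read off the global
curve, so it uses the unclipped sum. And the tidal image is the simple
endpoint frame difference rather than a per-pixel regression over the
breath — the simplest reading of "from the beginning to the end of
inspiration"; the regression alternative is noted but not implemented.

Breath landmarks on the EIT clock are found from the global signal: the
start-of-inspiration frame is its minimum within ±0.5 s of the
flow-derived inspiration start, the end-of-inspiration frame its
maximum within the breath; ties take the earliest frame. A negative TIV
flags the breath incomplete rather than silently dropping it.

## Volumetric capnography

The expirogram is built per breath by cumulative trapezoidal
integration of the negated expiratory flow, resampled onto a uniform
1-mL grid. From it:

* Phase III slope (S~III~) — least squares over the 60–90%
  expired-volume window; its intercept at volume 0 is Y~int~.
* Airway dead space (VD~aw~) — the expired volume at the inflection
  point, located as the maximum of the smoothed derivative dPCO~2~/dV;
  alveolar tidal volume is the remainder. The equal-area construction
  is an equivalent alternative for symmetric phase II transitions.
* Phase II slope (S~II~) — the tangent at the inflection, capped for
  near-vertical (square-wave) transitions; X~int~ is where that tangent
  crosses zero.
* The alpha angle — 180° minus the angle between the two fitted lines
  in normalized coordinates (volume scaled by VT, CO~2~ by the
  end-tidal value). Identical lines give 180°; under this convention
  the angle *rises* toward 180° as S~III~ steepens or S~II~ flattens,
  matching the airway-narrowing direction reported clinically.
* Gas exchange — CO~2~ elimination per breath VCO~2~br = ∫ FCO~2~ dV
  with the dry-gas conversion FCO~2~ = PCO~2~/(P~b~ − P~H2O~)
  (defaults 760 and 47 mmHg, configurable for altitude); mixed-expired
  tension PĒCO~2~ = (1/VT)∫ PCO~2~ dV; mean alveolar tension PACO~2~
  from the phase III line at the window midpoint; Bohr dead-space ratio
  VD~Bohr~ = (PACO~2~ − PĒCO~2~)/PACO~2~; alveolar dead space
  VD~alv~ = VD~Bohr~·VT − VD~aw~. VCO~2~br is reported at measurement
  conditions (no STPD correction).

**Numerical choice — adaptive smoothing.** The derivative is smoothed
with a moving window of at least 5 mL, widened automatically to the
coarsest raw volume step of the expirogram. During fast passive
expiration a 100-Hz acquisition moves ~20 mL between samples across
phase II; with a fixed 5-mL window the derivative of the interpolated
curve is piecewise constant over such segments and its maximum can sit
anywhere within one, giving dead-space errors of several percent. The
widened window restores sub-sample localization (±1 mL on noise-free
sigmoidal transitions).

## Respiratory mechanics

Per breath: inspired/expired tidal volumes (trapezoidal flow
integrals), PIP (maximum airway pressure before expiratory flow),
plateau pressure (mean over the zero-flow end-inspiratory pause,
missing when no pause exists), PEEP (mean pressure over the final 10%
of expiration), peak expiratory flow, and:

* Raw = (PIP − P~plat~) / mean inspiratory flow. The classic bedside
  phrasing inverts this quotient; only this orientation has resistance
  units, so it is the default, with `literalRaw = TRUE` reproducing the
  literal wording for comparison. The mean inspiratory flow is taken
  over the central 5–95% of the constant-flow segment.
* C~dyn~ = VT / (PIP − PEEP), reading the "peak expiratory pressure" of
  the bedside formula as the measured end-expiratory pressure — the
  only reading that makes the quotient a compliance. Note that this
  dynamic compliance includes the resistive pressure component, so it
  is systematically below the single-compartment compliance; the
  simulator's ground-truth tables record the dynamic value the formula
  defines.

## Breath segmentation, synchronization, quality control

Inspiration starts at a positive flow-threshold crossing (default
0.02 L/s, held for 50 ms of hysteresis — robust to the configured noise
floor) and ends at the last positive-flow sample before sustained
non-positive flow; expiration runs to the next inspiration start.
Synchronization uses the pre-recording apnea: the longest quiescent
window in each modality (|flow| below threshold; EIT global signal flat
to 0.1% of its range) ends at the common sync point, and airway time
maps to frame index linearly from there. Two QC rules flag breaths for
exclusion: a leak flag when inspired and expired VT differ by more than
10% of the first breath's expired volume, and a spontaneous-effort flag
when airway pressure drops more than 2 cmH2O below PEEP — an
automatable replacement for retrospective visual curve inspection.

## Statistics

Per-breath values are expressed as a percentage of the subject's
baseline (the mean over its unflagged breaths in [−60, 0) s; at least
3 required). For each variable one linear mixed-effects model (REML,
`lme4`/`lmerTest`) is fitted on the normalized values with subject as
random intercept and breath time as a categorical fixed effect — all
baseline breaths pooled as the reference level plus one level per
post-start breath in the 0–120 s window. Each post-start level is
tested against baseline (Wald contrast, Satterthwaite degrees of
freedom) and Bonferroni-corrected by m, the *actual* number of
post-start breaths in the window (21 at 6-s spacing; m is returned in
the results). Breaths are matched across subjects by ordinal, which is
equivalent to clock time under a fixed ventilator rate. If the model
cannot be fitted at all the procedure falls back to per-breath
one-sample t-tests against 100% with a warning. The first significant
breath per variable is reported without a persistence requirement by
default; `requirePersistence = TRUE` adds a two-consecutive-breath rule
for sensitivity.

## The synthetic cohort

The simulator generates, per subject, the full synchronized recording:
EIT frames from the apnea onward, airway signals on the same clock, the
event log, and a ground-truth table for every breath.

**Lung mask.** Two elliptical lobes joined by a thin central bridge
(connected, left–right symmetric, ~40% of the 32 x 32 grid),
deterministic for fixed geometry. It stands in for a subject-specific
anatomical model; it is not an anatomically realistic thorax.

**Ventilation field.** Per breath, a per-pixel tidal field is
constructed to carry the requested features exactly: band sums are set
first and held exact; the ventro-dorsal centroid is met by an
exponential tilt of within-band pixel weights (renormalized per band),
solved by a monotone root search, and the right–left centroid by an
analogous per-row column tilt; the silent-space ground truth is
realized as zero-change pixels spread evenly across the rows on either
side of the CoV plane. Requests beyond the attainable centroid range
(e.g. 100% with all mass in the most dorsal rows) clamp to the
attainable extreme. Because silent fractions quantize to whole pixels
and extreme parameter draws can push further pixels under the 10%
threshold, the truth tables record the *realized* field features,
obtained by direct counting, independent of the feature-extraction code
paths.

**Frames.** Each frame is an end-expiratory baseline field (EELI spread
uniformly over the mask) plus the tidal field scaled by the
intrapulmonary volume fraction of the breath. The baseline field steps
to the next breath's level mid-expiration, where the tidal component
has decayed, so between-breath EELI changes never fall inside a
landmark search window.

**Airway signals.** A single-compartment lung under volume-controlled
ventilation: constant inspiratory flow (I:E 1:2 with a 10% of cycle
end-inspiratory pause — timing the ventilator protocol does not state,
chosen so a plateau pressure exists), passive exponential expiration
with time constant Raw·C~rs~, and Paw = Raw·flow + V/C~rs~ + PEEP.
Expired CO~2~ follows a three-phase expirogram: zero over the airway
dead space, a logistic transition of configurable width (default
10 mL), and a linear phase III. The delivery phase is closed at its
endpoint so a grid-aligned sample sees the true end-inspiratory peak.
Optional spontaneous-effort contamination (negative pressure
deflections, off by default) exercises the exclusion rule.

**Edema trajectory.** Every affected quantity follows
s(t) = 1 ∓ A·g(t), with g a logistic time course (midpoint 30 s,
timescale 20 s) anchored to be exactly 0 for t ≤ 0 and to approach 1.
Default amplitudes are derived from the configured baseline and 120-s
plateau values so the trajectory passes exactly through the plateau at
120 s. Band-fraction changes are parameterized as fractions of ventral
and centro-ventral ventilation reassigned dorsally, with a fixed share
going to the dorsal band — emulating the gravitational dorsal shift of
ventilation as dependent alveoli flood. The published in-vivo decline
is closer to linear over 42–120 s than this logistic; the trajectory is
a parametric stand-in for unavailable kinetics, tuned only at its
endpoints, not a physiologic claim.

**Defaults and noise.** Baseline EIT features default to the published
healthy-sheep baselines (CoV~VD~ 52.8%, TIV 1460 AU, EELI 2445 AU, NSS
7.04%, DSS 8.42%, bands 7.64/36.9/41.8/13.7% — renormalized to sum to
exactly 100). Mechanics and capnography baselines (Raw 8 cmH2O/(L/s),
C~rs~ 25 mL/cmH2O, end-tidal CO~2~ 40 mmHg, VD~aw~ 30% of VT, S~III~
6 mmHg/L) are physiologic choices for a ~50-kg ewe with a large-bore
endotracheal tube; the corresponding published table was not available
for verification, so no quantitative claim is tied to them. Per-breath
noise is multiplicative on the feature targets (1–10% by variable);
between-subject spread is drawn once per subject from the published
baseline confidence intervals where available. One root seed drives
everything; per-subject streams are derived by fixed offsets so cohort
size changes do not reshuffle earlier subjects.

**What the generator does not emulate.** Electrode-level voltages and
image reconstruction; cardiogenic oscillations; anatomically realistic
thoraces; breath-to-breath autocorrelation of noise; drift or sensor
artifacts. Passing tests therefore demonstrate correctness of the
analysis chain under the stated model, not robustness to every property
of real recordings.

## Problem sizes

The test suite and the acceptance script run everything at desk scale:
single-subject frame simulations cover 70–180 s of recording; the
family-wise error study uses 500 null cohorts of 15 subjects simulated
at the feature level (the mixed-model procedure, not pixel synthesis,
is the quantity under study there); the onset study uses 40 stochastic
cohorts. A full 15-subject frame-level cohort to +360 s is supported
but takes tens of seconds and ~150 MB per subject.

## Known limitations

* The logistic edema kinetics are faster mid-course than the in-vivo
  time courses they bracket; onset-time comparisons against the
  published in-vivo breath ordinals are qualitative only (raw animal
  data are unavailable).
* With Table-scale effect sizes and default noise, the mixed-model
  contrast detects the EELI change several breaths before the logistic
  midpoint — "first significant breath" measures detectability, not
  the trajectory midpoint.
* VD~aw~ localization is limited by the volume step between CO~2~
  samples during early passive expiration (~20 mL at 100 Hz); the
  adaptive smoothing recovers the center of symmetric transitions but
  strongly asymmetric phase II shapes would bias it.
* The spontaneous-effort rule is a fixed-threshold surrogate for expert
  visual review; its 2 cmH2O default is a convention, not a fitted
  value.
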