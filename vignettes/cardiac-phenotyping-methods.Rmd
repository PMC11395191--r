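---
title: "Methods: cardiac phenotyping of two-genotype mouse cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiac phenotyping of two-genotype mouse cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiophen)
```

cardiophen analyzes four modalities of a murine cardiac phenotyping study —
Lead-I ECG, left-ventricular pressure–volume (PV) catheterization under
preload reduction, Fura-2 AM calcium photometry in paced isolated
cardiomyocytes, and M-mode echocardiography — and applies a consistent set
of two-group statistical conventions on top. This vignette documents the
models, the measurement conventions and their tunable parameters, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where the underlying procedures are conventionally under-specified.

## ECG: averaged cycles, the T-end rule, and QT variation

A murine QT interval at 350–500 BPM is 24–32 ms, so the analysis leans on
beat averaging rather than single-beat delineation. `qt_variation()` splits
a 30 s trace into six 5 s windows; in each window, beats are aligned on
their R peaks and averaged over one median RR interval (one third before the
peak, two thirds after). White noise of SD $\sigma$ shrinks to
$\sigma/\sqrt{N}$ on the averaged cycle ($N \approx 30$–40 beats per
window).

**R-peak detection.** 5–90 Hz zero-phase Butterworth band-pass, squared
derivative as an energy envelope, adaptive threshold at 40% of the rolling
2 s envelope maximum, 40 ms refractory period, peak refinement on the
band-passed voltage. Inter-beat intervals are checked against a configurable
300–900 BPM physiologic band; the anesthesia titration band (300–500 BPM) is
enforced as a warning, not an error, since a titrated cohort can still drift
slightly outside it.

**Landmarks.** On the averaged cycle, smoothed with a Savitzky–Golay filter
(order 3, width 5 ms by default):

* *Isoelectric level and noise band* come from the TP segment (the last
  quarter of the post-R extent, after the T wave and before the next P).
  The band is $\max(3\,\hat\sigma_{TP},\ 0.015\,A_R)$ with $A_R$ the R
  amplitude, so it scales with the trace — landmark positions are invariant
  under voltage scaling and offsets, and so is the QT CV.
* *Q onset* is the last point before R where the smoothed trace is inside
  the band (QT is conventionally measured from QRS onset).
* *J wave*: first local maximum 2–20 ms after the S-wave minimum.
* *T end*: the first point after the steepest post-J repolarization slope
  (the most negative smoothed derivative after the J wave) where the
  derivative returns to zero, resolved by linear interpolation. Anchoring on
  the steepest *descending* slope makes the same rule find the end of an
  entirely positive T wave (which need not return to the isoelectric
  baseline) and the trough of a T wave with a negative undershoot.

Two numerical choices deserve comment. First, the smoothing width: murine
QRS features are 2–6 ms wide, and a 9 ms window — a common default for
larger species — systematically drags the detected T end 2–4 ms late on
sharp waveforms; 5 ms keeps the noiseless QT error under 2 ms across
350–500 BPM and both T-wave polarities while still stabilizing the
derivative under realistic noise (the width is a parameter of
`locate_landmarks()`). Second, "derivative equals zero" is read as the first
crossing of a small threshold, −2% of the anchor slope, rather than an exact
sign change: a positive T wave returns to baseline tangentially, so its
smoothed derivative approaches zero asymptotically and an exact-zero reading
is biased late by the smoothing span. The threshold crossing removes that
bias and is negligible for transversal crossings such as an undershoot
trough.

QT-length variation is the sample coefficient of variation (SD/mean,
$n-1$ denominator) of the six window QTs. Windows whose T end cannot be
located are dropped with a warning; fewer than three surviving windows abort
the analysis. Per-animal CV from six windows is intrinsically noisy
(sampling SD roughly $CV/\sqrt{10}$), which is why the group comparison, not
the single-animal value, carries the inference.

## PV loops: elastance, ESPVR/EDPVR, and the exclusion rule

End-systole is defined by maximal elastance: the sample maximizing
$P/(V - V_0)$, with $V_0$ configurable (default 0) because the acquisition
software's convention — $V_0$-anchored elastance versus upper-left-corner
detection — is generally not recoverable from a published study; the
configurable offset covers both. End-diastole is the volume maximum, which
also defines cycle boundaries for segmentation. dP/dt uses centered finite
differences; channels are smoothed (5 ms moving average) for *selection* of
the extremal samples, but the reported point values are read from the raw
channels, so smoothing cannot bias the fitted slopes.

ESPVR and EDPVR are ordinary least-squares lines through the end-systolic
and end-diastolic points of 5–16 occlusion-ordered cycles. The exclusion
rule for perfusion compromise retains the first five cycles unconditionally
and then admits each further cycle only if the incremental slope between its
point and the previous retained point is non-negative; a violating cycle is
excluded with reason `"negative-slope"`. This incremental reading is
deterministic and testable, and on the simulated artifact (below) it removes
exactly the planted cycles.

A documented limitation: the same exclusion rule biases the *EDPVR* upward
when pressure noise is comparable to the per-cycle end-diastolic pressure
decrement (0.3–0.5 mmHg for a 0.18–0.25 mmHg/µL slope and a 2 µL/cycle
ramp), because it censors noise-flipped increments of a near-flat
relationship. ESPVR, whose per-cycle decrement is an order of magnitude
larger, is unaffected at realistic noise. EDPVR estimates under heavy
pressure noise should therefore be read as upper bounds; the package's
recovery checks run the EDPVR at 0.25 mmHg pressure noise where the bias is
within ~2%.

## Calcium transients: ratio, averaging, and kinetics

Backgrounds are scalars — the channel means over an empty-field window
(default: the segment after the last pacing period); a window overlapping
the paced segment is rejected, and a denominator $F_{380} - b_{380} \le 0$
anywhere is a signal-to-background error. The ensemble average aligns
one-period segments at the stimulus onsets (50 samples at 5 Hz pacing and
250 Hz sampling) after checking stimulus regularity (>5% period jitter is an
error).

Metrics follow vendor-style conventions, stated explicitly because vendors
differ:

* **baseline** — mean of the pre-stimulus samples (the last 10% of the
  period before the next onset);
* **peak amplitude** — sampled maximum minus baseline; at 250 Hz the
  4 ms grid limits landmark precision, and a 21 ms linear rise peaks between
  samples, so the recoverable (sampled) amplitude sits a few percent below
  the continuous-time amplitude. The generators therefore label both the
  nominal and the *realized* (sampled-waveform) values, and recovery is
  measured against the realized labels;
* **time to 90% baseline** — from stimulus onset (configurable to
  peak-referenced) to the first interpolated crossing of
  baseline + 0.1·amplitude; a transient still rising at the period end
  reports this metric as missing with a flag rather than erroring;
* **tau** — nonlinear least squares of $A e^{-(t-t_{peak})/\tau} + c$ over
  the decay segment, initialized from a log-linear fit. The offset $c$ is a
  *free* parameter: at 5 Hz pacing the decay is truncated by the 200 ms
  period, so the pre-stimulus level overestimates the true asymptote by
  $\approx A\,e^{-(T - t_{peak})/\tau}$ (1.5% of A at τ = 40 ms, 12% at
  τ = 80 ms), and fixing the baseline there biases a two-parameter fit low
  by 5–25%. With the free offset, noiseless truncated trains recover τ
  exactly across 20–101 ms, and with 1% noise the error stays well under
  5% for τ ∈ {20, 40, 80} ms.

The closed-form identity $t_{90} - t_{peak} = \tau \ln 10$ holds for a pure
exponential with a known baseline and is used as an internal oracle; note it
does *not* hold between the period-truncated, convention-bound $t_{90}$ and
the fitted τ of real paced data, which is why a measured
$t_{90} \approx 139$ ms can coexist with τ ≈ 101 ms in a 200 ms period.

## Echo derivations

Implemented verbatim: FS = (LVIDd − LVIDs)/LVIDd × 100%;
Teichholz V = 7/(2.4 + LVID)·LVID³ with diameters in mm and volumes in µL
(the printed-formula convention that reproduces murine magnitudes);
SV = EDV − ESV; EF = SV/EDV × 100%. Group summaries are means of per-animal
derived values — a mean of ratios, deliberately not the ratio of group-mean
diameters, so group-mean FS/EF cannot be reproduced from group-mean LVIDs.

## Group statistics

The outlier rule is the a-priori convention: per parameter and per group,
one pass with the mean and sample SD of all values, exclusion of points with
|z| > 2, capped at two exclusions per group (if more qualify, the two most
extreme are taken and a warning is raised). The rule is deliberately not
iterated. Student's t is pooled-variance and two-tailed ("Student's"
implying pooled; Welch is available as an option). The nested t for
cell-level data is a one-way nested ANOVA — genotype tested against the
between-animal (within-genotype) mean square, reported as
$t = \mathrm{sign}(\Delta)\sqrt{F}$ with $df = \text{animals} - 2$ — which
collapses exactly to the pooled t when each animal contributes one cell, and
is cross-checked against `aov(value ~ genotype + Error(animal))` in the test
suite. Under animal-level variance (intraclass correlation 0.5, 8
cells/animal) its simulated type-I error is calibrated near 0.05 while the
naive cell-level t exceeds 0.35 — the pseudoreplication the hierarchical
test exists to prevent. The Livak fold change uses the arithmetic mean of
the two reference genes' Ct as the reference Ct (geometric mean of
abundances), per-sample when a sample column is present.

## What the generators emulate — and what they do not

The generators produce data with the statistical structure the estimators
assume, plus exact labels:

* `simulate_ecg()` builds beats from compact-support raised cosines, so
  every landmark is analytic: Q onset at −6 ms from R, and the T end (or
  undershoot trough) placed so that QT$_{true}$ = T$_{end}$ − Q$_{onset}$
  exactly. QT varies on two levels: window-mean QTs drawn with the target
  CV, and per-beat jitter of the whole T complex. Both T-wave polarities are
  generated. Not emulated: conduction physiology, respiration or motion
  artifact, P/QRS morphology variation, arrhythmia.
* `simulate_pv()` uses a time-varying elastance
  $E(t) = E_{es}(1 - \cos 2\pi t/T_{sys})/2$ with the pressure blending
  systolic and diastolic relationships so both true relations are exactly
  linear, an EDV ramp for the occlusion, and corrupt tail cycles with
  depressed activation and collapsed ejection — end-systolic volume rises
  while pressure falls, which is what makes the incremental slope negative
  and is the physiologic signature of perfusion compromise. Not emulated:
  Windkessel afterload, conductance-catheter calibration, atrial kick.
* `simulate_fura()` restarts the transient shape at each stimulus (linear
  rise, exponential decay, truncated by the period with a recorded warning)
  and synthesizes channels so that scalar background subtraction recovers
  the ratio exactly in the noiseless case. Not emulated: photobleaching,
  dye compartmentalization, motion, Ca²⁺ sparks/waves.
* `simulate_cohort()` draws animal effects and cell values hierarchically
  and can plant flagged outliers.

Noise everywhere is additive white Gaussian governed by one integer seed per
generator call; identical spec + seed gives bit-identical output. Because no
raw recordings accompany published group means, the noise and
between-animal-variability magnitudes are package choices picked to make
simulated group SEMs plausible for cohorts of 10–15 animals (e.g. ECG noise
2% of the R amplitude by default, elastance SD 0.8 mmHg/µL between animals);
they are not calibrated to real data. Passing recovery tests on these
simulations demonstrates correctness of the estimators under the stated
model, not robustness to every artifact of real recordings.

## Pipeline and problem sizes

`run_pipeline()` simulates a full two-genotype study (default WT-like and
KO-like group parameters: QT CV 0.050 vs 0.083, elastance 6.0 vs
3.9 mmHg/µL, transient amplitude 0.107 vs 0.083 at a 40 vs 43 ms τ — τ
values chosen inside the identifiable range of a 200 ms pacing window —
and LVIDs 3.0/1.9 vs 3.7/2.8 mm), analyzes every animal, applies the
outlier rule to per-animal means, and tests each parameter between
genotypes. All randomness derives from one master seed through a
deterministic child-seed stream; reports carry a config hash and no
timestamps, so a rerun is byte-identical.

The shipped checks run at desk scale by design: 15–30 s traces at 1 kHz,
cohorts of up to 60 simulated animals per genotype for the QT-CV separation
check (cohort replicates resample animals from those pools), 20-seed
recovery averages, and 600–1000 null simulations for type-I calibration.
These sizes put Monte-Carlo error comfortably inside the asserted
tolerances; all of them scale up linearly if finer calibration is wanted.

## Known limitations

* The T-end rule needs a J wave to anchor on; morphologies without any
  post-S positivity (not generated here) would require a different anchor.
* QT is not rate-corrected (no Bazett/Fridericia) — cohorts are expected to
  be rate-matched by anesthesia titration, mirroring study practice.
* EDPVR slopes under heavy pressure noise are upward-biased by the exclusion
  rule (see above).
* τ beyond ~100 ms is not identifiable inside a 200 ms pacing window with a
  tail-contaminated baseline; the generator flags truncation, and the free
  offset in the fit mitigates but cannot beat a window shorter than the
  decay.
* The nested test assumes approximate normality at both levels; it is exact
  for balanced designs and a good approximation for the mild imbalance
  typical of these cohorts.
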