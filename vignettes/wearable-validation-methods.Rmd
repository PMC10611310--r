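---
title: "Methods: validating wrist-worn HRV and EDA against gold-standard recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating wrist-worn HRV and EDA against gold-standard recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wristvalid)
```

`wristvalid` quantifies the agreement between a wrist-worn device's heart
rate variability (HRV) and electrodermal activity (EDA) metrics and those
of a gold-standard system (chest ECG, finger/shoulder EDA) across a
six-condition protocol: Baseline (180 s), Video Clip (720 s), Scream
(150 s) and three driving simulations of increasing risk (210 s each).
This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic-data tests do and do not
establish about real recordings.

## 1. BVP beat reconstruction

The device samples the blood volume pulse (BVP) at 64 Hz and emits a
native inter-beat interval (IBI) only when it trusts the pulse wave, so
its native stream is gappy wherever the wrist moves. The reconstruction
turns the continuous BVP into a complete IBI series:

1. **Artifact-free segment mining** (`find_artifact_free_segments`). Runs
   of at least `min_run = 10` consecutive native intervals in which each
   interval bridges the gap to the previous beat within 1 ms mark
   motion-free stretches. The floor of 10 intervals trades bias (too few
   segments on active subjects) against frequency resolution of the
   per-segment spectra.
2. **Subject band selection** (`subject_band_from_psd_subtraction`).
   Per segment, rectangular-window periodogram PSDs of the BVP and of the
   conditioned acceleration magnitude are each scaled by their own
   maximum and subtracted; the argmax of the difference is the segment's
   cardiac fundamental, retained only inside the physiological 0.5–3 Hz
   range. The subject band is the min/max of retained fundamentals
   widened by a 0.1 Hz safety margin. Long segments are chopped into
   `window_s = 30` s windows first: a periodogram argmax measures the
   *average* rate over its window, so a single whole-recording segment
   would collapse the band to ±0.1 Hz around one number and the
   subsequent filter would erase most beat-to-beat variability (we
   measured 20–60 % SDNN/RMSSD loss). Thirty-second windows track the
   slow heart-rate wander while retaining ~0.03 Hz resolution.
   With no retained fundamental the default 0.5–3 Hz band is used and a
   warning is raised.
3. **Foot-point detection** (`reconstruct_bvp_ibi`). The BVP is filtered
   with a zero-phase third-order Butterworth band-pass at the subject
   band; diastolic foot points are local minima with a prominence of at
   least `min_prominence_frac = 0.3` of the filtered signal's IQR and a
   separation of at least `0.7 / high_cut` s. The separation floor is
   deliberately below one period of the upper cut-off: the windowed
   fundamentals track average rate, so the fastest individual beats run
   above `high_cut` and a full-period floor would censor them.
4. **Timing refinement.** The narrow band is excellent at *locating*
   beats but, like any narrow-band filter, it low-passes the beat-to-beat
   frequency modulation and so distorts fine timing (~34 ms fiducial
   jitter on synthetic data). Each candidate foot is therefore refined by
   cross-correlating the drift-removed (0.3 Hz high-pass), mildly
   denoised (6 Hz low-pass) raw waveform with the subject's
   ensemble-average pulse, with parabolic sub-sample interpolation
   (~7 ms jitter). Refinement can be disabled (`refine = FALSE`).

The assumption behind the PSD subtraction is that motion corruption is
*additive* in the BVP and spectrally coherent with the accelerometer — a
good model for optical coupling artifacts, a poor one for perfusion
changes that do not show up in the accelerometer.

## 2. ECG path and artifact correction

R peaks are detected with the Pan–Tompkins chain (5–15 Hz band-pass,
derivative, squaring, 150 ms moving-window integration, adaptive
signal/noise thresholds with search-back), refined on the raw ECG.
Both IBI paths then pass the distribution-based artifact detector
(`berntson_detect`): the criterion is the robust SD of successive
interval differences (MAD scaled by 1/0.6745) times `multiplier = 4`,
with a 50 ms floor so that near-constant series are not flagged
wholesale; an interval is flagged only when it disagrees with *both*
neighbours, which isolates the aberrant interval rather than its
neighbours. Flagged intervals are classified missing beats (≈ 2× the
local 9-beat running median), extra beats (≈ 0.5×) or generic artifacts,
and replaced by a natural cubic spline over beat index fitted to clean
intervals. More than 50 % flagged intervals aborts the series.

## 3. HRV metrics

Per condition (half-open `[start, stop)` windows, beats assigned by beat
time): Mean IBI, SDNN (sample SD, n−1 denominator — the convention of the
HRV literature), RMSSD, and normalized spectral powers. The corrected
IBI series is resampled at 4 Hz by monotone piecewise-cubic (pchip)
interpolation and its Lomb–Scargle periodogram evaluated on a
0.005–0.5 Hz grid in 0.005 Hz steps. LFnu and HFnu are normalized over
LF + HF only (VLF excluded), so they sum to 100 by construction; this is
the natural reading of "normalized units" when VLF is explicitly
discarded. The resample-then-Lomb–Scargle chain is redundant in theory
(the estimator tolerates uneven sampling) but is kept because it is the
processing chain being validated.

## 4. EDA pipeline

Both EDA channels are smoothed with a centered 1-s moving average,
decimated to a common 4 Hz analysis rate (the smoothing is the
anti-alias filter), and z-scored over the full recording — normalizing
before condition slicing keeps one scale per subject and stabilizes the
decomposition.

**Decomposition** (`cvxeda_decompose`). The standardized signal is
modeled as `driver ⊛ h + tonic + residual` with a non-negative sparse
driver, `h(t) = e^{−t/τ0} − e^{−t/τ1}` (defaults τ0 = 2 s, τ1 = 0.7 s,
unit peak), and a tonic of cubic B-splines on a 10 s knot grid plus an
unpenalized affine part. The objective is
`½‖residual‖² + α‖driver‖₁ + ½γ‖D²ℓ‖²` with `α = 8·10⁻⁴` and a
**P-spline second-difference penalty** (`γ = 1`) on the spline
coefficients. A plain coefficient-magnitude penalty cannot separate time
scales in this basis: small weights let the spline absorb SCR-shaped
transients, large weights push slow tonic wander into the driver. The
curvature penalty makes smooth drift of any amplitude cheap while
SCR-speed kinks stay expensive, which is the identifiability argument
the decomposition rests on. The model kernel is passed through the same
1-s smoothing as the data, so the model matches the signal actually
decomposed. The program is solved by alternating a closed-form
(Cholesky) tonic solve with FISTA iterations on the driver using FFT
convolutions, plus a guarded support-pruning step (driver values below
1 % of the maximum are dropped and the tonic re-solved, accepted only if
the objective decreases) that clears the slow tail of the L1 shrinkage.
For *recovery* experiments against synthetic ground truth the time
constants are set to the generating kernel (τ0 = 4, τ1 = 1); recovery of
known events is only well-posed under the generating model, while the
defaults remain the field-standard values for real data.

**Artifact detection** (`wavelet_artifact_detect`). Level-1 stationary
Haar detail coefficients respond to abrupt changes; coefficients whose
magnitude exceeds 3× the centered 1000 s moving average of coefficient
magnitudes (absolute values — signed averages are ≈ 0 and would flag
everything; windows truncated at the edges) are outliers, and runs of
consecutive outliers padded by 1 s become candidates. The padding is
needed because a two-sample candidate spanning a clean step edge is
strictly monotone by construction. A candidate is kept as an artifact
only if it passes three vetoes: the raw signal across it is **not
strictly monotone** (clean ramps are physiology), it shows a
**significant level shift** (medians of 1 s flanks differ by more than
the 3× criterion mapped to raw units — isolated noise excursions do
not), and the shift is **abrupt with a plateau** (concentrated in
essentially one sampling step, with the post-interval signal flat on the
2–5 s horizon relative to the shift). The last two vetoes formalize what
visual inspection of "abrupt changes due to contact losses" does: an SCR
rises over ~1 s and keeps evolving on its decay time constant, a contact
loss jumps and stays. Detection runs at the 4 Hz analysis rate for both
systems; at 500 Hz the per-sample noise outlier rate makes padded
candidates merge into unusable chains.

**Metrics** (`eda_metrics`). Samples inside artifact intervals are
excluded from every statistic. Mean tonic; NS.EDR frequency as phasic
peaks with prominence ≥ 0.05 z-units (a value that, at unit signal SD,
sits well above solver ripple and below any credible SCR) per retained
second; time-normalized trapezoidal area of the non-negative phasic;
VLF (0–0.045 Hz) and LF (0.045–0.15 Hz) normalized periodogram content
of the phasic over the longest artifact-free stretch; responsiveness =
at least one phasic peak. Cells with under 30 s of retained signal are
flagged unusable.

## 5. Agreement statistics

Differences are device − gold standard throughout. Bland–Altman reports
the mean bias, its 95 % CI half-width `t(0.975, n−1)·SD/√n`, the
two-sided one-sample t p-value, and limits of agreement `bias ±
1.96·SD`. These conventions were fixed by verifying that the published
summary rows are mutually consistent under them (the bias, CI and LOAs
of each row derive from a single SD). When the differences trend
significantly (p < 0.05) on the pair means, a regression-based bias line
with ±1.96 residual-SD limits is additionally computed and flagged.
Spearman bands: high (ρ > 0.9), moderate (0.7–0.9), low (< 0.7), none
when p ≥ 0.05 or ρ is undefined. Friedman tests use the tie-corrected
χ² with df = k−1; an exact within-row permutation p-value is available
for small designs. The post hoc default is Dunn-type rank-sum z tests
with Bonferroni adjustment — the convention of the mainstream
statistical suites for this design — with paired Wilcoxon available;
the choice is configurable precisely because the underlying procedure is
conventionally under-reported. Absolute errors entering the Friedman
test are scaled by the parameter's full scale, defined as the range of
the Bland–Altman mean axis across all subjects and conditions. The
Shapiro–Wilk gate justifies the nonparametric choices in the report; it
never branches the pipeline.

## 6. The synthetic cohort: what it emulates and what it does not

`simulate_cohort` generates paired recordings with complete ground
truth:

- **Beats** by integral pulse frequency modulation: a modulating signal
  — two band-limited Gaussian components in 0.04–0.15 Hz and
  0.15–0.4 Hz with configurable power ratio (default LF/HF = 2) and
  total CV `SDNN/MeanIBI` — drives an integrate-and-fire threshold. A
  coefficient of variation above 0.3 is rejected as infeasible. Subject
  level: mean IBI ~ N(800, 60²) ms clamped to 550–1200, SDNN ~
  N(50, 10²) ms floored at 10 — short-term values typical of healthy
  adults, and the between-subject spread is what makes across-subject
  correlation meaningful at all.
- **ECG** as a unit-amplitude Gaussian R wave (10 ms SD) per beat at
  500 Hz, noise SD 0.02. **BVP** as a gamma-shaped pulse per beat at
  64 Hz with additive corruption proportional (gain 3) to the
  high-passed acceleration magnitude inside motion bursts, noise SD
  0.05.
- **Motion** as Hann-tapered sinusoidal bursts on the gravity axis
  (so the magnitude deflection is linear in amplitude), 3 s long,
  carrier 2–4 Hz (fast steering/gear gestures), amplitude 0.4 g, at
  per-condition rates 0/0.2/1/2/3/4 bursts·min⁻¹ from Baseline to
  high-risk driving. The protocol gives no quantitative motion profile,
  so these are package defaults chosen once as plausible for simulated
  driving; the burst windows are also where the native IBI stream drops
  its entries.
- **EDA** as baseline 6 µS + 0.1 µS/min drift, bi-exponential SCRs
  (rise ≈ 1 s, decay ≈ 4 s, amplitude ~ N(0.5, 0.15²) µS, wrist
  amplitudes × 0.5 attenuation) at per-condition rates 2–6 min⁻¹,
  noise SD 0.02 µS, and boxcar step artifacts (±2 µS, 5–15 s) emulating
  contact losses. Twenty percent of subjects are non-responders (no
  SCRs), mirroring the non-responsiveness rates reported for such
  protocols.

Passing tests on this cohort establish that the *algorithms* recover
what they claim under a controlled data-generating model. They do not
establish robustness to pulse-morphology variation, perfusion-driven BVP
artifacts uncorrelated with acceleration, electrode drift that is not a
clean boxcar, or SCR shapes far from the bi-exponential — all of which
real recordings contain.

## 7. Problem sizes and determinism

The test suite runs short (60–120 s per condition) recordings for unit
tests and full-length cohorts where the claim is cohort-level: 20
motion-free subjects for HRV parameter recovery (|ΔMean IBI| < 2 ms,
SDNN/RMSSD within 10 %, Spearman ρ > 0.95 across subjects), 10 subjects
with bursts covering ~30 % of the driving conditions for the
reconstruction gain (Detection Rate ≥ 95 % while native capture < 80 %),
20 seeds for the artifact detector (sensitivity ≥ 0.9, ≤ 1 false
interval per 10 min), and 8 seeds for driver-mass recovery (≥ 80 %
within ±2 s of true SCR onsets). Every generator and every pipeline run
is deterministic given its seed; identical configurations reproduce
byte-identical recordings and reports.

## 8. Known limitations

- The subject band logic assumes the native IBI stream yields at least
  one artifact-free run; pathologically motion-corrupted recordings fall
  back to the 0.5–3 Hz default band.
- Template refinement assumes a stable pulse shape within a recording;
  strong morphology drift would dilute the ensemble template.
- The EDA artifact vetoes are tuned to contact-loss physics (abrupt,
  sustained level shifts); gradual electrode detachment will present as
  tonic drift instead and pass undetected.
- Manual review steps of interactive workflows are replaced by
  deterministic rules plus override hooks; borderline artifacts that a
  human would adjudicate are resolved by the rules above.
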