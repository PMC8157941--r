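---
title: "Methods: signal processing for wireless maternal-fetal monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal processing for wireless maternal-fetal monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfv)
```

# The system

`mfv` processes the streams of a three-node wireless maternal-fetal sensor
network: a chest patch (ECG at 512 Hz, tri-axial accelerometry at 52 Hz for
vitals and 416 Hz for high-rate inertial work, skin temperature at 0.2 Hz),
a limb unit on the finger (red/infrared PPG at 256 Hz, temperature), and an
abdominal patch (Doppler ultrasound envelope at 504 Hz, two biopotential
channels at 500 Hz carrying electrohysterogram and abdominal ECG). The nodes
share a session clock; out-of-band synchronization holds inter-sensor skew
to about 1 ms, which is what makes beat-to-beat pulse arrival time (PAT)
meaningful. All event times in the package are milliseconds on that session
clock, because PAT physiology lives at millisecond resolution.

Missing samples are `NA`; operations skip — never silently interpolate
across — gaps longer than two sample periods. EDF is the primary waveform
container (multi-rate channels in one file; 5-s data records so the 0.2 Hz
temperature channel has an integer number of samples per record); a long
CSV dialect (`time_ms, sensor, channel, value, units`) is the plain-text
alternative. Doppler audio is exported as 16-bit PCM WAV at the original
504 Hz after normalization to [-1, 1].

# Maternal chain

## QRS detection

`detect_r_peaks()` implements the classic Pan-Tompkins chain: 5-15 Hz
zero-phase Butterworth band-pass, five-point derivative, squaring, 150 ms
moving-window integration, adaptive dual thresholds (signal and noise
levels updated as exponential moving averages; acceptance at noise +
0.25 x (signal - noise)), a 200 ms refractory period, and search-back at
1.66 x the running R-R average with half the threshold. The literature
names many "modified" variants without specifying the modification; we
therefore expose every constant in `pan_tompkins_config()` and add two
pragmatic refinements: within the refractory period the stronger of two
competing integrated peaks wins (filter ripple inside the QRS plateau
otherwise shadows the true peak), and each accepted detection is refined to
the raw-ECG maximum near the integrated peak — the whole chain is
zero-phase, so the integrated peak sits on the complex itself and the
refined time lands on the R wave to within a sample.

Beats whose integrated peak is less than twice the running noise level are
flagged `suspect`, as are beats bounding R-R intervals outside [250, 2000]
ms; rate computation uses good beats only. HR is 60000 / mean(R-R ms) per
sliding window, kept unrounded internally; `format_vital()` applies the
clinical display convention (HR/FHR/RR to integers, SpO2 to one decimal).
A 635 ms mean interval therefore displays as 94 bpm, and a 344 ms interval
as 174 bpm — the unrounded 174.42 is retained. (Published summaries
sometimes round such a fetal interval to 170 bpm; 60000/344 does not
support that figure, so we do not reproduce it.)

## SpO2

The ratio of ratios R = (AC_red/DC_red)/(AC_IR/DC_IR) is computed per
window from detected pulse peak-to-trough amplitudes (AC) and window means
(DC), then mapped through the linear empirical curve SpO2 = c0 - c1 R with
c0 = 110, c1 = 25. Device-specific coefficients are always proprietary
calibrations; ours are the conventional textbook pair and overridable.
The upper clamp at 100% is the single place a vital is clipped rather than
set missing; everywhere else out-of-range values become `NA` so downstream
statistics cannot be silently biased.

## Respiratory rate

Three estimators per window (default 60 s, at least 30 s): the dominant
0.1-1.0 Hz frequency of the x and y accelerometer axes (chest-wall
excursion), and of the ECG-derived respiration signal (R-peak amplitudes
interpolated to 4 Hz). Each estimate carries a quality score — the fraction
of in-band spectral power within 0.05 Hz of the peak, on a zero-padded,
Hann-windowed periodogram with parabolic peak interpolation — and three
gates: concentration at least 0.35, in-band variance at least 5% of the
detrended window variance, and a peak at least two resolution bins above
the lower band edge (sub-band drift leaks exactly onto that edge). Survivors
are fused by quality-weighted median; if none survive the window is
missing. The exact fusion rule for combining accelerometer and ECG sources
is not standardized anywhere; the weighted median is our choice, favored
because a single corrupted source cannot drag the output. The 52 Hz
accelerometer stream is the default respiration source (the band sits far
below its 26 Hz Nyquist); the 416 Hz stream is accepted and decimated.
Estimates are invariant to accelerometer DC offset and uniform gain. With
the default window, the minimum reportable rate is about 8 breaths/min.

## Temperature

Direct readings, smoothed by a moving median (5 min default): identity on
constants, immune to single-sample spikes, and within 0.05 degC of a
2 degC/h ramp. Chest (central) and limb (peripheral) channels stay
separate.

# Abdominal chain

## Doppler fetal heart rate

Each fetal cardiac cycle produces two audible valve closures, S1
(tricuspid/mitral) and S2 (pulmonary semilunar), 80-250 ms apart. Naive
peak counting on the envelope therefore doubles the rate. `detect_fhr()`
attacks this twice: envelope peaks are paired greedily into S1/S2 doublets
under the gap prior, and the rate itself comes from windowed
autocorrelation of the envelope (3.75 s windows stepped by 0.25 s —
cardiotocography convention), searched over lags corresponding to 60-240
bpm with parabolic lag refinement. At the true period the autocorrelation
aligns S1 with S1 and S2 with S2 (energy a1^2 + a2^2); at the spurious
S2-to-next-S1 lag it aligns unlike sounds (a1 a2), which is always smaller
— that inequality is why the right peak wins for any amplitude pair.
Windows whose normalized autocorrelation peak falls below 0.45 report a
missing rate, which is what silence and signal dropouts produce. The input
may be raw audio-band Doppler or an already-demodulated envelope; a
spectral-content heuristic (fraction of power above 40 Hz) distinguishes
them, with a config override, since sensor firmware differs in where
demodulation happens.

## Contractions

Per biopotential channel: decimate to 10 Hz, band-pass 0.34-1.0 Hz (the
established electrohysterography band; uterine bursts concentrate there,
maternal ECG mostly does not), 60 s RMS envelope; fuse channels by
pointwise maximum (the two electrode pairs are interchangeable and either
may see a given contraction better). Because contractions can occupy most
of a labor record, the detection baseline is the 10th envelope percentile
and its fluctuation (MAD of the lower 30%), not a global median. Candidate
regions above baseline + max(6 x spread, baseline) are then refined: onset
and offset move to the half-height crossings of each event's own peak,
which undoes the +-30 s smearing the RMS window imposes — on simulated
bursts the onset lands within ~12 s of truth, inside the +-15 s the
evaluation demands. Event durations outside [30, 300] s are flagged, not
dropped. The tocogram (fused envelope) maps to mmHg through a two-parameter
affine calibration against a reference tocodynamometer segment; nothing
more elaborate is justifiable, since surface EHG amplitude is not an
absolute pressure.

## Fetal ECG isolation

The abdominal biopotential sees the maternal ECG at roughly ten times the
fetal amplitude. The chest sensor's R-peak times (shared session clock)
index the maternal complexes; a median template over +-400 ms windows —
wide enough to span the full PQRST including the T-wave tail — is
subtracted at every beat. Three details carry the performance:

- **Least squares on (template, template derivative).** The chest grid
  (512 Hz) and abdominal grid (500 Hz) never sample a beat at the same
  sub-sample phase; the derivative regressor absorbs that misalignment to
  first order.
- **Inter-beat cell clipping.** At steady rhythm, consecutive +-400 ms
  windows overlap, and the median template itself contains the neighbor
  bleed present in every window. Subtracting full windows would remove that
  bleed twice. Each beat therefore subtracts only inside its own cell
  (midpoint to midpoint), where the template's neighbor content correctly
  models the neighbor's actual contribution.
- **A second pass.** The residual is re-templated (median across beats) and
  subtracted again: beat-coherent leftovers — fit bias from fetal overlap,
  edge effects — survive the median and are removed; the incoherent fetal
  signal does not.

Guards: a channel with no coherent maternal projection yields a near-flat
median template (max below 25% of the typical window peak), in which case
subtraction is skipped entirely rather than projecting out fetal signal;
and detected fetal beats must exceed 5% of the maternal template peak,
which separates true fetal complexes (~10%) from cancellation residue
(~2-4%). Fetal R-peaks are then detected on the residual with the QRS
chain retuned (8-30 Hz band for the narrower fetal complexes, 80 ms
integration, 200 ms refractory — fetal rates run 1.7-4 Hz). On simulated
mixtures at amplitude ratio 0.1 this recovers over 95% of fetal beats with
maternal residue under 5%.

# Blood pressure from pulse arrival time

PAT — R-peak to the first PPG pulse strictly after it and before the next
R-peak — shortens as pressure rises. The model is linear and additive,
BP = a_pat PAT + b_hr HR + c, fitted separately for systolic and diastolic
pressure by ordinary least squares; HR enters because it measurably
improves the translation, and the term can be dropped by configuration.
We apply the same form to both pressures (whether diastolic calibration
should also use HR is genuinely open; symmetry is the simpler choice).
Two calibration modes: `continuous` (dense reference, default window the
first 50 s of overlap — matching how a cold-pressor calibration segment is
used) and `cuff` (sparse sphygmomanometer readings; PAT/HR averaged within
+-30 s of each cuff time, global fit, then the intercept shifted so the
mean residual at the reference times is zero — a per-subject offset, the
simplest reading of "apply the necessary offsets"). A rank-deficient
design (constant PAT and HR) is a hard error: a calibration fitted on no
variation is not a calibration. Predictions are per-beat, median-smoothed,
and values outside [40, 280] mmHg become missing. For negative `a_pat` and
fixed HR the prediction is strictly decreasing in PAT, and regression
through the means guarantees that constant inputs at the calibration means
return the mean reference pressure. The default PAT fiducial is the PPG
pulse peak; the foot (pre-peak minimum) is available, being less sensitive
to pulse-shape change. Under sensor noise the per-beat peak fiducial
jitters by tens of milliseconds on a flat pulse apex; the beat-level
median smoothing in `predict_bp()` is what makes the output clinically
smooth, and no attempt is made to re-calibrate over time (drift handling
beyond the offset step is out of scope).

# Posture

Chest-mounted accelerometry at rest measures the gravity vector in the
sensor frame, which pins torso orientation. `fit_posture_model()` fits a
full-covariance Gaussian mixture with 8 components on up to 50,000
randomly sampled low-motion triples (2 s windowed variance of the
acceleration magnitude below 0.02 g^2), after normalizing to unit gravity
so uniform gain cancels. Initialization is k-means++, ten restarts keep
the best log-likelihood, EM runs to a 1e-6 relative tolerance with
covariance ridge regularization and revival of collapsed components; the
whole fit is bit-reproducible given its seed, and the EM log-likelihood
trace (non-decreasing, an internal correctness check) is kept on the
model object. Eight components over four postures deliberately
over-segments: real posture classes are not single Gaussians (a "lateral"
patient rolls through a range of angles), and extra components absorb that
structure. Each cluster mean is then merged onto the nearest canonical
gravity direction — supine (0,0,-1), lateral (+-1,0,0), hands-knees
(0,0,+1), high Fowler's (0,-0.71,-0.71), i.e. a torso elevated at least 45
degrees — a geometric reconstruction of a merge step that no published
description specifies; the canonical vectors are configuration so other
mounting conventions can be remapped.

Classification is maximum posterior at the *posture* level: clusters merged
to one posture pool their posterior mass, so a posture split across
components is not penalized — with per-cluster posteriors and a 0.6
threshold, duplicated clusters would push everything to "unknown".
Two guards label a sample `unknown`: pooled posterior below 0.6, or mixture
log-density below the 0.5th percentile of the training data (an
off-manifold gate; walking and pushing produce accelerations no static
posture explains, and posterior ratios alone cannot see that). A 5 s
majority filter smooths the label stream. Per-posture vital summaries
(`posture_vital_summary()`) report n, mean, SD and a histogram per posture
x vital, excluding postures with under 60 s of dwell time.

# Agreement analytics

`bland_altman()` pairs device and reference points by nearest time within
a 5 s tolerance, each reference point used at most once (no published
pairing rule exists for monitor comparisons; nearest-within-tolerance is
the defensible default), and reports mean difference, sample SD (n-1),
and mean +- 1.96 SD limits of agreement. `time_to_vital_heatmap()` pools
sessions into a (session time x value) histogram — default bins 1 bpm HR,
1% SpO2, 1 breath/min RR, 2 mmHg SBP, 5 min time, all overridable since no
standard bin widths exist — and renormalizes within each 4-h window up to
24 h so that the few long labors remain visible next to the majority that
finish within about five hours; every populated window block of the
normalized matrix sums to one. `session_report()` assembles a
deterministic Markdown document with seven vital panels (HR, SpO2, RR,
temperature, FHR, uterine activity, posture; BP appears when a calibration
exists), marking absent inputs rather than failing.

# The simulator

`simulate_session()` is first-class, tested code, not a fixture: it emits
every stream at its native rate with exact ground truth. Morphology
choices favor timing fidelity over visual realism, which is what detector
testing needs: ECG beats are Gaussian-sum PQRST templates (R-amplitude
modulated 15% at the respiratory frequency, which is what makes
ECG-derived respiration recoverable); PPG pulses are asymmetric Gaussians
peaking exactly at beat + PAT, with red/IR AC amplitudes chosen to realize
the configured ratio-of-ratios exactly (the pulse waveform is mean-centered
so the window DC is exactly the baseline); Doppler beats are Hann-windowed
tone bursts (S1: 50 ms at 90 Hz; S2: 30 ms at 110 Hz, 150 ms apart by
default); the abdominal channels mix the maternal projection (~100 uV),
the fetal ECG at the configured amplitude ratio (0.1 — an order of
magnitude down, as observed on real abdominal records), and
Tukey-windowed 0.34-1 Hz oscillation bursts per scheduled contraction;
the accelerometer holds the scheduled posture's gravity vector plus a
respiratory sinusoid and optional motion bursts. Beats whose complexes
would be truncated by the recording edge are not emitted, so ground truth
counts what is actually in the stream. Default per-channel noise levels
are mild realistic floors (ECG 0.01 mV, PPG 0.1% of DC, accelerometer
0.01 g, EHG 2 uV); scenario fields accept constants, step schedules, or
functions of time. Everything is deterministic given the seed.
`cold_pressor_scenario()` inserts one 120 s epoch mid-session with PAT
down 15%, HR up 10 bpm and systolic pressure up 20 mmHg — the stereotyped
response used to exercise the BP chain end to end.

What the simulator does *not* emulate bounds what green tests prove:
morphology variability (ectopy, fetal decelerations beyond schedulable
rate changes), electrode motion artifact with realistic spectra, Doppler
beam loss, multi-fetus mixtures, and drifting sensor clocks beyond a
static offset. Passing tests demonstrate algorithmic correctness at the
stated operating points, not clinical performance on patient data — the
cohort-level agreement figures reported for the physical system (e.g.
sub-bpm mean differences against bedside monitors over hundreds of
participants) require exactly the human recordings a desk-scale package
cannot contain.

# Numerical and design notes

- Filters are zero-phase (`filtfilt`) with reflection padding at the
  record edges; low-band work (EHG, respiration) happens after decimation
  (10 Hz, 4 Hz) because sub-1% normalized Butterworth corners at native
  rates are numerically fragile.
- Sliding-window vitals timestamp at window centers; windows with
  insufficient events yield `NA`, never extrapolation.
- Problem sizes in the test suite and acceptance script (60-120 s
  detection runs, 600 s contraction sessions, 1600 s posture sessions,
  100-draw calibration recovery, n = 10000 Monte-Carlo agreement) were
  chosen so each check exercises its asymptotics while the whole suite
  runs in minutes.
- `align()` is an additive group action on per-sensor clock offsets;
  applying and removing a 3.6 ms skew (a day-scale synchronization SD)
  leaves PAT bit-identical, which is the property the session clock
  contract exists to protect.
- EDF round-trips are exact for durations filling whole 5-s records and
  quantization-limited (16-bit over the per-signal physical range)
  otherwise; CSV round-trips are float-exact.
- The GMM is fitted in-package (the initialization, restart and tolerance
  policy above is part of the method's definition, and the log-likelihood
  trace is asserted in tests); an independent mixture implementation is
  used in the test suite only as a cross-check oracle on separated
  clusters.
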