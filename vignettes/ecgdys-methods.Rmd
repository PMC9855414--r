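---
title: "Personalized dysglycemia screening from single-lead ECG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized dysglycemia screening from single-lead ECG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Blood glucose (BG) in critically ill and ambulatory patients is monitored by
finger-prick or indwelling sensors, both invasive. Dysglycemia — BG above
200 mg/dL or below 70 mg/dL — leaves an electrophysiological signature on the
ECG: shortened R-R intervals, prolonged Q-T and S-T intervals, and lower
R-wave amplitudes. `ecgdys` implements a personalized screening pipeline that
exploits this signature using nothing but a single lead-II channel sampled at
125 Hz:

1. segment the signal into fixed one-second beats anchored on the R peak
   (50 samples before, 75 after — the 2:3 split);
2. delineate the P, Q, R, S, T fiducial peaks of each beat;
3. extract 26 morphology features — 10 pairwise intervals, the R-R interval
   to the next beat, 10 pairwise absolute amplitude differences, and 5 signed
   slope gradients;
4. train, per subject, a *linear ν one-class SVM* on beats recorded during
   euglycemia only (10 ten-minute strips, 100 min of signal), with shared
   hyperparameters (ν = 0.75, linear kernel);
5. flag dysglycemia per beat by the sign of the decision value, and per
   10-second window by majority vote over its beats.

One-class training matters clinically: dysglycemic episodes are rare and
expensive to collect per patient, while euglycemic signal is abundant. The
model learns only what "normal" looks like for one person.

Every stage is verifiable without access to clinical waveform archives via a
calibrated synthetic generator (below).

## Glycemic labelling

Dysglycemia is *strictly* BG > 200 or BG < 70 mg/dL; euglycemia is the
*inclusive* band 80–180 mg/dL. The two buffer bands in between — 70–80 and
180–200, boundary values included — are labelled `excluded` and barred from
training and validation, so no run of consecutive heartbeats can be
attributed to both a normal and an abnormal state. Whether "between 80 and
180" should be read inclusively is not decidable from the published
description; the inclusive reading is this package's documented convention,
and only the buffer-zone behaviour depends on it.

Each BG record claims the 10 minutes of signal in the half-open window
`[t − 600 s, t)` before its storage time. Subjects enter the cohort with at
least 20 BG records, at least 5 dysglycemic records, enough euglycemic
records for the 10 + 5 split, and no atrial-fibrillation/pacemaker flag.

## The synthetic generator

### Beat morphology model

A beat is a sum of five Gaussians (P, Q, R, S, T), each with a centre offset
relative to R, a signed peak amplitude and a width — the classical
ECG-synthesis parameterization, sufficient here because the feature set uses
peak positions only, never wave onsets or offsets. Because neighbouring
Gaussians overlap slightly, `wave_params()` solves a 5×5 linear system so the
*summed* trace passes exactly through each designed peak.

`solve_wave_params()` inverts the feature definitions: interval targets map
linearly to centre offsets (Q at −`qr`, P at −`pr`, S at `rs`, T at
`rs + st`), and amplitude targets map through the spanning tree
{P–Q, Q–R, R–S, S–T} anchored at the R amplitude. The reference targets
(`feature_targets()`) are per-state means reported for an ICU cohort: R-R
0.74 s euglycemic vs 0.66 s dysglycemic, Q-T 0.37 vs 0.44 s, S-T 0.25 vs
0.32 s, Q-R amplitude 0.68 vs 0.56 mV, and so on. Three design details:

* **Interval consistency.** The solver requires `qt = qr + rs + st` and
  `pr = pq + qr`; the reference table satisfies both exactly, and an
  inconsistent target system is a calibration error naming the conflict.
* **Amplitude gauge.** Pairwise amplitude differences leave one degree of
  freedom free; the R-peak anchor (0.60 mV euglycemic, 0.52 dysglycemic) is
  chosen so Q and S are genuinely negative deflections and P and T genuinely
  positive — otherwise "minimum before R" has nothing to find. The reference
  amplitude table is *not* jointly consistent in the dysglycemic column
  (Q–R 0.56 and R–S 0.71 imply |Q–S| = 0.15 where 0.05 is printed); the
  spanning tree is matched exactly and Q–S falls where it falls.
* **Grid snapping.** Designed centres are snapped to the 125 Hz grid, so
  designed fiducials sit on integer sample indices. Extraction then rounds
  jittered positions symmetrically around a grid point, making pooled means
  unbiased; the snapped dysglycemic geometry lands exactly on Q-T = 0.44 s
  and S-T = 0.32 s.

### Within-subject variability and noise

Each beat perturbs its wave centres, peak amplitudes and the R-R period with
truncated Gaussian jitter. The SD of each parameter is `jitter_frac` times
its between-state shift (floors of 2 ms / 5 µV keep a minimum of
variability). The default `jitter_frac = 0.2` reflects that the published
per-feature SDs pool across subjects and are not usable as within-subject
values; the performance experiments below raise it to 1 (SD equal to the
shift), a deliberately hard regime.

Jitter is beat-independent by default. Real morphology variability is
dominated by minutes-scale autonomic and electrolyte drift, and the
generator exposes `jitter_slow_frac` to move variance into a per-strip
component; it defaults to 0 because beat independence is what gives the
1/√n convergence of pooled feature means to their designed values and keeps
validation strips exchangeable — the properties a *verification* generator
must have. This is a stated non-realism: passing tests demonstrate correct
mechanics and calibration, not robustness to temporally correlated
physiology.

Additive measurement noise is white Gaussian (default SD 0.01 mV), with an
optional 0.3 Hz baseline-wander sine (default off); samples are quantized to
1 µV, the amplitude resolution of bedside-monitor archives (which also makes
the WFDB round trip bit-exact at gain 1000). BG timelines draw one value per
10-minute strip with a fixed class composition — euglycemic, hypoglycemic,
hyperglycemic, and deliberately included buffer-zone strips to exercise the
exclusion logic. Cohorts draw per-subject baseline physiology (heart-period
factor ~ N(1, 0.07), amplitude gain ~ N(1, 0.10), truncated) and derive
child seeds arithmetically from the master seed; no global RNG state is
touched (`withr::with_seed`).

The generator does **not** emulate arrhythmia, ectopy, atrial fibrillation
(excluded subjects), respiration coupling, electrode motion artefacts, or
multi-lead geometry.

## Signal processing

**R-peak detection** is a deterministic Pan–Tompkins-style chain: zero-phase
Butterworth band-pass 5–15 Hz, derivative, squaring, 150 ms moving-window
integration, a fixed quantile threshold, greedy peak-picking under a 0.3 s
refractory period, and refinement to the raw-signal extremum. The published
pipeline delegated this step to a library default; a surrogate specified
bit-exactly and validated against the generator's designed beat times
(≥ 99% within ±1 sample) replaces it.

**Quality filtering** replaces manual noise inspection with three rules:
template correlation (Pearson r against the strip's median beat ≥ 0.8),
peak-to-peak amplitude within 0.2–5× the strip median, and finiteness. All
thresholds are config keys; the filter is idempotent.

**Delineation** runs on a wavelet-denoised beat: a stationary (undecimated)
Daubechies-4 transform, 3 levels at 125 Hz, with a per-beat universal
threshold estimated from the MAD of the finest detail band. *Hard*
thresholding is used because it leaves retained coefficients unshrunk, so
peak amplitudes are unbiased (soft thresholding was measured to bias
fiducial amplitudes by ~2–3 µV, violating the 1 µV round-trip budget).
Search windows follow standard ECG physiology and are config keys:

* Q: minimum in the 100 ms window before R. 80 ms is the textbook figure,
  but the euglycemic designed Q–R interval is exactly 80 ms, which would put
  Q on the window edge and clip half of all jittered beats; 100 ms pre-R is
  still comfortably inside the QRS complex.
* S: minimum in the 120 ms window after R.
* P: maximum of the low-frequency reconstruction (approximation + coarsest
  detail) in a 180 ms window before Q, refined on the denoised trace. The
  window is bounded — rather than "anywhere before Q" — because at short
  dysglycemic R-R the previous beat's T peak enters the beat window and
  would otherwise be mistaken for P.
* T: extremum of largest |amplitude| from 40 ms after S to the end of the
  beat, so inverted T waves are found with their sign preserved. At short
  R-R the next beat's P wave can graze the window end, biasing the pooled
  T position by ≲ 0.5 sample — inside the quantization budget.

Failure (monotone Q/S window with an edge extremum, or fiducial ordering
violation) flags the beat; it is counted and excluded downstream, never an
error. Amplitude features are absolute differences — the reference table
reports them non-negative — while slopes are signed; this split is the only
reading consistent with that table. The canonical feature count is 26
(10 intervals + R-R + 10 amplitudes + 5 slopes). The final beat of each
strip is dropped from feature extraction because the R-R interval *to the
next beat* is a required input feature.

## The personalized one-class model

A ν one-class SVM with linear kernel separates the training cloud from the
origin with maximal margin; ν upper-bounds the fraction of training points
outside the boundary and lower-bounds the support-vector fraction. At
ν = 0.75 both are observed at 0.750 to three decimals on every fitted
subject. The decision score is oriented `score = −(w·x − ρ)`: positive means
dysglycemic (anomalous), zero sits on the boundary and is labelled
euglycemic.

**Why features enter in raw units.** The natural impulse is to z-score
mixed-unit features, but for a *linear* one-class SVM centring is
degenerate: the dual minimizes ½‖Σᵢαᵢxᵢ‖² over the capped simplex, uniform
weights are feasible, and on centred data they give w = 0 — the global
optimum — so the solver returns numerical noise. (Empirically: near-chance
beat AUC under any centred or near-centred scaling.) The reference pipeline
describes no scaling step, and the default here is therefore none;
`feature_scaling = "sd"` (scale without centring) is available. Training
means and SDs are recorded on the model either way, zero-variance features
are dropped with a note, and the solver runs at tolerance 1e-6 with no
randomized initialization, so fitting is deterministic for a fixed input
order.

**Feature importance** is |w| per feature (the longer the component of the
hyperplane normal, the more the feature moves the decision), ranked with
canonical-order tie-breaks and optionally averaged across a cohort. One
caveat is structural: the model is fitted on euglycemic beats only, so the
ranking reflects the geometry of *normal* beats — a between-state shift in
the dysglycemic distribution cannot influence it. A separate, clearly
labelled per-feature ANOVA-F report (`feature_f_scores()`) answers the
"which features differ between states" question; the two rankings are
different statistics and neither is asserted against published values.

## Voting and evaluation

Each validation strip partitions into sixty consecutive 10-s windows
anchored at the strip start; beats vote by R time. A window is dysglycemic
when dysglycemic votes reach at least half its beats — ties break toward
dysglycemia because sensitivity is the clinically primary property — and the
continuous window score is the dysglycemic vote fraction. Empty windows are
emitted unlabelled and excluded from metrics.

Metrics use dysglycemia as the positive class throughout: AUC by the
Mann-Whitney rank statistic with midranks (verified against an explicit
threshold-sweep trapezoidal ROC to 1e-12), sensitivity/specificity/PPV/NPV
at the stated operating point. Cohort tables report the unweighted
per-subject mean and sample SD, never pooled beats. The state-comparison
table uses Welch's two-sided t-test on pooled beats per feature; the
published analysis does not name its test, and Welch is the conservative
default.

## Performance at the published operating points

With between-state shifts at the reference magnitudes and within-subject SD
equal to those shifts (`jitter_frac = 1`, a 10-subject cohort), the pipeline
reaches a mean per-subject beat-level AUC of about 0.94–0.95 — above the
published single-heartbeat figure of 0.92 — and a null cohort
(`effect_scale = 0`) sits at 0.50 within ±0.01, confirming no leakage
anywhere in the pipeline.

The 10-s majority-vote AUC, published as 0.97, is **not** reproduced: the
pipeline reaches about 0.75–0.77 under these conditions, and the shortfall
is structural rather than an implementation defect. ν = 0.75 pins ~75% of
*euglycemic* beats outside the one-class boundary (this is the ν-property,
not a bug), so euglycemic windows vote dysglycemic at rate ~0.74 against
~0.99 for dysglycemic windows; telling Binomial(n, 0.74) from
Binomial(n, 0.99) vote fractions at AUC ≥ 0.97 needs n ≳ 13 beats per
window, i.e. near-full beat retention. But at within-subject SD equal to the
between-state shift, the T-peak position alone has an SD of 0.08 s — ten
samples, a third of the T wave's own support — so most beats fall below the
0.8 template-correlation threshold and only ~4 beats per window survive. The published performance table carries the
same internal tension (beat specificity 0.84 and window specificity 0.96
are jointly inconsistent with ν = 0.75 plus sign-threshold majority voting),
so the window-level bound inherits an inconsistency of its source. The
corresponding check is left failing by design, with this analysis as its
documentation.

## Numerical and reproducibility choices

* Solver tolerances: libsvm 1e-6; wavelet and linear-algebra steps are
  direct (no iteration). Reruns with the same config and seed are
  bit-identical through segmentation and deterministic through metrics.
* Degenerate inputs: flat signal → empty detection with a warning; fewer
  than 8 beats → quality filter skipped with a warning; single-class
  metrics → explicit error; zero-variance features → dropped (model) or
  noted (comparison table).
* Problem sizes: the test suite runs one 20-strip subject for calibration
  checks (> 2000 beats per state), two 10-subject cohorts (effect and null)
  for the performance checks, and 2-subject studies for pipeline plumbing —
  about 350 assertions in ~4 minutes. The acceptance script simulates
  5 calibration subjects and one 10-subject cohort, ~1 minute end to end.
* The CLI (`inst/cli/ecgdys`) is a thin wrapper: `simulate` writes
  WFDB/CSV + BG tables, `run-study` writes models, metrics and a manifest
  with config digest, seeds and per-stage counts (the audit trail standing
  in for manual-inspection logs).

## Known limitations

* The generator's beat-level independence understates real temporal
  correlation; see above for why it is the right default here.
* Fiducials are peak points only — no wave onsets/offsets, no QTc
  correction, no biphasic-wave decomposition.
* The pipeline neither distinguishes hypo- from hyperglycemia (a one-class
  detector sees only "abnormal") nor handles arrhythmic rhythms; subjects
  with atrial fibrillation or pacemakers are excluded by metadata flag, and
  no arrhythmia detector is included.
* Resampling is out of scope: inputs must already be 125 Hz.
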