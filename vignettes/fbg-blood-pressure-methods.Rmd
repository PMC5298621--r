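---
title: "Methods: FBG pulse-wave demodulation and PLS blood-pressure calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FBG pulse-wave demodulation and PLS blood-pressure calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
```

```{r setup, message = FALSE}
library(fbgbp)
```

# The measurement model

A fiber Bragg grating (FBG) is a strain sensor: a periodic refractive-index
grating of pitch $\Lambda$ written into a fiber core of effective index
$n_\mathrm{eff}$ reflects the Bragg wavelength

$$\lambda_B = 2\, n_\mathrm{eff}\, \Lambda .$$

Taped over a pulsation point (e.g. the radial artery at the wrist), the skin
strain from each arterial pressure pulse modulates $\Lambda$ and hence
$\lambda_B$. The interrogator converts the wavelength modulation into an
interferometric phase with an unbalanced Mach-Zehnder interferometer whose
arms differ by an optical path $d$:

$$\Delta\phi = \frac{2\pi\, n_\mathrm{eff}\, d}{\lambda_B^2}\,\Delta\lambda_B .$$

Homodyne detection splits the interferometer output onto three detectors
whose optical phases are offset by $0$, $2\pi/3$ and $4\pi/3$:

$$V_n = \alpha_n\left(C + \cos\!\big(\phi(t) + \tfrac{2\pi (n-1)}{3}\big)\right),
\qquad n = 1, 2, 3,$$

with channel gains $\alpha_n$ and shared offset $C$. After a calibration
measurement normalizes gains and offset to 1 (the sensor is held off the
pulsation point while slow drift sweeps the phase through at least one full
fringe, so each channel traverses its full excursion; gain is half the
peak-to-peak range), the three channels combine to

$$\tan\phi(t) = \frac{\sqrt3\,(V_2 - V_3)}{V_2 + V_3 - 2V_1},$$

an identity that holds exactly for the cosine model above: the numerator is
$-3\sin\phi$ and the denominator $-3\cos\phi$. `demodulate_phase()` therefore
evaluates the *two-argument* arctangent of the negated numerator and
denominator, which lands in the correct quadrant, and then unwraps by forcing
successive phase differences into $(-\pi, \pi]$. Samples where numerator and
denominator both vanish (all channels equal) carry no phase information and
are filled by interpolation. On noiseless synthetic channels the phase is
recovered to machine precision (the package's acceptance checks bound the
error below $10^{-6}$ rad over multi-fringe ramps), up to the inherent global
$2\pi k$ ambiguity of any interferometric measurement — irrelevant here,
because only phase *variations* carry pulse information and the trace mean is
removed before conversion to a wavelength shift.

Two readings of the instrument constants deserve a note. First, the phase
offset term is indexed by the *detector number*; that is the only reading
under which the three-channel arctangent identity holds, and the package
implements it that way. Second, whether $d$ is a geometric or an optical path
difference is an instrument-specification convention; `bragg_config()` takes
it as a plain user value (default 3.33 mm) rather than resolving the
ambiguity silently.

# From wavelength shift to a normalized averaged beat

The FBG measures strain *rate* structure: the recorded waveform is close to
the acceleration pulse wave (the second derivative of the volume pulse), with
its characteristic extrema A (early systolic positive), B (early systolic
negative), C (late systolic re-increase), D (late systolic re-decrease) and
E (early diastolic positive).

`bandpass()` applies the pulse band of 0.5–5 Hz as a zero-phase Butterworth
filter with 4th-order low and high corners. Two numerical choices matter:

* A recursive band-pass designed directly at a 10 kHz sampling rate has
  normalized corners near $10^{-4}$ and is numerically unstable in
  transfer-function form. The trace is therefore decimated by block means to
  roughly $40 f_{hi}$ Hz (an adequate anti-alias pre-filter, since all signal
  content sits far below the decimated Nyquist rate), filtered there, and
  interpolated back onto the original grid.
* The forward–backward pass uses steady-state initial conditions plus
  odd-reflection padding. Zero initial filter state would leave step
  transients that decay over thousands of samples at a 0.5 Hz corner; with
  initial conditions a constant input is annihilated to numerical precision.
  Within a couple of time constants of the record edges some in-band edge
  artifact is unavoidable; beats whose windows touch the record boundary are
  discarded downstream, which also removes this region from the analysis.

`segment_beats()` finds systolic anchors as local maxima above 30 % of the
robust amplitude (90th percentile of $|x|$), thinned by height to a minimum
separation of $60/\mathrm{max\_bpm}$ s. Each beat window spans 30 % of the
median inter-anchor interval before the anchor and 70 % after.
`average_and_normalize()` resamples every beat to a fixed length $L$ with the
anchor pinned at fraction 0.3 (piecewise-linear time normalization; no
dynamic time warping, which the protocol does not call for), averages
pointwise, and applies the affine map that sends the minimum to 0 and the
anchor ("clipping position") to exactly 1. The anchor is pinned rather than
re-detected so the normalization is deterministic; if the averaged beat's
maximum is not at the anchor the function warns instead of silently
re-anchoring. Averaging order is a config switch: `average_first` (default)
averages raw beats then normalizes; `normalize_first` rescales each beat
before averaging. For well-aligned beats the two differ only at second
order.

Defaults: $L = 100$ samples and anchor fraction 0.3. The explanatory-variable
dimension is not dictated by the measurement protocol; 100 points resolve the
five peaks of a beat comfortably while keeping the calibration matrices
small, and the value is a configuration key so experiments are reproducible.

`detect_peaks_abcde()` reports A as the global maximum and B–E as the
alternating local extrema that follow, with amplitudes relative to the
diastolic baseline (mean of the first and last 5 % of samples), so B and D
are negative for a healthy-pattern beat. An extremum that does not exist is
reported as missing, never fabricated. Clinical pattern *classification*
(the seven age/vascular-disease waveform patterns) is deliberately out of
scope: no published decision rule accompanies the pattern catalogue, so the
package stops at peak geometry and amplitude ratios.

# PLS1 calibration with PRESS/F-test factor selection

The normalized beat (length $L$) is the explanatory variable; the
cuff-reference systolic pressure is the objective variable, which carries
measurement error of its own — the reason partial least squares is preferred
over principal-component regression here. `fit_pls()` implements NIPALS PLS1
from first principles on mean-centered data without variance scaling (beats
already share the $[0,1]$ scale):

1. $w \propto X^\top y$, normalized;
2. scores $t = Xw$; loadings $p = X^\top t / t^\top t$,
   $q = y^\top t/t^\top t$;
3. deflation $X \leftarrow X - t p^\top$, $y \leftarrow y - q\,t$; repeat.

The regression vector is $b = W (P^\top W)^{-1} q$. At full rank the fit
coincides with ordinary least squares — the test suite checks this against an
independent normal-equations oracle, and checks leave-one-out PRESS against a
brute-force re-implementation built on the Krylov-subspace formulation of
PLS1, to $10^{-8}$.

The factor count is chosen sequentially: starting from the mean-only model
($k=0$, whose PRESS is defined by predicting each held-out record with the
mean of the rest), factor $k+1$ is admitted iff
$\mathrm{PRESS}(k)/\mathrm{PRESS}(k+1)$ exceeds the upper $\alpha$ critical
value of $F(n, n)$. The first non-significant step stops the sequence and
the smaller model is kept. Conventions the protocol leaves open, fixed here
and exposed in the configuration:

* degrees of freedom $(n, n)$ and $\alpha = 0.05$;
* *consecutive* model comparison (not each model against the global PRESS
  minimum, the Haaland–Thomas variant);
* the minimum returned factor count is 1 — a zero-factor "calibration
  curve" is not a curve.

Evaluation on a held-out validation set reports
$\mathrm{SEP} = \sqrt{\sum (\hat y - y)^2/(n-1)}$ (the "measurement
accuracy", in mmHg; bias is reported separately rather than removed) and the
Pearson correlation R between predicted and reference pressure on the
validation set (not the calibration fit).

# What the synthetic subjects emulate

Real subjects are replaced by a generative model whose structure matches what
the calibration method assumes:

* **Morphology.** One beat is a sum of five Gaussian bumps (A positive and
  dominant at beat fraction 0.30, B and D negative, C and E positive). Each
  bump amplitude moves *linearly* with the latent pressure,
  $a_j(\mathrm{bp}) = a_j^0 + s_j\,(\mathrm{bp} - \mathrm{bp}_\mathrm{anchor})$
  — the minimal coupling under which a linear calibration of beat shape on
  pressure is correct. Slopes are a few $10^{-3}$ amplitude units per mmHg,
  i.e. shape ratios change by a few percent across a subject's pressure
  range.
* **Three subjects on one line.** The presets (means 111.3, 123.1 and
  100.9 mmHg; per-subject spreads of 5.6, 5.1 and 4.0 mmHg, so a 50-record
  draw spans roughly ±10–12 mmHg) share a single pressure–morphology line
  anchored at the pooled mean of 111.8 mmHg. Individual differences enter
  as small idiosyncratic bump-amplitude offsets off that line, bump-width
  differences, and per-subject sensitivity scales (1.0, 1.2, 0.85). This is
  what makes the pooled experiment behave like the study it emulates: pooled
  data are mutually consistent (the pooled calibration resembles the
  identity line, so its correlation coefficient is *higher* than any
  within-subject correlation), while the off-line offsets and slope
  mismatches cost the pooled curve accuracy relative to the individual
  curves.
* **Noise sources.** Detector noise (additive Gaussian per channel, default
  0.01 of the fringe amplitude — a high-SNR interrogator), cuff-reference
  error (2 mmHg, a documented assumption: reference-device error is not part
  of the published protocol), and record-level physiological variability:
  each record perturbs every bump amplitude by `Normal(0, 0.003)`. The last
  is the dominant error source, as it is in practice — posture, sensor
  coupling and vasomotor state move beat shape between repeated measurements
  without moving blood pressure, and unlike detector noise it does not
  average out over the ~20 beats of a record. Its default was set so the
  synthetic bench lands in the accuracy regime the method reports on real
  subjects (individual SEP of roughly 2–4 mmHg rather than fractions of a
  mmHg), which is what makes the individual-vs-pooled comparison meaningful.
* **Record assembly.** Beats are tiled at the subject's heart rate with ±3 %
  interval jitter, scaled to an interferometric phase (2 rad per unit
  amplitude) and superposed on a slow (< 0.2 Hz) baseline drift large enough
  to sweep a full fringe — so channel calibration can be estimated from the
  record itself — before three-phase encoding. All randomness flows from one
  master seed through named sub-streams (subject / split / record), so
  regenerating one split never perturbs another and the full experiment is
  byte-reproducible.

What the generator does **not** emulate: mechanistic hemodynamics
(Windkessel-type models), elderly or arteriosclerotic waveform patterns,
motion artifacts, respiration coupling, or sensor placement effects. Passing
tests on synthetic subjects therefore demonstrate that the *pipeline and
calibration machinery* are correct under the method's own assumptions — not
that the method generalizes across real physiology.

# The individual-vs-overall experiment

`run_experiment()` reproduces the two-arm design: 50 calibration and 25
validation records per subject, 20 s each at 10 kHz. Arm one fits one
calibration curve per subject on that subject's calibration records only
(individual differences cannot influence its validation). Arm two fits a
single curve on the pooled 150 calibration records and evaluates it on each
subject's validation set and on the pooled validation set. Validation is a
genuinely separate record set; leave-one-out is used only inside factor
selection, never for the final evaluation.

```{r experiment, eval = FALSE}
report <- run_experiment(experiment_config(seed = 1))
report$results
autoplot(report)
```

On the default seed this produces individual curves with R of about
0.83–0.94 and SEP of 2.1–2.8 mmHg, and a pooled curve whose pooled-validation
R (~0.97) exceeds every within-subject R while its SEP (~2.6 mmHg) cannot
beat the best individual curve — the qualitative signature of pooling
mutually consistent subjects. (These numbers are computed by
`scripts/acceptance.R` and the acceptance tests; the vignette does not
restate results the code does not produce.) Subject C, whose pressure range
is the narrowest, has the least stable correlation across re-simulations —
the within-subject spread is only about twice the achievable accuracy, so r
fluctuates considerably from one 25-record draw to the next; the same
subject is the weakest correlation in the real study too.

Reduced problem sizes (shorter records at 2 kHz, 5–8 records per split) are
used in the unit tests and the determinism check; they exercise identical
code paths, and the full 3 × 75-record experiment at 10 kHz is run in the
acceptance suite.

# Degenerate inputs and numerical conventions

* Channel calibration refuses a record with a zero peak-to-peak channel
  (no fringe sweep); demodulation refuses a record that is degenerate at
  every sample.
* Beat segmentation requires ≥ 5 s of signal and ≥ 3 complete beats;
  averaging requires ≥ 3 beats; the normalization errors out if the anchor
  value equals the beat minimum.
* `fit_pls()` requires a non-constant objective variable and
  $k \le \min(n-1, \mathrm{rank}(X_c))$; leave-one-out tightens this to
  $n - 2$. PRESS ties at exactly zero stop factor growth (no improvement).
* Ties in peak detection resolve to the first index; plateaus are not
  extrema.
* SEP uses the $n-1$ denominator without bias removal; bias is reported
  separately.

# Known limitations

* The linear morphology–pressure coupling is an idealization; real
  acceleration-pulse-wave ratios saturate and drift with vasomotor tone.
* The affine beat normalization makes the map from morphology to the
  explanatory variables mildly nonlinear (division by the anchor-minus-min
  scale); in the noiseless limit this leaves a residual of ~0.1 mmHg,
  absorbed by extra PLS factors.
* Pattern labeling (A–G waveform classes) is out of scope, as is any
  pulse-transit-time method, respiration or stress extraction, and real
  acquisition hardware.
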