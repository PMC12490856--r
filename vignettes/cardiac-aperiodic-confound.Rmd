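---
title: "Cardiac contamination of aperiodic spectral slopes: models, estimators, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac contamination of aperiodic spectral slopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardioslope)
```

## 1. The scientific question

Power spectra of cortical field recordings decay roughly as
$P(f) \propto 1/f^{\chi}$. The exponent $\chi$ (equivalently the signed
log–log slope $b = -\chi$) changes with age and cognitive state and is a
popular readout of excitation/inhibition balance. The confound this
package studies: the heart's field is volume-conducted into MEG/EEG
sensors, the ECG's own aperiodic spectrum also changes with age, and the
standard cleaning step — ICA with a correlation threshold against a
concurrent ECG channel — removes cardiac activity only partially. A
"cortical" slope–age association may therefore be inherited from the
heart. The package provides (i) generative models for both signal
classes, (ii) the full estimation chain, and (iii) an inference layer
that classifies effects, so that the confound can be created, measured,
and removed under controlled conditions.

## 2. Generative models

**Colored noise.** `generate_colored_noise()` shapes Gaussian white
noise in the frequency domain by $(k + f^{\chi})^{-1/2}$ and rescales to
a target variance, so the target spectrum
$P(f) \propto 1/(k + f^{\chi})$ holds exactly in expectation. $k = 0$
gives a pure power law; $k = f_k^{\chi}$ places a plateau ("knee") at
$f_k$ Hz.

**Neural signals.** `generate_neural_ei()` implements the
excitation/inhibition convolution model: pooled excitatory and
inhibitory Poisson spike trains (default 2 Hz × 8000 and × 2000 neurons,
collapsed to one train per population) are convolved with bi-exponential
synaptic kernels (rise/decay 0.1/2 ms excitatory, 0.5/10 ms inhibitory)
and summed as $exc + r \cdot inh$ with the inhibitory weight $r = 2$
("1:2" E/I balance) by default. Kernels are normalized to unit *peak*,
not unit area, so the slower inhibitory kernel carries more charge per
event — this is what makes the summed current's high-frequency slope
steepen as $r$ grows, the model family's defining behavior. The
30–70 Hz exponent at the defaults is ≈ 1.3 and increases with $r$.

**Cardiac signals.** `generate_cardiac()` places a PQRST template — the
standard sum-of-five-Gaussians synthetic ECG, R wave dominant, broad low
T wave — at onsets $i/\text{rate} + \mathcal N(0, \sigma_j^2)$ (default
rate 1 Hz, jitter SD 50 ms) and adds colored noise scaled by
`noise_weight`. Specs where $4\sigma_j > 0.5/\text{rate}$ are rejected
so complexes can never overlap; draws beyond 4 SD are clipped for the
same reason (negligible mass at admissible specs).

**Mixing.** `mix_two_sources()` z-scores both sources before weighting,
so the cardiac weight is an interpretable amplitude (SNR) ratio.
`mix_multichannel()` emulates volume conduction: channels are fixed
weighted sums of z-scored sources plus white sensor noise, with an
`ecg_ref` channel carrying the cardiac source nearly clean. The default
topographies (`default_mixing_matrix()`) are sine/cosine harmonics over
the channel axis — spatially smooth, mutually near-orthogonal patterns,
as distinct generators project onto a sensor array.

**Cohorts.** `generate_cohort()` has two modes. *Slope-level* draws a
per-subject slope $\beta_{true}\,z(\text{age}) + \mathcal N(0,\sigma)$
(default $\sigma = 1$, so $\beta_{true} = 0.5$ implies a standardized
effect $\beta/\sqrt{\beta^2+\sigma^2} = 0.447$) — the fast path for
calibrating the inference layer. *Signal-level* builds one multichannel
recording per subject in which the targeted source class (cardiac,
neural, or both) has exponent
$\chi_i = \chi_0 + \beta_{true}\,s\,z(\text{age}_i) + \mathcal N(0, 0.2)$
with $\chi_0 = 1.5$ and scale $s = 0.4$.

## 3. The synthetic world: what it states and why

Three properties of the synthetic world were fixed after their absence
proved to make the target phenomena physically unmeasurable; they are
part of the stated world, not tuning knobs.

**Low-frequency plateaus.** A *pure* power law normalized to unit
variance parks almost all of its variance at the lowest representable
frequencies once $\chi \gtrsim 2$ (the integral $\int f^{-\chi} df$
diverges toward DC). In any mixture normalized this way, the steepest
source is then essentially absent from the analysis band, so neither
contamination ordering nor cohort effects can be expressed. Real
physiological spectra flatten toward DC. Cohort sources therefore carry
a knee at 0.5 Hz (`knee_hz`), and the contamination demonstrations use
kneed noise likewise.

**Amplitude modulation.** Stationary Gaussian colored noise is
*unseparable* by non-Gaussianity-maximizing ICA: within a Gaussian
subspace the unmixing rotation is indeterminate and FastICA provably
oscillates. Real field recordings are amplitude-modulated and
leptokurtic. `modulate_amplitude()` imposes a slow positive envelope
(bounded below at 0.2, depth 0.5, bandwidth 1 Hz) that leaves the
spectrum essentially unchanged while giving sources the excess kurtosis
that makes blind separation possible. ICA-bearing fixtures use it;
`fit_ica` keeps its contract of erroring with diagnostics when the
rotation genuinely cannot converge (e.g., components requested beyond
the non-Gaussian rank).

**Instrument noise floor.** The white sensor-noise SD defaults to 0.01
relative to unit-variance sources. At 0.05 the flat floor overtakes
$\chi \ge 2$ source spectra above ≈ 60 Hz, which *inverts* age effects:
steeper true exponents hit the floor earlier and measure flatter. Real
magnetometer noise floors sit well below in-band physiological signal;
the synthetic world matches that.

What a green test therefore establishes: the estimation chain recovers
the stated generative structure — it does not establish that real MEG
spectra have 0.5 Hz knees, nor that real sensor noise is negligible,
nor anything about any particular empirical dataset.

## 4. Estimators

**Welch.** Hann window, 50% overlap, per-segment constant detrend, mean
averaging; segment length = `sfreq / resolution` samples, so the stated
resolution is exactly the bin spacing. Density scaling satisfies
Parseval within windowing loss.

**IRASA.** For each factor $h$ in the default set 1.10–1.90 (step
0.05), the signal is resampled by $h$ and $1/h$ (FFT sinc resampling,
implicitly anti-aliased) and the geometric mean of the two Welch
spectra taken; the fractal spectrum is the median over the set and the
oscillatory residual is the original PSD minus the fractal — possibly
negative, never clipped. Self-similar activity is invariant; narrowband
peaks are displaced and removed by the median. The analysis band must
stay below $f_s/(2 h_{max})$.

**Aperiodic fits.** Fixed mode is analytic OLS of $\log_{10} P$ on
$\log_{10} f$ (tested to $10^{-9}$ against an independent `lm()`
oracle). Knee mode minimizes squared log-residuals of
$offset - \log_{10}(k + f^{\chi})$ by Nelder–Mead in
$(\log\chi, \log k, offset)$, initialized from a fixed fit above 30 Hz
with three start points; non-convergence is flagged, never silently
replaced. `parametrize_spectrum()` adds the specparam-style loop:
robust aperiodic fit (top 2.5% residuals dropped), iterative Gaussian
peak extraction (height > 2 SD of the flattened spectrum, widths
clipped to 1–6 Hz, ≤ 2 peaks), final refit on the peak-subtracted
spectrum. `slope_grid()` crosses lower limits 0.5–10 Hz (1 Hz steps)
with upper limits 45–145 Hz (5 Hz steps) — 210 cells — by default;
ECG-style analyses use the low (0.25–20 Hz) / high (10–145 Hz) split
that keeps the ~15 Hz cardiac knee out of mid-range. Grid fits operate
on one broadband IRASA split refit per range (not one split per range).

**ICA and conditions.** FastICA with logcosh contrast, symmetric
decorrelation, tolerance $10^{-4}$, ≤ 500 iterations, seeded random
init; fit on a 1 Hz high-passed copy, applied to the original data;
components scaled to unit variance (sign arbitrary, hence |r|
thresholds). Classification: cardiac iff $|r_{ECG}| > 0.4$, else ocular
iff $|r_{EOG}| > 0.8$; every component above threshold is labeled — no
argmax. The three conditions are back-projections (cardiac kept /
removed / alone); variance outside the retained ICA subspace stays with
the first two conditions, and additivity
(`rejected + components = kept`) holds to machine tolerance by
linearity. The Riemannian potato computes per-epoch covariances
(trace-scaled ridge if near-singular), the affine-invariant Karcher
mean, and rejects epochs beyond 2.5 SD of distance, re-iterating twice.

**TRFs.** $y_t = \sum_{\tau} h_\tau x_{t-\tau}$ over ±250 ms, kernel in
a basis of 50 ms Hamming bumps at 50% overlap (spacing is the one
free choice; 50% is the common default and is config-exposed). Inputs
are 45 Hz low-passed, resampled to 100 Hz, z-scored. Ridge penalty from
$10^{-3}..10^{3}$ chosen by four-fold nested cross-validation on
contiguous time blocks (two train, one validation, one test; every
block tests once); accuracy is held-out Pearson r averaged over
rotations. Rows with out-of-range lags are dropped, not zero-padded.
Note the basis cannot represent a perfect delta for broadband signals;
for band-limited (M/EEG-like) inputs the identity mapping is recovered
with r > 0.99.

## 5. Inference

Both variables are z-scored, so coefficients are standardized. The
default backend bootstraps subject pairs (≥ 2000 resamples) and
summarizes the OLS slope draws by their median and 94% highest-density
interval; the Bayesian backend is a conjugate Gibbs sampler
(Normal(0,1) priors on slope and intercept, Inv-Gamma(2,1) on the
residual variance — weakly informative on the standardized scale) with
split-chain R-hat < 1.05 and ESS > 400 enforced. The ROPE decision
rule on the signed-slope scale: interval entirely outside ±0.1 →
steepening (negative) or flattening (positive); entirely inside → null;
otherwise undecided, direction from the median (an exact zero ties
toward steepening, the a-priori direction — logged here once). No
multiplicity correction is applied across the grid: the ROPE + HDI
taxonomy *is* the decision procedure, matching the analysis style the
package reproduces. `task_contrast()` estimates
`slope ~ 1 + phase + (1 | subject)` by REML (lme4) and takes the 94%
HDI of normal draws around the fixed effect — a flat-prior large-sample
approximation chosen over a per-subject bootstrap of mixed-model fits
for tractability.

Calibration (tested): at $n = 600$ the null false-significance rate is
≤ 6%, intervals cover the true standardized effect at 94% ± 3%, and no
directional error occurs at $|\beta| = 0.45$ across hundreds of
replicates.

## 6. The demonstration and its two scenarios

`run_demo()` composes everything: generate a signal-level cohort, run
per-subject ICA → three conditions → Welch slope grids (signed slopes
$b = -\chi$), then the bootstrap multiverse with ROPE classification, a
joint model (age ~ components-slope + rejected-slope), and a backward-TRF
decoding diagnostic. In the *cardiac* scenario (the heart's exponent
drifts with age) significant cells concentrate overwhelmingly in the
ECG-components condition and vanish in the ECG-rejected condition; in
the *neural* scenario effects survive cardiac rejection. Reruns with
the same config are byte-identical (every stochastic stage's seed
derives from the config seed). The desk-scale default (100 subjects,
60 s at 250 Hz, 8 channels, reduced 4 × 5 grid) completes in minutes on
one CPU; the full 210-cell grid is available by passing
`default_meg_grid()` limits.

## 7. Numerical choices and degenerate inputs

- Colored-noise realizations are exact in expectation, so exponent
  recovery error is pure estimator variance (< 0.1 mean absolute error
  at 60 s × 500 Hz).
- Welch bin SD scales as $1/\sqrt{T}$; per-bin statements about IRASA's
  oscillatory residual need several minutes of signal.
- Knee fits are exact (≪ 1%) on model-generated spectra; on real-world
  spectra the knee/exponent trade-off near the band edge is the usual
  caveat.
- Zero-variance channels, non-positive power in a fit range, collinear
  predictors (|r| > 0.99), zero-variance references, and sub-minimum
  sample sizes all raise immediate, specific errors rather than
  propagating NaNs.
- The R-peak detector's constants (100 ms envelope smoothing, 1.5 ×
  rolling median threshold, 250 ms refractory) are config-exposed;
  detection is amplitude-scale invariant by construction.

## 8. Known limitations

- No head-model forward solutions: mixing matrices are abstract
  topographies, so spatial claims do not transfer.
- Heart-rate dynamics are Gaussian onset jitter only — no respiratory
  sinus arrhythmia or RR autocorrelation; SDNN ≈ √2 × jitter SD but
  RMSSD/SDNN ratios of real HRV are not emulated.
- The Bayesian backend covers the univariate standardized model only;
  grid-scale runs use the bootstrap.
- EDF I/O is not implemented (no reader available in the dependency
  budget); recordings interchange as headered delimited text.
- The frequency-domain and nonlinear HRV battery is out of scope; the
  association machinery (`correlate_hrv_slope`) is index-agnostic so it
  can be extended.
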