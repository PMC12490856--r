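#' Specification of colored (1/f-like) noise
#'
#' Describes an aperiodic noise process with target power spectrum
#' \eqn{P(f) \propto 1/(k + f^{\chi})}: `exponent_chi` is the aperiodic
#' exponent \eqn{\chi} (0 = white noise), `knee_param` the knee constant
#' \eqn{k} (0 = pure power law), and `variance` the target signal variance.
#'
#' @param exponent_chi aperiodic exponent, >= 0.
#' @param knee_param knee constant, >= 0 (0 for a pure power law).
#' @param variance target variance of the generated signal, > 0.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(exponent_chi = 1, knee_param = 0, variance = 1) {
  assert_scalar_num(exponent_chi, "exponent_chi", lower = 0)
  assert_scalar_num(knee_param, "knee_param", lower = 0)
  assert_scalar_num(variance, "variance", lower = 0, strict_lower = TRUE)
  structure(list(exponent_chi = exponent_chi, knee_param = knee_param,
                 variance = variance),
            class = "noise_spec")
}

#' Specification of a synthetic cardiac (PQRST) signal
#'
#' A quasi-periodic train of PQRST complexes at `beat_rate` Hz with
#' Gaussian-jittered onsets, optionally riding on colored noise. The
#' PQRST template is a sum of five Gaussians (the standard synthetic-ECG
#' construction) with lead-II-like defaults: a dominant narrow R wave and
#' a broad low T wave.
#'
#' @param beat_rate heart rate in Hz (~1 Hz resting).
#' @param onset_jitter_sd SD of the Gaussian beat-onset jitter, seconds.
#'   Specs where `4 * onset_jitter_sd > 0.5 / beat_rate` are rejected so
#'   adjacent complexes can never overlap.
#' @param wave_params data.frame with columns `wave`, `amplitude`,
#'   `center` (s, offset from beat onset), `width` (s, Gaussian SD).
#' @param noise a [noise_spec()] for the additive aperiodic component.
#' @param noise_weight weight in `[0, 1]` of the (unit-variance) noise
#'   relative to the (unit-peak-normalized) PQRST train.
#' @return An object of class `cardiac_spec`.
#' @export
cardiac_spec <- function(beat_rate = 1,
                         onset_jitter_sd = 0.05,
                         wave_params = default_pqrst_waves(),
                         noise = noise_spec(exponent_chi = 1),
                         noise_weight = 0.5) {
  assert_scalar_num(beat_rate, "beat_rate", lower = 0, strict_lower = TRUE)
  assert_scalar_num(onset_jitter_sd, "onset_jitter_sd", lower = 0)
  assert_scalar_num(noise_weight, "noise_weight", lower = 0, upper = 1)
  stopifnot(inherits(noise, "noise_spec"))
  req <- c("wave", "amplitude", "center", "width")
  if (!is.data.frame(wave_params) || !all(req %in% names(wave_params)))
    stop_invalid("`wave_params` needs columns %s", paste(req, collapse = ", "))
  if (any(wave_params$width <= 0))
    stop_invalid("wave widths must be > 0")
  r_amp <- abs(wave_params$amplitude[wave_params$wave == "R"])
  if (!length(r_amp) || any(abs(wave_params$amplitude) > r_amp))
    stop_invalid("the R wave must carry the largest absolute amplitude")
  if (4 * onset_jitter_sd > 0.5 / beat_rate)
    stop_invalid(
      "onset jitter too large: adjacent complexes could overlap (need 4*jitter_sd <= 0.5/beat_rate)")
  structure(list(beat_rate = beat_rate, onset_jitter_sd = onset_jitter_sd,
                 wave_params = wave_params, noise = noise,
                 noise_weight = noise_weight),
            class = "cardiac_spec")
}

#' Default PQRST wave parameters (lead-II-like)
#'
#' Amplitudes in arbitrary units (R normalized to 1), centers in seconds
#' relative to beat onset, widths as Gaussian SDs in seconds.
#' @return data.frame with one row per wave.
#' @export
default_pqrst_waves <- function() {
  data.frame(
    wave      = c("P", "Q", "R", "S", "T"),
    amplitude = c(0.15, -0.10, 1.00, -0.25, 0.35),
    center    = c(0.10, 0.23, 0.25, 0.27, 0.45),
    width     = c(0.025, 0.010, 0.011, 0.010, 0.045),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic neural (E/I convolution) signal
#'
#' Local-field-like activity modeled as pooled excitatory and inhibitory
#' Poisson spike trains convolved with bi-exponential synaptic kernels;
#' the summed current is `exc + ei_ratio * inh`. Larger `ei_ratio`
#' (relatively more inhibition, with its slower decay) steepens the
#' high-frequency spectral slope.
#'
#' @param ei_ratio inhibitory:excitatory weight ratio (2 = the "1:2"
#'   E/I balance).
#' @param exc_rise,exc_decay excitatory kernel time constants, seconds.
#' @param inh_rise,inh_decay inhibitory kernel time constants, seconds.
#' @param spike_rate mean rate per neuron, Hz.
#' @param n_exc,n_inh pooled population sizes (collapsed to one Poisson
#'   train per population).
#' @return An object of class `neural_spec`.
#' @export
neural_spec <- function(ei_ratio = 2,
                        exc_rise = 0.0001, exc_decay = 0.002,
                        inh_rise = 0.0005, inh_decay = 0.010,
                        spike_rate = 2, n_exc = 8000, n_inh = 2000) {
  assert_scalar_num(ei_ratio, "ei_ratio", lower = 0)
  assert_scalar_num(spike_rate, "spike_rate", lower = 0)
  for (nm in c("exc_rise", "exc_decay", "inh_rise", "inh_decay"))
    assert_scalar_num(get(nm), nm, lower = 0, strict_lower = TRUE)
  if (exc_decay <= exc_rise || inh_decay <= inh_rise)
    stop_invalid("synaptic kernels need decay > rise > 0")
  if (inh_decay <= exc_decay)
    stop_invalid("inhibitory decay must exceed excitatory decay")
  structure(list(ei_ratio = ei_ratio,
                 exc_rise = exc_rise, exc_decay = exc_decay,
                 inh_rise = inh_rise, inh_decay = inh_decay,
                 spike_rate = spike_rate, n_exc = n_exc, n_inh = n_inh),
            class = "neural_spec")
}

#' Generate colored noise with a prescribed aperiodic spectrum
#'
#' Spectral shaping: Gaussian white noise is transformed to the frequency
#' domain, multiplied by \eqn{(k + f^{\chi})^{-1/2}} (for \eqn{k = 0}
#' this is \eqn{f^{-\chi/2}}), transformed back, and rescaled to the
#' target variance — so the target spectrum holds exactly in expectation.
#'
#' @param n_samples number of samples (>= 2 s worth).
#' @param sfreq sampling rate, Hz.
#' @param spec a [noise_spec()].
#' @param seed RNG seed; the generator is a pure function of it.
#' @return numeric vector, zero mean, variance `spec$variance`.
#' @export
#' @examples
#' x <- generate_colored_noise(5000, 500, noise_spec(exponent_chi = 1.5), seed = 1)
#' var(x)
generate_colored_noise <- function(n_samples, sfreq, spec = noise_spec(),
                                   seed = 1) {
  assert_scalar_num(n_samples, "n_samples", lower = 0, strict_lower = TRUE)
  assert_scalar_num(sfreq, "sfreq", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(spec, "noise_spec"))
  n <- as.integer(n_samples)
  if (n < 2 * sfreq)
    stop_invalid("need at least 2 s of samples (n_samples >= 2*sfreq)")
  w <- with_local_seed(seed, stats::rnorm(n))
  freqs <- seq(0, n - 1) * (sfreq / n)
  freqs <- pmin(freqs, sfreq - freqs)       # two-sided |f|
  amp <- rep(0, n)
  pos <- freqs > 0
  amp[pos] <- (spec$knee_param + freqs[pos]^spec$exponent_chi)^(-0.5)
  x <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sqrt(spec$variance) / stats::sd(x)
}

# bi-exponential synaptic kernel, unit peak amplitude (so the slower
# inhibitory kernel carries more charge per event, as in conductance-based
# E/I models)
bi_exp_kernel <- function(rise, decay, sfreq, n_taps = NULL) {
  if (is.null(n_taps)) n_taps <- ceiling(8 * decay * sfreq)
  t <- seq(0, n_taps) / sfreq
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

#' Generate a neural signal from the E/I convolution model
#'
#' Pooled Poisson spike counts per sample (one train per population, rate
#' `spike_rate * n_pop`) are convolved with the population's bi-exponential
#' kernel; the output is `exc_current + ei_ratio * inh_current`, mean
#' removed. Its spectrum decays monotonically above a few Hz with a slope
#' governed by the kernel time constants and the E/I ratio.
#'
#' @param duration seconds, >= 10.
#' @param sfreq sampling rate, Hz.
#' @param spec a [neural_spec()].
#' @param seed RNG seed.
#' @return numeric vector of `duration * sfreq` samples.
#' @export
generate_neural_ei <- function(duration, sfreq, spec = neural_spec(),
                               seed = 1) {
  assert_scalar_num(duration, "duration", lower = 10)
  assert_scalar_num(sfreq, "sfreq", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(spec, "neural_spec"))
  n <- as.integer(round(duration * sfreq))
  lam_e <- spec$spike_rate * spec$n_exc / sfreq
  lam_i <- spec$spike_rate * spec$n_inh / sfreq
  trains <- with_local_seed(seed, list(
    exc = stats::rpois(n, lam_e),
    inh = stats::rpois(n, lam_i)))
  if (spec$spike_rate == 0) return(numeric(n))
  ke <- bi_exp_kernel(spec$exc_rise, spec$exc_decay, sfreq)
  ki <- bi_exp_kernel(spec$inh_rise, spec$inh_decay, sfreq)
  cur_e <- causal_convolve(trains$exc - lam_e, ke)
  cur_i <- causal_convolve(trains$inh - lam_i, ki)
  x <- cur_e + spec$ei_ratio * cur_i
  x - mean(x)
}

causal_convolve <- function(x, h) {
  n <- length(x); m <- length(h)
  nfft <- next_pow2(n + m - 1L)
  y <- Re(stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                       stats::fft(c(h, rep(0, nfft - m))),
                     inverse = TRUE)) / nfft
  y[1:n]
}

#' Generate a quasi-periodic cardiac (PQRST) signal
#'
#' Places one Gaussian-sum PQRST template at each jittered beat onset
#' `i / beat_rate + N(0, jitter_sd)` and adds `noise_weight`-scaled
#' colored noise. The template train is normalized to unit R-peak
#' amplitude; the noise to unit SD, so `noise_weight` acts as a
#' noise-to-beat amplitude ratio.
#'
#' @param duration seconds, >= 10.
#' @param sfreq sampling rate, >= 100 Hz.
#' @param spec a [cardiac_spec()].
#' @param seed RNG seed.
#' @return numeric vector of `duration * sfreq` samples.
#' @export
generate_cardiac <- function(duration, sfreq, spec = cardiac_spec(),
                             seed = 1) {
  assert_scalar_num(duration, "duration", lower = 10)
  assert_scalar_num(sfreq, "sfreq", lower = 100)
  stopifnot(inherits(spec, "cardiac_spec"))
  n <- as.integer(round(duration * sfreq))
  n_beats <- floor(duration * spec$beat_rate)
  onsets <- (seq_len(n_beats) - 1) / spec$beat_rate
  if (spec$onset_jitter_sd > 0) {
    jit <- with_local_seed(seed, stats::rnorm(n_beats, 0,
                                              spec$onset_jitter_sd))
    # truncate pathological draws (>4 SD) so complexes can never collide;
    # at admissible specs this clips a negligible fraction of the mass
    lim <- min(4 * spec$onset_jitter_sd, 0.25 / spec$beat_rate)
    onsets <- onsets + pmax(pmin(jit, lim), -lim)
  }
  t <- (seq_len(n) - 1) / sfreq
  x <- numeric(n)
  for (k in seq_len(n_beats)) {
    for (w in seq_len(nrow(spec$wave_params))) {
      mu <- onsets[k] + spec$wave_params$center[w]
      sdw <- spec$wave_params$width[w]
      lo <- max(1L, floor((mu - 5 * sdw) * sfreq) + 1L)
      hi <- min(n, ceiling((mu + 5 * sdw) * sfreq) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] + spec$wave_params$amplitude[w] *
        exp(-0.5 * ((t[idx] - mu) / sdw)^2)
    }
  }
  r_amp <- abs(spec$wave_params$amplitude[spec$wave_params$wave == "R"][1])
  x <- x / r_amp
  if (spec$noise_weight > 0) {
    nz <- generate_colored_noise(
      n, sfreq, noise_spec(spec$noise$exponent_chi, spec$noise$knee_param,
                           variance = 1),
      seed = seed + 104729)               # decoupled noise substream
    x <- x + spec$noise_weight * nz
  }
  x
}

#' Mix one neural and one cardiac source into a single trace
#'
#' Both sources are z-scored before mixing so `cardiac_weight` is an
#' interpretable cardiac-to-neural amplitude (SNR) ratio:
#' `z(neural) + cardiac_weight * z(cardiac)`.
#'
#' @param neural,cardiac equal-length numeric vectors.
#' @param cardiac_weight nonnegative mixing weight.
#' @return numeric vector.
#' @export
mix_two_sources <- function(neural, cardiac, cardiac_weight = 1) {
  assert_scalar_num(cardiac_weight, "cardiac_weight", lower = 0)
  if (length(neural) != length(cardiac))
    stop_invalid("`neural` and `cardiac` must have equal length")
  zscore(neural) + cardiac_weight * zscore(cardiac)
}

#' Mix sources into a multichannel sensor recording
#'
#' Emulates volume conduction: each sensor channel is a fixed weighted sum
#' of the (z-scored) sources plus white sensor noise. An `ecg_ref` channel
#' carrying the cardiac source plus a small amount of white noise is
#' appended when `cardiac_index` is given.
#'
#' @param sources list of equal-length numeric source signals.
#' @param mixing_matrix channels x sources weight matrix.
#' @param sfreq sampling rate, Hz.
#' @param sensor_noise_sd white sensor noise SD (sources are z-scored, so
#'   this is relative to unit source amplitude).
#' @param cardiac_index index into `sources` of the cardiac source used
#'   for the ECG reference channel, or `NULL` for none.
#' @param ecg_noise_sd white noise SD on the ECG reference channel.
#' @param seed RNG seed.
#' @return a [ts_recording()] with sensor channels plus the ECG reference.
#' @export
mix_multichannel <- function(sources, mixing_matrix, sfreq,
                             sensor_noise_sd = 0.1, cardiac_index = NULL,
                             ecg_noise_sd = 0.05, seed = 1) {
  assert_scalar_num(sensor_noise_sd, "sensor_noise_sd", lower = 0)
  if (!is.list(sources) || !length(sources))
    stop_invalid("`sources` must be a non-empty list of signals")
  n <- unique(vapply(sources, length, 1L))
  if (length(n) != 1L)
    stop_invalid("all sources must have equal length")
  mixing_matrix <- as.matrix(mixing_matrix)
  if (ncol(mixing_matrix) != length(sources))
    stop_invalid("mixing_matrix must have one column per source")
  if (all(mixing_matrix == 0))
    stop_invalid("mixing_matrix has rank 0 (all-zero weights)")
  S <- vapply(sources, zscore, numeric(n))       # n x n_sources
  X <- S %*% t(mixing_matrix)                    # n x n_channels
  nch <- ncol(X)
  noise <- with_local_seed(seed, stats::rnorm(n * (nch + 1L)))
  X <- X + sensor_noise_sd * matrix(noise[1:(n * nch)], n, nch)
  roles <- rep("sensor", nch)
  if (!is.null(cardiac_index)) {
    ecg <- S[, cardiac_index] + ecg_noise_sd * noise[(n * nch + 1L):(n * (nch + 1L))]
    X <- cbind(X, ecg)
    roles <- c(roles, "ecg_ref")
  }
  nm <- c(sprintf("ch%02d", seq_len(nch)),
          if (!is.null(cardiac_index)) "ecg")
  ts_recording(X, sfreq = sfreq, roles = roles, channel_names = nm)
}

#' Specification of a synthetic age-structured cohort
#'
#' @param n_subjects number of subjects, >= 2.
#' @param age_range `(min, max)` age in years, sampled uniformly.
#' @param beta_true regression coefficient of the targeted aperiodic
#'   parameter on z-scored age (unstandardized outcome scale).
#' @param noise_sd residual SD of the targeted parameter. The implied
#'   standardized effect is `beta_true / sqrt(beta_true^2 + noise_sd^2)`.
#' @param target which source class carries the age effect:
#'   `"cardiac"`, `"neural"`, or `"both"`.
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 100, age_range = c(18, 88),
                        beta_true = 0.5, noise_sd = 1, target = "cardiac",
                        seed = 1) {
  assert_scalar_num(n_subjects, "n_subjects", lower = 2)
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop_invalid("`age_range` must be (min, max) with min < max")
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  target <- match.arg(target, c("cardiac", "neural", "both"))
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 beta_true = beta_true, noise_sd = noise_sd, target = target,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Two modes. `"slope"`: draws, per subject, an aperiodic-slope value
#' `beta_true * z(age) + N(0, noise_sd)` — the fast path for calibrating
#' the inference machinery. `"signal"`: additionally builds a full
#' multichannel recording per subject in which the targeted source's
#' aperiodic exponent is a linear function of z(age); exponents are
#' clipped to `[0.1, 4]`.
#'
#' @param spec a [cohort_spec()].
#' @param mode `"slope"` or `"signal"`.
#' @param duration,sfreq,n_channels recording geometry (signal mode).
#' @param chi_base baseline aperiodic exponent of the age-targeted
#'   source(s) at mean age (signal mode).
#' @param chi_scale exponent change per SD of age per unit `beta_true`
#'   (signal mode); subject exponent =
#'   `chi_base + beta_true * chi_scale * z(age) + N(0, chi_noise_sd)`.
#' @param chi_noise_sd between-subject residual SD of the source
#'   exponents (signal mode). The default 0.2 puts the measurable
#'   standardized age effect at the targeted source near the magnitudes
#'   reported for cardiac components in large resting-state cohorts
#'   (~0.5) when `beta_true = 0.5`.
#' @param cardiac_weight sensor-level cardiac mixing weight (signal mode).
#' @param background_weight mixing-weight scale of the two non-targeted
#'   background sources relative to the cardiac/neural sources.
#' @param sensor_noise_sd white instrument-noise SD per channel. Kept
#'   well below the (unit-variance) sources so the flat noise floor
#'   stays under the physiological 1/f spectra across the fitted band —
#'   a noticeable floor flattens measured slopes for the steepest
#'   subjects and inverts age effects.
#' @param knee_hz low-frequency plateau (knee) of every source's
#'   aperiodic spectrum, Hz. Physiological spectra flatten toward DC;
#'   without this plateau a pure power law with a steep exponent parks
#'   almost all of its (unit) variance below the analysis band, making
#'   the exponent unmeasurable in mixtures.
#' @return `"slope"` mode: data.frame `(subject_id, age, slope)`.
#'   `"signal"` mode: list with the covariate data.frame (including each
#'   subject's true source exponents) and a list of recordings.
#' @export
generate_cohort <- function(spec, mode = c("slope", "signal"),
                            duration = 60, sfreq = 250, n_channels = 8,
                            chi_base = 1.5, chi_scale = 0.4,
                            chi_noise_sd = 0.2, cardiac_weight = 1,
                            background_weight = 0.5,
                            sensor_noise_sd = 0.01, knee_hz = 0.5) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  n <- spec$n_subjects
  draws <- with_local_seed(spec$seed, {
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    eps <- stats::rnorm(n, 0, spec$noise_sd)
    eps2 <- stats::rnorm(n, 0, spec$noise_sd)
    list(age = age, eps = eps, eps2 = eps2)
  })
  zage <- zscore(draws$age)
  tab <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    age = draws$age,
    stringsAsFactors = FALSE
  )
  if (mode == "slope") {
    tab$slope <- spec$beta_true * zage + draws$eps
    return(tab)
  }
  clip <- function(x) pmax(0.1, pmin(4, x))
  drift <- spec$beta_true * chi_scale * zage
  sd_scl <- chi_noise_sd / max(spec$noise_sd, 1e-12)
  chi_card <- clip(chi_base +
                     (if (spec$target %in% c("cardiac", "both")) drift else 0) +
                     sd_scl * draws$eps)
  chi_neur <- clip(chi_base +
                     (if (spec$target %in% c("neural", "both")) drift else 0) +
                     sd_scl * draws$eps2)
  tab$chi_cardiac <- chi_card
  tab$chi_neural <- chi_neur
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    sub_seed <- (spec$seed * 7919 + i * 104729) %% 2147483647
    nsamp <- round(duration * sfreq)
    ns <- function(chi) noise_spec(chi, knee_param = knee_hz^chi)
    cardiac <- generate_cardiac(
      duration, sfreq,
      cardiac_spec(noise = ns(chi_card[i]), noise_weight = 0.8),
      seed = sub_seed)
    neural <- modulate_amplitude(
      generate_colored_noise(nsamp, sfreq, ns(chi_neur[i]),
                             seed = sub_seed + 1),
      sfreq, seed = sub_seed + 11)
    extra1 <- modulate_amplitude(
      generate_colored_noise(nsamp, sfreq, ns(1),
                             seed = sub_seed + 2),
      sfreq, seed = sub_seed + 12)
    extra2 <- modulate_amplitude(
      generate_colored_noise(nsamp, sfreq, ns(1),
                             seed = sub_seed + 3),
      sfreq, seed = sub_seed + 13)
    M <- default_mixing_matrix(n_channels, cardiac_weight = cardiac_weight)
    M[, 3:4] <- M[, 3:4] * background_weight
    recs[[i]] <- mix_multichannel(
      list(cardiac, neural, extra1, extra2),
      mixing_matrix = M,
      sfreq = sfreq, sensor_noise_sd = sensor_noise_sd, cardiac_index = 1L,
      seed = sub_seed + 4)
  }
  list(covariates = tab, recordings = recs)
}

#' Default sensor mixing matrix for synthetic cohorts
#'
#' Spatially smooth, mutually near-orthogonal topographies built from
#' sine/cosine harmonics over the channel axis — distinct "projection
#' patterns" for each source, the way spatially separated generators
#' project differently onto a sensor array. Column 1 (the cardiac
#' source) is scaled by `cardiac_weight`.
#'
#' @param n_channels number of sensor channels.
#' @param n_sources number of sources (first one cardiac).
#' @param cardiac_weight overall scale of the cardiac column.
#' @return `n_channels x n_sources` matrix.
#' @export
default_mixing_matrix <- function(n_channels = 8, n_sources = 4,
                                  cardiac_weight = 1) {
  ch <- seq_len(n_channels)
  M <- vapply(seq_len(n_sources), function(s) {
    harm <- (s + 1) %/% 2
    ph <- pi * ch * harm / (n_channels + 1)
    if (s %% 2 == 1) sin(ph) else cos(ph)
  }, numeric(n_channels))
  M[, 1] <- M[, 1] * cardiac_weight
  M
}

#' Impose a slow amplitude envelope on a signal
#'
#' Multiplies the signal by a positive, slowly varying envelope
#' `max(0.2, 1 + depth * z(lowpassed noise))` and rescales to the input
#' SD. Neural field recordings are amplitude-modulated rather than
#' stationary Gaussian; the resulting heavy tails are also what makes a
#' source recoverable by non-Gaussianity-seeking blind source
#' separation. The power spectrum (hence the aperiodic exponent) is only
#' marginally affected because the envelope is confined below `cutoff`.
#'
#' @param x numeric signal.
#' @param sfreq sampling rate, Hz.
#' @param depth modulation depth (SD of the envelope around 1).
#' @param cutoff envelope bandwidth, Hz.
#' @param seed RNG seed for the envelope noise.
#' @return numeric vector, same SD as `x`.
#' @export
modulate_amplitude <- function(x, sfreq, depth = 0.5, cutoff = 1,
                               seed = 1) {
  assert_scalar_num(depth, "depth", lower = 0)
  if (depth == 0) return(x)
  e <- generate_colored_noise(length(x), sfreq, noise_spec(0), seed = seed)
  e <- fir_filter(e, cutoff, sfreq, "low")
  env <- pmax(0.2, 1 + depth * zscore(e))
  y <- x * env
  y * stats::sd(x) / stats::sd(y)
}
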