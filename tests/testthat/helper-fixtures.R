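# Shared fixtures, generated in code (no stored data).

# Standard 8-channel synthetic mixture: one cardiac source (PQRST + pink
# noise) and three amplitude-modulated colored-noise "neural" sources,
# mixed through near-orthogonal topographies, plus an ECG reference.
make_mixture_recording <- function(duration = 60, sfreq = 250, seed = 1,
                                   cardiac_weight = 1,
                                   sensor_noise_sd = 0.05,
                                   leak = 0) {
  n <- round(duration * sfreq)
  cardiac <- generate_cardiac(
    duration, sfreq,
    cardiac_spec(noise = noise_spec(1), noise_weight = 0.3),
    seed = seed)
  neur <- lapply(1:3, function(k) {
    chi <- c(1, 1.5, 0.8)[k]
    modulate_amplitude(
      generate_colored_noise(n, sfreq, noise_spec(chi), seed = seed + k),
      sfreq, seed = seed + 10 + k)
  })
  sources <- c(list(cardiac), neur)
  M <- default_mixing_matrix(8, 4, cardiac_weight = cardiac_weight)
  if (leak > 0) {
    # 5th source: an under-threshold cardiac leak (|r| with ECG ~ leak)
    lk <- leak * scale(cardiac)[, 1] +
      sqrt(1 - leak^2) * scale(neur[[1]] * 0 +
        generate_colored_noise(n, sfreq, noise_spec(1),
                               seed = seed + 99))[, 1]
    lk <- modulate_amplitude(lk, sfreq, depth = 0.4, seed = seed + 98)
    sources <- c(sources, list(lk))
    M <- cbind(M, 0.8 * cos(pi * seq_len(8) * 3 / 9))
  }
  mix_multichannel(sources, M, sfreq, sensor_noise_sd = sensor_noise_sd,
                   cardiac_index = 1L, seed = seed + 5)
}

# Independent log-log least-squares oracle for the aperiodic exponent of
# a signal: Welch spectrum via the package, fit via stats::lm (the fit
# path under test is fit_aperiodic's analytic OLS).
oracle_exponent <- function(signal, sfreq, lo = 1, hi = 100,
                            resolution = 0.5) {
  ps <- welch_psd(signal, sfreq, fmin = lo, fmax = hi,
                  resolution = resolution)
  unname(-stats::coef(stats::lm(log10(ps$power) ~ log10(ps$freqs)))[2])
}

# Exact knee-model spectrum generator for self-consistency checks
knee_spectrum <- function(freqs, offset, knee, chi) {
  power_spectrum(freqs, 10^(offset - log10(knee + freqs^chi)))
}
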