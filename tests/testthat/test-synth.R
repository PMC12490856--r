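test_that("colored noise hits its target exponent, variance, and is deterministic", {
  sf <- 500
  # white-noise limit
  w <- generate_colored_noise(60 * sf, sf, noise_spec(0), seed = 1)
  expect_lt(abs(oracle_exponent(w, sf)), 0.1)
  # chi = 1.5 across seeds
  fits <- vapply(1:10, function(s)
    oracle_exponent(generate_colored_noise(60 * sf, sf, noise_spec(1.5),
                                           seed = s), sf),
    numeric(1))
  expect_gt(mean(fits), 1.4)
  expect_lt(mean(fits), 1.6)
  # variance and mean
  x <- generate_colored_noise(30 * sf, sf, noise_spec(1, variance = 3),
                              seed = 4)
  expect_equal(var(x), 3, tolerance = 1e-10)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  # determinism
  expect_identical(generate_colored_noise(2000, 500, noise_spec(1), seed = 9),
                   generate_colored_noise(2000, 500, noise_spec(1), seed = 9))
  expect_false(identical(
    generate_colored_noise(2000, 500, noise_spec(1), seed = 9),
    generate_colored_noise(2000, 500, noise_spec(1), seed = 10)))
  expect_error(generate_colored_noise(100, 500, noise_spec(1), seed = 1),
               "2 s")
  expect_error(noise_spec(-1), "exponent_chi")
})

test_that("exponent recovery error < 0.1 for chi in 0.5..2 (spectral fidelity)", {
  sf <- 500
  for (chi in c(0.5, 1, 1.5, 2)) {
    err <- mean(vapply(1:5, function(s)
      abs(oracle_exponent(generate_colored_noise(60 * sf, sf,
                                                 noise_spec(chi),
                                                 seed = s), sf) - chi),
      numeric(1)))
    expect_lt(err, 0.1)
  }
})

test_that("E/I neural generator responds to the inhibition ratio", {
  sf <- 500
  # zero rate -> silence
  expect_equal(generate_neural_ei(10, sf, neural_spec(spike_rate = 0),
                                  seed = 1),
               numeric(10 * sf))
  lo <- generate_neural_ei(60, sf, neural_spec(ei_ratio = 0.5), seed = 2)
  hi <- generate_neural_ei(60, sf, neural_spec(ei_ratio = 6), seed = 2)
  chi_lo <- oracle_exponent(lo, sf, 30, 70)
  chi_hi <- oracle_exponent(hi, sf, 30, 70)
  expect_gt(chi_hi, chi_lo)       # more inhibition -> steeper
  # the 1:2 E/I default lands in a plausible slope band at 30-70 Hz
  x <- generate_neural_ei(60, sf, neural_spec(), seed = 3)
  expect_true(all(is.finite(x)) && sd(x) > 0)
  chi <- oracle_exponent(x, sf, 30, 70)
  expect_gt(chi, 1); expect_lt(chi, 4)
  # PSD decays monotonically above ~5 Hz (coarse log-band means)
  ps <- welch_psd(x, sf, fmin = 5, fmax = 200, resolution = 0.5)
  bands <- exp(seq(log(5), log(200), length.out = 8))
  bmeans <- vapply(seq_len(7), function(i)
    mean(ps$power[ps$freqs >= bands[i] & ps$freqs < bands[i + 1]]),
    numeric(1))
  expect_true(all(diff(bmeans) < 0))
  expect_error(neural_spec(exc_rise = 0.01, exc_decay = 0.002), "decay")
})

test_that("cardiac generator: periodicity, jitter bounds, beat count", {
  sf <- 250
  # jitter 0, no noise: exactly periodic, PSD peaks at 1 Hz harmonics
  x <- generate_cardiac(60, sf, cardiac_spec(onset_jitter_sd = 0,
                                             noise_weight = 0), seed = 1)
  period <- sf  # 1 Hz at 250 Hz
  expect_equal(x[(period + 1):(5 * period)], x[1:(4 * period)],
               tolerance = 1e-10)
  ps <- welch_psd(x, sf, fmin = 0.5, fmax = 20, resolution = 0.25)
  peak_freqs <- ps$freqs[order(ps$power, decreasing = TRUE)[1:5]]
  expect_true(all(abs(peak_freqs - round(peak_freqs)) < 0.26))
  # overlapping-jitter spec rejected
  expect_error(cardiac_spec(beat_rate = 1, onset_jitter_sd = 0.2),
               "overlap")
  expect_error(cardiac_spec(wave_params = within(default_pqrst_waves(),
                                                 amplitude[3] <- 0.1)),
               "R wave")
  # noise exponent ordering: chi 3 vs 0.5 noise at weight 1
  mk <- function(chi) generate_cardiac(
    60, 500, cardiac_spec(noise = noise_spec(chi, knee_param = 0.5^chi),
                          noise_weight = 1), seed = 5)
  expect_gt(oracle_exponent(mk(3), 500, 0.5, 10, 0.5),
            oracle_exponent(mk(0.5), 500, 0.5, 10, 0.5))
})

test_that("two-source mixing is an SNR dial over z-scored sources", {
  sf <- 500
  neural <- generate_neural_ei(60, sf, neural_spec(), seed = 1)
  cardiac <- generate_cardiac(60, sf,
                              cardiac_spec(noise = noise_spec(3,
                                                              knee_param = 0.5^3),
                                           noise_weight = 1), seed = 2)
  # weight 0 -> z-scored neural
  m0 <- mix_two_sources(neural, cardiac, 0)
  expect_equal(m0, as.numeric(scale(neural)), tolerance = 1e-12)
  expect_error(mix_two_sources(neural, cardiac[-1], 1), "equal length")
  # weight -> infinity: exponent converges to cardiac-only
  chi_card <- fit_aperiodic(
    irasa(as.numeric(scale(cardiac)), sf, fmin = 0.5, fmax = 45),
    c(0.5, 10))$exponent_chi
  chi_100 <- fit_aperiodic(
    irasa(mix_two_sources(neural, cardiac, 100), sf, fmin = 0.5,
          fmax = 45),
    c(0.5, 10))$exponent_chi
  expect_lt(abs(chi_100 - chi_card), 0.1)
})

test_that("multichannel mixing produces an ECG-tagged recording", {
  set.seed(1)
  s1 <- rnorm(2000); s2 <- rnorm(2000)
  # identity matrix, zero noise: channels equal z-scored sources
  rec <- mix_multichannel(list(s1, s2), diag(2), 100, sensor_noise_sd = 0,
                          seed = 1)
  expect_equal(rec$data[, 1], as.numeric(scale(s1)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rec$roles, c("sensor", "sensor"))
  rec2 <- mix_multichannel(list(s1, s2), diag(2), 100, cardiac_index = 1,
                           seed = 1)
  expect_equal(rec2$roles[3], "ecg_ref")
  expect_gt(cor(rec2$data[, 3], s1), 0.99)
  expect_error(mix_multichannel(list(s1), matrix(0, 3, 1), 100), "rank")
})

test_that("cohort generator calibrates to beta_true and is deterministic", {
  cs <- cohort_spec(n_subjects = 600, beta_true = 0.5, noise_sd = 1,
                    seed = 11)
  tab <- generate_cohort(cs, "slope")
  zage <- as.numeric(scale(tab$age))
  b <- unname(coef(lm(tab$slope ~ zage))[2])
  expect_lt(abs(b - 0.5), 0.05)
  # implied correlation r = beta / sqrt(beta^2 + sigma^2) = 0.447
  expect_lt(abs(cor(tab$age, tab$slope) - 0.447), 0.07)
  # null cohort
  tab0 <- generate_cohort(cohort_spec(n_subjects = 600, beta_true = 0,
                                      seed = 12), "slope")
  expect_lt(abs(cor(tab0$age, tab0$slope)), 0.1)
  # determinism
  expect_identical(generate_cohort(cs, "slope"), generate_cohort(cs, "slope"))
  # signal mode wires the exponent drift into the targeted source
  sig <- generate_cohort(cohort_spec(n_subjects = 5, seed = 3,
                                     target = "cardiac"),
                         "signal", duration = 12, sfreq = 250)
  expect_equal(nrow(sig$covariates), 5)
  expect_length(sig$recordings, 5)
  expect_s3_class(sig$recordings[[1]], "ts_recording")
  expect_true("ecg_ref" %in% sig$recordings[[1]]$roles)
})

test_that("amplitude modulation preserves the spectrum but fattens tails", {
  sf <- 250
  x <- generate_colored_noise(60 * sf, sf, noise_spec(1), seed = 1)
  y <- modulate_amplitude(x, sf, depth = 0.5, seed = 2)
  expect_equal(sd(y), sd(x), tolerance = 1e-10)
  expect_lt(abs(oracle_exponent(y, sf) - oracle_exponent(x, sf)), 0.15)
  kurt <- function(v) mean(scale(v)^4)
  expect_gt(kurt(y), kurt(x) + 0.5)
})
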