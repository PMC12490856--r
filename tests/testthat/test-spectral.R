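test_that("welch_psd: Parseval, bin spacing, white-noise level", {
  sf <- 500
  t <- seq(1 / sf, 60, by = 1 / sf)
  # pure sine: peak bin and integrated power ~ A^2/2
  A <- 2
  x <- A * sin(2 * pi * 10 * t)
  ps <- welch_psd(x, sf, fmin = 0, fmax = sf / 2, resolution = 0.5)
  expect_equal(ps$freqs[which.max(ps$power)], 10)
  expect_equal(sum(ps$power) * ps$resolution, A^2 / 2, tolerance = 0.05)
  # sensor settings: spacing exactly 0.5 Hz
  ps2 <- welch_psd(rnorm(10 * sf), sf, fmin = 0.1, fmax = 145,
                   resolution = 0.5)
  expect_equal(unique(round(diff(ps2$freqs), 10)), 0.5)
  expect_equal(ps2$resolution, 0.5)
  # white noise of variance s2: flat density ~ s2/(sfreq/2)
  set.seed(2)
  s2 <- 4
  w <- rnorm(120 * sf, sd = sqrt(s2))
  psw <- welch_psd(w, sf, fmin = 0, fmax = sf / 2, resolution = 0.5)
  expect_equal(mean(psw$power), s2 / (sf / 2), tolerance = 0.1)
  # Parseval on broadband noise
  expect_equal(sum(psw$power) * psw$resolution, var(w), tolerance = 0.05)
  expect_error(welch_psd(rnorm(100), sf, resolution = 0.5), "segment")
})

test_that("irasa separates fractal from oscillatory structure", {
  sf <- 500
  x <- generate_colored_noise(120 * sf, sf, noise_spec(1), seed = 3)
  # degenerate identity hset: fractal == original
  fs1 <- irasa(x, sf, hset = 1, fmin = 1, fmax = 100)
  expect_equal(fs1$fractal$power, fs1$original$power, tolerance = 1e-12)
  # peak-free noise: fractal exponent within 0.15 of truth; residual small
  fs <- irasa(x, sf, fmin = 1, fmax = 100)
  expect_lt(abs(fit_aperiodic(fs, c(1, 100))$exponent_chi - 1), 0.15)
  # per-bin residual bound needs long averaging (Welch bin SD ~ 1/sqrt(T))
  xl <- generate_colored_noise(600 * sf, sf, noise_spec(1), seed = 3)
  fsl <- irasa(xl, sf, fmin = 1, fmax = 100)
  inner <- seq_along(fsl$fractal$freqs)
  inner <- inner[inner > 3 & inner < length(inner) - 3]
  expect_true(all(abs(fsl$oscillatory[inner]) <
                    0.2 * fsl$fractal$power[inner]))
  # added 10 Hz sine: oscillatory residual peaks at 10 Hz, fractal stable
  t <- seq(1 / sf, 120, by = 1 / sf)
  x2 <- x + 0.5 * sin(2 * pi * 10 * t)
  fs2 <- irasa(x2, sf, fmin = 1, fmax = 100)
  expect_equal(fs2$fractal$freqs[which.max(fs2$oscillatory)], 10,
               tolerance = 0.51)
  expect_lt(abs(fit_aperiodic(fs2, c(1, 100))$exponent_chi -
                  fit_aperiodic(fs, c(1, 100))$exponent_chi), 0.15)
  expect_error(irasa(x, sf, hset = c(0.9, 1.1)), "> 1")
})

test_that("irasa fractal fit agrees with the direct fit on peak-free noise", {
  sf <- 500
  for (chi in c(0.5, 1.5, 2.5)) {
    x <- generate_colored_noise(60 * sf, sf, noise_spec(chi), seed = 7)
    direct <- oracle_exponent(x, sf, 1, 100)
    frac <- fit_aperiodic(irasa(x, sf, fmin = 1, fmax = 100),
                          c(1, 100))$exponent_chi
    expect_lt(abs(direct - frac), 0.15)
  }
})

test_that("fixed-mode fit equals the least-squares oracle and solves exact inputs", {
  f <- seq(0.5, 145, by = 0.5)
  # exact power law: chi = 2, offset 0, r2 = 1 at machine precision
  fit <- fit_aperiodic(power_spectrum(f, f^-2), c(1, 40), "fixed")
  expect_equal(fit$exponent_chi, 2, tolerance = 1e-12)
  expect_equal(fit$offset, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # flat spectrum -> chi = 0
  expect_equal(fit_aperiodic(power_spectrum(f, rep(2, length(f))),
                             c(1, 40))$exponent_chi, 0, tolerance = 1e-12)
  # oracle equivalence on rough data
  set.seed(4)
  p <- f^-1.3 * exp(rnorm(length(f), 0, 0.2))
  fit2 <- fit_aperiodic(power_spectrum(f, p), c(1, 100), "fixed")
  sub <- f >= 1 & f <= 100
  oracle <- unname(-coef(lm(log10(p[sub]) ~ log10(f[sub])))[2])
  expect_lt(abs(fit2$exponent_chi - oracle), 1e-9)
  expect_error(fit_aperiodic(power_spectrum(f, p), c(1, 1.5)), "5 frequency")
  pneg <- p; pneg[30] <- -1
  expect_error(fit_aperiodic(power_spectrum(f, pneg), c(1, 100)),
               "non-positive")
})

test_that("knee-mode fit recovers model-generated knee spectra within 1%", {
  f <- seq(0.25, 145, by = 0.25)
  # the ~15 Hz knee regime seen in cardiac spectra
  chi <- 2; k <- 15^chi
  fit <- fit_aperiodic(knee_spectrum(f, 1, k, chi), c(0.25, 145), "knee")
  expect_lt(abs(fit$exponent_chi - chi) / chi, 0.01)
  expect_lt(abs(fit$knee_param - k) / k, 0.01)
  expect_equal(fit$knee_freq_hz, 15, tolerance = 0.15)
  expect_true(fit$converged)
  # a second regime
  fit2 <- fit_aperiodic(knee_spectrum(f, -0.5, 5^1.5, 1.5), c(0.25, 145),
                        "knee")
  expect_lt(abs(fit2$exponent_chi - 1.5) / 1.5, 0.01)
  expect_lt(abs(fit2$knee_freq_hz - 5) / 5, 0.02)
})

test_that("specparam-style parametrization extracts peaks and cleans the aperiodic fit", {
  f <- seq(0.5, 100, by = 0.5)
  ap <- 10^(0.5 - 1.5 * log10(f))
  g <- function(c0, h, w) h * exp(-0.5 * ((f - c0) / w)^2)
  # one 10 Hz peak
  p1 <- 10^(log10(ap) + g(10, 0.6, 1))
  res1 <- parametrize_spectrum(power_spectrum(f, p1), c(0.5, 100))
  expect_equal(nrow(res1$peaks), 1)
  expect_lt(abs(res1$peaks$center - 10), 0.5)
  expect_lt(abs(res1$aperiodic$exponent_chi - 1.5), 0.1)
  # pure aperiodic input: zero peaks, matches fit_aperiodic
  res0 <- parametrize_spectrum(power_spectrum(f, ap), c(0.5, 100))
  expect_equal(nrow(res0$peaks), 0)
  direct <- fit_aperiodic(power_spectrum(f, ap), c(0.5, 100))
  expect_lt(abs(res0$aperiodic$exponent_chi - direct$exponent_chi), 0.05)
  # three peaks, max 2 retained: the two tallest by injected height
  p3 <- 10^(log10(ap) + g(6, 0.5, 1) + g(11, 0.9, 1.2) + g(22, 0.7, 1.5))
  res3 <- parametrize_spectrum(power_spectrum(f, p3), c(0.5, 100))
  expect_equal(nrow(res3$peaks), 2)
  expect_setequal(round(res3$peaks$center), c(11, 22))
})

test_that("slope grid: cell count, scale invariance, knee distortion", {
  g <- default_meg_grid()
  expect_length(g$lower, 10)
  expect_length(g$upper, 21)
  f <- seq(0.5, 145, by = 0.5)
  ps <- power_spectrum(f, 3 * f^-1.8)
  tab <- slope_grid(ps, g$lower, g$upper)
  expect_equal(nrow(tab), 210)
  # scale-free input: identical exponent everywhere
  expect_lt(max(abs(tab$exponent - 1.8)), 1e-6)
  # positive rescaling shifts offsets only
  tab10 <- slope_grid(power_spectrum(f, 30 * f^-1.8), g$lower, g$upper)
  expect_equal(tab10$exponent, tab$exponent, tolerance = 1e-10)
  expect_equal(tab10$offset - tab$offset, rep(1, 210), tolerance = 1e-10)
  # knee spectrum under fixed-mode fits: chi grows as lo passes the knee
  ks <- knee_spectrum(f, 1, 10^2, 2)
  kt <- slope_grid(ks, c(0.5, 2, 8, 20), 100)
  expect_true(all(diff(kt$exponent) > 0))
  expect_error(slope_grid(ps, numeric(0), 45), "empty")
  expect_error(slope_grid(ps, 50, 45), "below")
  # ECG convention ranges are exposed
  er <- default_ecg_ranges()
  expect_equal(er$lo_hz, c(0.25, 10))
  expect_equal(er$hi_hz, c(20, 145))
})
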