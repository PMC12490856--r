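test_that("FastICA recovers independent Laplacian sources", {
  set.seed(1)
  n <- 5000
  S <- matrix(sign(rnorm(3 * n)) * rexp(3 * n), n, 3)
  A <- matrix(rnorm(24), 8, 3)
  rec <- ts_recording(S %*% t(A), 100)
  dec <- fit_ica(rec, n_components = 3, highpass_hz = NULL, seed = 2)
  cc <- abs(cor(dec$timecourses, S))
  expect_true(all(apply(cc, 2, max) > 0.95))
  # determinism up to sign
  dec2 <- fit_ica(rec, n_components = 3, highpass_hz = NULL, seed = 2)
  expect_equal(abs(dec$unmixing), abs(dec2$unmixing), tolerance = 1e-8)
  expect_error(fit_ica(rec, n_components = 10), "exceeds")
})

test_that("full-rank back-projection reconstructs the input", {
  set.seed(3)
  n <- 4000
  S <- matrix(sign(rnorm(4 * n)) * rexp(4 * n), n, 4)
  A <- matrix(rnorm(16), 4, 4)
  X <- S %*% t(A)
  rec <- ts_recording(X, 100)
  dec <- fit_ica(rec, n_components = 4, highpass_hz = NULL, seed = 4)
  recon <- dec$timecourses %*% t(dec$mixing)
  recon <- sweep(recon, 2, dec$means, "+")
  expect_lt(max(abs(recon - X)), 1e-6)
})

test_that("component classification applies the r thresholds with no argmax", {
  set.seed(5)
  n <- 3000
  tc <- matrix(rnorm(n * 4), n, 4)
  ecg <- tc[, 1]
  dec <- structure(list(timecourses = tc, n_components = 4),
                   class = "ica_decomposition")
  lab <- classify_components(dec, ecg)
  expect_equal(lab$label, c("cardiac", "other", "other", "other"))
  expect_equal(lab$r_ecg[1], 1)
  # two components above threshold are BOTH cardiac
  tc2 <- cbind(ecg, 0.6 * ecg + 0.8 * rnorm(n), rnorm(n))
  dec2 <- structure(list(timecourses = tc2, n_components = 3),
                    class = "ica_decomposition")
  lab2 <- classify_components(dec2, ecg)
  expect_equal(sum(lab2$label == "cardiac"), 2)
  # all-noise: all other
  dec3 <- structure(list(timecourses = matrix(rnorm(3 * n), n, 3),
                         n_components = 3),
                    class = "ica_decomposition")
  expect_true(all(classify_components(dec3, ecg)$label == "other"))
  # lowering the threshold never reduces the cardiac count (monotone)
  n_card <- vapply(c(0.8, 0.4, 0.2, 0.05), function(th)
    sum(classify_components(dec2, ecg, threshold_ecg = th)$label ==
          "cardiac"), integer(1))
  expect_true(all(diff(n_card) >= 0))
  # EOG labeling is secondary to cardiac
  eog <- tc2[, 2]
  lab4 <- classify_components(dec2, ecg, eog_refs = eog)
  expect_equal(lab4$label[2], "cardiac")
  expect_error(classify_components(dec2, rep(1, n)), "zero-variance")
})

test_that("the mixture fixture separates the cardiac source at |r| > 0.9", {
  rec <- make_mixture_recording(duration = 60, seed = 1)
  dec <- fit_ica(rec, n_components = 4, seed = 2)
  ecg <- channels_by_role(rec, "ecg_ref")[, 1]
  lab <- classify_components(dec, ecg)
  expect_gt(max(abs(lab$r_ecg)), 0.9)
  expect_gte(sum(lab$label == "cardiac"), 1)
  # zero cardiac mixing: nothing correlates above the 0.4 threshold
  rec0 <- make_mixture_recording(duration = 60, seed = 1,
                                 cardiac_weight = 0)
  dec0 <- fit_ica(rec0, n_components = 3, seed = 2)
  lab0 <- classify_components(dec0, channels_by_role(rec0, "ecg_ref")[, 1])
  expect_lt(max(abs(lab0$r_ecg)), 0.4)
})

test_that("condition reconstruction is additive and handles the no-cardiac case", {
  rec <- make_mixture_recording(duration = 40, seed = 6)
  dec <- fit_ica(rec, n_components = 4, seed = 7)
  ecg <- channels_by_role(rec, "ecg_ref")[, 1]
  lab <- classify_components(dec, ecg)
  cs <- reconstruct_conditions(rec, dec, lab)
  expect_lt(max(abs(cs$ecg_rejected$data + cs$ecg_components$data -
                      cs$ecg_not_rejected$data)), 1e-8)
  # no cardiac components: ecg_components all-zero, rejected == kept
  lab_none <- lab; lab_none$label[] <- "other"
  cs0 <- reconstruct_conditions(rec, dec, lab_none)
  expect_true(all(cs0$ecg_components$data == 0))
  expect_equal(cs0$ecg_rejected$data, cs0$ecg_not_rejected$data,
               tolerance = 1e-12)
  # without EOG references, ecg_not_rejected equals the original sensors
  expect_equal(cs$ecg_not_rejected$data,
               channels_by_role(rec, "sensor"), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("riemannian potato flags deviant epochs and only those", {
  # near-identical epochs: none rejected
  set.seed(8)
  base <- matrix(rnorm(50 * 500 * 4), ncol = 4)
  rec <- ts_recording(base, 250)
  pr <- riemannian_potato_reject(rec, epoch_len = 2)
  expect_length(pr$rejected, 0)
  # one epoch scaled x10 among the rest
  X <- base
  idx <- (5 * 500 + 1):(6 * 500)  # epoch 6 at 2 s epochs @ 250 Hz
  X[idx, ] <- X[idx, ] * 10
  pr2 <- riemannian_potato_reject(ts_recording(X, 250), epoch_len = 2)
  expect_true(6 %in% pr2$rejected)
  expect_length(pr2$rejected, 1)
  # infinite threshold keeps everything
  pr3 <- riemannian_potato_reject(ts_recording(X, 250), epoch_len = 2,
                                  z_threshold = Inf)
  expect_length(pr3$rejected, 0)
  expect_error(riemannian_potato_reject(ts_recording(base[1:1000, ], 250)),
               "10 epochs")
})
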