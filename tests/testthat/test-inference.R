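test_that("HDI is the shortest interval at the requested mass", {
  set.seed(1)
  d <- rnorm(20000)
  ci <- hdi_interval(d, 0.94)
  expect_equal(unname(ci[1]), qnorm(0.03), tolerance = 0.08)
  expect_equal(unname(ci[2]), qnorm(0.97), tolerance = 0.08)
  # skewed draws: HDI shorter than the equal-tailed interval
  ds <- exp(rnorm(20000))
  hi <- hdi_interval(ds, 0.94)
  et <- quantile(ds, c(0.03, 0.97))
  expect_lt(diff(hi), diff(et))
  expect_error(hdi_interval(1:5), "10")
})

test_that("standardized effects: exact, null, and cohort fixtures", {
  set.seed(2)
  x <- rnorm(100)
  e <- standardized_effect(x, x, seed = 3)
  expect_equal(e$beta, 1, tolerance = 1e-10)
  expect_gt(e$lower, 0.9)
  # cohort fixture: beta_true = 0.5, noise 1 -> standardized 0.447
  tab <- generate_cohort(cohort_spec(n_subjects = 600, beta_true = 0.5,
                                     seed = 4), "slope")
  e2 <- standardized_effect(tab$age, tab$slope, seed = 5)
  expect_gt(e2$beta, 0.4); expect_lt(e2$beta, 0.6)
  expect_error(standardized_effect(x, rep(1, 100)), "zero variance")
  expect_error(standardized_effect(x[1:5], x[1:5]), "n >= 10")
})

test_that("bayesian and bootstrap backends agree and report diagnostics", {
  tab <- generate_cohort(cohort_spec(n_subjects = 600, beta_true = 0.5,
                                     seed = 6), "slope")
  eb <- standardized_effect(tab$age, tab$slope, backend = "bootstrap",
                            seed = 7)
  ey <- standardized_effect(tab$age, tab$slope, backend = "bayesian",
                            seed = 8)
  expect_lt(abs(eb$beta - ey$beta), 0.03)
  expect_equal(classify_effect(eb), classify_effect(ey))
  expect_lt(ey$diagnostics$rhat, 1.05)
  expect_gt(ey$diagnostics$ess, 400)
  # null fixture agrees too
  tab0 <- generate_cohort(cohort_spec(n_subjects = 600, beta_true = 0,
                                      seed = 9), "slope")
  e0b <- standardized_effect(tab0$age, tab0$slope, seed = 10)
  e0y <- standardized_effect(tab0$age, tab0$slope, backend = "bayesian",
                             seed = 11)
  expect_equal(classify_effect(e0b), classify_effect(e0y))
})

test_that("ROPE classification follows the five-way taxonomy", {
  mk <- function(b, l, u) list(beta = b, lower = l, upper = u)
  expect_equal(classify_effect(mk(-0.5, -0.6, -0.4)), "steepening")
  expect_equal(classify_effect(mk(0.5, 0.4, 0.6)), "flattening")
  expect_equal(classify_effect(mk(0.02, -0.05, 0.08)), "null")
  expect_equal(classify_effect(mk(-0.12, -0.25, 0.02)),
               "undecided_steepening")
  expect_equal(classify_effect(mk(0.12, -0.02, 0.25)),
               "undecided_flattening")
  # boundary: interval exactly on the ROPE edge is not outside it
  expect_equal(classify_effect(mk(-0.3, -0.5, -0.1)),
               "undecided_steepening")
  # zero-median tie breaks toward steepening
  expect_equal(classify_effect(mk(0, -0.3, 0.3)), "undecided_steepening")
  expect_error(classify_effect(mk(0, -1, 1), rope = c(0.2, -0.2)), "rope")
})

test_that("multiverse summaries: single cell, completeness, permutation invariance", {
  tab <- generate_cohort(cohort_spec(n_subjects = 200, beta_true = -0.8,
                                     noise_sd = 0.5, seed = 12), "slope")
  st <- data.frame(subject_id = tab$subject_id, condition = "c1",
                   channel = "ch01", lo_hz = 1, hi_hz = 45,
                   slope = tab$slope)
  mv <- run_multiverse(st, tab, seed = 13)
  expect_equal(nrow(mv$cells), 1)
  expect_equal(sum(mv$summary$percent), 100)
  expect_equal(mv$summary$percent[mv$summary$category ==
                                    mv$cells$category[1]], 100)
  # two conditions x two ranges; percentages sum to 100 per condition
  st2 <- do.call(rbind, lapply(c("a", "b"), function(cond)
    do.call(rbind, lapply(c(45, 85), function(hi)
      transform(st, condition = cond, hi_hz = hi)))))
  mv2 <- run_multiverse(st2, tab, seed = 14)
  sums <- tapply(mv2$summary$percent, mv2$summary$condition, sum)
  expect_true(all(abs(sums - 100) < 0.01))
  # permuting rows leaves the summary unchanged
  set.seed(15)
  mv2p <- run_multiverse(st2[sample(nrow(st2)), ], tab, seed = 14)
  expect_equal(mv2p$summary, mv2$summary)
})

test_that("joint partial regression disentangles mediated from independent effects", {
  # full mediation: age -> cardiac slope; 'neural' slope = cardiac + noise
  ok <- vapply(1:10, function(s) {
    set.seed(100 + s)
    n <- 600
    age <- rnorm(n)
    s_card <- 0.6 * age + rnorm(n)
    s_rej <- s_card + rnorm(n)
    pr <- partial_regression(age, s_card, s_rej, seed = s)
    pr$ecg_component$category %in% c("steepening", "flattening") &&
      pr$ecg_rejected$category %in% c("null", "undecided_steepening",
                                      "undecided_flattening")
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  # independent effects: both retained
  set.seed(16)
  n <- 600
  u1 <- rnorm(n); u2 <- rnorm(n)
  age <- 0.5 * u1 + 0.5 * u2 + 0.5 * rnorm(n)
  pr2 <- partial_regression(age, u1, u2, seed = 17)
  expect_true(pr2$ecg_component$category %in% c("steepening", "flattening"))
  expect_true(pr2$ecg_rejected$category %in% c("steepening", "flattening"))
  expect_error(partial_regression(age, u1, u1, seed = 1), "collinear")
})

test_that("task contrast recovers within-subject shifts via random intercepts", {
  sim_contrast <- function(delta, seed) {
    set.seed(seed)
    n_sub <- 48
    sub <- rep(sprintf("s%02d", 1:n_sub), each = 2)
    phase <- rep(c("Baseline", "Delay"), n_sub)
    slope <- ifelse(phase == "Delay", delta, 0) +
      rep(rnorm(n_sub, 0, 0.3), each = 2) + rnorm(2 * n_sub, 0, 0.2)
    task_contrast(data.frame(subject_id = sub, phase = phase,
                             slope = slope), "contrast", seed = seed)
  }
  est <- sim_contrast(0.3, 18)$phaseDelay
  expect_gt(est$beta, 0.2); expect_lt(est$beta, 0.4)
  # null calibration
  cats <- vapply(1:10, function(s) sim_contrast(0, 200 + s)$phaseDelay$category,
                 character(1))
  expect_gte(mean(!cats %in% c("steepening", "flattening")), 0.9)
  # load variant returns one estimate per level
  set.seed(19)
  sub <- rep(sprintf("s%02d", 1:30), each = 3)
  load <- rep(c("Baseline", "load5", "load9"), 30)
  slope <- ifelse(load == "load9", 0.4, ifelse(load == "load5", 0.2, 0)) +
    rep(rnorm(30, 0, 0.2), each = 3) + rnorm(90, 0, 0.1)
  tc <- task_contrast(data.frame(subject_id = sub, load = load,
                                 slope = slope), "load", seed = 20)
  expect_length(tc, 2)
  expect_gt(tc$loadload9$beta, tc$loadload5$beta)
})
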