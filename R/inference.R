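#' Highest-density interval of a sample
#'
#' Shortest interval containing `level` of the draws (empirical HDI).
#'
#' @param draws numeric vector of posterior/bootstrap draws.
#' @param level probability mass, default 0.94.
#' @return numeric `(lower, upper)`.
#' @export
hdi_interval <- function(draws, level = 0.94) {
  draws <- sort(draws[is.finite(draws)])
  n <- length(draws)
  if (n < 10) stop_invalid("need >= 10 finite draws for an HDI")
  m <- max(1L, floor(level * n))
  if (m >= n) return(c(draws[1], draws[n]))
  widths <- draws[(m + 1):n] - draws[1:(n - m)]
  i <- which.min(widths)
  c(draws[i], draws[i + m])
}

#' Standardized effect of one predictor on one outcome
#'
#' Both variables are z-scored, so the regression coefficient is a
#' standardized beta. Backends: `"bootstrap"` (default) resamples
#' subject pairs (>= 2000 resamples) and summarizes the OLS slope
#' distribution; `"bayesian"` runs a Gibbs sampler for the linear model
#' with weakly informative priors — Normal(0, 1) on the standardized
#' slope and intercept, Inv-Gamma(2, 1) on the residual variance — and
#' checks split-chain R-hat < 1.05 and effective sample size > 400. The
#' point summary is the posterior/bootstrap median; the interval is the
#' 94% highest-density interval.
#'
#' @param x predictor values.
#' @param y outcome values.
#' @param level interval mass, default 0.94.
#' @param backend `"bootstrap"` or `"bayesian"`.
#' @param n_draws bootstrap resamples / posterior draws per chain.
#' @param seed RNG seed.
#' @return An object of class `effect_estimate`: `beta` (median),
#'   `lower`, `upper`, `level`, `backend`, `n`, `diagnostics`.
#' @export
standardized_effect <- function(x, y, level = 0.94,
                                backend = c("bootstrap", "bayesian"),
                                n_draws = 2000, seed = 1) {
  backend <- match.arg(backend)
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop_invalid("need n >= 10 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_invalid("zero variance in x or y")
  zx <- zscore(x); zy <- zscore(y)
  draws <- if (backend == "bootstrap") {
    boot_slope_draws(zx, zy, n_draws = max(n_draws, 2000), seed = seed)
  } else {
    bayes_lm_draws(zx, zy, n_draws = n_draws, seed = seed)
  }
  ci <- hdi_interval(draws$draws, level)
  structure(list(beta = stats::median(draws$draws),
                 lower = ci[1], upper = ci[2], level = level,
                 backend = backend, n = n,
                 diagnostics = draws$diagnostics),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate %s> beta = %.3f, %d%% HDI [%.3f, %.3f], n = %d\n",
              x$backend, x$beta, round(100 * x$level), x$lower, x$upper, x$n))
  invisible(x)
}

# vectorized pair-resampling bootstrap of the z-scored OLS slope
boot_slope_draws <- function(zx, zy, n_draws, seed) {
  n <- length(zx)
  draws <- with_local_seed(seed, {
    idx <- matrix(sample.int(n, n * n_draws, replace = TRUE), n, n_draws)
    xs <- matrix(zx[idx], n, n_draws)
    ys <- matrix(zy[idx], n, n_draws)
    mx <- colMeans(xs); my <- colMeans(ys)
    sxy <- colMeans(xs * ys) - mx * my
    sxx <- colMeans(xs * xs) - mx * mx
    sxy / sxx
  })
  list(draws = draws, diagnostics = list(n_resamples = n_draws))
}

# Gibbs sampler for zy = a + b*zx + e; priors a, b ~ N(0,1),
# sigma2 ~ InvGamma(2, 1). 4 chains; split R-hat and a crude ESS.
bayes_lm_draws <- function(zx, zy, n_draws = 1000, n_chains = 4,
                           warmup = 500, seed = 1) {
  n <- length(zx)
  sxx <- sum(zx^2); sx <- sum(zx); sy <- sum(zy); sxy <- sum(zx * zy)
  chains <- with_local_seed(seed, {
    lapply(seq_len(n_chains), function(ch) {
      a <- stats::rnorm(1); b <- stats::rnorm(1); s2 <- 1
      out <- numeric(n_draws)
      for (i in seq_len(warmup + n_draws)) {
        # b | a, s2  (prior variance 1)
        vb <- 1 / (sxx / s2 + 1)
        mb <- vb * ((sxy - a * sx) / s2)
        b <- stats::rnorm(1, mb, sqrt(vb))
        # a | b, s2
        va <- 1 / (n / s2 + 1)
        ma <- va * ((sy - b * sx) / s2)
        a <- stats::rnorm(1, ma, sqrt(va))
        # s2 | a, b
        res <- zy - a - b * zx
        s2 <- 1 / stats::rgamma(1, 2 + n / 2, 1 + sum(res^2) / 2)
        if (i > warmup) out[i - warmup] <- b
      }
      out
    })
  })
  rhat <- split_rhat(chains)
  ess <- ess_bulk(chains)
  if (!is.finite(rhat) || rhat >= 1.05 || ess <= 400)
    stop(sprintf(
      "bayesian backend did not converge: R-hat = %.3f, ESS = %.0f",
      rhat, ess), call. = FALSE)
  list(draws = unlist(chains),
       diagnostics = list(rhat = rhat, ess = ess, n_chains = n_chains,
                          n_draws = n_draws))
}

split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(ch) {
    h <- length(ch) %/% 2
    list(ch[1:h], ch[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, 1)
  vars <- vapply(halves, stats::var, 1)
  B <- n * stats::var(means)
  W <- mean(vars)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_bulk <- function(chains) {
  # effective size from lag-1 autocorrelation (AR(1) approximation)
  rho <- mean(vapply(chains, function(ch) {
    stats::cor(ch[-1], ch[-length(ch)])
  }, 1))
  rho <- max(min(rho, 0.99), 0)
  length(chains) * length(chains[[1]]) * (1 - rho) / (1 + rho)
}

#' Classify an effect against a region of practical equivalence
#'
#' Decision taxonomy on the signed log-log slope scale (`b = -chi`, so a
#' negative age coefficient means the spectrum steepens with age):
#' interval entirely outside the ROPE gives `"steepening"` (negative) or
#' `"flattening"` (positive); interval entirely inside gives `"null"`;
#' anything else is `"undecided_steepening"` / `"undecided_flattening"`
#' by the sign of the point estimate (an exactly zero median breaks the
#' tie toward steepening, the a-priori direction).
#'
#' @param est an `effect_estimate` (or list with `beta`, `lower`,
#'   `upper`).
#' @param rope `(lower, upper)` bounds of the region of practical
#'   equivalence, default `c(-0.1, 0.1)`.
#' @return character scalar, one of `steepening`, `flattening`, `null`,
#'   `undecided_steepening`, `undecided_flattening`.
#' @export
classify_effect <- function(est, rope = c(-0.1, 0.1)) {
  if (length(rope) != 2 || rope[1] >= rope[2])
    stop_invalid("`rope` must be (lower, upper) with lower < upper")
  lo <- est$lower; hi <- est$upper; b <- est$beta
  if (hi < rope[1]) return("steepening")
  if (lo > rope[2]) return("flattening")
  if (lo >= rope[1] && hi <= rope[2]) return("null")
  if (b > 0) "undecided_flattening" else "undecided_steepening"
}

#' Multiverse of age effects across conditions, channels, and fit ranges
#'
#' Runs [standardized_effect()] + [classify_effect()] for every cell of
#' a long slope table and summarizes category percentages per condition.
#' Slopes are expected on the signed scale (`b = -chi`).
#'
#' @param slope_table data.frame with columns `subject_id`, `condition`,
#'   `channel`, `lo_hz`, `hi_hz`, `slope`.
#' @param ages data.frame `(subject_id, age)`.
#' @param rope ROPE bounds.
#' @param backend passed to [standardized_effect()].
#' @param n_draws resamples per cell.
#' @param seed base seed; each cell uses a deterministic offset.
#' @return list of class `multiverse_result`: `cells` (one row per cell
#'   with beta, interval, category), `summary` (per-condition category
#'   percentages, summing to 100), `diagnostics` (skipped cells).
#' @export
run_multiverse <- function(slope_table, ages, rope = c(-0.1, 0.1),
                           backend = "bootstrap", n_draws = 2000,
                           seed = 1) {
  req <- c("subject_id", "condition", "channel", "lo_hz", "hi_hz", "slope")
  if (!all(req %in% names(slope_table)))
    stop_invalid("slope_table needs columns %s", paste(req, collapse = ", "))
  age_lookup <- stats::setNames(ages$age, ages$subject_id)
  key <- interaction(slope_table$condition, slope_table$channel,
                     slope_table$lo_hz, slope_table$hi_hz, drop = TRUE)
  cells <- split(slope_table, key)
  skipped <- character(0)
  rows <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    age <- age_lookup[cell$subject_id]
    est <- try(standardized_effect(age, cell$slope, backend = backend,
                                   n_draws = n_draws,
                                   seed = seed + i),
               silent = TRUE)
    if (inherits(est, "try-error")) {
      skipped <- c(skipped, names(cells)[i])
      next
    }
    rows[[i]] <- data.frame(
      condition = cell$condition[1], channel = cell$channel[1],
      lo_hz = cell$lo_hz[1], hi_hz = cell$hi_hz[1],
      beta = est$beta, lower = est$lower, upper = est$upper,
      category = classify_effect(est, rope), stringsAsFactors = FALSE)
  }
  cells_df <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(cells_df))
    stop_invalid("every multiverse cell failed (first: %s)",
                 if (length(skipped)) skipped[1] else "none")
  lev <- c("steepening", "flattening", "null",
           "undecided_steepening", "undecided_flattening")
  summ <- do.call(rbind, lapply(split(cells_df, cells_df$condition),
                                function(d) {
    counts <- table(factor(d$category, levels = lev))
    data.frame(condition = d$condition[1], category = lev,
               percent = as.numeric(counts) / nrow(d) * 100,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(cells = cells_df, summary = summ,
                 diagnostics = list(skipped = skipped)),
            class = "multiverse_result")
}

#' @export
print.multiverse_result <- function(x, ...) {
  cat(sprintf("<multiverse_result> %d cells, %d condition(s)\n",
              nrow(x$cells), length(unique(x$cells$condition))))
  print(utils::head(stats::reshape(
    x$summary, direction = "wide", idvar = "condition",
    timevar = "category"), 10))
  invisible(x)
}

#' Joint (partial) regression of age on two slope predictors
#'
#' Multiple regression `age ~ slope_ecg_component + slope_ecg_rejected`
#' with all variables z-scored; per-predictor standardized coefficients
#' with 94% HDIs, classified against the ROPE. Disentangles whether the
#' cardiac-component slope and the cardiac-cleaned slope carry
#' independent information about age.
#'
#' @param age outcome vector.
#' @param slope_ecg_component,slope_ecg_rejected predictor vectors.
#' @param rope ROPE bounds.
#' @param n_draws bootstrap resamples.
#' @param seed RNG seed.
#' @return list with one `effect_estimate` (+ `category`) per predictor.
#' @export
partial_regression <- function(age, slope_ecg_component,
                               slope_ecg_rejected, rope = c(-0.1, 0.1),
                               n_draws = 2000, seed = 1) {
  n <- length(age)
  if (n < 20) stop_invalid("need n >= 20")
  if (abs(stats::cor(slope_ecg_component, slope_ecg_rejected)) > 0.99)
    stop_invalid("predictors are collinear (|r| > 0.99)")
  Z <- cbind(1, zscore(slope_ecg_component), zscore(slope_ecg_rejected))
  zy <- zscore(age)
  draws <- with_local_seed(seed, {
    out <- matrix(NA_real_, n_draws, 2)
    for (i in seq_len(n_draws)) {
      idx <- sample.int(n, n, replace = TRUE)
      cf <- try(stats::.lm.fit(Z[idx, , drop = FALSE], zy[idx])$coefficients,
                silent = TRUE)
      if (!inherits(cf, "try-error")) out[i, ] <- cf[2:3]
    }
    out
  })
  mk <- function(col) {
    d <- draws[is.finite(draws[, col]), col]
    ci <- hdi_interval(d, 0.94)
    est <- structure(list(beta = stats::median(d), lower = ci[1],
                          upper = ci[2], level = 0.94,
                          backend = "bootstrap", n = n,
                          diagnostics = list(n_resamples = length(d))),
                     class = "effect_estimate")
    est$category <- classify_effect(est, rope)
    est
  }
  list(ecg_component = mk(1), ecg_rejected = mk(2))
}

#' Random-intercept task contrast of spectral slopes
#'
#' Mixed model `slope ~ 1 + phase + (1 | subject)` (or the load variant
#' `slope ~ 1 + load + (1 | subject)` with one fixed effect per load
#' level against baseline), estimated by REML via `lme4`. The 94%
#' interval is the HDI of normal draws centered on the REML estimate
#' with its standard error — a large-sample approximation of the
#' posterior under a flat prior.
#'
#' @param slope_table data.frame with columns `subject_id`, `slope`, and
#'   the contrast column (`phase` with a `"Baseline"` reference level,
#'   or `load`).
#' @param formula `"contrast"` (phase) or `"load"`.
#' @param rope ROPE bounds for classification.
#' @param n_draws draws for the interval.
#' @param seed RNG seed.
#' @return list of `effect_estimate`s (one per non-baseline level), each
#'   with a `category` field.
#' @export
task_contrast <- function(slope_table, formula = c("contrast", "load"),
                          rope = c(-0.1, 0.1), n_draws = 4000, seed = 1) {
  formula <- match.arg(formula)
  var <- if (formula == "contrast") "phase" else "load"
  req <- c("subject_id", "slope", var)
  if (!all(req %in% names(slope_table)))
    stop_invalid("slope_table needs columns %s", paste(req, collapse = ", "))
  if (any(table(slope_table$subject_id) < 2))
    stop_invalid("need >= 2 observations per subject")
  slope_table[[var]] <- stats::relevel(
    factor(slope_table[[var]]),
    ref = if ("Baseline" %in% slope_table[[var]]) "Baseline"
          else levels(factor(slope_table[[var]]))[1])
  n_sub <- length(unique(slope_table$subject_id))
  fml <- stats::as.formula(sprintf("slope ~ 1 + %s + (1 | subject_id)", var))
  fit <- if (n_sub >= 3) {
    lme4::lmer(fml, data = slope_table, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  } else {
    # degenerate: too few subjects for a variance component
    warning("fewer than 3 subjects: falling back to a pooled contrast")
    stats::lm(stats::as.formula(sprintf("slope ~ 1 + %s", var)),
              data = slope_table)
  }
  cf <- if (inherits(fit, "lmerMod")) lme4::fixef(fit) else stats::coef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  idx <- which(names(cf) != "(Intercept)")
  out <- list()
  for (j in idx) {
    d <- with_local_seed(seed + j, stats::rnorm(n_draws, cf[j], se[j]))
    ci <- hdi_interval(d, 0.94)
    est <- structure(list(beta = stats::median(d), lower = ci[1],
                          upper = ci[2], level = 0.94,
                          backend = "bootstrap", n = n_sub,
                          diagnostics = list(se = se[j])),
                     class = "effect_estimate")
    est$category <- classify_effect(est, rope)
    out[[names(cf)[j]]] <- est
  }
  out
}
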