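# Synthetic ambulatory-blood-pressure-like data with known truth.

#' Simulation configuration
#'
#' Describes a two-group synthetic monitoring study: group sizes (default 87
#' "OSA" and 135 "CTR" subjects), a half-hourly 24-hour sampling grid,
#' optional monotone late-interval dropout, a known group-specific truth in
#' the same truncated-power parameterization the fitter uses, covariate
#' effects, and the variance components of the error model (subject random
#' intercepts, optional exponentially correlated serial noise, white noise).
#'
#' The default truth is a nocturnal-dip shape on a log blood-pressure scale:
#' a negative quadratic bowl reaching its minimum roughly 8-9 hours after
#' sleep onset, with a spline term flattening the curve after the wake-up
#' rise, and a modest OSA-vs-control quadratic difference. Default covariates
#' are age (uniform on 5-18 years), BMI z-score (standard normal) and two
#' 0/1 indicators (gender, race), each Bernoulli(0.5).
#'
#' @param n_per_group named integer vector of subjects per group; names are
#'   the group labels and the *last* name is the reference level used for
#'   indicator coding (default `c(OSA = 87, CTR = 135)`).
#' @param times sampling grid in hours (default `seq(0, 24, 0.5)`, 49 points).
#' @param knots truth spline knots; default: quantile knots ([select_knots()])
#'   of `times` with `K = 9`.
#' @param beta reference-group polynomial: intercept, linear, quadratic.
#' @param delta non-reference-group additive polynomial difference.
#' @param b_shared truth spline coefficients shared by the groups (length =
#'   number of knots). `NULL` selects the built-in dip coefficients when
#'   `times` spans the default 24-hour half-hourly grid, otherwise zeros.
#' @param b_group optional named list of per-group spline coefficient vectors
#'   *replacing* `b_shared` (used for truths with group-specific smoothing).
#' @param covariates logical: draw the four default covariates and add their
#'   effects `theta`?
#' @param theta named covariate effects (response units per covariate unit).
#' @param sigma2_u subject random-intercept variance.
#' @param serial `"none"`, `"exponential"` or `"gaussian"` serial noise.
#' @param sigma2_delta,tau serial variance and decay scale (hours).
#' @param sigma2_omega white-noise variance.
#' @param dropout `NULL` for complete sampling, or `list(start=, rate=)`:
#'   each subject's last retained time is `start` plus an Exp(rate) draw, so
#'   retention decays monotonically across the late interval.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c(OSA = 87, CTR = 135),
                       times = seq(0, 24, by = 0.5),
                       knots = NULL,
                       beta = c(4.25, -0.05, 0.003),
                       delta = c(0.06, -0.008, 0.0004),
                       b_shared = NULL,
                       b_group = NULL,
                       covariates = TRUE,
                       theta = c(age = 0.004, bmiz = 0.012,
                                 gender = 0.01, race = 0.005),
                       sigma2_u = 0.01,
                       serial = c("exponential", "none", "gaussian"),
                       sigma2_delta = 0.004, tau = 2,
                       sigma2_omega = 0.004,
                       dropout = NULL) {
  serial <- match.arg(serial)
  if (is.null(names(n_per_group)) || length(n_per_group) != 2L) {
    stop("n_per_group must be a named vector with two groups")
  }
  if (is.null(knots)) knots <- select_knots(times, K = 9L)
  K <- length(knots)
  if (is.null(b_shared)) {
    b_shared <- if (isTRUE(all.equal(range(times), c(0, 24))) && K == 9L) {
      # small wiggle plus a flattening term at the mid-interval knot so the
      # post-wake rise levels off instead of growing quadratically
      c(6e-4, -8e-4, 5e-4, 9e-4, -3.2e-3, 4e-4, -2e-4, 3e-4, -2e-4)
    } else if (K > 0L) {
      # grid-adaptive modest wiggle: each truncated term contributes about
      # +/-0.02 response units at the right edge of the sampled interval
      0.02 * (-1)^seq_len(K) / (max(times) - knots)^2
    } else {
      numeric(0)
    }
  }
  if (length(b_shared) != K) stop("b_shared must have one value per knot")
  if (!is.null(b_group)) {
    if (!setequal(names(b_group), names(n_per_group)) ||
        !all(lengths(b_group) == K)) {
      stop("b_group must name both groups, one coefficient per knot")
    }
  }
  stopifnot(sigma2_u >= 0, sigma2_delta >= 0, sigma2_omega >= 0, tau > 0,
            all(diff(times) > 0), length(beta) == 3L, length(delta) == 3L)
  if (!is.null(dropout)) {
    stopifnot(is.list(dropout), dropout$rate > 0)
  }
  structure(list(n_per_group = n_per_group, times = times, knots = knots,
                 beta = beta, delta = delta, b_shared = b_shared,
                 b_group = b_group, covariates = covariates, theta = theta,
                 sigma2_u = sigma2_u, serial = serial,
                 sigma2_delta = sigma2_delta, tau = tau,
                 sigma2_omega = sigma2_omega, dropout = dropout),
            class = "sim_config")
}

# Truth evaluators (exact basis arithmetic, shared with the fitter's basis).
.make_truth <- function(config) {
  groups <- names(config$n_per_group)
  ref <- groups[length(groups)]
  bs <- basis_spec(2L, config$knots)
  coef_for <- function(group) {
    poly <- config$beta + if (group == ref) 0 else config$delta
    b <- if (!is.null(config$b_group)) config$b_group[[group]] else config$b_shared
    list(poly = poly, b = b)
  }
  f <- function(t, group) {
    cf <- coef_for(group)
    B <- tp_basis(t, bs)
    drop(cf$poly[1L] + B %*% c(cf$poly[2:3], cf$b))
  }
  fprime <- function(t, group) {
    cf <- coef_for(group)
    B <- tp_basis_deriv(t, bs)
    drop(B %*% c(cf$poly[2:3], cf$b))
  }
  structure(list(f = f, fprime = fprime, groups = groups, ref_group = ref,
                 knots = config$knots, config = config),
            class = "sp_truth")
}

#' Simulate a synthetic monitoring dataset
#'
#' Draws one dataset from a [sim_config()]: per subject, the group truth
#' curve plus covariate effects, a Gaussian random intercept, a serial
#' Gaussian-process draw (exact covariance construction via per-subject
#' Cholesky factorization) and white noise. Reproducible under `seed`.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed (optional but recommended).
#' @return List with `data` (an [sp_data]) and `truth` (class `sp_truth`,
#'   with exact evaluators `f(t, group)` and `fprime(t, group)` and all
#'   generating parameters).
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  truth <- .make_truth(config)
  .with_seed(seed, {
    groups <- names(config$n_per_group)
    rows <- list()
    sid <- 0L
    for (g in groups) {
      for (i in seq_len(config$n_per_group[[g]])) {
        sid <- sid + 1L
        tt <- config$times
        if (!is.null(config$dropout)) {
          last <- config$dropout$start + stats::rexp(1L, config$dropout$rate)
          tt <- tt[tt <= last]
          if (length(tt) < 2L) tt <- config$times[1:2]
        }
        n <- length(tt)
        mu <- truth$f(tt, g)
        cv <- NULL
        if (config$covariates) {
          cv <- c(age = stats::runif(1, 5, 18),
                  bmiz = stats::rnorm(1),
                  gender = stats::rbinom(1, 1, 0.5),
                  race = stats::rbinom(1, 1, 0.5))
          mu <- mu + sum(config$theta[names(cv)] * cv)
        }
        e <- stats::rnorm(1, 0, sqrt(config$sigma2_u)) +
          stats::rnorm(n, 0, sqrt(config$sigma2_omega))
        if (config$serial != "none" && config$sigma2_delta > 0) {
          Cm <- config$sigma2_delta * serial_corr(tt, config$serial, config$tau)
          e <- e + drop(crossprod(chol(Cm), stats::rnorm(n)))
        }
        row <- data.frame(subject = sprintf("s%04d", sid), group = g,
                          time = tt, response = mu + e)
        if (!is.null(cv)) for (nm in names(cv)) row[[nm]] <- cv[[nm]]
        rows[[sid]] <- row
      }
    }
    df <- do.call(rbind, rows)
    covnames <- if (config$covariates) c("age", "bmiz", "gender", "race") else character()
    list(data = sp_data(df, covariates = covnames, group_levels = groups),
         truth = truth)
  })
}

#' Stepwise-selection simulation study
#'
#' Per replicate: draw one spline-coefficient variance per group from
#' Uniform(0, 1), draw group-specific truth spline coefficients from those
#' variances, simulate a dataset (white noise + random intercepts by
#' default), run [stepwise_group_selection()], and tally which structure the
#' criterion selects. Boundary-flagged winning fits and failed replicates are
#' counted separately.
#'
#' @param config a [sim_config()]; its `b_group` is overwritten each
#'   replicate by the Uniform-variance draws.
#' @param n_reps number of replicates.
#' @param K_fit number of quantile knots used by the fitted models (default:
#'   the truth's knot count).
#' @param criterion,method passed to [stepwise_group_selection()].
#' @param serial_fit serial structure used when fitting (default `"none"`).
#' @param seed integer seed.
#' @return Object of class `sp_simstudy`: list with `counts` and `rates`
#'   (named by structure), `n_boundary`, `n_failed`, `n_reps`, `seed`.
#' @export
simulation_study <- function(config, n_reps = 100L, K_fit = NULL,
                             criterion = "aic_adj", method = "ML",
                             serial_fit = "none", seed = 1L) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1L)
  groups <- names(config$n_per_group)
  K <- length(config$knots)
  if (is.null(K_fit)) K_fit <- K
  structures <- c("1.1", "1.2", "1.3", "1.4", "1.5")
  counts <- stats::setNames(integer(length(structures)), structures)
  n_boundary <- 0L; n_failed <- 0L
  .with_seed(seed, {
    for (r in seq_len(n_reps)) {
      v <- stats::runif(2L)
      bg <- stats::setNames(lapply(v, function(s2) stats::rnorm(K, 0, sqrt(s2))),
                            groups)
      cfg_r <- config
      cfg_r$b_group <- bg
      sim <- simulate_dataset(cfg_r, seed = NULL)
      sel <- tryCatch({
        d <- sim$data$data
        bs <- basis_spec(2L, select_knots(d$time, K_fit))
        stepwise_group_selection(sim$data, bs, cov_spec(serial_fit),
                                 covariates = sim$data$covariates,
                                 ref_group = groups[length(groups)],
                                 criterion = criterion, method = method)
      }, error = function(e) e)
      if (inherits(sel, "error")) {
        n_failed <- n_failed + 1L
      } else {
        counts[sel$chosen] <- counts[sel$chosen] + 1L
        win <- sel$table[sel$table$structure == sel$chosen, ]
        if (isTRUE(win$boundary)) n_boundary <- n_boundary + 1L
      }
    }
  })
  done <- sum(counts)
  structure(list(counts = counts,
                 rates = if (done) counts / done else counts,
                 n_boundary = n_boundary, n_failed = n_failed,
                 n_reps = n_reps, seed = seed),
            class = "sp_simstudy")
}

#' @export
print.sp_simstudy <- function(x, ...) {
  cat("Structure selection over", x$n_reps, "replicates (seed", x$seed, ")\n")
  print(round(x$rates, 3))
  cat("boundary-flagged winners:", x$n_boundary,
      "| failed replicates:", x$n_failed, "\n")
  invisible(x)
}

#' Empirical coverage of the difference-curve bands
#'
#' Per replicate: simulate from `config`, fit the stated structure, build
#' pointwise and simultaneous bands for the non-reference-minus-reference
#' group difference on an equally spaced grid, and record whether the true
#' difference curve lies inside the simultaneous band at every grid point
#' (simultaneous coverage) and inside the pointwise band per point.
#'
#' @param config a [sim_config()] with two groups.
#' @param n_reps number of simulated datasets.
#' @param structure fitted structure (default `"1.3"`).
#' @param level nominal band level.
#' @param n_sim simulation draws per band.
#' @param grid_length grid points across the sampled range (default 25).
#' @param method fit method (default `"REML"`: band inference is conditional
#'   on variance components, which REML estimates with less small-sample
#'   bias).
#' @param seed integer seed.
#' @return Object of class `sp_coverage`: list with `simultaneous`
#'   (proportion of replicates fully covered), `pointwise` (mean per-point
#'   coverage), `mc_se` (binomial Monte-Carlo SE of `simultaneous`),
#'   `n_fail`, `n_reps`, `level`, `seed`.
#' @export
coverage_study <- function(config, n_reps = 200L, structure = "1.3",
                           level = 0.95, n_sim = 500L, grid_length = 25L,
                           method = "REML", seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  groups <- names(config$n_per_group)
  ref <- groups[length(groups)]
  nonref <- groups[1L]
  grid <- seq(min(config$times), max(config$times), length.out = grid_length)
  covered <- logical(0); pw <- numeric(0); n_fail <- 0L
  .with_seed(seed, {
    for (r in seq_len(n_reps)) {
      sim <- simulate_dataset(config, seed = NULL)
      band_seed <- sample.int(.Machine$integer.max, 1L)
      res <- tryCatch({
        d <- sim$data$data
        bs <- basis_spec(2L, select_knots(d$time, length(config$knots)))
        spec <- model_spec(structure, bs,
                           covariates = sim$data$covariates,
                           ref_group = ref)
        fit <- withCallingHandlers(
          sp_fit(sim$data, spec, cov_spec(config$serial), method = method),
          warning = function(w) invokeRestart("muffleWarning"))
        sb <- simultaneous_band(fit, grid, nonref, ref, level = level,
                                n_sim = n_sim, seed = band_seed)
        pb <- pointwise_band(fit, grid, nonref, ref, level = level)
        truth_d <- sim$truth$f(grid, nonref) - sim$truth$f(grid, ref)
        list(sim_cov = all(truth_d >= sb$lower & truth_d <= sb$upper),
             pw_cov = mean(truth_d >= pb$lower & truth_d <= pb$upper))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_fail <- n_fail + 1L
      } else {
        covered <- c(covered, res$sim_cov)
        pw <- c(pw, res$pw_cov)
      }
    }
  })
  ph <- mean(covered)
  structure(list(simultaneous = ph, pointwise = mean(pw),
                 mc_se = sqrt(ph * (1 - ph) / max(length(covered), 1L)),
                 n_fail = n_fail, n_reps = n_reps, level = level,
                 seed = seed),
            class = "sp_coverage")
}

#' @export
print.sp_coverage <- function(x, ...) {
  cat(sprintf("Empirical band coverage over %d replicates (nominal %.0f%%)\n",
              x$n_reps, 100 * x$level))
  cat(sprintf("  simultaneous: %.3f (MC SE %.3f) | mean pointwise: %.3f | failures: %d\n",
              x$simultaneous, x$mc_se, x$pointwise, x$n_fail))
  invisible(x)
}
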