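# Difference curves and confidence bands.
#
# Inference is conditional on the estimated variance components: the joint
# error of the fixed effects and spline EBLUPs is Gaussian with covariance
# (C'R^{-1}C + B)^{-1}, where C = [X Z_b] and B penalizes only the spline
# blocks. A contrast design C_g stacked over a time grid turns that
# covariance into pointwise standard deviations, and a simulated sup
# statistic turns the pointwise multiplier into a simultaneous one.

# Contrast rows over the grid for f_l - f_l' (or a single group's curve),
# on the curve or derivative scale.
.contrast_design <- function(fit, grid, group, group2 = NULL,
                             derivative = FALSE) {
  g1 <- grid_design(fit$design, grid, group, derivative = derivative)
  if (is.null(group2)) {
    Cg <- cbind(g1$X, g1$Z)
  } else {
    if (identical(group, group2)) stop("the two groups must differ")
    g2 <- grid_design(fit$design, grid, group2, derivative = derivative)
    Cg <- cbind(g1$X - g2$X, g1$Z - g2$Z)
  }
  Cg
}

.band_sd <- function(fit, Cg) {
  # sqrt(diag(Cg (C'R^{-1}C + B)^{-1} Cg'))
  W <- backsolve(fit$precision_chol, t(Cg), transpose = TRUE)
  sqrt(colSums(W^2))
}

#' Between-group difference curve with pointwise SD
#'
#' Evaluates `f_l(t) - f_l'(t)` over a grid together with its conditional
#' standard deviation from the joint precision of the fixed effects and
#' spline coefficients. Covariate effects cancel in the difference.
#'
#' @param fit an `sp_fit` object.
#' @param grid numeric vector of grid times (typically equally spaced).
#' @param group,group2 the two group levels; the difference is
#'   `group - group2`.
#' @return Data frame with columns `time`, `estimate`, `sd`.
#' @export
difference_curve <- function(fit, grid, group, group2) {
  stopifnot(inherits(fit, "sp_fit"))
  if (identical(group, group2)) stop("the two groups must differ")
  f1 <- predict_curve(fit, grid, group)
  f2 <- predict_curve(fit, grid, group2)
  Cg <- .contrast_design(fit, grid, group, group2)
  data.frame(time = grid, estimate = f1$estimate - f2$estimate,
             sd = .band_sd(fit, Cg))
}

.band_result <- function(grid, estimate, sd, multiplier, level, n_sim = NA,
                         seed = NA, type) {
  structure(data.frame(time = grid, estimate = estimate, sd = sd,
                       lower = estimate - multiplier * sd,
                       upper = estimate + multiplier * sd),
            multiplier = multiplier, level = level, n_sim = n_sim,
            seed = seed, band_type = type,
            class = c("band_result", "data.frame"))
}

#' Pointwise confidence band for a difference curve
#'
#' `estimate +/- z_{1-alpha/2} * SD` at each grid point; at level 0.95 the
#' multiplier is 1.959964 (the familiar 1.96).
#'
#' @inheritParams difference_curve
#' @param level confidence level in (0, 1).
#' @return A `band_result` data frame with columns `time`, `estimate`, `sd`,
#'   `lower`, `upper`; the multiplier, level and band type are attributes.
#' @export
pointwise_band <- function(fit, grid, group, group2, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  dc <- difference_curve(fit, grid, group, group2)
  z <- stats::qnorm((1 + level) / 2)
  .band_result(grid, dc$estimate, dc$sd, z, level, type = "pointwise")
}

# Shared simulation core: sup_t |(Cg E)_t / SD_t| over draws E from
# N(0, (C'R^{-1}C + B)^{-1}); h = the ceiling((level) * n_sim)-th order
# statistic. The plug-in SD is held fixed across draws.
.sup_quantile <- function(fit, Cg, sd, level, n_sim, seed) {
  if (n_sim < 100L) stop("n_sim must be at least 100")
  d <- nrow(fit$precision)
  sims <- .with_seed(seed, {
    Zm <- matrix(stats::rnorm(d * n_sim), d, n_sim)
    E <- backsolve(fit$precision_chol, Zm)       # cov = (U'U)^{-1}
    apply(abs((Cg %*% E) / sd), 2L, max)
  })
  k <- ceiling(level * n_sim)
  sort(sims)[k]
}

# Evaluate expr with a temporary RNG state; restores the caller's state.
.with_seed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Simulation-based simultaneous confidence band
#'
#' Draws coefficient errors from the conditional Gaussian with covariance
#' `(C'R^{-1}C + B)^{-1}`, forms the sup over the grid of the absolute
#' standardized contrast per draw, and uses the `ceiling(level * n_sim)`-th
#' order statistic as the simultaneous multiplier `h_level` (rank 9,500 at
#' `n_sim = 10000`, level 0.95). The band `estimate +/- h * SD` then covers
#' the whole true difference curve with approximately the nominal
#' probability; `h >= z` always, so simultaneous bands are at least as wide
#' as pointwise ones.
#'
#' @inheritParams pointwise_band
#' @param n_sim number of simulation draws (>= 100; default 10000).
#' @param seed integer seed making the band reproducible; stored in the
#'   result.
#' @return A `band_result` data frame; attributes carry the multiplier
#'   `h`, `level`, `n_sim` and `seed`.
#' @export
simultaneous_band <- function(fit, grid, group, group2, level = 0.95,
                              n_sim = 10000L, seed = 1L) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  dc <- difference_curve(fit, grid, group, group2)
  Cg <- .contrast_design(fit, grid, group, group2)
  h <- .sup_quantile(fit, Cg, dc$sd, level, n_sim, seed)
  .band_result(grid, dc$estimate, dc$sd, h, level, n_sim, seed,
               type = "simultaneous")
}

#' Simultaneous band for derivative curves
#'
#' As [simultaneous_band()], with the contrast built from the derivative
#' basis: either a single group's rate-of-change curve (`group2 = NULL`) or
#' the between-group difference of derivatives.
#'
#' @inheritParams simultaneous_band
#' @param group2 second group for a derivative difference, or `NULL` for a
#'   single group's derivative band.
#' @return A `band_result` data frame on the derivative scale.
#' @export
simultaneous_band_derivative <- function(fit, grid, group, group2 = NULL,
                                         level = 0.95, n_sim = 10000L,
                                         seed = 1L) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  est1 <- derivative_curve(fit, grid, group)$estimate
  est <- if (is.null(group2)) est1 else {
    est1 - derivative_curve(fit, grid, group2)$estimate
  }
  Cg <- .contrast_design(fit, grid, group, group2, derivative = TRUE)
  sd <- .band_sd(fit, Cg)
  h <- .sup_quantile(fit, Cg, sd, level, n_sim, seed)
  .band_result(grid, est, sd, h, level, n_sim, seed,
               type = "simultaneous-derivative")
}

#' @export
print.band_result <- function(x, ...) {
  cat(sprintf("%s %.0f%% confidence band: %d grid points, multiplier %.4f\n",
              attr(x, "band_type"), 100 * attr(x, "level"), nrow(x),
              attr(x, "multiplier")))
  NextMethod()
}
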