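#' Fit a semiparametric mixed model
#'
#' Maximizes the marginal (ML) or restricted (REML) Gaussian log-likelihood
#' of the penalized-spline linear mixed model over log variance components,
#' with fixed effects profiled out by generalized least squares at every
#' iterate. Spline coefficients are Gaussian random effects (one variance per
#' spline block), subjects contribute random intercepts, and the residual may
#' carry exponential or Gaussian serial correlation plus white noise.
#'
#' Estimation is deterministic given the data, options and starting point:
#' a Nelder-Mead search on the log scale, restarted once from its own
#' optimum. Variance components estimated below `boundary_tol` (natural
#' scale, relative to the response variance) set a boundary flag, mirroring
#' the near-zero spline-variance pathology that makes such fits questionable.
#'
#' @param data an [sp_data] object.
#' @param spec an [model_spec()] object.
#' @param cov an [cov_spec()] object (default: no serial correlation).
#' @param method `"ML"` (default; required for likelihood-ratio comparison of
#'   fixed-effect structures) or `"REML"` (preferred for conditional band
#'   inference and variance components).
#' @param start optional named numeric vector of starting variance components
#'   (natural scale).
#' @param control list: `maxit` (per Nelder-Mead pass, default 1000),
#'   `reltol` (default 1e-10), `boundary_tol` (default 1e-8).
#' @return Object of class `sp_fit` with components `beta` (fixed effects),
#'   `b` (spline EBLUPs), `u` (subject-intercept EBLUPs), `varcomp`, `m2ll`
#'   (-2 log-likelihood of `method`'s criterion), `precision` / `precision_chol`
#'   (the joint (beta, b) precision `C'R^{-1}C + B` and its Cholesky factor),
#'   `ep` (effective number of parameters), `convergence`, and the design
#'   bookkeeping needed for prediction and bands.
#' @export
sp_fit <- function(data, spec, cov = cov_spec("none"),
                   method = c("ML", "REML"), start = NULL,
                   control = list()) {
  method <- match.arg(method)
  stopifnot(inherits(data, "sp_data"), inherits(spec, "sp_model"),
            inherits(cov, "sp_cov"))
  ctl <- utils::modifyList(list(maxit = 1000L, reltol = 1e-10,
                                boundary_tol = 1e-8), control)
  design <- build_design(data, spec)
  y <- data$data$response
  time <- data$data$time
  N <- length(y)
  p <- ncol(design$X); q <- ncol(design$Z)
  vcn <- .vc_names(design, cov$serial)
  m_par <- p + length(vcn)
  if (N <= m_par) stop("fewer observations (", N, ") than counted parameters (", m_par, ")")
  blocks <- .make_blocks(design, y, time)

  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  st <- c(sigma2_u = 0.3 * vy, sigma2_omega = 0.5 * vy)
  if (q > 0L) {
    zsc <- mean(rowSums(design$Z^2))
    if (!is.finite(zsc) || zsc <= 0) zsc <- 1
    bstart <- 0.2 * vy / zsc
    nb <- max(design$spline_block)
    bn <- if (nb == 1L) "sigma2_b" else paste0("sigma2_b", seq_len(nb))
    st <- c(st, stats::setNames(rep(bstart, nb), bn))
  }
  if (cov$serial != "none") {
    st <- c(st, sigma2_delta = 0.2 * vy, tau = diff(range(time)) / 8)
  }
  st <- st[vcn]
  if (!is.null(start)) st[names(start)] <- start

  neval <- 0L
  obj <- function(lp) {
    neval <<- neval + 1L
    lp <- pmin(pmax(lp, -40), 40)
    vc <- stats::setNames(exp(lp), vcn)
    res <- .profile_m2ll(blocks, design, cov$serial, vc, method)
    if (is.null(res) || !is.finite(res$m2ll)) return(.Machine$double.xmax / 1e6)
    res$m2ll
  }
  lp0 <- log(pmax(st, 1e-12))
  o1 <- stats::optim(lp0, obj, method = "Nelder-Mead",
                     control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  o2 <- stats::optim(o1$par, obj, method = "Nelder-Mead",
                     control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  if (o2$value > o1$value) o2 <- o1
  lp_hat <- pmin(pmax(o2$par, -40), 40)
  vc_hat <- stats::setNames(exp(lp_hat), vcn)
  res <- .profile_m2ll(blocks, design, cov$serial, vc_hat, method)
  if (is.null(res)) stop("likelihood evaluation failed at the optimum")
  converged <- (o2$convergence == 0L) || (o1$convergence == 0L)
  if (!converged) {
    warning("optimizer did not report convergence; returning best iterate")
  }

  boundary <- vc_hat < ctl$boundary_tol * max(vy, 1e-12)
  boundary["tau"] <- FALSE  # tau is a scale, not a variance
  boundary <- boundary[!is.na(boundary)]
  if (any(boundary)) {
    warning("variance component(s) at the zero boundary: ",
            paste(names(vc_hat)[boundary], collapse = ", "),
            "; results may be questionable")
  }

  fit <- .finalize_fit(blocks, design, cov, vc_hat, res, method)
  fit$convergence <- list(converged = converged, evaluations = neval,
                          optim_convergence = o2$convergence,
                          boundary = boundary)
  fit$data <- data
  class(fit) <- "sp_fit"
  fit
}

# Assemble EBLUPs, joint precision and E_p from the optimum's cross-products.
.finalize_fit <- function(blocks, design, cov, vc, res, method) {
  cp <- res$cp
  p <- cp$p; q <- cp$q
  ix <- seq_len(p); iz <- p + seq_len(q); iy <- p + q + 1L
  A <- cp$CtRC[c(ix, iz), c(ix, iz), drop = FALSE]   # C'R^{-1}C
  Cty <- cp$CtRC[c(ix, iz), iy]
  Mfull <- A
  if (q > 0L) {
    gv <- .gvec(design, vc)
    diag(Mfull)[iz] <- diag(Mfull)[iz] + 1 / gv
  }
  cMf <- chol(Mfull)
  coef <- backsolve(cMf, backsolve(cMf, Cty, transpose = TRUE))
  ep <- sum(diag(backsolve(cMf, backsolve(cMf, A, transpose = TRUE))))

  # subject-intercept EBLUPs: u_i = sigma2_u * 1' A_i^{-1} (y_i - C_i coef)
  fitted_fix <- drop(cbind(design$X, design$Z) %*% coef)
  resid <- blocks$y - fitted_fix
  u <- vapply(seq_along(blocks$idx), function(i) {
    ii <- blocks$idx[[i]]
    U <- cp$chols[[blocks$sig[i]]]
    s <- backsolve(U, backsolve(U, resid[ii], transpose = TRUE))
    vc[["sigma2_u"]] * sum(s)
  }, numeric(1))
  names(u) <- names(blocks$idx)

  beta <- stats::setNames(coef[ix], colnames(design$X))
  b <- if (q > 0L) stats::setNames(coef[iz], colnames(design$Z)) else numeric(0)

  list(beta = beta, b = b, u = u, varcomp = vc, m2ll = res$m2ll,
       method = method, ep = ep, precision = Mfull, precision_chol = cMf,
       design = design, cov = cov, N = cp$N, p_fixed = p, q_spline = q,
       n_varcomp = length(vc), logdetV = res$logdetV, quad = res$quad)
}

#' Extract estimated coefficients and EBLUPs
#'
#' @param fit an `sp_fit` object.
#' @return List with `beta` (fixed effects), `b` (spline EBLUPs) and `u`
#'   (subject-intercept EBLUPs).
#' @export
eblup_coefficients <- function(fit) {
  stopifnot(inherits(fit, "sp_fit"))
  list(beta = fit$beta, b = fit$b, u = fit$u)
}

#' @export
logLik.sp_fit <- function(object, ...) {
  structure(-object$m2ll / 2, df = object$p_fixed + object$n_varcomp,
            class = "logLik")
}

#' @export
print.sp_fit <- function(x, ...) {
  cat(sprintf("Semiparametric mixed model (structure %s, serial %s, %s)\n",
              x$design$spec$structure, x$cov$serial, x$method))
  cat(sprintf("  %d observations, %d subjects; -2 logLik = %.4f\n",
              x$N, length(x$u), x$m2ll))
  cat("  Fixed effects:\n")
  print(round(x$beta, 6))
  cat("  Variance components:\n")
  print(signif(x$varcomp, 6))
  cat(sprintf("  Effective number of parameters: %.4f\n", x$ep))
  if (any(x$convergence$boundary)) {
    cat("  NOTE: variance component(s) at the zero boundary; fit questionable\n")
  }
  invisible(x)
}

#' Predict a group-specific mean curve
#'
#' Evaluates the fitted group curve `f_l(t)` on a time grid: the group's
#' fixed polynomial terms plus its spline block, with covariates held at
#' reference values (zero by default, so the curve is the mean response at
#' covariate values equal to zero).
#'
#' @param fit an `sp_fit` object.
#' @param grid numeric vector of times; extrapolation beyond the fitted range
#'   triggers a warning.
#' @param group group level to evaluate.
#' @param covariate_values optional named vector of covariate reference values.
#' @return Data frame (class `curve_table`) with columns `time`, `group`,
#'   `estimate`.
#' @export
predict_curve <- function(fit, grid, group, covariate_values = NULL) {
  stopifnot(inherits(fit, "sp_fit"))
  tr <- range(fit$data$data$time)
  if (min(grid) < tr[1L] || max(grid) > tr[2L]) {
    warning("grid extends beyond the fitted time range; extrapolating")
  }
  gd <- grid_design(fit$design, grid, group, covariate_values)
  est <- drop(gd$X %*% fit$beta + if (fit$q_spline) gd$Z %*% fit$b else 0)
  structure(data.frame(time = grid, group = group, estimate = est),
            class = c("curve_table", "data.frame"))
}

#' Plug-in derivative ("rate of change") curve
#'
#' Substitutes the fitted coefficients into the first derivative of the
#' truncated power basis, giving the estimated rate of change of the group
#' curve. With degree-1 splines the result is piecewise constant.
#'
#' @inheritParams predict_curve
#' @return Data frame (class `curve_table`) with columns `time`, `group`,
#'   `estimate` (derivative units: response per hour).
#' @export
derivative_curve <- function(fit, grid, group) {
  stopifnot(inherits(fit, "sp_fit"))
  gd <- grid_design(fit$design, grid, group, derivative = TRUE)
  est <- drop(gd$X %*% fit$beta + if (fit$q_spline) gd$Z %*% fit$b else 0)
  structure(data.frame(time = grid, group = group, estimate = est),
            class = c("curve_table", "data.frame"))
}
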