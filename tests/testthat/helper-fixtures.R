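# Shared fixtures: small synthetic configurations and dense-matrix oracles.
# The dense oracles rebuild the marginal covariance V = Z G Z' + R as an
# explicit N x N matrix and evaluate the Gaussian likelihood / penalized
# normal equations directly, independent of the package's low-rank path.

# A small, fast two-group configuration with white noise + random intercepts.
quick_config <- function(n1 = 8, n2 = 8, t_max = 10, by = 1,
                         knots = c(3, 5, 7), serial = "none",
                         beta = c(4, -0.3, 0.02), delta = c(0.3, -0.05, 0.002),
                         b_shared = 0.05 * (-1)^(seq_along(knots) + 1),
                         sigma2_u = 0.5, sigma2_omega = 0.2, ...) {
  sim_config(n_per_group = c(OSA = n1, CTR = n2),
             times = seq(0, t_max, by = by), knots = knots,
             covariates = FALSE, serial = serial,
             beta = beta, delta = delta, b_shared = b_shared,
             sigma2_u = sigma2_u, sigma2_omega = sigma2_omega, ...)
}

# Dense residual covariance R = blockdiag_i(sigma2_u J + Sigma_i).
dense_R <- function(data, serial, vc) {
  d <- data$data
  N <- nrow(d)
  R <- matrix(0, N, N)
  for (s in unique(d$subject)) {
    ii <- which(d$subject == s)
    tt <- d$time[ii]
    A <- matrix(vc[["sigma2_u"]], length(ii), length(ii)) +
      diag(vc[["sigma2_omega"]], length(ii))
    if (serial != "none" && vc[["sigma2_delta"]] > 0) {
      dd <- abs(outer(tt, tt, "-"))
      cor <- if (serial == "exponential") exp(-dd / vc[["tau"]]) else
        exp(-(dd / vc[["tau"]])^2)
      A <- A + vc[["sigma2_delta"]] * cor
    }
    R[ii, ii] <- A
  }
  R
}

# Dense -2 log-likelihood (ML or REML) with beta profiled by GLS.
dense_m2ll <- function(data, spec, serial, vc, method = "ML") {
  des <- build_design(data, spec)
  X <- des$X; Z <- des$Z
  y <- data$data$response
  N <- length(y)
  gv <- if (ncol(Z) > 0) {
    nb <- max(des$spline_block)
    bn <- if (nb == 1) "sigma2_b" else paste0("sigma2_b", seq_len(nb))
    unname(vc[bn][des$spline_block])
  } else numeric(0)
  V <- dense_R(data, serial, vc)
  if (ncol(Z) > 0) V <- V + Z %*% (gv * t(Z))
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  quad <- drop(t(r) %*% Vi %*% r)
  ld <- as.numeric(determinant(V)$modulus)
  if (method == "ML") {
    N * log(2 * pi) + ld + quad
  } else {
    (N - ncol(X)) * log(2 * pi) + ld +
      as.numeric(determinant(XtVi %*% X)$modulus) + quad
  }
}

# Dense penalized-normal-equation solve for (beta, b) and the E_p trace.
dense_blup <- function(fit) {
  data <- fit$data
  X <- fit$design$X; Z <- fit$design$Z
  y <- data$data$response
  R <- dense_R(data, fit$cov$serial, fit$varcomp)
  Ri <- solve(R)
  C <- cbind(X, Z)
  gv <- spcurve:::.gvec(fit$design, fit$varcomp)
  B <- diag(c(rep(0, ncol(X)), 1 / gv), ncol(C))
  A <- t(C) %*% Ri %*% C
  M <- A + B
  list(coef = drop(solve(M, t(C) %*% Ri %*% y)),
       ep = sum(diag(solve(M, A))))
}

# Tiny three-row single-subject data frame for I/O tests.
toy_df <- function() {
  data.frame(subject = "s1", group = "A", time = c(0, 0.5, 1),
             response = c(4.1, 4.2, 4.0))
}
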