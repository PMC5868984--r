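# Low-rank marginal likelihood machinery.
#
# Marginal covariance of the data is V = Z G Z' + R, with
#   R  = blockdiag_i( sigma2_u * J + Sigma_i ),   Sigma_i from serial_covariance()
#   G  = diag, one variance per spline block.
# Subject blocks are small (<= number of sampling points), so R factors
# cheaply; the spline part is low rank (q columns), so all solves against V
# use the Woodbury identity
#   V^{-1} = R^{-1} - R^{-1} Z (G^{-1} + Z'R^{-1}Z)^{-1} Z'R^{-1}
# and log|V| = log|R| + log|G| + log|G^{-1} + Z'R^{-1}Z|, without ever
# materializing the N x N matrix. Subjects sharing an identical time vector
# share one Cholesky factor of their R block.

# Split data/design into per-subject blocks with a time-signature id.
.make_blocks <- function(design, y, time) {
  subj <- design$subject
  idx <- split(seq_along(y), subj)
  sig <- vapply(idx, function(ii) paste(signif(time[ii], 12), collapse = ","), "")
  usig <- unique(sig)
  list(idx = idx, sig = match(sig, usig),
       times = lapply(idx[match(usig, sig)], function(ii) time[ii]),
       y = y, X = design$X, Z = design$Z)
}

# Variance-component vector layout for a given design + serial structure.
.vc_names <- function(design, serial) {
  nb <- if (ncol(design$Z) > 0L) max(design$spline_block) else 0L
  c("sigma2_u",
    if (nb == 1L) "sigma2_b" else if (nb > 1L) paste0("sigma2_b", seq_len(nb)),
    if (serial != "none") c("sigma2_delta", "tau"),
    "sigma2_omega")
}

# Accumulate cross-products against R^{-1}. Returns the sufficient pieces
# for the profile likelihood and the EBLUP system.
.whitened_crossprods <- function(blocks, serial, vc) {
  p <- ncol(blocks$X); q <- ncol(blocks$Z)
  d <- p + q + 1L
  CtRC <- matrix(0, d, d)
  logdetR <- 0
  nsig <- length(blocks$times)
  chols <- vector("list", nsig)
  for (s in seq_len(nsig)) {
    tt <- blocks$times[[s]]
    A <- diag(vc[["sigma2_omega"]], length(tt)) + vc[["sigma2_u"]]
    if (serial != "none" && vc[["sigma2_delta"]] > 0) {
      A <- A + vc[["sigma2_delta"]] * serial_corr(tt, serial, vc[["tau"]])
    }
    U <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    chols[[s]] <- U
  }
  for (i in seq_along(blocks$idx)) {
    ii <- blocks$idx[[i]]
    U <- chols[[blocks$sig[i]]]
    M <- cbind(blocks$X[ii, , drop = FALSE], blocks$Z[ii, , drop = FALSE],
               blocks$y[ii])
    S <- backsolve(U, M, transpose = TRUE)
    CtRC <- CtRC + crossprod(S)
    logdetR <- logdetR + 2 * sum(log(diag(U)))
  }
  list(CtRC = CtRC, logdetR = logdetR, p = p, q = q,
       N = length(blocks$y), chols = chols)
}

# Spline-variance vector per Z column.
.gvec <- function(design, vc) {
  if (ncol(design$Z) == 0L) return(numeric(0))
  nb <- max(design$spline_block)
  bnames <- if (nb == 1L) "sigma2_b" else paste0("sigma2_b", seq_len(nb))
  unname(vc[bnames][design$spline_block])
}

# Profile -2 log-likelihood (ML or REML) at variance components vc.
# Returns a list so the optimum's pieces can be reused; or NULL if the
# covariance is numerically indefinite at vc.
.profile_m2ll <- function(blocks, design, serial, vc, method) {
  cp <- .whitened_crossprods(blocks, serial, vc)
  if (is.null(cp)) return(NULL)
  p <- cp$p; q <- cp$q; N <- cp$N
  ix <- seq_len(p); iz <- p + seq_len(q); iy <- p + q + 1L
  Axx <- cp$CtRC[ix, ix, drop = FALSE]
  Xty <- cp$CtRC[ix, iy]
  yty <- cp$CtRC[iy, iy]
  logdetV <- cp$logdetR
  if (q > 0L) {
    gv <- .gvec(design, vc)
    Azz <- cp$CtRC[iz, iz, drop = FALSE]
    Azx <- cp$CtRC[iz, ix, drop = FALSE]
    Zty <- cp$CtRC[iz, iy]
    M <- Azz + diag(1 / gv, q)
    cM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(cM)) return(NULL)
    Minv_Azx <- backsolve(cM, backsolve(cM, Azx, transpose = TRUE))
    Minv_Zty <- backsolve(cM, backsolve(cM, Zty, transpose = TRUE))
    Sxx <- Axx - crossprod(Azx, Minv_Azx)
    Sxy <- Xty - crossprod(Azx, Minv_Zty)
    Syy <- yty - sum(Zty * Minv_Zty)
    logdetV <- logdetV + sum(log(gv)) + 2 * sum(log(diag(cM)))
  } else {
    Sxx <- Axx; Sxy <- Xty; Syy <- yty
  }
  cS <- tryCatch(chol(Sxx), error = function(e) NULL)
  if (is.null(cS)) return(NULL)
  beta <- backsolve(cS, backsolve(cS, Sxy, transpose = TRUE))
  quad <- Syy - sum(beta * Sxy)
  if (!is.finite(quad) || quad < 0) return(NULL)
  m2ll <- if (method == "ML") {
    N * log(2 * pi) + logdetV + quad
  } else {
    (N - p) * log(2 * pi) + logdetV + 2 * sum(log(diag(cS))) + quad
  }
  list(m2ll = m2ll, beta = drop(beta), quad = quad, logdetV = logdetV,
       cp = cp)
}

# Dense-oracle-checkable entry point: -2 log marginal (or restricted)
# likelihood at given variance components, with beta profiled out by GLS.
# Used internally by the optimizer and exposed for cross-checks.
.m2ll_at <- function(data, spec, cov, vc, method = "ML") {
  design <- build_design(data, spec)
  blocks <- .make_blocks(design, data$data$response, data$data$time)
  res <- .profile_m2ll(blocks, design, cov$serial, vc, method)
  if (is.null(res)) stop("covariance numerically indefinite at supplied components")
  res$m2ll
}
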