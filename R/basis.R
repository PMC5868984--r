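#' Quantile-based interior knot selection
#'
#' Places `K` interior knots at the j/(K+1) empirical quantiles
#' (j = 1, ..., K) of the *distinct* observed times, the standard automatic
#' placement for penalized-spline mixed models on densely sampled monitoring
#' data. The quantile definition is linear interpolation of order statistics
#' (`stats::quantile` type 7).
#'
#' @param times numeric vector of observed times.
#' @param K number of interior knots (default 9, matching a 24-hour recording
#'   sampled half-hourly).
#' @return Strictly increasing numeric vector of `K` knots, all strictly
#'   inside the observed time range.
#' @export
select_knots <- function(times, K = 9L) {
  if (K < 0L) stop("K must be non-negative")
  if (K == 0L) return(numeric(0))
  ut <- sort(unique(times[is.finite(times)]))
  if (length(ut) < K + 2L) {
    stop("knot selection needs at least K + 2 distinct times (have ",
         length(ut), ", need ", K + 2L, ")")
  }
  kn <- as.numeric(stats::quantile(ut, probs = seq_len(K) / (K + 1),
                                   type = 7, names = FALSE))
  if (any(diff(kn) <= 0)) {
    stop("tied quantiles: cannot place ", K, " strictly increasing knots")
  }
  if (kn[1L] <= ut[1L] || kn[K] >= ut[length(ut)]) {
    stop("knots must lie strictly inside the observed time range")
  }
  kn
}

#' Truncated power basis specification
#'
#' Degree-`p` truncated power basis with interior knots `knots`. The spline
#' side contributes one column per knot, `(t - kappa_k)_+^p`; the polynomial
#' columns `t, ..., t^p` are emitted by [tp_basis()] but the intercept lives
#' in the design layer (so group-specific intercepts never duplicate it).
#'
#' @param degree polynomial degree p, one of 1, 2, 3 (default 2: quadratic
#'   splines give continuously differentiable fits, needed for rate-of-change
#'   estimation).
#' @param knots strictly increasing numeric vector of interior knots (possibly
#'   empty), e.g. from [select_knots()].
#' @return Object of class `sp_basis` with fields `degree` and `knots`.
#' @export
basis_spec <- function(degree = 2L, knots = numeric(0)) {
  degree <- as.integer(degree)
  if (!degree %in% 1:3) stop("degree must be 1, 2 or 3")
  knots <- as.numeric(knots)
  if (length(knots) > 1L && any(diff(knots) <= 0)) {
    stop("knots must be strictly increasing")
  }
  if (anyNA(knots) || any(!is.finite(knots))) stop("knots must be finite")
  structure(list(degree = degree, knots = knots), class = "sp_basis")
}

#' @export
print.sp_basis <- function(x, ...) {
  cat(sprintf("Truncated power basis: degree %d, %d interior knot(s)\n",
              x$degree, length(x$knots)))
  if (length(x$knots)) cat("  knots:", paste(format(x$knots, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the truncated power basis
#'
#' Returns the matrix `[t, ..., t^p, (t-kappa_1)_+^p, ..., (t-kappa_K)_+^p]`;
#' `(x)_+ = max(x, 0)` sets each truncated column to zero below its knot.
#' The intercept column is *not* included (see [basis_spec()]).
#'
#' @param t numeric vector of evaluation times.
#' @param spec an `sp_basis` object.
#' @return Numeric matrix with `length(t)` rows and `degree + K` columns.
#' @export
tp_basis <- function(t, spec) {
  stopifnot(inherits(spec, "sp_basis"))
  p <- spec$degree
  K <- length(spec$knots)
  out <- matrix(0, nrow = length(t), ncol = p + K)
  for (j in seq_len(p)) out[, j] <- t^j
  for (k in seq_len(K)) out[, p + k] <- pmax(t - spec$knots[k], 0)^p
  colnames(out) <- c(paste0("t", ifelse(seq_len(p) == 1L, "", paste0("^", seq_len(p)))),
                     if (K) paste0("tp", seq_len(K)))
  out
}

#' First derivative of the truncated power basis
#'
#' Columns map as t^j -> j t^(j-1) and (t-kappa)_+^p -> p (t-kappa)_+^(p-1),
#' so that applying a fit's coefficients to this matrix yields the plug-in
#' derivative curve. Only the first derivative is supported.
#'
#' @inheritParams tp_basis
#' @param order derivative order; must be 1.
#' @return Numeric matrix with the same shape and column names as [tp_basis()].
#' @export
tp_basis_deriv <- function(t, spec, order = 1L) {
  stopifnot(inherits(spec, "sp_basis"))
  if (order != 1L) stop("only first-order derivatives are supported")
  p <- spec$degree
  K <- length(spec$knots)
  out <- matrix(0, nrow = length(t), ncol = p + K)
  for (j in seq_len(p)) out[, j] <- j * t^(j - 1)
  for (k in seq_len(K)) out[, p + k] <- p * pmax(t - spec$knots[k], 0)^(p - 1)
  colnames(out) <- colnames(tp_basis(numeric(0), spec))
  out
}

#' B-spline basis on the same knots (verification-only)
#'
#' A B-spline basis of equal degree and interior knots spans the same function
#' space as intercept + [tp_basis()]; this wrapper around
#' [splines::splineDesign()] exists so tests and users can verify basis
#' equivalence of unpenalized fits, not as an alternative fitting basis.
#'
#' @param t numeric vector of evaluation times.
#' @param knots strictly increasing interior knots.
#' @param degree polynomial degree.
#' @param boundary length-2 numeric boundary knots; defaults to `range(t)`.
#' @return Matrix with `length(knots) + degree + 1` columns.
#' @export
bspline_basis <- function(t, knots, degree = 2L, boundary = range(t)) {
  all_knots <- c(rep(boundary[1L], degree + 1L), knots,
                 rep(boundary[2L], degree + 1L))
  splines::splineDesign(all_knots, x = t, ord = degree + 1L,
                        outer.ok = FALSE)
}
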