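#' Group-comparison model structure
#'
#' The stepwise class of mean-response structures for comparing group-specific
#' smooth curves:
#'
#' * `"1.1"` common curve: intercept + polynomial + shared spline.
#' * `"1.2"` adds a group indicator (constant vertical shift between groups).
#' * `"1.3"` adds group-by-polynomial interactions (group difference follows a
#'   global degree-p polynomial trend).
#' * `"1.4"` as 1.3, but with a distinct spline coefficient vector per group
#'   (indicator-masked truncated columns), sharing one spline variance.
#' * `"1.5"` as 1.4 with a separate spline variance per group block.
#'
#' Structures 1.4 and 1.5 require exactly two groups.
#'
#' @param structure one of `"1.1"`, `"1.2"`, `"1.3"`, `"1.4"`, `"1.5"`.
#' @param basis an [basis_spec()] object.
#' @param covariates character vector of covariate column names entering the
#'   fixed effects linearly.
#' @param ref_group optional reference group level (indicator-coded levels are
#'   the non-reference ones, so e.g. `ref_group = "CTR"` reproduces a
#'   "1 = OSA, 0 = Control" coding); defaults to the dataset's first level.
#' @return Object of class `sp_model`.
#' @export
model_spec <- function(structure = c("1.1", "1.2", "1.3", "1.4", "1.5"),
                       basis, covariates = character(), ref_group = NULL) {
  structure_id <- match.arg(structure)
  stopifnot(inherits(basis, "sp_basis"))
  structure(list(structure = structure_id, basis = basis,
                 covariates = covariates, ref_group = ref_group),
            class = "sp_model")
}

#' Serial covariance specification
#'
#' Within-subject residual structure: a stationary serial process with
#' variance `sigma2_delta` and correlation decaying with lag (exponential
#' `exp(-|dt|/tau)` or Gaussian `exp(-(dt/tau)^2)`), plus white measurement
#' noise `sigma2_omega`. `serial = "none"` leaves white noise only. White
#' noise is always present, which keeps every per-subject covariance positive
#' definite even as the serial variance vanishes.
#'
#' @param serial `"none"`, `"exponential"` or `"gaussian"`.
#' @return Object of class `sp_cov`.
#' @export
cov_spec <- function(serial = c("none", "exponential", "gaussian")) {
  structure(list(serial = match.arg(serial)), class = "sp_cov")
}

#' Serial correlation matrix for one subject
#'
#' @param times observation times for a subject.
#' @param serial `"exponential"` or `"gaussian"`.
#' @param tau decay scale in hours (> 0).
#' @return Correlation matrix (unit diagonal).
#' @keywords internal
serial_corr <- function(times, serial, tau) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  d <- abs(outer(times, times, "-"))
  switch(serial,
         exponential = exp(-d / tau),
         gaussian = exp(-(d / tau)^2),
         stop("unknown serial structure: ", serial))
}

#' Per-subject residual covariance
#'
#' Builds `Sigma_i = sigma2_delta * Corr(times; tau) + sigma2_omega * I`,
#' the serial-plus-white-noise residual covariance for one subject. With
#' `serial = "none"` the serial term is dropped.
#'
#' @param times observation times for a subject.
#' @param spec an [cov_spec()] object.
#' @param sigma2_delta serial process variance (>= 0).
#' @param tau decay scale in hours (> 0 when serial is present).
#' @param sigma2_omega white-noise variance (> 0).
#' @return Symmetric positive-definite matrix with diagonal
#'   `sigma2_delta + sigma2_omega` (or `sigma2_omega` when serial is none).
#' @export
serial_covariance <- function(times, spec, sigma2_delta = 0, tau = 1,
                              sigma2_omega = 1) {
  stopifnot(inherits(spec, "sp_cov"))
  if (sigma2_omega <= 0) stop("sigma2_omega must be positive")
  if (sigma2_delta < 0) stop("sigma2_delta must be non-negative")
  n <- length(times)
  out <- diag(sigma2_omega, n)
  if (spec$serial != "none" && sigma2_delta > 0) {
    out <- out + sigma2_delta * serial_corr(times, spec$serial, tau)
  } else if (spec$serial != "none") {
    # validate tau even when the serial variance is zero
    if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  }
  out
}

#' Assemble fixed and random design matrices
#'
#' Realizes a model structure as the matrices of the mixed-model form
#' `y = X beta + Z_b b + Z_u u + eps`: `X` fixed effects (intercept, group
#' indicators, polynomial terms, group-by-polynomial interactions, covariates,
#' depending on structure), `Z_b` spline random effects (shared or
#' indicator-masked per group), and the subject index standing in for the 0/1
#' incidence matrix `Z_u`. `spline_block` records which `Z_b` columns share a
#' variance: a single block for structures 1.1-1.4, one block per group for
#' 1.5.
#'
#' @param data an [sp_data] object.
#' @param spec an [model_spec()] object.
#' @return List with elements `X`, `Z`, `spline_block` (integer vector, one
#'   entry per `Z` column), `subject` (factor), `groups`, `ref_group`,
#'   `nonref` (indicator-coded levels), and the originating `spec`.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(data, "sp_data"), inherits(spec, "sp_model"))
  d <- data$data
  lv <- data$groups
  ref <- spec$ref_group
  if (is.null(ref)) ref <- lv[1L]
  if (!ref %in% lv) stop("reference group '", ref, "' not among group levels")
  nonref <- setdiff(lv, ref)
  L <- length(lv)
  st <- spec$structure
  if (st %in% c("1.4", "1.5") && L != 2L) {
    stop("structure ", st, " supports exactly two groups (have ", L, ")")
  }
  if (st != "1.1" && L < 2L) {
    stop("structure ", st, " needs at least two groups")
  }
  miss <- setdiff(spec$covariates, names(d))
  if (length(miss)) stop("covariate(s) not in dataset: ", paste(miss, collapse = ", "))

  p <- spec$basis$degree
  t <- d$time
  P <- tp_basis(t, basis_spec(p, numeric(0)))   # polynomial columns only
  Tmat <- if (length(spec$basis$knots)) {
    tp_basis(t, spec$basis)[, p + seq_along(spec$basis$knots), drop = FALSE]
  } else {
    matrix(0, nrow(d), 0)
  }

  IND <- NULL
  if (st != "1.1") {
    IND <- vapply(nonref, function(g) as.numeric(d$group == g),
                  numeric(nrow(d)))
    IND <- matrix(IND, nrow = nrow(d),
                  dimnames = list(NULL, paste0("grp", nonref)))
  }

  Xparts <- list(`(Intercept)` = matrix(1, nrow(d), 1,
                                        dimnames = list(NULL, "(Intercept)")))
  if (st != "1.1") Xparts$group <- IND
  Xparts$poly <- P
  if (st %in% c("1.3", "1.4", "1.5")) {
    inter <- do.call(cbind, lapply(seq_len(ncol(IND)), function(i) {
      m <- IND[, i] * P
      colnames(m) <- paste0(colnames(IND)[i], ":", colnames(P))
      m
    }))
    Xparts$inter <- inter
  }
  if (length(spec$covariates)) {
    CV <- as.matrix(d[, spec$covariates, drop = FALSE])
    Xparts$covar <- CV
  }
  X <- do.call(cbind, Xparts)

  if (st %in% c("1.4", "1.5")) {
    # indicator-masked spline blocks, non-reference group first
    ord <- c(nonref, ref)
    Z <- do.call(cbind, lapply(ord, function(g) {
      m <- (d$group == g) * Tmat
      if (ncol(Tmat)) colnames(m) <- paste0(colnames(Tmat), ".", g)
      m
    }))
    spline_block <- if (st == "1.5") rep(seq_along(ord), each = ncol(Tmat))
                    else rep(1L, ncol(Z))
  } else {
    Z <- Tmat
    spline_block <- rep(1L, ncol(Z))
  }

  list(X = X, Z = Z, spline_block = spline_block,
       subject = factor(d$subject, levels = unique(d$subject)),
       groups = lv, ref_group = ref, nonref = nonref, spec = spec)
}

#' Design rows for prediction on a time grid
#'
#' Builds the fixed and spline design rows for a single group evaluated on a
#' grid, with covariates held at reference values (zero by default), and the
#' corresponding first-derivative rows.
#'
#' @param design a list from [build_design()].
#' @param grid numeric vector of times.
#' @param group group level to evaluate.
#' @param covariate_values named numeric vector of reference covariate values;
#'   missing names default to zero.
#' @param derivative logical; evaluate the derivative basis instead.
#' @return List with matrices `X` and `Z` (rows = grid points, columns aligned
#'   with the fitted design).
#' @keywords internal
grid_design <- function(design, grid, group, covariate_values = NULL,
                        derivative = FALSE) {
  spec <- design$spec
  st <- spec$structure
  if (!group %in% design$groups) stop("unknown group label: ", group)
  p <- spec$basis$degree
  polyspec <- basis_spec(p, numeric(0))
  P <- if (derivative) tp_basis_deriv(grid, polyspec) else tp_basis(grid, polyspec)
  Tm <- if (length(spec$basis$knots)) {
    B <- if (derivative) tp_basis_deriv(grid, spec$basis) else tp_basis(grid, spec$basis)
    B[, p + seq_along(spec$basis$knots), drop = FALSE]
  } else matrix(0, length(grid), 0)

  one <- if (derivative) 0 else 1
  Xparts <- list(matrix(one, length(grid), 1))
  if (st != "1.1") {
    indvals <- as.numeric(design$nonref == group)
    IND <- matrix(rep(indvals, each = length(grid)) * one,
                  nrow = length(grid))
    Xparts <- c(Xparts, list(IND))
  }
  Xparts <- c(Xparts, list(P))
  if (st %in% c("1.3", "1.4", "1.5")) {
    indvals <- as.numeric(design$nonref == group)
    inter <- do.call(cbind, lapply(seq_along(indvals), function(i) indvals[i] * P))
    Xparts <- c(Xparts, list(inter))
  }
  if (length(spec$covariates)) {
    cv <- stats::setNames(rep(0, length(spec$covariates)), spec$covariates)
    if (!is.null(covariate_values)) {
      cv[names(covariate_values)] <- covariate_values
    }
    CV <- matrix(rep(cv, each = length(grid)) * one, nrow = length(grid))
    Xparts <- c(Xparts, list(CV))
  }
  X <- do.call(cbind, Xparts)
  colnames(X) <- colnames(design$X)

  if (st %in% c("1.4", "1.5")) {
    ord <- c(design$nonref, design$ref_group)
    Z <- do.call(cbind, lapply(ord, function(g) {
      (g == group) * Tm
    }))
  } else {
    Z <- Tm
  }
  list(X = X, Z = Z)
}
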