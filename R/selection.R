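# Fit statistics, nested tests and stepwise selection.

#' Effective number of parameters
#'
#' Trace of the influence operator of the penalized fit,
#' `E_p = tr( C (C'R^{-1}C + B)^{-1} C' R^{-1} )` with `C = [X Z_b]` and `B`
#' penalizing only the spline blocks. It interpolates between the fixed
#' column count (spline variance -> 0) and the full column count of `C`
#' (no penalization), and is the spline-complexity penalty entering the
#' adjusted AIC.
#'
#' @param fit an `sp_fit` object.
#' @return Scalar effective number of parameters.
#' @export
effective_params <- function(fit) {
  stopifnot(inherits(fit, "sp_fit"))
  fit$ep
}

#' Adjusted and marginal AIC arithmetic
#'
#' `marginal_aic` is the conventional mixed-model AIC `-2LL + 2m`, with `m`
#' counting fixed-effect columns plus free variance components (the serial
#' decay scale counts as a component). `adjusted_aic` replaces the count by
#' the effective number of parameters: `-2LL + 2 E_p`.
#'
#' @param m2ll -2 log-likelihood.
#' @param m counted parameters.
#' @param ep effective number of parameters.
#' @return Scalar criterion value.
#' @export
marginal_aic <- function(m2ll, m) m2ll + 2 * m

#' @rdname marginal_aic
#' @export
adjusted_aic <- function(m2ll, ep) m2ll + 2 * ep

#' Fit statistics for model selection
#'
#' Collects `-2LL`, the counted-parameter AIC and BIC, the effective number
#' of parameters `E_p` and the adjusted AIC `-2LL + 2 E_p` for one fit. The
#' identities `AIC - (-2LL) = 2m` and `AIC_adj - (-2LL) = 2 E_p` hold exactly
#' by construction.
#'
#' @param fit an `sp_fit` object.
#' @param bic_n `"nobs"` (default) uses the total observation count in
#'   `log(N)`; `"nsubj"` uses the subject count.
#' @return Object of class `sp_fit_stats`: list with `m2ll`, `m`, `aic`,
#'   `bic`, `ep`, `aic_adj`.
#' @export
fit_stats <- function(fit, bic_n = c("nobs", "nsubj")) {
  stopifnot(inherits(fit, "sp_fit"))
  bic_n <- match.arg(bic_n)
  m <- fit$p_fixed + fit$n_varcomp
  N <- if (bic_n == "nobs") fit$N else length(fit$u)
  ep <- effective_params(fit)
  structure(list(m2ll = fit$m2ll, m = m,
                 aic = marginal_aic(fit$m2ll, m),
                 bic = fit$m2ll + m * log(N),
                 ep = ep,
                 aic_adj = adjusted_aic(fit$m2ll, ep)),
            class = "sp_fit_stats")
}

#' @export
print.sp_fit_stats <- function(x, ...) {
  cat(sprintf("-2LL %.4f | AIC %.4f (m = %d) | BIC %.4f | E_p %.4f | AIC_adj %.4f\n",
              x$m2ll, x$aic, x$m, x$bic, x$ep, x$aic_adj))
  invisible(x)
}

#' Likelihood-ratio test for nested fixed-effect structures
#'
#' Compares two ML fits whose fixed effects are nested and whose random
#' structure is identical; the statistic `-2LL_0 - (-2LL_1)` is referred to a
#' chi-square with df equal to the difference in fixed-effect column counts.
#' REML fits with differing fixed effects are refused, since restricted
#' likelihoods of different fixed-effect spaces are not comparable.
#'
#' @param fit0,fit1 null and alternative `sp_fit` objects (both ML).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(fit0, fit1) {
  stopifnot(inherits(fit0, "sp_fit"), inherits(fit1, "sp_fit"))
  if (fit0$method != "ML" || fit1$method != "ML") {
    if (fit0$p_fixed != fit1$p_fixed ||
        !identical(colnames(fit0$design$X), colnames(fit1$design$X))) {
      stop("fixed-effect structures differing under REML cannot be compared ",
           "by the likelihood-ratio test; refit with method = \"ML\"")
    }
  }
  if (!identical(fit0$cov$serial, fit1$cov$serial)) {
    stop("fits must share the same serial covariance structure")
  }
  df <- fit1$p_fixed - fit0$p_fixed
  if (df < 0L) stop("fit0 must be the smaller (null) model")
  stat <- fit0$m2ll - fit1$m2ll
  if (stat < 0) {
    if (stat < -1e-6) warning("negative LRT statistic (", format(stat),
                              "); models may not be nested or a fit did not converge")
    stat <- max(stat, 0)
  }
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Approximate F test using residual degrees of freedom
#'
#' Nested-model F test in which effective numbers of parameters stand in for
#' parameter counts: `F = [(RSS0 - RSS1)/(E1 - E0)] / [RSS1/(N - E1)]`, with
#' residual sums of squares weighted by the alternative fit's estimated
#' residual covariance (so the test reduces exactly to the classical OLS F
#' test when both models are spline-free with iid errors).
#'
#' @param fit0,fit1 null and alternative `sp_fit` objects.
#' @return List with `statistic`, `df1`, `df2`, `p_value`.
#' @export
approx_f_test <- function(fit0, fit1) {
  stopifnot(inherits(fit0, "sp_fit"), inherits(fit1, "sp_fit"))
  e0 <- effective_params(fit0); e1 <- effective_params(fit1)
  if (e1 <= e0 + 1e-8) {
    if (abs(e1 - e0) < 1e-8 && abs(fit0$m2ll - fit1$m2ll) < 1e-8) {
      return(list(statistic = 0, df1 = 0, df2 = fit1$N - e1, p_value = 1))
    }
    stop("alternative model must have larger effective df than the null")
  }
  rss0 <- .weighted_rss(fit0, fit1)
  rss1 <- .weighted_rss(fit1, fit1)
  df1 <- e1 - e0
  df2 <- fit1$N - e1
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  if (f < 0) f <- 0
  list(statistic = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Residual sum of squares of `fit`, weighted by `wfit`'s estimated
# subject-intercept-plus-serial residual covariance.
.weighted_rss <- function(fit, wfit) {
  y <- fit$data$data$response
  r <- y - drop(cbind(fit$design$X, fit$design$Z) %*% c(fit$beta, fit$b))
  blocks <- .make_blocks(wfit$design, wfit$data$data$response,
                         wfit$data$data$time)
  cpw <- .whitened_crossprods(blocks, wfit$cov$serial, wfit$varcomp)
  total <- 0
  for (i in seq_along(blocks$idx)) {
    ii <- blocks$idx[[i]]
    U <- cpw$chols[[blocks$sig[i]]]
    s <- backsolve(U, r[ii], transpose = TRUE)
    total <- total + sum(s^2)
  }
  total
}

#' Stepwise selection over the group-comparison structures
#'
#' Fits structures 1.1-1.5 with a common basis and serial structure, tabulates
#' `-2LL`, AIC, BIC, `E_p` and adjusted AIC per structure, and selects the
#' criterion minimizer among the structures that fit successfully. Fits whose
#' variance components sit at the zero boundary are flagged as questionable
#' (but not excluded).
#'
#' @param data an [sp_data] object.
#' @param basis an [basis_spec()] object shared by all structures.
#' @param cov an [cov_spec()] object.
#' @param covariates covariate names entering every structure.
#' @param ref_group reference group level.
#' @param criterion `"aic_adj"` (default), `"aic"` or `"bic"`.
#' @param method `"ML"` (default) or `"REML"`.
#' @param structures subset of the five structures to evaluate.
#' @return Object of class `sp_selection`: list with `table` (one row per
#'   structure), `chosen`, `criterion`, `fits` (named list of `sp_fit`s),
#'   `errors` (messages for failed structures).
#' @export
stepwise_group_selection <- function(data, basis, cov = cov_spec("none"),
                                     covariates = character(),
                                     ref_group = NULL,
                                     criterion = c("aic_adj", "aic", "bic"),
                                     method = "ML",
                                     structures = c("1.1", "1.2", "1.3",
                                                    "1.4", "1.5")) {
  criterion <- match.arg(criterion)
  fits <- list(); errors <- character()
  for (st in structures) {
    spec <- model_spec(st, basis, covariates, ref_group)
    f <- tryCatch(withCallingHandlers(
      sp_fit(data, spec, cov, method = method),
      warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(f, "error")) errors[st] <- conditionMessage(f) else fits[[st]] <- f
  }
  if (!length(fits)) stop("every structure failed to fit")
  tab <- do.call(rbind, lapply(names(fits), function(st) {
    s <- fit_stats(fits[[st]])
    data.frame(structure = st, m2ll = s$m2ll, aic = s$aic, bic = s$bic,
               m = s$m, ep = s$ep, aic_adj = s$aic_adj,
               boundary = any(fits[[st]]$convergence$boundary))
  }))
  rownames(tab) <- NULL
  chosen <- tab$structure[.parsimonious_min(tab[[criterion]])]
  structure(list(table = tab, chosen = chosen, criterion = criterion,
                 fits = fits, errors = errors),
            class = "sp_selection")
}

# Index of the criterion minimizer, breaking numerical ties (within tol on
# the -2LL scale) in favour of the earlier = simpler candidate: structures
# whose extra terms are estimated away (e.g. a spline variance at zero)
# produce criterion values identical up to optimizer noise, and the
# parsimonious member of such a tie is the defensible selection.
.parsimonious_min <- function(crit, tol = 1e-4) {
  which(crit <= min(crit) + tol)[1L]
}

#' @export
print.sp_selection <- function(x, ...) {
  cat("Stepwise structure selection by", x$criterion, "\n")
  print(x$table, digits = 8)
  if (length(x$errors)) {
    cat("Failed structures:", paste(names(x$errors), collapse = ", "), "\n")
  }
  cat("Chosen:", x$chosen, "\n")
  invisible(x)
}

#' Covariance model selection for a fixed mean structure
#'
#' Holds the mean structure fixed and compares candidate serial covariance
#' models (subject random intercepts only, exponential, Gaussian) by
#' adjusted AIC.
#'
#' @inheritParams stepwise_group_selection
#' @param structure the group-comparison structure to hold fixed (default
#'   `"1.3"`).
#' @param serial_candidates subset of `c("none", "exponential", "gaussian")`.
#' @return Object of class `sp_selection` with one table row per candidate
#'   (column `serial` instead of `structure`).
#' @export
covariance_selection <- function(data, basis, structure = "1.3",
                                 covariates = character(), ref_group = NULL,
                                 serial_candidates = c("none", "exponential",
                                                       "gaussian"),
                                 criterion = c("aic_adj", "aic", "bic"),
                                 method = "ML") {
  criterion <- match.arg(criterion)
  serial_candidates <- match.arg(serial_candidates, several.ok = TRUE)
  spec <- model_spec(structure, basis, covariates, ref_group)
  fits <- list(); errors <- character()
  for (sc in serial_candidates) {
    f <- tryCatch(withCallingHandlers(
      sp_fit(data, spec, cov_spec(sc), method = method),
      warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(f, "error")) errors[sc] <- conditionMessage(f) else fits[[sc]] <- f
  }
  if (!length(fits)) stop("every covariance candidate failed to fit")
  tab <- do.call(rbind, lapply(names(fits), function(sc) {
    s <- fit_stats(fits[[sc]])
    data.frame(serial = sc, m2ll = s$m2ll, aic = s$aic, bic = s$bic,
               m = s$m, ep = s$ep, aic_adj = s$aic_adj,
               boundary = any(fits[[sc]]$convergence$boundary))
  }))
  rownames(tab) <- NULL
  chosen <- tab$serial[.parsimonious_min(tab[[criterion]])]
  structure(list(table = tab, chosen = chosen, criterion = criterion,
                 fits = fits, errors = errors),
            class = "sp_selection")
}
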