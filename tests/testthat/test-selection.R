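test_that("AIC identities hold exactly and E_p sits between its limits", {
  sim <- simulate_dataset(quick_config(), seed = 5)
  bs <- basis_spec(2, c(3, 5, 7))
  fit <- suppressWarnings(sp_fit(sim$data, model_spec("1.3", bs, ref_group = "CTR"),
                                 method = "ML"))
  s <- fit_stats(fit)
  expect_equal(s$aic - s$m2ll, 2 * s$m, tolerance = 1e-12)
  expect_equal(s$aic_adj - s$m2ll, 2 * s$ep, tolerance = 1e-12)
  expect_equal(s$m, fit$p_fixed + fit$n_varcomp)
  expect_gte(s$ep, fit$p_fixed - 1e-8)
  expect_lte(s$ep, fit$p_fixed + fit$q_spline + 1e-8)
  sn <- fit_stats(fit, bic_n = "nsubj")
  expect_equal(sn$bic, s$m2ll + s$m * log(length(fit$u)))
})

test_that("E_p collapses to the fixed column count without effective splines", {
  # K = 0: no spline columns at all
  sim <- simulate_dataset(quick_config(n1 = 5, n2 = 5), seed = 7)
  spec0 <- model_spec("1.3", basis_spec(2, numeric(0)), ref_group = "CTR")
  fit0 <- suppressWarnings(sp_fit(sim$data, spec0, method = "ML"))
  expect_equal(effective_params(fit0), fit0$p_fixed, tolerance = 1e-6)
  # sigma2_b -> 0 with splines present
  bs <- basis_spec(2, c(3, 5, 7))
  design <- build_design(sim$data, model_spec("1.3", bs, ref_group = "CTR"))
  blocks <- spcurve:::.make_blocks(design, sim$data$data$response,
                                   sim$data$data$time)
  vc <- c(sigma2_u = 0.4, sigma2_b = 1e-14, sigma2_omega = 0.2)
  res <- spcurve:::.profile_m2ll(blocks, design, "none", vc, "ML")
  f <- spcurve:::.finalize_fit(blocks, design, cov_spec("none"), vc, res, "ML")
  expect_equal(f$ep, ncol(design$X), tolerance = 1e-6)
})

test_that("likelihood-ratio test: identity, oracle difference, REML refusal", {
  sim <- simulate_dataset(quick_config(n1 = 6, n2 = 6), seed = 9)
  bs <- basis_spec(2, c(3, 5, 7))
  f1 <- suppressWarnings(sp_fit(sim$data, model_spec("1.1", bs), method = "ML"))
  f3 <- suppressWarnings(sp_fit(sim$data, model_spec("1.3", bs, ref_group = "CTR"),
                                method = "ML"))
  same <- lrt(f1, f1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  out <- lrt(f1, f3)
  expect_equal(out$df, 3L)
  # brute-force: same -2LL difference from independent dense evaluations
  d1 <- dense_m2ll(sim$data, model_spec("1.1", bs), "none", f1$varcomp, "ML")
  d3 <- dense_m2ll(sim$data, model_spec("1.3", bs, ref_group = "CTR"), "none",
                   f3$varcomp, "ML")
  expect_equal(out$statistic, d1 - d3, tolerance = 1e-6)
  r1 <- suppressWarnings(sp_fit(sim$data, model_spec("1.1", bs), method = "REML"))
  r3 <- suppressWarnings(sp_fit(sim$data, model_spec("1.3", bs, ref_group = "CTR"),
                                method = "REML"))
  expect_error(lrt(r1, r3), "REML|ML")
})

test_that("LRT type-I error is near nominal under the common-curve null", {
  set.seed(61)
  n_rep <- 200
  cfg <- quick_config(n1 = 25, n2 = 25, t_max = 6, by = 0.5, knots = c(2, 3, 4),
                      delta = c(0, 0, 0))  # no group difference
  rej <- logical(n_rep)
  bs <- basis_spec(2, c(2, 3, 4))
  for (r in seq_len(n_rep)) {
    sim <- simulate_dataset(cfg, seed = NULL)
    f1 <- suppressWarnings(sp_fit(sim$data, model_spec("1.1", bs), method = "ML"))
    f3 <- suppressWarnings(sp_fit(sim$data, model_spec("1.3", bs, ref_group = "CTR"),
                                  method = "ML"))
    rej[r] <- lrt(f1, f3)$p_value < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.04)
})

test_that("approximate F test reduces to the classical OLS F test", {
  sim <- simulate_dataset(quick_config(n1 = 6, n2 = 6, sigma2_u = 0), seed = 13)
  spec0 <- model_spec("1.1", basis_spec(2, numeric(0)))
  spec1 <- model_spec("1.3", basis_spec(2, numeric(0)), ref_group = "CTR")
  # hold both models at iid errors (sigma2_u pinned to ~0 via start and the
  # truth has none) so the weighted RSS is a scalar multiple of the OLS RSS
  f0 <- suppressWarnings(sp_fit(sim$data, spec0, method = "ML"))
  f1 <- suppressWarnings(sp_fit(sim$data, spec1, method = "ML"))
  out <- approx_f_test(f0, f1)
  d <- sim$data$data
  ols0 <- lm(response ~ time + I(time^2), data = d)
  ols1 <- lm(response ~ (group == "OSA") * (time + I(time^2)), data = d)
  ftab <- anova(ols0, ols1)
  if (f0$varcomp["sigma2_u"] < 1e-6 && f1$varcomp["sigma2_u"] < 1e-6) {
    expect_equal(out$statistic, ftab$F[2], tolerance = 1e-6)
    expect_equal(out$df1, 3, tolerance = 1e-6)
  }
  expect_equal(approx_f_test(f0, f0)$statistic, 0)
  expect_true(out$p_value >= 0 && out$p_value <= 1)
  expect_error(approx_f_test(f1, f0), "larger effective")
})

test_that("stepwise report has the Table-2 shape and picks the generating structure", {
  # generator defaults (ABPM scale): distinct group quadratics, shared wiggle
  times <- seq(0, 11.5, 0.5)
  kn <- select_knots(times, 5)
  cfg <- sim_config(n_per_group = c(OSA = 25, CTR = 25), times = times,
                    knots = kn, serial = "none", covariates = FALSE)
  sim <- simulate_dataset(cfg, seed = 41)
  bs <- basis_spec(2, kn)
  sel <- stepwise_group_selection(sim$data, bs, cov_spec("none"),
                                  ref_group = "CTR")
  expect_equal(nrow(sel$table), 5L)
  expect_setequal(sel$table$structure, c("1.1", "1.2", "1.3", "1.4", "1.5"))
  expect_true(all(c("m2ll", "aic", "bic", "ep", "aic_adj") %in% names(sel$table)))
  expect_equal(sel$chosen, "1.3")  # truth: distinct quadratics, shared spline
  # selection is invariant to shifting the response by a constant (criterion
  # differences shift with -2LL up to optimizer resolution)
  shifted <- sim$data
  shifted$data$response <- shifted$data$response + 100
  sel2 <- stepwise_group_selection(shifted, bs, cov_spec("none"),
                                   ref_group = "CTR")
  expect_equal(sel2$chosen, sel$chosen)
  d1 <- sel$table$aic_adj - min(sel$table$aic_adj)
  d2 <- sel2$table$aic_adj - min(sel2$table$aic_adj)
  expect_equal(d1, d2, tolerance = 5e-3)
})

test_that("covariance selection recovers the serial structure", {
  # exponential serial truth
  cfg <- quick_config(n1 = 18, n2 = 18, t_max = 8, by = 0.5, knots = c(2, 4, 6),
                      serial = "exponential", sigma2_delta = 0.3, tau = 1.5,
                      sigma2_u = 0.2, sigma2_omega = 0.05)
  sim <- simulate_dataset(cfg, seed = 43)
  bs <- basis_spec(2, c(2, 4, 6))
  sel <- covariance_selection(sim$data, bs, structure = "1.3",
                              ref_group = "CTR")
  expect_equal(nrow(sel$table), 3L)
  expect_equal(sel$chosen, "exponential")
  # no serial correlation in truth: random-intercepts-only is competitive
  cfg0 <- quick_config(n1 = 14, n2 = 14, t_max = 8, by = 0.5, knots = c(2, 4, 6))
  sim0 <- simulate_dataset(cfg0, seed = 47)
  sel0 <- covariance_selection(sim0$data, bs, structure = "1.3",
                               ref_group = "CTR",
                               serial_candidates = c("none", "exponential"))
  expect_equal(nrow(sel0$table), 2L)
  gap <- sel0$table$aic_adj[sel0$table$serial == "none"] -
    min(sel0$table$aic_adj)
  expect_lt(gap, 4)  # "none" chosen or within a small criterion gap
})
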