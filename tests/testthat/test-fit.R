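test_that("low-rank profile likelihood equals the dense multivariate-normal oracle", {
  cfg <- quick_config(n1 = 2, n2 = 2, t_max = 4, by = 1, knots = c(1.3, 2.6),
                      serial = "exponential", sigma2_delta = 0.3, tau = 1.5)
  d <- simulate_dataset(cfg, seed = 5)$data
  spec <- model_spec("1.3", basis_spec(2, c(1.3, 2.6)), ref_group = "CTR")
  vc <- c(sigma2_u = 0.4, sigma2_b = 0.1, sigma2_delta = 0.25, tau = 1.2,
          sigma2_omega = 0.3)
  for (method in c("ML", "REML")) {
    expect_equal(spcurve:::.m2ll_at(d, spec, cov_spec("exponential"), vc, method),
                 dense_m2ll(d, spec, "exponential", vc, method),
                 tolerance = 1e-8)
  }
  # Gaussian serial correlation and a two-block (1.5) structure
  spec5 <- model_spec("1.5", basis_spec(2, c(1.3, 2.6)), ref_group = "CTR")
  vc5 <- c(sigma2_u = 0.4, sigma2_b1 = 0.12, sigma2_b2 = 0.05,
           sigma2_delta = 0.25, tau = 1.2, sigma2_omega = 0.3)
  expect_equal(spcurve:::.m2ll_at(d, spec5, cov_spec("gaussian"), vc5, "ML"),
               dense_m2ll(d, spec5, "gaussian", vc5, "ML"),
               tolerance = 1e-8)
})

test_that("noiseless data recover the generating fixed effects", {
  cfg <- quick_config(n1 = 6, n2 = 6, b_shared = c(0, 0, 0),
                      sigma2_u = 0, sigma2_omega = 1e-6)
  sim <- simulate_dataset(cfg, seed = 2)
  bs <- basis_spec(2, c(3, 5, 7))
  fit <- suppressWarnings(sp_fit(sim$data, model_spec("1.3", bs, ref_group = "CTR"),
                                 method = "ML"))
  truth <- c(4, 0.3, -0.3, 0.02, -0.05, 0.002)  # intercept, grp, t, t2, grp:t, grp:t2
  est <- unname(fit$beta[c("(Intercept)", "grpOSA", "t", "t^2",
                           "grpOSA:t", "grpOSA:t^2")])
  expect_equal(est, truth[c(1, 2, 3, 4, 5, 6)], tolerance = 1e-4)
})

test_that("EBLUPs solve the penalized normal equations (dense oracle)", {
  cfg <- quick_config()
  sim <- simulate_dataset(cfg, seed = 5)
  bs <- basis_spec(2, c(3, 5, 7))
  fit <- suppressWarnings(sp_fit(sim$data, model_spec("1.3", bs, ref_group = "CTR"),
                                 method = "ML"))
  oracle <- dense_blup(fit)
  expect_equal(unname(c(fit$beta, fit$b)), unname(oracle$coef), tolerance = 1e-8)
  expect_equal(fit$ep, oracle$ep, tolerance = 1e-8)
  co <- eblup_coefficients(fit)
  expect_named(co, c("beta", "b", "u"))
  expect_length(co$u, 16L)
})

test_that("first-order conditions: residuals orthogonal to unpenalized columns", {
  cfg <- quick_config(n1 = 5, n2 = 5)
  sim <- simulate_dataset(cfg, seed = 11)
  bs <- basis_spec(2, c(3, 5, 7))
  fit <- suppressWarnings(sp_fit(sim$data, model_spec("1.2", bs, ref_group = "CTR"),
                                 method = "ML"))
  y <- sim$data$data$response
  r <- y - drop(cbind(fit$design$X, fit$design$Z) %*% c(fit$beta, fit$b))
  Ri <- solve(dense_R(sim$data, "none", fit$varcomp))
  # X' R^{-1} (y - C coef) = 0 at the penalized optimum; with R = sigma^2 I
  # this is plain residual orthogonality
  expect_lt(max(abs(crossprod(fit$design$X, Ri %*% r))), 1e-6)

  # as sigma2_b -> infinity the penalty vanishes: coefficients approach the
  # unpenalized GLS solve on [X Z]
  vc_inf <- fit$varcomp
  vc_inf["sigma2_b"] <- 1e10
  blocks <- spcurve:::.make_blocks(fit$design, y, sim$data$data$time)
  res <- spcurve:::.profile_m2ll(blocks, fit$design, "none", vc_inf, "ML")
  fit2 <- spcurve:::.finalize_fit(blocks, fit$design, cov_spec("none"),
                                  vc_inf, res, "ML")
  C <- cbind(fit$design$X, fit$design$Z)
  Ri2 <- solve(dense_R(sim$data, "none", vc_inf))
  gls <- solve(t(C) %*% Ri2 %*% C, t(C) %*% Ri2 %*% y)
  expect_equal(unname(c(fit2$beta, fit2$b)), unname(drop(gls)),
               tolerance = 1e-5)
})

test_that("ML -2LL is non-increasing along the nested structure chain", {
  cfg <- quick_config(n1 = 6, n2 = 6)
  sim <- simulate_dataset(cfg, seed = 13)
  bs <- basis_spec(2, c(3, 5, 7))
  m2 <- vapply(c("1.1", "1.2", "1.3"), function(st) {
    suppressWarnings(sp_fit(sim$data, model_spec(st, bs, ref_group = "CTR"),
                            method = "ML"))$m2ll
  }, numeric(1))
  expect_true(all(diff(m2) <= 1e-6))
})

test_that("boundary variance components raise the questionable-fit warning", {
  cfg <- quick_config(n1 = 6, n2 = 6, b_shared = c(0, 0, 0))  # no true wiggle
  sim <- simulate_dataset(cfg, seed = 21)
  bs <- basis_spec(2, c(3, 5, 7))
  expect_warning(
    fit <- sp_fit(sim$data, model_spec("1.1", bs), method = "ML"),
    "boundary")
  expect_true(any(fit$convergence$boundary))
})

test_that("optimized -2LL agrees with an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  cfg <- quick_config(n1 = 10, n2 = 10, b_shared = c(0.6, -0.9, 0.7),
                      sigma2_u = 0.3, sigma2_omega = 0.1)
  sim <- simulate_dataset(cfg, seed = 17)
  bs <- basis_spec(2, c(3, 5, 7))
  fit <- sp_fit(sim$data, model_spec("1.1", bs), method = "ML")
  dd <- sim$data$data
  Zs <- tp_basis(dd$time, bs)[, 3:5]
  dd$Zs1 <- Zs[, 1]; dd$Zs2 <- Zs[, 2]; dd$Zs3 <- Zs[, 3]
  dd$all <- factor(rep(1, nrow(dd)))
  lm1 <- nlme::lme(response ~ time + I(time^2), data = dd,
                   random = list(all = nlme::pdIdent(~ Zs1 + Zs2 + Zs3 - 1),
                                 subject = nlme::pdIdent(~1)),
                   method = "ML", control = nlme::lmeControl(opt = "optim"))
  m2_nlme <- -2 * as.numeric(stats::logLik(lm1))
  # same optimum to numerical-optimizer resolution, never worse
  expect_lt(fit$m2ll, m2_nlme + 1e-3)
  expect_equal(fit$m2ll, m2_nlme, tolerance = 1e-4)
  expect_equal(unname(fit$beta), unname(nlme::fixef(lm1)), tolerance = 1e-3)
})

test_that("REML and ML variance estimates converge together as subjects grow", {
  gaps <- vapply(c(6L, 24L), function(n) {
    cfg <- quick_config(n1 = n, n2 = n, b_shared = c(0, 0, 0))
    sim <- simulate_dataset(cfg, seed = 31)
    bs <- basis_spec(2, c(3, 5, 7))
    spec <- model_spec("1.2", bs, ref_group = "CTR")
    ml <- suppressWarnings(sp_fit(sim$data, spec, method = "ML"))
    rl <- suppressWarnings(sp_fit(sim$data, spec, method = "REML"))
    abs(ml$varcomp["sigma2_u"] - rl$varcomp["sigma2_u"]) /
      rl$varcomp["sigma2_u"]
  }, numeric(1))
  expect_lt(gaps[2], gaps[1])
})
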