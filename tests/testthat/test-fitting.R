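# Regression toolbox: breakpoint fit, polynomial smoother, growth-law fit,
# f_b0 estimation and the linearity diagnostic.

test_that("saturated fit recovers exact piecewise data and its degenerate
           shapes", {
  lam <- sort(unique(c(seq(0.05, 0.8, length.out = 11), 0.25)))
  eta <- 0.06 - 0.2 * pmin(lam, 0.25)
  fit <- saturated_linear_fit(data.frame(growth_rate_per_h = lam,
                                         degradation_rate_per_h = eta))
  expect_equal(fit$slope, -0.2, tolerance = 1e-10)
  expect_equal(fit$breakpoint, 0.25, tolerance = 1e-10)
  expect_equal(fit$plateau, 0.01, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-20)
  # constant data: zero slope, plateau at the mean
  cfit <- saturated_linear_fit(x = 1:6, y = rep(2, 6))
  expect_equal(cfit$slope, 0)
  expect_equal(cfit$plateau, 2)
  # strictly linear data: breakpoint at the right edge
  lfit <- saturated_linear_fit(x = 1:8, y = 3 + 2 * (1:8))
  expect_equal(lfit$breakpoint, 8)
  expect_equal(lfit$slope, 2, tolerance = 1e-10)
  expect_lt(lfit$rss, 1e-20)
  expect_error(saturated_linear_fit(x = 1:3, y = 1:3), "4 points")
})

test_that("saturated fit nests both the pure line and the pure constant", {
  set.seed(8)
  for (i in 1:20) {
    x <- sort(runif(12, 0, 1))
    y <- 0.05 - 0.1 * x + rnorm(12, 0, 0.01)
    fit <- saturated_linear_fit(x = x, y = y)
    # best pure line
    lfit <- stats::lm(y ~ x)
    expect_lte(fit$rss, sum(stats::residuals(lfit)^2) + 1e-12)
    # best constant
    expect_lte(fit$rss, sum((y - mean(y))^2) + 1e-12)
    expect_gte(fit$breakpoint, min(x))
    expect_lte(fit$breakpoint, max(x))
  }
})

test_that("saturated fit is deterministic and prediction is continuous at
           the breakpoint", {
  gen <- generate_deg_vs_growth(n = 12, noise_sd = 0.005, seed = 4)
  f1 <- saturated_linear_fit(gen$data)
  f2 <- saturated_linear_fit(gen$data)
  expect_identical(tidy(f1), tidy(f2))
  eps <- 1e-9
  expect_equal(predict(f1, f1$breakpoint - eps),
               predict(f1, f1$breakpoint + eps), tolerance = 1e-6)
})

test_that("polynomial smoother recovers exact polynomials and guards its
           range", {
  p <- polynomial_interpolate(1:6, 2 - 3 * (1:6) + 0.5 * (1:6)^2, degree = 2)
  expect_equal(p$coefficients, c(2, -3, 0.5), tolerance = 1e-8)
  expect_equal(p$fun(2.5), 2 - 3 * 2.5 + 0.5 * 2.5^2, tolerance = 1e-8)
  expect_warning(p$fun(10), "extrapolation")
  p0 <- polynomial_interpolate(1:5, c(1, 2, 3, 2, 1), degree = 0)
  expect_equal(p0$coefficients, 1.8)
  expect_equal(p0$fun(3), 1.8)
  # noisy quadratic: coefficients within a loose band of the truth
  set.seed(12)
  x <- seq(0, 2, length.out = 30)
  y <- 1 + 0.5 * x - 0.2 * x^2 + rnorm(30, 0, 0.01)
  pn <- polynomial_interpolate(x, y, degree = 2)
  expect_equal(pn$coefficients, c(1, 0.5, -0.2), tolerance = 0.1)
  expect_error(polynomial_interpolate(c(1, 1, 2), c(1, 2, 3), degree = 2),
               "Ill-conditioned")
})

test_that("growth-law fit recovers gamma and eta from noiseless and noisy
           degradation-model data", {
  lam <- seq(0, 1.5, length.out = 10)
  cond <- data.frame(growth_rate_per_h = lam,
                     ribosome_fraction = (lam + 0.25) / 7.2)
  fit <- growth_law_fit(cond)
  expect_equal(fit$slope, 1 / 7.2, tolerance = 1e-10)
  expect_equal(fit$slope, 0.13889, tolerance = 1e-4)
  expect_equal(fit$intercept, 0.03472, tolerance = 1e-4)
  expect_equal(fit$gamma_hat, 7.2, tolerance = 1e-8)
  expect_equal(fit$eta_hat, 0.25, tolerance = 1e-8)
  # eta = 0: intercept vanishes
  fit0 <- growth_law_fit(data.frame(growth_rate_per_h = lam,
                                    ribosome_fraction = lam / 7.2 + 1e-9))
  expect_equal(fit0$intercept, 0, tolerance = 1e-6)
  # noisy recovery within 2 standard errors
  set.seed(0)
  noisy <- data.frame(
    growth_rate_per_h = seq(0.1, 1.5, length.out = 8),
    ribosome_fraction = (seq(0.1, 1.5, length.out = 8) + 0.25) / 7.2 +
      rnorm(8, 0, 0.003)
  )
  fitn <- growth_law_fit(noisy)
  expect_lt(abs(fitn$slope - 1 / 7.2), 2 * fitn$slope_se)
  expect_lt(abs(fitn$intercept - 0.25 / 7.2), 2 * fitn$intercept_se)
  expect_error(growth_law_fit(cond[1:2, ]), "3 conditions")
  expect_error(
    growth_law_fit(data.frame(growth_rate_per_h = rep(0.5, 5),
                              ribosome_fraction = runif(5, 0.1, 0.2))),
    "Zero variance"
  )
})

test_that("f_b0 estimation is exact on noiseless ansatz data for any
           parameter choice", {
  for (fb0 in c(0.1, 0.2, 0.5, 0.9)) {
    gen <- generate_growth_law_dataset(n = 7, fb0 = fb0, gamma = 6.5,
                                       phi_R_min = 0.06, phi_R_slope = 0.12,
                                       seed = 1)
    est <- estimate_fb0(gen$conditions, lambda_max = Inf)
    expect_equal(est$fb0, fb0, tolerance = 1e-12)
    expect_equal(est$sd, 0, tolerance = 1e-12)
    # regression aggregation agrees on noiseless data
    est_r <- estimate_fb0(gen$conditions, lambda_max = Inf,
                          method = "regression")
    expect_equal(est_r$fb0, fb0, tolerance = 1e-12)
  }
  # eta = 0 everywhere gives fb0 = 0
  gen0 <- generate_growth_law_dataset(n = 6, fb0 = 0, seed = 2)
  expect_equal(estimate_fb0(gen0$conditions, lambda_max = Inf)$fb0, 0)
})

test_that("f_b0 estimation tolerates multiplicative noise and respects the
           slow-growth filter", {
  gen <- generate_growth_law_dataset(n = 10, fb0 = 0.2, noise_eta = 0.05,
                                     seed = 0)
  est <- estimate_fb0(gen$conditions, lambda_max = Inf)
  expect_lt(abs(est$fb0 - 0.2), 0.02)
  # the filter retains only slow conditions
  est_slow <- estimate_fb0(gen$conditions, lambda_max = 0.2)
  expect_equal(est_slow$n_used,
               sum(gen$conditions$growth_rate_per_h <= 0.2))
  expect_error(estimate_fb0(gen$conditions, lambda_max = 0.001),
               "No conditions")
  expect_error(estimate_fb0(gen$conditions[, 1:2]), "missing column")
})

test_that("linearity diagnostic flags constant versus growth-dependent
           bound fractions", {
  # constant f_b: exact line with slope 1/f_b, zero residuals
  lam <- seq(0.05, 1, length.out = 9)
  fb <- 0.8
  gamma <- 7.2
  eta <- rep(0.04, 9)
  phi <- (lam + eta) / (gamma * fb)
  cond <- data.frame(growth_rate_per_h = lam, ribosome_fraction = phi,
                     gamma_per_h = gamma, degradation_rate_per_h = eta)
  chk <- lambda_linearity_check(cond)
  expect_equal(chk$slope, 1 / fb, tolerance = 1e-10)
  expect_equal(chk$fb_implied, fb, tolerance = 1e-10)
  expect_lt(max(abs(chk$residuals$residual)), 1e-12)
  # eta = 0, f_b = 1: the identity line
  cond0 <- data.frame(growth_rate_per_h = lam,
                      ribosome_fraction = lam / gamma,
                      gamma_per_h = gamma,
                      degradation_rate_per_h = 0)
  chk0 <- lambda_linearity_check(cond0)
  expect_equal(chk0$slope, 1, tolerance = 1e-10)
  expect_equal(chk0$intercept, 0, tolerance = 1e-12)
  # ansatz data with fb0 < 1 and a linear allocation profile are linear in
  # Lambda but with a nonzero intercept: the implied 1/slope no longer equals
  # any single f_b and the line misses the origin
  gen <- generate_growth_law_dataset(n = 12, fb0 = 0.2, seed = 6)
  chka <- lambda_linearity_check(gen$conditions)
  expect_gt(abs(chka$intercept), 1e-4)
  # a genuinely growth-dependent f_b with constant eta produces curvature
  fb_var <- 0.5 + 0.3 * lam
  cond_var <- data.frame(
    growth_rate_per_h = lam,
    ribosome_fraction = (lam + 0.04) / (gamma * fb_var),
    gamma_per_h = gamma,
    degradation_rate_per_h = 0.04
  )
  chkv <- lambda_linearity_check(cond_var)
  expect_gt(abs(chkv$curvature), 1e-6)
  expect_gt(max(abs(chkv$residuals$residual)), 1e-8)
})
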