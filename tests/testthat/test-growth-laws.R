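# Closed-form growth-law algebra: worked values, limits, error contracts and
# algebraic identities on random grids.

test_that("active fraction of the standard model matches direct arithmetic", {
  expect_equal(fa_standard(0, 7.2, 0.08), 0)
  expect_equal(fa_standard(1, 5, 0.2), 1) # boundary: all ribosomes active
  expect_equal(fa_standard(0.5, 7.2, 0.1389), 0.5 / (7.2 * 0.1389))
  expect_error(fa_standard(2, 5, 0.2), "Infeasible")
  expect_error(fa_standard(0.5, -1, 0.2), "gamma")
  expect_error(fa_standard(0.5, 5, 1), "phi_R")
})

test_that("degradation-only law has offset eta/gamma and recovers the
           proportional law at eta = 0", {
  expect_equal(phi_r_degradation(0, 7.2, 0.25), 0.25 / 7.2)
  expect_equal(phi_r_degradation(0, 7.2, 0.25), 0.03472, tolerance = 1e-4)
  expect_equal(phi_r_degradation(1, 7.2, 0.25), 1.25 / 7.2)
  expect_equal(phi_r_degradation(1, 7.2, 0.25), 0.17361, tolerance = 1e-4)
  lam <- seq(0, 2, by = 0.25)
  expect_equal(phi_r_degradation(lam, 7.2, 0), lam / 7.2)
  expect_error(phi_r_degradation(1, 0, 0.1), "gamma")
})

test_that("combined bound fraction reduces to the standard model and obeys
           the capacity bounds", {
  expect_equal(fb_combined(0.5, 7.2, 0.1, 0), fa_standard(0.5, 7.2, 0.1))
  expect_equal(fb_combined(0, 5, 0.05, 0.05), 0.2) # maintenance-only limit
  expect_equal(fb_combined(0.5, 7.2, 0.1, 0.05), 0.55 / 0.72)
  expect_equal(fb_combined(0.5, 7.2, 0.1, 0.05), 0.76389, tolerance = 1e-5)
  expect_error(fb_combined(1, 5, 0.1, 0.2), "Infeasible")
  # lower bound of the feasibility interval, random grid
  set.seed(11)
  for (i in 1:50) {
    lam <- runif(1, 0, 0.5)
    gam <- runif(1, 4, 10)
    phi <- runif(1, 0.1, 0.3)
    eta <- runif(1, 0, 0.1)
    fb <- fb_combined(lam, gam, phi, eta)
    expect_gte(fb, lam / (gam * phi))
    expect_lte(fb, 1)
  }
})

test_that("maintenance/growth split depends on eta/lambda only, sums to one,
           and reaches all-maintenance at vanishing growth", {
  s <- maintenance_split(0.3, 0.3)
  expect_equal(s$f_bm, 0.5)
  expect_equal(s$f_bg, 0.5)
  expect_equal(maintenance_split(0.7, 0)$f_bm, 0)
  expect_equal(maintenance_split(0, 0.1), tibble::tibble(f_bm = 1, f_bg = 0))
  expect_error(maintenance_split(0, 0), "undefined")
  # collapse property: invariant under joint rescaling of (lambda, eta)
  set.seed(4)
  lam <- runif(20, 0.01, 1)
  eta <- runif(20, 0, 0.3)
  for (c_scale in c(0.1, 3, 42)) {
    expect_equal(maintenance_split(c_scale * lam, c_scale * eta),
                 maintenance_split(lam, eta))
  }
  expect_equal(maintenance_split(lam, eta)$f_bm +
                 maintenance_split(lam, eta)$f_bg, rep(1, 20))
})

test_that("constant-ratio ansatz hits its endpoints and implies the stated
           degradation rates", {
  expect_equal(fb_constant_ratio(0, 7.2, 0.1, 0.2), 0.2)
  expect_equal(fb_constant_ratio(0.5, 7.2, 0.1, 1), 1)
  # x = 1 boundary gives f_b = 1 for any fb0
  expect_equal(fb_constant_ratio(0.72, 7.2, 0.1, 0.33), 1)
  expect_warning(fb_constant_ratio(1, 7.2, 0.1, 0.2), "exceeds 1")
  # implied eta: worked value and the two degenerate cases
  expect_equal(eta_constant_ratio(0.1, 7.2, 0.08, 0.2), 0.0952,
               tolerance = 1e-4)
  lam <- seq(0.05, 0.5, by = 0.05)
  expect_equal(eta_constant_ratio(lam, 7.2, 0.1, 0), rep(0, length(lam)))
  expect_equal(eta_constant_ratio(0, 7.2, 0.1, 0.35), 7.2 * 0.1 * 0.35)
  # fb0 = 1 reduces to the degradation-only prediction
  expect_equal(eta_constant_ratio(lam, 7.2, 0.12, 1), 7.2 * 0.12 - lam)
})

test_that("f_a to f_b conversion and the maintenance identity agree across
           models on random grids", {
  expect_equal(fa_to_fb(0.1, 0.1, 0.1), 0.2)
  expect_equal(fa_to_fb(0.5, 0.4, 0.1), 0.625)
  expect_equal(fa_to_fb(0.3, 0.5, 0), 0.3)
  expect_error(fa_to_fb(0.3, 0, 0.1), "fb_combined")
  set.seed(7)
  for (i in 1:50) {
    lam <- runif(1, 0.01, 0.6)
    gam <- runif(1, 4, 10)
    phi <- runif(1, 0.1, 0.3)
    eta <- runif(1, 0, 0.15)
    fb <- fb_combined(lam, gam, phi, eta)
    fa <- fa_standard(lam, gam, phi)
    # Eq for f_b from f_a
    expect_equal(fa_to_fb(fa, lam, eta), fb, tolerance = 1e-12)
    # f_bm from the bound fraction equals the eta/lambda split
    expect_equal(fbm_from_fb(eta, gam, phi, fb),
                 maintenance_split(lam, eta)$f_bm, tolerance = 1e-12)
    # and equals the relative difference (f_b - f_a)/f_b
    expect_equal(fbm_from_fb(eta, gam, phi, fb), (fb - fa) / fb,
                 tolerance = 1e-12)
  }
})

test_that("worked maintenance-share value and the lambda = 0 limit hold", {
  fb <- fb_combined(0.5, 7.2, 0.1, 0.05)
  expect_equal(fbm_from_fb(0.05, 7.2, 0.1, fb), 0.09091, tolerance = 1e-4)
  expect_equal(fbm_from_fb(0, 7.2, 0.1, 0.5), 0)
  # at lambda = 0 the bound fraction is eta/(gamma phi_R): all maintenance
  expect_equal(fbm_from_fb(0.05, 5, 0.05, fb_combined(0, 5, 0.05, 0.05)), 1)
  expect_error(fbm_from_fb(0.5, 5, 0.05, 0.2), "exceeds 1")
})

test_that("sector-weighted degradation agrees between both algebraic forms", {
  expect_equal(eta_sector_weighted(0.02, 0.1, 0.3), 0.076)
  expect_equal(eta_sector_weighted(0.1, 0.1, 0.25), 0.1) # e = 0
  expect_equal(eta_sector_weighted(0, 0.1, 0.3), 0.1 * 0.7)
  expect_error(eta_sector_weighted(0.1, 0.1, 0.3, 0.6), "phi_R \\+ phi_P")
  set.seed(3)
  for (i in 1:30) {
    eR <- runif(1, 0, 0.2)
    eP <- runif(1, 0.01, 0.2)
    phiR <- runif(1, 0.05, 0.4)
    e <- 1 - eR / eP
    expect_equal(eta_sector_weighted(eR, eP, phiR), eP * (1 - e * phiR),
                 tolerance = 1e-14)
  }
})

test_that("dimensionless demand variable round-trips the combined law", {
  st <- dimensionless_state(0.5, 0.1, 6, 1)
  expect_equal(st$Lambda, 0.1)
  expect_equal(dimensionless_state(0.3, 0, 6, 1)$phi_R_pred, 0.05)
  set.seed(9)
  for (i in 1:40) {
    lam <- runif(1, 0, 1)
    eta <- runif(1, 0, 0.2)
    gam <- runif(1, 3, 10)
    fb <- runif(1, 0.2, 1)
    st <- dimensionless_state(lam, eta, gam, fb)
    expect_equal(st$phi_R_pred * fb * gam - eta, lam, tolerance = 1e-12)
  }
})

test_that("degradation-only and standard models are mathematically
           equivalent under eta = gamma * phi_Ri", {
  lam <- seq(0, 1, by = 0.1)
  gam <- 7.2
  phi_Ri <- 0.03
  eta <- gam * phi_Ri
  # same predicted phi_R(lambda): lambda/gamma + phi_Ri vs (lambda+eta)/gamma
  expect_equal(phi_r_degradation(lam, gam, eta), lam / gam + phi_Ri)
})

test_that("ansatz-generated partitions keep phi_Ri/phi_Rbm constant at
           1/fb0 - 1", {
  fb0 <- 0.25
  gen <- generate_growth_law_dataset(n = 9, fb0 = fb0, seed = 2)
  parts <- partition_ribosomes(gen$conditions)
  ratio <- parts$phi_Ri / parts$phi_Rbm
  expect_equal(ratio, rep(1 / fb0 - 1, nrow(parts)), tolerance = 1e-10)
  # the ratio identity of the ansatz holds per condition
  u <- parts$degradation_rate_per_h /
    (parts$gamma_per_h * parts$ribosome_fraction)
  expect_equal(u / (1 - parts$x), rep(fb0, nrow(parts)), tolerance = 1e-12)
})

test_that("partition table is internally consistent", {
  gen <- generate_growth_law_dataset(n = 8, fb0 = 0.3, seed = 5)
  parts <- partition_ribosomes(gen$conditions)
  expect_equal(parts$f_bm + parts$f_bg, rep(1, 8))
  expect_equal(parts$phi_Ri + parts$phi_Rbm + parts$phi_Rbg,
               parts$ribosome_fraction, tolerance = 1e-12)
  expect_true(all(parts$f_a <= parts$f_b + 1e-12))
  expect_equal(parts$rel_diff_fb, parts$f_bm, tolerance = 1e-12)
  expect_error(partition_ribosomes(gen$conditions[, 1:2]), "missing column")
})

test_that("elongation-rate conversion reproduces tabulated gamma values", {
  expect_equal(gamma_from_k(20, 7300), 20 * 3600 / 7300)
  expect_equal(signif(gamma_from_k(10.5, 12500), 1), 3)
})
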