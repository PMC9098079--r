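# Microscopic translation kinetics: initiation-limited ribosome density on
# transcripts, partition of the ribosome pool into free/bound/inactive, the
# biosynthesis mass flux, and two numerical oracles (a mass-balance ODE
# integrator and a self-consistent growth-rate solver) used to cross-check
# the closed-form growth laws.

#' Steady-state ribosome density on a transcript
#'
#' For initiation rate `alpha` and elongation rate `k`, with a ribosome
#' footprint of `ell` codons, the low-traffic steady density is
#' `rho = (alpha/k) / (1 + (ell - 1) * alpha/k)`. When initiation is much
#' slower than elongation this is approximately `alpha / k`; as `alpha` grows
#' it saturates at `1 / (ell - 1)`.
#'
#' @param alpha Translation initiation rate, 1/s.
#' @param k Codon elongation rate, codons/s (same time units as `alpha`).
#' @param ell Ribosome footprint in codons (about 10).
#' @return Ribosome density in ribosomes per codon.
#' @examples
#' ribosome_density(0.1, 10, ell = 10)
#' @export
ribosome_density <- function(alpha, k, ell = 10) {
  .check_positive(alpha, "alpha")
  .check_positive(k, "k")
  if (any(ell < 1)) stop("`ell` must be >= 1.", call. = FALSE)
  r <- alpha / k
  r / (1 + (ell - 1) * r)
}

#' Partition the ribosome pool into free, bound and inactive
#'
#' Free ribosomes bind transcripts by first-order kinetics; at steady state
#' `R_f = k * (R - R_i) / (k + L * c_m * alpha0)`, with the remainder of the
#' non-inactive pool bound (`R_b = R - R_i - R_f`). Only the dimensionless
#' ratio `L * c_m * alpha0 / k` matters, so it can be supplied directly via
#' `binding_ratio` instead of the individual kinetic constants.
#'
#' @param R Total ribosome count.
#' @param R_i Inactive (sequestered) ribosome count, `0 <= R_i <= R`.
#' @param k Codon elongation rate, codons/s.
#' @param L Protein length in codons.
#' @param c_m Transcript concentration (abstract units).
#' @param alpha0 Initiation rate constant (per concentration per second).
#' @param binding_ratio Optional shortcut: the value of
#'   `L * c_m * alpha0 / k`. When supplied, `k`, `L`, `c_m` and `alpha0` are
#'   ignored.
#' @return A tibble with columns `R_f`, `R_b`, `R_i` summing to `R`.
#' @examples
#' free_ribosomes(10000, 2000, binding_ratio = 1) # symmetric free/bound split
#' @export
free_ribosomes <- function(R, R_i = 0, k = NULL, L = NULL, c_m = NULL,
                           alpha0 = NULL, binding_ratio = NULL) {
  .check_nonneg(R, "R")
  .check_nonneg(R_i, "R_i")
  if (any(R_i > R)) {
    stop("Partition error: `R_i` exceeds the total ribosome count `R`.",
         call. = FALSE)
  }
  if (is.null(binding_ratio)) {
    if (is.null(k) || is.null(L) || is.null(c_m) || is.null(alpha0)) {
      stop("Supply either `binding_ratio` or all of `k`, `L`, `c_m`, ",
           "`alpha0`.", call. = FALSE)
    }
    .check_positive(k, "k")
    .check_nonneg(L, "L")
    .check_nonneg(c_m, "c_m")
    .check_nonneg(alpha0, "alpha0")
    binding_ratio <- L * c_m * alpha0 / k
  }
  .check_nonneg(binding_ratio, "binding_ratio")
  R_f <- (R - R_i) / (1 + binding_ratio)
  tibble::tibble(R_f = R_f, R_b = R - R_i - R_f, R_i = R_i)
}

#' Biosynthesis mass flux of actively translating ribosomes
#'
#' In the initiation-limited regime (elongation time much longer than the
#' free-ribosome waiting time) every mass-producing ribosome adds amino acids
#' at rate `k`, so the flux is `J_tl = m_aa * k * R_active`, converted to
#' picograms per hour.
#'
#' @param R_active Number of mass-producing (bound) ribosomes.
#' @param k Codon elongation rate, aa/s.
#' @param m_aa Mean amino-acid mass in pg (default 1.8e-10).
#' @param tau_ratio Optional value of `tau_e / tau_i` (elongation time over
#'   initiation waiting time). A warning is emitted below 10, where the
#'   linear flux expression degrades.
#' @return Mass flux in pg/h.
#' @examples
#' translation_flux(1e4, 10)
#' @export
translation_flux <- function(R_active, k, m_aa = 1.8e-10, tau_ratio = NULL) {
  .check_nonneg(R_active, "R_active")
  .check_positive(k, "k")
  .check_positive(m_aa, "m_aa")
  if (!is.null(tau_ratio) && any(tau_ratio < 10)) {
    warning("tau_e / tau_i < 10: the initiation-limited flux approximation ",
            "J_tl = m_aa * k * R is inaccurate in this regime.",
            call. = FALSE)
  }
  m_aa * k * 3600 * R_active
}

#' Integrate the protein mass balance forward in time
#'
#' Integrates `dM/dt = (gamma * f_b * phi_R - eta) * M` with a fixed-step
#' classical Runge-Kutta scheme. The trajectory serves as an independent
#' numerical oracle for the closed-form growth laws: the asymptotic log-slope
#' must equal `gamma * f_b * phi_R - eta`.
#'
#' @inheritParams fbm_from_fb
#' @param M0 Initial protein mass in pg.
#' @param T_h Total integration time in hours.
#' @param dt Time step in hours; defaults to `1e-3 / (abs(net rate) + 1)`.
#' @return A tibble with columns `t_h`, `mass_pg` and `log_slope_per_h`
#'   (centred finite-difference slope of `log(M)`; `NA` at the endpoints).
#' @examples
#' simulate_mass_balance(7.2, 0.1, 1, eta = 0.25, M0 = 1, T_h = 5)
#' @export
simulate_mass_balance <- function(gamma, phi_R, f_b, eta, M0 = 1, T_h = 10,
                                  dt = NULL) {
  .check_positive(gamma, "gamma")
  .check_fraction(phi_R, "phi_R")
  .check_positive(f_b, "f_b")
  .check_nonneg(eta, "eta")
  .check_positive(M0, "M0")
  .check_positive(T_h, "T_h")
  rate <- gamma * f_b * phi_R - eta
  if (is.null(dt)) dt <- 1e-3 / (abs(rate) + 1)
  if (dt > T_h) stop("`dt` must not exceed the horizon `T_h`.", call. = FALSE)

  n <- ceiling(T_h / dt)
  t <- seq(0, by = dt, length.out = n + 1)
  # linear ODE: one RK4 step has a constant amplification factor
  step <- {
    k1 <- rate
    k2 <- rate * (1 + dt * k1 / 2)
    k3 <- rate * (1 + dt * k2 / 2)
    k4 <- rate * (1 + dt * k3)
    1 + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  M <- M0 * step^(seq_len(n + 1) - 1)
  logM <- log(M)
  slope <- c(NA_real_, (logM[-(1:2)] - logM[1:(n - 1)]) / (2 * dt), NA_real_)
  tibble::tibble(t_h = t, mass_pg = M, log_slope_per_h = slope)
}

#' Asymptotic growth rate of a simulated trajectory
#'
#' Least-squares log-slope of the mass trajectory over its final half,
#' the quantity compared against the closed form `gamma * f_b * phi_R - eta`.
#'
#' @param trajectory Output of [simulate_mass_balance()].
#' @return Growth rate in 1/h.
#' @export
trajectory_growth_rate <- function(trajectory) {
  tail_rows <- trajectory$t_h >= max(trajectory$t_h) / 2
  t <- trajectory$t_h[tail_rows]
  y <- log(trajectory$mass_pg[tail_rows])
  stats::cov(t, y) / stats::var(t)
}

#' Self-consistent growth rate under the constant-ratio ansatz
#'
#' Solves `lambda = gamma(lambda) * phi_R * f_b(lambda) - eta(lambda)` for
#' `lambda`, with the bound fraction from the constant-ratio ansatz. `gamma`
#' and `eta` may be constants or functions of the growth rate (e.g.
#' interpolators built from condition data).
#'
#' @param phi_R Ribosomal mass fraction (held fixed).
#' @param fb0 Null-growth bound fraction of the ansatz.
#' @param gamma Ribosome self-replication rate in 1/h, or a function of
#'   `lambda` returning it.
#' @param eta Degradation rate in 1/h, or a function of `lambda`.
#' @param interval Bracket for the root search, in 1/h.
#' @return The growth rate `lambda*` at which supply balances demand, with a
#'   residual below 1e-10.
#' @examples
#' self_consistent_growth(0.1, fb0 = 1, gamma = 6, eta = 0.1) # 0.5/h
#' @export
self_consistent_growth <- function(phi_R, fb0, gamma, eta,
                                   interval = c(0, 5)) {
  .check_fraction(phi_R, "phi_R")
  gamma_fun <- if (is.function(gamma)) gamma else function(l) gamma
  eta_fun <- if (is.function(eta)) eta else function(l) eta
  residual <- function(l) {
    g <- gamma_fun(l)
    # bracket endpoints may lie beyond capacity; the extrapolation is benign
    fb <- suppressWarnings(fb_constant_ratio(l, g, phi_R, fb0))
    g * phi_R * fb - eta_fun(l) - l
  }
  lo <- residual(interval[1])
  hi <- residual(interval[2])
  if (sign(lo) == sign(hi)) {
    stop("No solution: the balance residual does not change sign over the ",
         "bracket [", interval[1], ", ", interval[2], "].", call. = FALSE)
  }
  root <- stats::uniroot(residual, interval, tol = 1e-14)
  lambda_star <- root$root
  if (abs(residual(lambda_star)) > 1e-10) {
    stop("Root refinement failed to reach the 1e-10 residual tolerance.",
         call. = FALSE)
  }
  lambda_star
}
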