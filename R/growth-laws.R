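# Closed-form algebra of the first growth law with and without protein
# turnover. All rates are in 1/h internally; elongation rates in aa/s are
# converted on entry (see gamma_from_k). Fractions are proteome mass
# fractions or ribosome-number fractions, both dimensionless in [0, 1].

# Slack allowed on the hard physical bound f_b <= 1 before raising.
.FEAS_TOL <- 1e-9

.check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("`", name, "` must be finite and > 0.", call. = FALSE)
  }
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("`", name, "` must be finite and >= 0.", call. = FALSE)
  }
  invisible(x)
}

.check_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    stop("`", name, "` must lie strictly between 0 and 1.", call. = FALSE)
  }
  invisible(x)
}

#' Convert a codon elongation rate to a ribosome self-replication rate
#'
#' The rate `gamma = k / L_R` is the inverse of the time a ribosome needs to
#' synthesise one ribosome's worth of protein. Elongation rates are
#' conventionally reported in amino acids per second while growth and
#' degradation rates are per hour, so the conversion multiplies by 3600.
#'
#' @param k_aa_s Codon elongation rate in amino acids per second.
#' @param L_R Number of amino acids in all proteins of one ribosome
#'   (about 7300 for *E. coli*, about 12500 for *S. cerevisiae*).
#' @return `gamma` in 1/h.
#' @examples
#' gamma_from_k(20, 7300) # fast-growing E. coli, ~10 per hour
#' @export
gamma_from_k <- function(k_aa_s, L_R) {
  .check_positive(k_aa_s, "k_aa_s")
  .check_positive(L_R, "L_R")
  k_aa_s * 3600 / L_R
}

#' Active ribosome fraction in the standard (no-degradation) model
#'
#' In the standard growth-law model all net protein synthesis comes from a
#' fraction `f_a` of ribosomes, and mass balance at steady exponential growth
#' gives `lambda = gamma * phi_R * f_a`, i.e. `f_a = lambda / (gamma * phi_R)`.
#'
#' @param lambda Growth rate in 1/h.
#' @param gamma Ribosome self-replication rate `k / L_R` in 1/h.
#' @param phi_R Ribosomal proteome mass fraction, strictly in (0, 1).
#' @return The active fraction `f_a`, vectorised over the inputs.
#' @examples
#' fa_standard(0.5, 7.2, 0.1389)
#' @export
fa_standard <- function(lambda, gamma, phi_R) {
  .check_nonneg(lambda, "lambda")
  .check_positive(gamma, "gamma")
  .check_fraction(phi_R, "phi_R")
  f_a <- lambda / (gamma * phi_R)
  if (any(f_a > 1 + .FEAS_TOL)) {
    stop("Infeasible condition: lambda / (gamma * phi_R) exceeds 1; ",
         "more growth than the total ribosome pool allows.", call. = FALSE)
  }
  pmin(f_a, 1)
}

#' Ribosomal mass fraction under the degradation-only model
#'
#' When every ribosome is bound and translating but proteins turn over at a
#' first-order rate `eta`, flux balance gives `lambda = gamma * phi_R - eta`,
#' so `phi_R = (lambda + eta) / gamma`. The law keeps its linear form but
#' acquires an offset `phi_R(0) = eta / gamma`.
#'
#' @inheritParams fa_standard
#' @param eta Mean protein degradation rate in 1/h.
#' @return The predicted ribosomal mass fraction.
#' @examples
#' phi_r_degradation(0, 7.2, 0.25) # the zero-growth offset eta / gamma
#' @export
phi_r_degradation <- function(lambda, gamma, eta) {
  .check_nonneg(lambda, "lambda")
  .check_positive(gamma, "gamma")
  .check_nonneg(eta, "eta")
  (lambda + eta) / gamma
}

#' Bound/active ribosome fraction in the combined model
#'
#' With both inactive ribosomes and protein turnover, mass balance reads
#' `lambda = gamma * phi_R * f_b - eta`, so the bound (equivalently active)
#' fraction is `f_b = (lambda + eta) / (gamma * phi_R)`. It is bounded below
#' by the no-degradation value `lambda / (gamma * phi_R)` and above by 1.
#'
#' @inheritParams phi_r_degradation
#' @param phi_R Ribosomal proteome mass fraction, strictly in (0, 1).
#' @return The bound fraction `f_b`.
#' @examples
#' fb_combined(0.5, 7.2, 0.1, eta = 0.05)
#' @export
fb_combined <- function(lambda, gamma, phi_R, eta) {
  .check_nonneg(lambda, "lambda")
  .check_positive(gamma, "gamma")
  .check_fraction(phi_R, "phi_R")
  .check_nonneg(eta, "eta")
  f_b <- (lambda + eta) / (gamma * phi_R)
  if (any(f_b > 1 + .FEAS_TOL)) {
    stop("Infeasible condition: (lambda + eta) / (gamma * phi_R) exceeds 1; ",
         "the demanded synthesis flux exceeds total ribosome capacity.",
         call. = FALSE)
  }
  pmin(f_b, 1)
}

#' Split bound ribosomes into growth and maintenance shares
#'
#' Bound ribosomes partition into a growth share `f_bg = 1 / (1 + eta/lambda)`
#' whose output accumulates as net biomass, and a maintenance share
#' `f_bm = (eta/lambda) / (1 + eta/lambda)` whose output exactly replaces
#' degraded protein. The split depends on the ratio `eta / lambda` only; as
#' growth vanishes with `eta > 0` the maintenance share tends to 1.
#'
#' @inheritParams phi_r_degradation
#' @return A tibble with columns `f_bm` and `f_bg` (rows recycled over the
#'   longer of the two inputs). `f_bm + f_bg == 1` always.
#' @examples
#' maintenance_split(lambda = 0.1, eta = 0.1) # symmetric split
#' maintenance_split(lambda = 0, eta = 0.1)   # all maintenance at null growth
#' @export
maintenance_split <- function(lambda, eta) {
  .check_nonneg(lambda, "lambda")
  .check_nonneg(eta, "eta")
  n <- max(length(lambda), length(eta))
  lambda <- rep_len(lambda, n)
  eta <- rep_len(eta, n)
  if (any(lambda == 0 & eta == 0)) {
    stop("The growth/maintenance split is undefined when both lambda and ",
         "eta are zero.", call. = FALSE)
  }
  # analytic limit at lambda = 0 (eta > 0): all bound ribosomes do maintenance
  ratio <- ifelse(lambda == 0, Inf, eta / lambda)
  f_bm <- ifelse(is.infinite(ratio), 1, ratio / (1 + ratio))
  tibble::tibble(f_bm = f_bm, f_bg = 1 - f_bm)
}

#' Bound fraction under the constant-ratio ansatz
#'
#' A one-parameter family for the growth dependence of the bound fraction:
#' `f_b(lambda) = f_b0 + (1 - f_b0) * lambda / (gamma * phi_R)`, where `f_b0`
#' is the fraction of active ribosomes at null growth (all of them doing
#' maintenance). The ansatz is equivalent to a constant ratio of inactive to
#' maintenance ribosomal mass fractions, `phi_Ri / phi_Rbm = 1/f_b0 - 1`.
#'
#' @inheritParams fb_combined
#' @param fb0 Bound fraction at null growth, in [0, 1].
#' @return The bound fraction `f_b`.
#' @export
fb_constant_ratio <- function(lambda, gamma, phi_R, fb0) {
  .check_nonneg(lambda, "lambda")
  .check_positive(gamma, "gamma")
  .check_fraction(phi_R, "phi_R")
  .check_nonneg(fb0, "fb0")
  if (any(fb0 > 1)) stop("`fb0` must lie in [0, 1].", call. = FALSE)
  x <- lambda / (gamma * phi_R)
  if (any(x > 1 + .FEAS_TOL)) {
    warning("lambda / (gamma * phi_R) exceeds 1: growth exceeds total ",
            "ribosome capacity; the ansatz value is extrapolated.",
            call. = FALSE)
  }
  fb0 + (1 - fb0) * x
}

#' Degradation rate implied by the constant-ratio ansatz
#'
#' Solving the combined growth law with the ansatz bound fraction gives the
#' predicted degradation rate `eta = gamma * phi_R * f_b(lambda) - lambda`.
#' With `fb0 = 1` (no inactive ribosomes) this reduces to the degradation-only
#' prediction `eta = gamma * phi_R - lambda`.
#'
#' @inheritParams fb_constant_ratio
#' @return Implied degradation rate in 1/h.
#' @export
eta_constant_ratio <- function(lambda, gamma, phi_R, fb0) {
  f_b <- fb_constant_ratio(lambda, gamma, phi_R, fb0)
  eta <- gamma * phi_R * f_b - lambda
  if (any(eta < -.FEAS_TOL)) {
    stop("Model-inconsistent data: implied degradation rate is negative.",
         call. = FALSE)
  }
  pmax(eta, 0)
}

#' Convert an active fraction without degradation to a bound fraction with it
#'
#' At the same growth rate, the bound fraction of the combined model relates
#' to the standard model's active fraction by `f_b = f_a * (lambda + eta) /
#' lambda`, so degradation always increases the inferred active pool.
#'
#' @param f_a Active fraction from the standard model.
#' @inheritParams phi_r_degradation
#' @return The bound fraction `f_b >= f_a` (equality iff `eta = 0`).
#' @export
fa_to_fb <- function(f_a, lambda, eta) {
  .check_nonneg(f_a, "f_a")
  .check_nonneg(eta, "eta")
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("`lambda` must be > 0 here; at lambda = 0 compute the bound ",
         "fraction directly with fb_combined().", call. = FALSE)
  }
  f_a * (lambda + eta) / lambda
}

#' Maintenance share from the bound fraction
#'
#' `f_bm = eta / (gamma * f_b * phi_R)`, algebraically identical to the
#' relative difference `(f_b - f_a) / f_b` between the combined and standard
#' models, and to the `eta/lambda` form of [maintenance_split()] whenever
#' `f_b` satisfies the combined growth law.
#'
#' @inheritParams fb_combined
#' @param f_b Bound ribosome fraction, in (0, 1].
#' @return The maintenance share of bound ribosomes, in [0, 1].
#' @export
fbm_from_fb <- function(eta, gamma, phi_R, f_b) {
  .check_nonneg(eta, "eta")
  .check_positive(gamma, "gamma")
  .check_fraction(phi_R, "phi_R")
  .check_positive(f_b, "f_b")
  f_bm <- eta / (gamma * f_b * phi_R)
  if (any(f_bm > 1 + .FEAS_TOL)) {
    stop("Inconsistent inputs: maintenance share exceeds 1.", call. = FALSE)
  }
  pmin(f_bm, 1)
}

#' Proteome-wide degradation rate from sector-specific rates
#'
#' If ribosomal and metabolic proteins degrade at different rates, the mean
#' rate entering the growth law is the mass-fraction-weighted average
#' `eta = eta_R * phi_R + eta_P * phi_P`, equivalently
#' `eta_P * (1 - e * phi_R)` with `e = 1 - eta_R / eta_P`.
#'
#' @param eta_R,eta_P Degradation rates of the ribosomal and non-ribosomal
#'   sectors, in 1/h.
#' @param phi_R Ribosomal mass fraction.
#' @param phi_P Non-ribosomal mass fraction; must satisfy
#'   `phi_R + phi_P = 1` (the two-sector simplification).
#' @return The sector-weighted mean degradation rate in 1/h.
#' @export
eta_sector_weighted <- function(eta_R, eta_P, phi_R, phi_P = 1 - phi_R) {
  .check_nonneg(eta_R, "eta_R")
  .check_nonneg(eta_P, "eta_P")
  if (any(abs(phi_R + phi_P - 1) > 1e-12)) {
    stop("Sector fractions must satisfy phi_R + phi_P = 1.", call. = FALSE)
  }
  eta_R * phi_R + eta_P * phi_P
}

#' Dimensionless demand variable restoring growth-law linearity
#'
#' The variable `Lambda = (lambda + eta) / gamma` measures total synthesis
#' demand (growth plus turnover) relative to ribosome self-replication speed.
#' Under the combined model `phi_R = Lambda / f_b`, so a plot of `phi_R`
#' against `Lambda` is linear whenever the bound fraction is constant.
#'
#' @inheritParams fbm_from_fb
#' @inheritParams phi_r_degradation
#' @return A tibble with columns `Lambda` and `phi_R_pred = Lambda / f_b`.
#' @export
dimensionless_state <- function(lambda, eta, gamma, f_b) {
  .check_nonneg(lambda, "lambda")
  .check_nonneg(eta, "eta")
  .check_positive(gamma, "gamma")
  .check_positive(f_b, "f_b")
  Lambda <- (lambda + eta) / gamma
  tibble::tibble(Lambda = Lambda, phi_R_pred = Lambda / f_b)
}

#' Per-condition ribosome partitioning table
#'
#' Takes a growth-condition table and returns, per row, the full partition of
#' the ribosome pool under the standard and combined models: the capacity
#' ratio `x = lambda / (gamma * phi_R)`, the active fraction without
#' degradation `f_a`, the bound fraction `f_b`, its growth/maintenance split
#' (`f_bg`, `f_bm`), the mass fractions of inactive, maintenance and growth
#' ribosomes (`phi_Ri`, `phi_Rbm`, `phi_Rbg`), the dimensionless demand
#' `Lambda`, and both conventions for the relative difference between models
#' (`rel_diff_fa = (f_b - f_a)/f_a`, `rel_diff_fb = (f_b - f_a)/f_b`; only
#' the latter equals `f_bm`).
#'
#' @param conditions A data frame with columns `growth_rate_per_h`,
#'   `ribosome_fraction`, `gamma_per_h` and (unless `fb0` is supplied)
#'   `degradation_rate_per_h`, as produced by [read_conditions()] or
#'   [generate_growth_law_dataset()].
#' @param fb0 Optional null-growth bound fraction. When given, `f_b` and the
#'   implied degradation rate come from the constant-ratio ansatz instead of
#'   the measured `degradation_rate_per_h` column.
#' @return A tibble: the input columns plus the partition columns above.
#' @examples
#' gen <- generate_growth_law_dataset(n = 5, fb0 = 0.2, seed = 1)
#' partition_ribosomes(gen$conditions)
#' @export
partition_ribosomes <- function(conditions, fb0 = NULL) {
  conditions <- tibble::as_tibble(conditions)
  req <- c("growth_rate_per_h", "ribosome_fraction", "gamma_per_h")
  missing_cols <- setdiff(req, names(conditions))
  if (length(missing_cols) > 0) {
    stop("`conditions` is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lambda <- conditions$growth_rate_per_h
  phi_R <- conditions$ribosome_fraction
  gamma <- conditions$gamma_per_h

  if (is.null(fb0)) {
    if (!"degradation_rate_per_h" %in% names(conditions)) {
      stop("`conditions` needs a `degradation_rate_per_h` column when `fb0` ",
           "is not supplied.", call. = FALSE)
    }
    eta <- conditions$degradation_rate_per_h
  } else {
    eta <- eta_constant_ratio(lambda, gamma, phi_R, fb0)
  }

  x <- lambda / (gamma * phi_R)
  f_a <- fa_standard(lambda, gamma, phi_R)
  f_b <- fb_combined(lambda, gamma, phi_R, eta)
  split <- maintenance_split(lambda, eta)
  phi_Ri <- phi_R * (1 - f_b)
  phi_Rbm <- phi_R * f_b * split$f_bm
  phi_Rbg <- phi_R * f_b * split$f_bg
  Lambda <- (lambda + eta) / gamma

  dplyr::bind_cols(
    conditions[setdiff(names(conditions), "degradation_rate_per_h")],
    tibble::tibble(
      degradation_rate_per_h = eta,
      x = x, f_a = f_a, f_b = f_b,
      f_bm = split$f_bm, f_bg = split$f_bg,
      phi_Ri = phi_Ri, phi_Rbm = phi_Rbm, phi_Rbg = phi_Rbg,
      Lambda = Lambda,
      rel_diff_fa = ifelse(f_a > 0, (f_b - f_a) / f_a, Inf),
      rel_diff_fb = (f_b - f_a) / f_b
    )
  )
}
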