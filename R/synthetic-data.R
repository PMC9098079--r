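# Synthetic datasets with known ground truth. Each generator forward-
# evaluates the model it emulates, attaches the noiseless truth alongside the
# noisy observables, and is deterministic given its seed. Defaults mirror the
# study conditions the estimators are meant for: E. coli-like growth-rate
# grids, a gamma of 7.2/h, slow-growth degradation rates of a few 0.01/h,
# and measurement noise of the order seen in allocation datasets (additive
# sigma = 0.003 on phi_R, 10% multiplicative lognormal on eta, additive
# sigma = 0.01 on labelled fractions).

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate a self-consistent growth-law condition table
#'
#' Produces growth conditions obeying the combined growth law with the
#' constant-ratio ansatz exactly: a growth-rate grid, a linear ribosome
#' allocation profile `phi_R(lambda) = phi_R_min + phi_R_slope * lambda`,
#' per-condition `gamma`, and the implied degradation rate
#' `eta = gamma * phi_R * f_b(lambda) - lambda` with
#' `f_b = fb0 + (1 - fb0) * lambda / (gamma * phi_R)`. Noiseless output
#' therefore satisfies the f_b0 ratio identity exactly; optional noise is
#' additive Gaussian on `phi_R` and multiplicative lognormal on `eta`, with
#' the noiseless truth kept in `ribosome_fraction_true` and
#' `degradation_rate_true`.
#'
#' @param n Number of conditions.
#' @param fb0 Ground-truth bound fraction at null growth.
#' @param gamma Ribosome self-replication rate in 1/h: a constant or a
#'   function of the growth rate.
#' @param lambda_range Growth-rate grid range in 1/h (evenly spaced grid).
#' @param phi_R_min,phi_R_slope Allocation profile parameters; defaults give
#'   an E. coli-like fraction rising from 0.05 towards 0.2 over
#'   `lambda = 0...1`.
#' @param noise_phi Additive Gaussian standard deviation on the observed
#'   ribosome fraction (0 for noiseless).
#' @param noise_eta Multiplicative lognormal coefficient of variation on the
#'   observed degradation rate (0 for noiseless).
#' @param organism Label stored in the `organism` column.
#' @param seed Integer seed; identical configuration and seed give identical
#'   output.
#' @return A list with `conditions` (tibble in the standard schema plus the
#'   `_true` columns) and `truth` (named list of generating parameters).
#' @examples
#' gen <- generate_growth_law_dataset(n = 6, fb0 = 0.2, seed = 42)
#' gen$conditions
#' @export
generate_growth_law_dataset <- function(n = 10, fb0 = 0.2, gamma = 7.2,
                                        lambda_range = c(0.05, 1),
                                        phi_R_min = 0.05, phi_R_slope = 0.15,
                                        noise_phi = 0, noise_eta = 0,
                                        organism = "synthetic",
                                        seed = NULL) {
  if (n < 3) stop("`n` must be at least 3.", call. = FALSE)
  .check_nonneg(noise_phi, "noise_phi")
  .check_nonneg(noise_eta, "noise_eta")
  lambda <- seq(lambda_range[1], lambda_range[2], length.out = n)
  gamma_fun <- if (is.function(gamma)) gamma else function(l) rep(gamma, length(l))
  g <- gamma_fun(lambda)
  phi_true <- phi_R_min + phi_R_slope * lambda
  if (any(phi_true <= 0) || any(phi_true >= 1)) {
    stop("Allocation profile leaves (0, 1); adjust phi_R_min/phi_R_slope.",
         call. = FALSE)
  }
  x <- lambda / (g * phi_true)
  if (any(x > 1)) {
    stop("Infeasible configuration: lambda / (gamma * phi_R) exceeds 1.",
         call. = FALSE)
  }
  eta_true <- eta_constant_ratio(lambda, g, phi_true, fb0)

  .with_seed(seed, {
    phi_obs <- phi_true + stats::rnorm(n, 0, noise_phi)
    eta_obs <- if (noise_eta > 0) {
      sdlog <- sqrt(log(1 + noise_eta^2))
      eta_true * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    } else {
      eta_true
    }
    conditions <- tibble::tibble(
      growth_rate_per_h = lambda,
      ribosome_fraction = phi_obs,
      gamma_per_h = g,
      degradation_rate_per_h = eta_obs,
      organism = organism,
      source = "generate_growth_law_dataset",
      ribosome_fraction_true = phi_true,
      degradation_rate_true = eta_true
    )
    list(conditions = conditions,
         truth = list(fb0 = fb0, gamma = gamma, phi_R_min = phi_R_min,
                      phi_R_slope = phi_R_slope, n = n,
                      noise_phi = noise_phi, noise_eta = noise_eta,
                      seed = seed))
  })
}

#' Generate pulse-chase decay curves from a known rate distribution
#'
#' Forward-evaluates the mixture decay law
#' `P_L(t)/P_L(0) = sum_c f_c exp(-eta_c t)` on the requested chase times and
#' adds optional Gaussian measurement noise, clipping noisy fractions to
#' (0, 1].
#'
#' @param times Chase times in hours, strictly increasing, starting at or
#'   after 0.
#' @param fractions,rates Ground-truth class fractions (summing to 1) and
#'   degradation rates in 1/h; defaults are a fast/slow/stable proteome
#'   (7% at 1.2/h, 23% at 0.02/h, 70% stable).
#' @param noise_sd Additive Gaussian standard deviation on the labelled
#'   fraction (default 0.01; 0 for noiseless).
#' @param n_curves Number of replicate curves.
#' @param seed Integer seed.
#' @return A list with `curve` (tibble `time_h`, `labelled_fraction`,
#'   `replicate`) and `truth` (the generating `rate_mixture` plus noise and
#'   seed).
#' @examples
#' generate_pulse_chase(times = 0:8, noise_sd = 0, seed = 1)$curve
#' @export
generate_pulse_chase <- function(times = seq(0, 10, by = 0.5),
                                 fractions = c(0.07, 0.23, 0.70),
                                 rates = c(1.2, 0.02, 0),
                                 noise_sd = 0.01, n_curves = 1,
                                 seed = NULL) {
  if (is.unsorted(times, strictly = TRUE) || any(times < 0)) {
    stop("`times` must be non-negative and strictly increasing.",
         call. = FALSE)
  }
  .check_nonneg(noise_sd, "noise_sd")
  dist <- decay_mixture(fractions, rates)
  clean <- mean_decay_curve(dist, times)$labelled_fraction
  .with_seed(seed, {
    curve <- purrr::map_dfr(seq_len(n_curves), function(rep) {
      obs <- clean + stats::rnorm(length(times), 0, noise_sd)
      obs <- pmin(pmax(obs, 1e-6), 1)
      if (times[1] == 0) obs[1] <- 1  # fraction is defined relative to t = 0
      tibble::tibble(time_h = times, labelled_fraction = obs,
                     replicate = rep)
    })
    list(curve = curve,
         truth = list(dist = dist, noise_sd = noise_sd, seed = seed))
  })
}

#' Generate a degradation-versus-growth table with a breakpoint
#'
#' Emulates the empirical trend of mean degradation rates: decreasing
#' linearly with growth rate at slow growth, constant beyond a breakpoint.
#' Noiseless output lies exactly on the saturated-linear model, so
#' [saturated_linear_fit()] recovers the generating parameters.
#'
#' @param n Number of growth conditions.
#' @param slope,intercept Linear segment `eta = intercept + slope * lambda`
#'   for `lambda < breakpoint` (slope is typically negative).
#' @param breakpoint Growth rate in 1/h beyond which `eta` is constant; must
#'   lie inside `lambda_range`.
#' @param lambda_range Growth-rate grid range in 1/h.
#' @param noise_sd Additive Gaussian standard deviation on `eta`.
#' @param seed Integer seed.
#' @return A list with `data` (tibble `growth_rate_per_h`,
#'   `degradation_rate_per_h`, `degradation_rate_true`) and `truth`.
#' @examples
#' generate_deg_vs_growth(n = 9, seed = 1)$data
#' @export
generate_deg_vs_growth <- function(n = 12, slope = -0.2, intercept = 0.06,
                                   breakpoint = 0.25,
                                   lambda_range = c(0.05, 1),
                                   noise_sd = 0, seed = NULL) {
  if (breakpoint <= lambda_range[1] || breakpoint >= lambda_range[2]) {
    stop("`breakpoint` must lie strictly inside `lambda_range`.",
         call. = FALSE)
  }
  .check_nonneg(noise_sd, "noise_sd")
  lambda <- sort(unique(c(seq(lambda_range[1], lambda_range[2],
                              length.out = n - 1), breakpoint)))
  eta_true <- intercept + slope * pmin(lambda, breakpoint)
  if (any(eta_true < 0)) {
    stop("Configuration implies negative degradation rates.", call. = FALSE)
  }
  .with_seed(seed, {
    eta_obs <- eta_true + stats::rnorm(length(lambda), 0, noise_sd)
    list(
      data = tibble::tibble(growth_rate_per_h = lambda,
                            degradation_rate_per_h = eta_obs,
                            degradation_rate_true = eta_true),
      truth = list(slope = slope, intercept = intercept,
                   breakpoint = breakpoint, plateau = intercept +
                     slope * breakpoint, noise_sd = noise_sd, seed = seed)
    )
  })
}

#' Write a generated dataset and its ground-truth sidecar
#'
#' Writes the tabular part of a generator result as CSV and the ground-truth
#' parameters as a `key=value` text sidecar next to it, so downstream
#' recovery checks can read back what generated the data.
#'
#' @param generated A list as returned by the `generate_*()` functions.
#' @param path Output CSV path; the sidecar is written to
#'   `paste0(path, ".truth")`.
#' @return Invisibly, the two paths written.
#' @export
write_dataset <- function(generated, path) {
  tab_name <- intersect(c("conditions", "curve", "data"), names(generated))[1]
  if (is.na(tab_name)) {
    stop("`generated` does not look like a generator result.", call. = FALSE)
  }
  readr::write_csv(generated[[tab_name]], path)
  truth <- generated$truth
  lines <- purrr::imap_chr(truth, function(v, k) {
    if (inherits(v, "rate_mixture")) {
      paste0(k, "=", paste0(
        "discrete[", paste(v$fractions, collapse = ","), ";",
        paste(v$rates, collapse = ","), "]"))
    } else if (is.function(v)) {
      paste0(k, "=<function>")
    } else if (is.null(v)) {
      paste0(k, "=NA")
    } else {
      paste0(k, "=", paste(v, collapse = ","))
    }
  })
  sidecar <- paste0(path, ".truth")
  writeLines(lines, sidecar)
  invisible(c(path, sidecar))
}

#' Read a ground-truth sidecar written by [write_dataset()]
#'
#' @param path Path to the `.truth` sidecar file.
#' @return A named list of character values (numeric where parseable).
#' @export
read_truth_sidecar <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- paste(p[-1], collapse = "=")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(kv, `[[`, character(1), 1))
}
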