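# Pulse-chase degradation analysis. A pulse labels the whole proteome; over
# the chase the labelled fraction P_L(t)/P_L(0) decays as a mixture of
# exponentials, one rate per protein. Estimators here recover the mean
# degradation rate from such curves: the classic single-exponential inversion
# (a lower bound, by Jensen's inequality), and two- and three-class mixture
# fits.

#' Construct a discrete mixture of degradation rates
#'
#' Represents a proteome as classes of proteins sharing a first-order
#' degradation rate. Fractions must sum to 1; a rate of 0 marks a stable
#' class.
#'
#' @param fractions Numeric vector of class mass fractions, summing to 1.
#' @param rates Non-negative degradation rates in 1/h, one per class.
#' @return An object of class `rate_mixture` with the analytic mean rate in
#'   `mean_eta`.
#' @examples
#' decay_mixture(c(0.07, 0.23, 0.70), c(1.2, 0.02, 0))
#' @export
decay_mixture <- function(fractions, rates) {
  if (length(fractions) != length(rates)) {
    stop("`fractions` and `rates` must have the same length.", call. = FALSE)
  }
  .check_nonneg(fractions, "fractions")
  .check_nonneg(rates, "rates")
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("Class fractions must sum to 1.", call. = FALSE)
  }
  structure(
    list(kind = "discrete", fractions = fractions, rates = rates,
         mean_eta = sum(fractions * rates)),
    class = "rate_mixture"
  )
}

#' Construct a lognormal distribution of degradation rates
#'
#' Continuous alternative to [decay_mixture()] for proteomes whose
#' degradation rates span decades: `eta ~ Lognormal(mu, sigma)` with analytic
#' mean `exp(mu + sigma^2 / 2)`.
#'
#' @param meanlog,sdlog Parameters of the lognormal on the log scale.
#' @return An object of class `rate_mixture` (kind `"lognormal"`).
#' @export
decay_lognormal <- function(meanlog, sdlog) {
  .check_nonneg(sdlog, "sdlog")
  structure(
    list(kind = "lognormal", meanlog = meanlog, sdlog = sdlog,
         mean_eta = exp(meanlog + sdlog^2 / 2)),
    class = "rate_mixture"
  )
}

#' @export
print.rate_mixture <- function(x, ...) {
  cat("<rate_mixture>", x$kind, "\n")
  if (x$kind == "discrete") {
    cat("  fractions:", paste(signif(x$fractions, 4), collapse = ", "), "\n")
    cat("  rates    :", paste(signif(x$rates, 4), collapse = ", "), "/h\n")
  } else {
    cat("  meanlog:", x$meanlog, " sdlog:", x$sdlog, "\n")
  }
  cat("  mean rate <eta>:", signif(x$mean_eta, 6), "/h\n")
  invisible(x)
}

#' Expected labelled-fraction decay curve of a rate distribution
#'
#' The population-level labelled fraction is the Laplace transform of the
#' rate distribution, `P_L(t)/P_L(0) = <exp(-eta * t)>`: a finite sum for
#' discrete mixtures, a numerical integral for the lognormal.
#'
#' @param dist A `rate_mixture` from [decay_mixture()] or [decay_lognormal()].
#' @param times Chase times in hours (non-negative).
#' @return A tibble with columns `time_h` and `labelled_fraction`.
#' @examples
#' mix <- decay_mixture(c(0.5, 0.5), c(0, 0.2))
#' mean_decay_curve(mix, times = c(0, 5, 10))
#' @export
mean_decay_curve <- function(dist, times) {
  stopifnot(inherits(dist, "rate_mixture"))
  .check_nonneg(times, "times")
  frac <- if (dist$kind == "discrete") {
    vapply(times, function(t) sum(dist$fractions * exp(-dist$rates * t)),
           numeric(1))
  } else {
    vapply(times, function(t) {
      stats::integrate(function(e) stats::dlnorm(e, dist$meanlog, dist$sdlog) *
                         exp(-e * t),
                       lower = 0, upper = Inf, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  tibble::tibble(time_h = times, labelled_fraction = frac)
}

.check_curve <- function(curve) {
  curve <- tibble::as_tibble(curve)
  req <- c("time_h", "labelled_fraction")
  if (!all(req %in% names(curve))) {
    stop("A pulse-chase curve needs columns `time_h` and ",
         "`labelled_fraction`.", call. = FALSE)
  }
  if (is.unsorted(curve$time_h, strictly = TRUE) || any(curve$time_h < 0)) {
    stop("`time_h` must be non-negative and strictly increasing.",
         call. = FALSE)
  }
  f <- curve$labelled_fraction
  if (any(f <= 0) || any(f > 1 + 1e-9)) {
    stop("Labelled fractions must lie in (0, 1].", call. = FALSE)
  }
  curve
}

#' Single-exponential estimate of the mean degradation rate
#'
#' Inverts the single-rate decay law `P_L(t) = P_L(0) exp(-eta t)`:
#' `eta = -log(fraction) / t` for one post-pulse timepoint, and the
#' zero-intercept least-squares slope of `-log(fraction)` on `t` when several
#' timepoints are available. For heterogeneous proteomes this estimator is a
#' lower bound on the true mean rate (see [jensen_gap()]).
#'
#' @param curve A data frame with columns `time_h` and `labelled_fraction`
#'   (fractions relative to the end of the pulse, in (0, 1]).
#' @return The estimated rate in 1/h.
#' @examples
#' single_exp_eta(data.frame(time_h = 2, labelled_fraction = exp(-0.2)))
#' @export
single_exp_eta <- function(curve) {
  curve <- .check_curve(curve)
  keep <- curve$time_h > 0
  if (!any(keep)) {
    stop("At least one timepoint with `time_h` > 0 is required.",
         call. = FALSE)
  }
  t <- curve$time_h[keep]
  y <- -log(curve$labelled_fraction[keep])
  sum(t * y) / sum(t^2)
}

#' Jensen gap of the single-exponential estimator
#'
#' For a heterogeneous proteome, `<exp(-eta t)> >= exp(-<eta> t)`, so the
#' single-exponential inversion underestimates the mean rate. This evaluates
#' the exact decay of a given rate distribution at time `t`, applies the
#' single-exponential estimator, and reports the bias.
#'
#' @inheritParams mean_decay_curve
#' @param t A single chase time in hours, > 0.
#' @return A tibble with columns `mean_eta` (true mean), `eta_hat`
#'   (single-exponential estimate) and `gap = mean_eta - eta_hat >= 0`.
#' @examples
#' jensen_gap(decay_mixture(c(0.5, 0.5), c(0, 0.2)), t = 5)
#' @export
jensen_gap <- function(dist, t) {
  .check_positive(t, "t")
  curve <- mean_decay_curve(dist, t)
  eta_hat <- -log(curve$labelled_fraction) / t
  tibble::tibble(mean_eta = dist$mean_eta, eta_hat = eta_hat,
                 gap = dist$mean_eta - eta_hat)
}

# Shared scaffolding for decay-class fits.
.new_decay_fit <- function(estimate, se, fitted, curve, method, classes) {
  structure(
    list(estimate = estimate, se = se, fitted = fitted,
         residuals = curve$labelled_fraction - fitted,
         rss = sum((curve$labelled_fraction - fitted)^2),
         n = nrow(curve), curve = curve, method = method, classes = classes),
    class = "decay_fit"
  )
}

.identifiability_warn <- function(eta_fast, times) {
  tt <- times[times > 0]
  scaled <- eta_fast * tt
  if (all(scaled < 0.2) || all(scaled > 5)) {
    warning("All sampled times fall outside the informative window for the ",
            "fast class (eta_fast * t in [0.2, 5]); the fit is poorly ",
            "constrained.", call. = FALSE)
  }
}

#' Two-class (fast + stable) fit of a pulse-chase curve
#'
#' Fits `P_L(t)/P_L(0) = f_fast * exp(-eta_fast * t) + (1 - f_fast)` by
#' bounded nonlinear least squares. The implied mean degradation rate is
#' `f_fast * eta_fast`.
#'
#' @inheritParams single_exp_eta
#' @return A `decay_fit` object; see [tidy.decay_fit()] and
#'   [glance.decay_fit()] for tabular summaries.
#' @examples
#' tr <- generate_pulse_chase(times = seq(0, 10, by = 0.5),
#'                            fractions = c(0.1, 0.9), rates = c(1, 0),
#'                            noise_sd = 0, seed = 1)
#' fit_two_class(tr$curve)
#' @export
fit_two_class <- function(curve) {
  curve <- .check_curve(curve)
  if (nrow(curve) < 4) {
    stop("At least 4 timepoints are required for a two-class fit.",
         call. = FALSE)
  }
  start <- .decay_start(curve)
  if (start$f_fast < 1e-10) {
    # flat curve: nothing decays
    fitted <- rep(1, nrow(curve))
    return(.new_decay_fit(
      c(f_fast = 0, eta_fast = 0, f_stable = 1, mean_eta = 0),
      c(f_fast = NA_real_, eta_fast = NA_real_), fitted, curve,
      method = "two_class", classes = 2
    ))
  }
  fit <- minpack.lm::nlsLM(
    labelled_fraction ~ f_fast * exp(-eta_fast * time_h) + (1 - f_fast),
    data = curve,
    start = list(f_fast = start$f_fast, eta_fast = start$eta_fast),
    lower = c(f_fast = 0, eta_fast = 1e-12),
    upper = c(f_fast = 1, eta_fast = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  cf <- stats::coef(fit)
  se <- .safe_se(fit)
  .identifiability_warn(cf[["eta_fast"]], curve$time_h)
  est <- c(f_fast = cf[["f_fast"]], eta_fast = cf[["eta_fast"]],
           f_stable = 1 - cf[["f_fast"]],
           mean_eta = cf[["f_fast"]] * cf[["eta_fast"]])
  .new_decay_fit(est, se, stats::fitted(fit), curve,
                 method = "two_class", classes = 2)
}

# Starting values: eta_fast from the first two log-slopes, f_fast from the
# late-time deficit below 1.
.decay_start <- function(curve) {
  t <- curve$time_h
  f <- curve$labelled_fraction
  deficit <- 1 - min(f)
  f_fast <- min(max(deficit, 1e-12), 1)
  i <- which(t > 0)[1]
  eta_fast <- if (deficit < 1e-10 || is.na(i)) {
    0.1
  } else {
    drop0 <- max(1 - f[i], 1e-12)
    max(-log(max(1 - drop0 / f_fast, 1e-12)) / t[i], 1e-3)
  }
  list(f_fast = f_fast, eta_fast = eta_fast)
}

.safe_se <- function(fit) {
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  if (is.null(se)) {
    cf <- stats::coef(fit)
    se <- stats::setNames(rep(NA_real_, length(cf)), names(cf))
  }
  se
}

#' Three-class fit of a pulse-chase curve
#'
#' Decomposes the proteome into fast-degrading, slow-degrading and stable
#' classes, `P_L(t)/P_L(0) = f_fast e^(-eta_fast t) + f_slow e^(-eta_slow t)
#' + f_stable`. Three fitting routes are provided:
#'
#' * `"mixture"` (default): bounded nonlinear least squares on the full
#'   three-class curve; reports `f_slow` and `eta_slow` separately as well as
#'   their product. Exact on mixture-generated data, which makes noiseless
#'   round-trips recover the generating parameters.
#' * `"integrated"`: linearises the slow class (`e^(-eta_slow t) ~ 1 -
#'   eta_slow t`, valid while `eta_slow * t << 1`) and fits
#'   `f_fast e^(-eta_fast t) + (1 - f_fast) - (f_slow eta_slow) t`, so only
#'   the product `f_slow * eta_slow` is identified.
#' * `"derivative"`: numerically differentiates the curve (central
#'   differences inside, one-sided at the ends) and fits
#'   `-dP/dt = f_fast eta_fast e^(-eta_fast t) + f_slow eta_slow`. Noisier,
#'   provided for comparison with the integrated route.
#'
#' In every case the mean degradation rate is
#' `mean_eta = f_fast * eta_fast + f_slow * eta_slow`.
#'
#' @inheritParams single_exp_eta
#' @param method Fitting route; see Details.
#' @return A `decay_fit` object.
#' @examples
#' tr <- generate_pulse_chase(times = seq(0, 10, by = 0.25),
#'                            fractions = c(0.07, 0.23, 0.70),
#'                            rates = c(1.2, 0.02, 0), noise_sd = 0, seed = 1)
#' fit_three_class(tr$curve)
#' @export
fit_three_class <- function(curve,
                            method = c("mixture", "integrated",
                                       "derivative")) {
  curve <- .check_curve(curve)
  method <- match.arg(method)
  if (nrow(curve) < 5) {
    stop("At least 5 timepoints are required for a three-class fit.",
         call. = FALSE)
  }
  switch(method,
         mixture = .fit_three_mixture(curve),
         integrated = .fit_three_integrated(curve),
         derivative = .fit_three_derivative(curve))
}

.fit_three_mixture <- function(curve) {
  start <- .decay_start(curve)
  fit <- minpack.lm::nlsLM(
    labelled_fraction ~ f_fast * exp(-eta_fast * time_h) +
      f_slow * exp(-eta_slow * time_h) + (1 - f_fast - f_slow),
    data = curve,
    start = list(f_fast = max(start$f_fast / 2, 1e-6),
                 eta_fast = max(start$eta_fast, 0.5),
                 f_slow = max(start$f_fast / 2, 1e-6),
                 eta_slow = max(start$eta_fast / 50, 1e-4)),
    lower = c(f_fast = 0, eta_fast = 1e-12, f_slow = 0, eta_slow = 0),
    upper = c(f_fast = 1, eta_fast = Inf, f_slow = 1, eta_slow = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  cf <- stats::coef(fit)
  # enforce the labelling eta_fast > eta_slow
  if (cf[["eta_slow"]] > cf[["eta_fast"]]) {
    cf <- c(f_fast = cf[["f_slow"]], eta_fast = cf[["eta_slow"]],
            f_slow = cf[["f_fast"]], eta_slow = cf[["eta_fast"]])
  }
  if (any(cf[c("eta_fast", "eta_slow")] < 0)) {
    stop("Fit error: negative fitted degradation rate.", call. = FALSE)
  }
  .identifiability_warn(cf[["eta_fast"]], curve$time_h)
  est <- c(
    f_fast = unname(cf["f_fast"]), eta_fast = unname(cf["eta_fast"]),
    f_slow = unname(cf["f_slow"]), eta_slow = unname(cf["eta_slow"]),
    fslow_etaslow = unname(cf["f_slow"] * cf["eta_slow"]),
    f_stable = unname(1 - cf["f_fast"] - cf["f_slow"]),
    mean_eta = unname(cf["f_fast"] * cf["eta_fast"] +
                        cf["f_slow"] * cf["eta_slow"])
  )
  .new_decay_fit(est, .safe_se(fit), stats::fitted(fit), curve,
                 method = "mixture", classes = 3)
}

.fit_three_integrated <- function(curve) {
  start <- .decay_start(curve)
  fit <- minpack.lm::nlsLM(
    labelled_fraction ~ f_fast * exp(-eta_fast * time_h) + (1 - f_fast) -
      fslow_etaslow * time_h,
    data = curve,
    start = list(f_fast = start$f_fast, eta_fast = max(start$eta_fast, 0.5),
                 fslow_etaslow = 1e-4),
    lower = c(f_fast = 0, eta_fast = 1e-12, fslow_etaslow = 0),
    upper = c(f_fast = 1, eta_fast = Inf, fslow_etaslow = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  cf <- stats::coef(fit)
  .identifiability_warn(cf[["eta_fast"]], curve$time_h)
  est <- c(f_fast = cf[["f_fast"]], eta_fast = cf[["eta_fast"]],
           fslow_etaslow = cf[["fslow_etaslow"]],
           mean_eta = cf[["f_fast"]] * cf[["eta_fast"]] +
             cf[["fslow_etaslow"]])
  .new_decay_fit(est, .safe_se(fit), stats::fitted(fit), curve,
                 method = "integrated", classes = 3)
}

.fit_three_derivative <- function(curve) {
  t <- curve$time_h
  f <- curve$labelled_fraction
  n <- length(t)
  d <- numeric(n)
  d[1] <- (f[2] - f[1]) / (t[2] - t[1])
  d[n] <- (f[n] - f[n - 1]) / (t[n] - t[n - 1])
  inner <- 2:(n - 1)
  d[inner] <- (f[inner + 1] - f[inner - 1]) / (t[inner + 1] - t[inner - 1])
  dcurve <- tibble::tibble(time_h = t, neg_deriv = -d)
  start <- .decay_start(curve)
  fit <- minpack.lm::nlsLM(
    neg_deriv ~ f_fast * eta_fast * exp(-eta_fast * time_h) + fslow_etaslow,
    data = dcurve,
    start = list(f_fast = start$f_fast, eta_fast = max(start$eta_fast, 0.5),
                 fslow_etaslow = max(min(dcurve$neg_deriv), 0) + 1e-6),
    lower = c(f_fast = 0, eta_fast = 1e-12, fslow_etaslow = 0),
    upper = c(f_fast = 1, eta_fast = Inf, fslow_etaslow = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  cf <- stats::coef(fit)
  if (any(cf[c("eta_fast", "fslow_etaslow")] < 0)) {
    stop("Fit error: negative fitted degradation rate.", call. = FALSE)
  }
  .identifiability_warn(cf[["eta_fast"]], t)
  est <- c(f_fast = cf[["f_fast"]], eta_fast = cf[["eta_fast"]],
           fslow_etaslow = cf[["fslow_etaslow"]],
           mean_eta = cf[["f_fast"]] * cf[["eta_fast"]] +
             cf[["fslow_etaslow"]])
  fitted_frac <- cf[["f_fast"]] * exp(-cf[["eta_fast"]] * t) +
    (1 - cf[["f_fast"]]) - cf[["fslow_etaslow"]] * t
  .new_decay_fit(est, .safe_se(fit), fitted_frac, curve,
                 method = "derivative", classes = 3)
}

#' Mean degradation rate implied by a decay-class fit
#'
#' `mean_eta = f_fast * eta_fast + f_slow * eta_slow`; the stable class
#' contributes nothing. Also accepts a named vector with the class
#' parameters.
#'
#' @param fit A `decay_fit` object, or a named numeric vector with elements
#'   `f_fast`, `eta_fast` and either `fslow_etaslow` or both `f_slow` and
#'   `eta_slow`.
#' @return The mean rate in 1/h.
#' @export
mean_eta_from_classes <- function(fit) {
  if (inherits(fit, "decay_fit")) {
    return(unname(fit$estimate[["mean_eta"]]))
  }
  p <- fit
  slow <- if ("fslow_etaslow" %in% names(p)) {
    p[["fslow_etaslow"]]
  } else if (all(c("f_slow", "eta_slow") %in% names(p))) {
    p[["f_slow"]] * p[["eta_slow"]]
  } else {
    0
  }
  unname(p[["f_fast"]] * p[["eta_fast"]] + slow)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit>", x$classes, "classes, method =", x$method, "\n")
  print(signif(x$estimate, 6))
  cat("RSS:", signif(x$rss, 4), "on", x$n, "timepoints\n")
  invisible(x)
}

#' Tidy a decay-class fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted or derived parameter
#'   (`term`, `estimate`, `std.error`).
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  se <- x$se[match(names(x$estimate), names(x$se))]
  tibble::tibble(term = names(x$estimate),
                 estimate = unname(x$estimate),
                 std.error = unname(se))
}

#' One-row summary of a decay-class fit
#'
#' @inheritParams tidy.decay_fit
#' @return A tibble with `mean_eta`, `rss`, `n`, `classes` and `method`.
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(mean_eta = x$estimate[["mean_eta"]], rss = x$rss, n = x$n,
                 classes = x$classes, method = x$method)
}
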