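# Regression toolbox for condition data: the saturated (linear-then-constant)
# breakpoint fit used to interpolate degradation rates across growth rates,
# polynomial smoothing of allocation data, the first-growth-law linear fit,
# the null-growth bound fraction (f_b0) estimator, and a linearity diagnostic
# in the dimensionless demand variable.

#' Saturated linear fit: linear below a breakpoint, constant above
#'
#' Fits `y = a + b * min(x, x0)`, a continuous piecewise model that is linear
#' for `x < x0` and flat at the plateau `a + b * x0` beyond. For each
#' candidate breakpoint the model is linear in `(a, b)`, so the search is an
#' ordinary least-squares profile over `x0`: a grid of observed `x` values
#' and their midpoints, followed by local refinement with
#' [stats::optimize()]. Ties in residual error break to the smallest
#' breakpoint. The fit nests both the pure line (breakpoint at the right
#' edge) and the constant (zero slope).
#'
#' @param data A data frame with the predictor and response, or `NULL` when
#'   `x` and `y` are given as vectors.
#' @param x,y Column names (strings) when `data` is supplied, otherwise
#'   numeric vectors. Defaults match the degradation-versus-growth table
#'   (`growth_rate_per_h`, `degradation_rate_per_h`).
#' @return An object of class `saturated_fit` with elements `slope`,
#'   `intercept`, `breakpoint`, `plateau` and `rss`; supports [predict()],
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' lam <- seq(0.05, 0.8, length.out = 12)
#' eta <- ifelse(lam < 0.25, 0.06 - 0.2 * lam, 0.01)
#' saturated_linear_fit(data.frame(growth_rate_per_h = lam,
#'                                 degradation_rate_per_h = eta))
#' @export
saturated_linear_fit <- function(data = NULL, x = "growth_rate_per_h",
                                 y = "degradation_rate_per_h") {
  if (is.null(data)) {
    xv <- x
    yv <- y
  } else {
    data <- tibble::as_tibble(data)
    if (!all(c(x, y) %in% names(data))) {
      stop("Columns `", x, "` and `", y, "` not found in `data`.",
           call. = FALSE)
    }
    xv <- data[[x]]
    yv <- data[[y]]
  }
  if (length(xv) < 4) {
    stop("At least 4 points are required for a saturated linear fit.",
         call. = FALSE)
  }
  ord <- order(xv)
  xv <- xv[ord]
  yv <- yv[ord]

  rss_at <- function(x0) {
    z <- pmin(xv, x0)
    if (stats::var(z) < .Machine$double.eps) {
      return(c(rss = sum((yv - mean(yv))^2), a = mean(yv), b = 0))
    }
    b <- stats::cov(z, yv) / stats::var(z)
    a <- mean(yv) - b * mean(z)
    c(rss = sum((yv - (a + b * z))^2), a = a, b = b)
  }

  xs <- sort(unique(xv))
  grid <- sort(unique(c(xs, (xs[-1] + xs[-length(xs)]) / 2)))
  grid_rss <- vapply(grid, function(x0) rss_at(x0)[["rss"]], numeric(1))
  # deterministic tie-break: smallest breakpoint within float slack
  best <- which(grid_rss <= min(grid_rss) * (1 + 1e-12))[1]
  x0 <- grid[best]
  lo <- if (best > 1) grid[best - 1] else grid[1]
  hi <- if (best < length(grid)) grid[best + 1] else grid[length(grid)]
  if (hi > lo) {
    opt <- stats::optimize(function(b0) rss_at(b0)[["rss"]], c(lo, hi),
                           tol = 1e-12)
    if (opt$objective < grid_rss[best] * (1 - 1e-12)) x0 <- opt$minimum
  }
  sol <- rss_at(x0)
  structure(
    list(slope = sol[["b"]], intercept = sol[["a"]], breakpoint = x0,
         plateau = sol[["a"]] + sol[["b"]] * x0, rss = sol[["rss"]],
         x = xv, y = yv, xname = if (is.null(data)) "x" else x,
         yname = if (is.null(data)) "y" else y),
    class = "saturated_fit"
  )
}

#' @export
print.saturated_fit <- function(x, ...) {
  cat("<saturated_fit> y =", signif(x$intercept, 6), "+",
      signif(x$slope, 6), "* min(x,", signif(x$breakpoint, 6), ")\n")
  cat("plateau:", signif(x$plateau, 6), " RSS:", signif(x$rss, 4), "\n")
  invisible(x)
}

#' @rdname saturated_linear_fit
#' @param object A `saturated_fit`.
#' @param newdata Optional numeric vector of predictor values.
#' @param ... Unused.
#' @export
predict.saturated_fit <- function(object, newdata = NULL, ...) {
  xv <- if (is.null(newdata)) object$x else newdata
  object$intercept + object$slope * pmin(xv, object$breakpoint)
}

#' @method tidy saturated_fit
#' @export
tidy.saturated_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept", "breakpoint", "plateau"),
    estimate = c(x$slope, x$intercept, x$breakpoint, x$plateau)
  )
}

#' @method glance saturated_fit
#' @export
glance.saturated_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = length(x$x), breakpoint = x$breakpoint)
}

#' Least-squares polynomial smoother with a range-guarded evaluator
#'
#' Fits a raw polynomial of the given degree by ordinary least squares and
#' returns the coefficients together with an evaluator function. Evaluating
#' outside the observed predictor range triggers an extrapolation warning:
#' these smoothers interpolate noisy allocation data and carry no meaning
#' beyond it.
#'
#' @param x,y Numeric vectors.
#' @param degree Polynomial degree, less than the number of distinct points;
#'   default 2.
#' @return A list with `coefficients` (intercept first), `fun` (the
#'   evaluator), `range` and `rss`.
#' @examples
#' p <- polynomial_interpolate(1:5, (1:5)^2, degree = 2)
#' p$fun(2.5)
#' @export
polynomial_interpolate <- function(x, y, degree = 2) {
  if (length(unique(x)) <= degree) {
    stop("Ill-conditioned design: need more than `degree` distinct x ",
         "values.", call. = FALSE)
  }
  fit <- if (degree == 0) {
    stats::lm(y ~ 1)
  } else {
    stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  }
  beta <- unname(stats::coef(fit))
  rng <- range(x)
  fun <- function(newx) {
    if (any(newx < rng[1] - 1e-12) || any(newx > rng[2] + 1e-12)) {
      warning("Evaluating the polynomial outside the observed range [",
              signif(rng[1], 4), ", ", signif(rng[2], 4),
              "]: extrapolation.", call. = FALSE)
    }
    drop(outer(newx, 0:degree, `^`) %*% beta)
  }
  list(coefficients = beta, fun = fun, range = rng,
       rss = sum(stats::residuals(fit)^2))
}

#' Linear fit of the first growth law
#'
#' Ordinary least squares of the ribosomal mass fraction on growth rate,
#' `phi_R = lambda / gamma + eta / gamma`. The reciprocal slope estimates the
#' ribosome self-replication rate `gamma`, and the intercept (the zero-growth
#' offset `phi_R_min`) times `gamma` estimates the degradation rate that
#' would fully account for the offset.
#'
#' @param conditions Data frame with columns `growth_rate_per_h` and
#'   `ribosome_fraction` (at least 3 rows).
#' @return An object of class `growth_law_fit` with `slope`, `intercept`,
#'   their standard errors, and the derived `gamma_hat` and `eta_hat`;
#'   supports [generics::tidy()] and [generics::glance()].
#' @examples
#' lam <- seq(0.1, 1, by = 0.1)
#' growth_law_fit(data.frame(growth_rate_per_h = lam,
#'                           ribosome_fraction = (lam + 0.25) / 7.2))
#' @export
growth_law_fit <- function(conditions) {
  conditions <- tibble::as_tibble(conditions)
  req <- c("growth_rate_per_h", "ribosome_fraction")
  if (!all(req %in% names(conditions))) {
    stop("`conditions` needs columns `growth_rate_per_h` and ",
         "`ribosome_fraction`.", call. = FALSE)
  }
  if (nrow(conditions) < 3) {
    stop("At least 3 conditions are required.", call. = FALSE)
  }
  if (stats::var(conditions$growth_rate_per_h) < .Machine$double.eps) {
    stop("Zero variance in growth rate: the law cannot be fitted.",
         call. = FALSE)
  }
  fit <- stats::lm(ribosome_fraction ~ growth_rate_per_h, data = conditions)
  # noiseless model-generated data trip lm's perfect-fit warning; expected
  cf <- suppressWarnings(summary(fit)$coefficients)
  slope <- cf["growth_rate_per_h", "Estimate"]
  intercept <- cf["(Intercept)", "Estimate"]
  if (intercept < 0) {
    warning("Negative fitted zero-growth offset (phi_R_min); the data are ",
            "inconsistent with a non-negative degradation rate.",
            call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = intercept,
         slope_se = cf["growth_rate_per_h", "Std. Error"],
         intercept_se = cf["(Intercept)", "Std. Error"],
         gamma_hat = 1 / slope, eta_hat = intercept / slope,
         rss = sum(stats::residuals(fit)^2), n = nrow(conditions),
         lm = fit),
    class = "growth_law_fit"
  )
}

#' @export
print.growth_law_fit <- function(x, ...) {
  cat("<growth_law_fit> phi_R =", signif(x$intercept, 6), "+",
      signif(x$slope, 6), "* lambda\n")
  cat("gamma_hat:", signif(x$gamma_hat, 6), "/h  eta_hat:",
      signif(x$eta_hat, 6), "/h\n")
  invisible(x)
}

#' @method tidy growth_law_fit
#' @export
tidy.growth_law_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept", "gamma_hat", "eta_hat"),
    estimate = c(x$slope, x$intercept, x$gamma_hat, x$eta_hat),
    std.error = c(x$slope_se, x$intercept_se, NA_real_, NA_real_)
  )
}

#' @method glance growth_law_fit
#' @export
glance.growth_law_fit <- function(x, ...) {
  tibble::tibble(gamma_hat = x$gamma_hat, eta_hat = x$eta_hat,
                 phi_R_min = x$intercept, rss = x$rss, n = x$n)
}

#' Estimate the null-growth bound fraction f_b0
#'
#' Under the constant-ratio ansatz the per-condition ratio
#' `r = [eta / (gamma * phi_R)] / [1 - lambda / (gamma * phi_R)]` equals
#' `f_b0` in every condition. Conditions at slow growth (default
#' `lambda <= 0.2`/h, where turnover and growth are comparable) are retained
#' and the estimate aggregates the per-condition ratios.
#'
#' @param conditions Data frame with columns `growth_rate_per_h`,
#'   `ribosome_fraction`, `gamma_per_h`, `degradation_rate_per_h`.
#' @param lambda_max Retain conditions with growth rate at or below this
#'   value, in 1/h. Use `Inf` to keep all conditions.
#' @param method `"ratio_mean"` (default) averages the per-condition ratios;
#'   `"regression"` fits `eta/(gamma phi_R)` on `1 - lambda/(gamma phi_R)`
#'   through the origin.
#' @return A list with `fb0` (the estimate), `sd` (dispersion of the
#'   per-condition ratios), `n_used`, and `ratios` (a tibble of retained
#'   conditions with their ratios).
#' @examples
#' gen <- generate_growth_law_dataset(n = 8, fb0 = 0.2, seed = 1)
#' estimate_fb0(gen$conditions, lambda_max = Inf)$fb0
#' @export
estimate_fb0 <- function(conditions, lambda_max = 0.2,
                         method = c("ratio_mean", "regression")) {
  method <- match.arg(method)
  conditions <- tibble::as_tibble(conditions)
  req <- c("growth_rate_per_h", "ribosome_fraction", "gamma_per_h",
           "degradation_rate_per_h")
  missing_cols <- setdiff(req, names(conditions))
  if (length(missing_cols) > 0) {
    stop("`conditions` is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- conditions[conditions$growth_rate_per_h <= lambda_max, ]
  if (nrow(keep) == 0) {
    stop("No conditions at or below lambda_max = ", lambda_max, "/h.",
         call. = FALSE)
  }
  x <- keep$growth_rate_per_h / (keep$gamma_per_h * keep$ribosome_fraction)
  if (any(x >= 1)) {
    stop("Infeasible condition: lambda / (gamma * phi_R) >= 1 in a retained ",
         "condition.", call. = FALSE)
  }
  u <- keep$degradation_rate_per_h /
    (keep$gamma_per_h * keep$ribosome_fraction)
  r <- u / (1 - x)
  fb0 <- if (method == "ratio_mean") mean(r) else sum(u * (1 - x)) / sum((1 - x)^2)
  list(
    fb0 = fb0,
    sd = if (nrow(keep) > 1) stats::sd(r) else 0,
    n_used = nrow(keep),
    method = method,
    ratios = dplyr::mutate(keep, capacity_ratio = x, fb0_ratio = r)
  )
}

#' Linearity diagnostic in the dimensionless demand variable
#'
#' Regresses the ribosomal mass fraction on `Lambda = (lambda + eta) / gamma`.
#' When the bound fraction is constant across conditions the relation is the
#' exact line `phi_R = Lambda / f_b`; curvature signals a growth-dependent
#' bound fraction. The diagnostic reports the fitted slope (an estimate of
#' `1 / f_b`), per-condition residuals, and a curvature statistic (the
#' t-statistic of a quadratic term in `Lambda`).
#'
#' @inheritParams estimate_fb0
#' @return A list with `slope`, `intercept`, `fb_implied = 1/slope`,
#'   `curvature` (quadratic coefficient), `curvature_t`, and `residuals`
#'   (tibble of conditions with `Lambda`, fitted values and residuals).
#' @export
lambda_linearity_check <- function(conditions) {
  conditions <- tibble::as_tibble(conditions)
  req <- c("growth_rate_per_h", "ribosome_fraction", "gamma_per_h",
           "degradation_rate_per_h")
  if (!all(req %in% names(conditions))) {
    stop("`conditions` needs columns ", paste(req, collapse = ", "), ".",
         call. = FALSE)
  }
  Lambda <- (conditions$growth_rate_per_h +
               conditions$degradation_rate_per_h) / conditions$gamma_per_h
  phi_R <- conditions$ribosome_fraction
  fit <- stats::lm(phi_R ~ Lambda)
  curv <- if (length(unique(Lambda)) > 3) {
    L2 <- Lambda^2
    # noiseless inputs make lm() warn about a perfect fit; that is expected
    qfit <- suppressWarnings(
      summary(stats::lm(phi_R ~ Lambda + L2))$coefficients
    )
    c(coef = qfit["L2", "Estimate"], t = qfit["L2", "t value"])
  } else {
    c(coef = NA_real_, t = NA_real_)
  }
  slope <- unname(stats::coef(fit)["Lambda"])
  list(
    slope = slope,
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    fb_implied = 1 / slope,
    curvature = unname(curv["coef"]),
    curvature_t = unname(curv["t"]),
    residuals = tibble::tibble(
      Lambda = Lambda, phi_R = phi_R,
      fitted = stats::fitted(fit),
      residual = stats::residuals(fit)
    )
  )
}
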