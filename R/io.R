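# Tabular I/O and the end-to-end pipeline. The growth-condition CSV schema:
# growth_rate_per_h, ribosome_fraction, then at least one of
# elongation_rate_aa_per_s or gamma_per_h, optionally degradation_rate_per_h,
# organism, source. Comma-separated, header required, UTF-8, '.' decimal.

# Ribosome protein lengths (aa) used to convert elongation rates to gamma.
.L_R_DEFAULTS <- c("E. coli" = 7300, "S. cerevisiae" = 12500)

#' Read a growth-condition table
#'
#' Reads the standard growth-condition CSV, validates the schema, and applies
#' unit conversions: when `gamma_per_h` is absent it is derived from
#' `elongation_rate_aa_per_s` via `gamma = k * 3600 / L_R`, with the ribosome
#' protein length looked up per organism (7300 aa for *E. coli*, 12500 aa for
#' *S. cerevisiae* by default).
#'
#' @param path Path to a CSV file with header row. Required columns:
#'   `growth_rate_per_h`, `ribosome_fraction`; at least one of
#'   `gamma_per_h` or `elongation_rate_aa_per_s` (with `organism` resolvable
#'   in `L_R`); optional: `degradation_rate_per_h`, `organism`, `source`.
#' @param L_R Named vector mapping organism labels to ribosome protein
#'   lengths in amino acids, used for the elongation-rate conversion.
#' @return A tibble with a populated `gamma_per_h` column.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("growth_rate_per_h,ribosome_fraction,elongation_rate_aa_per_s,organism",
#'              "0.5,0.1,20,E. coli"), f)
#' read_conditions(f)
#' @export
read_conditions <- function(path, L_R = c("E. coli" = 7300,
                                          "S. cerevisiae" = 12500)) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0 || ncol(tab) == 0) {
    stop("Schema error: `", path, "` is empty.", call. = FALSE)
  }
  req <- c("growth_rate_per_h", "ribosome_fraction")
  for (col in req) {
    if (!col %in% names(tab)) {
      stop("Schema error: required column `", col, "` is missing.",
           call. = FALSE)
    }
  }
  num_cols <- intersect(
    c("growth_rate_per_h", "ribosome_fraction", "elongation_rate_aa_per_s",
      "gamma_per_h", "degradation_rate_per_h"),
    names(tab)
  )
  for (col in num_cols) {
    if (!is.numeric(tab[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))))[1]
      stop("Non-numeric value in column `", col, "` at data row ", bad, ".",
           call. = FALSE)
    }
  }
  if (!"gamma_per_h" %in% names(tab)) {
    tab$gamma_per_h <- NA_real_
  }
  need_gamma <- is.na(tab$gamma_per_h)
  if (any(need_gamma)) {
    if (!"elongation_rate_aa_per_s" %in% names(tab)) {
      stop("Schema error: need `gamma_per_h` or `elongation_rate_aa_per_s`.",
           call. = FALSE)
    }
    org <- if ("organism" %in% names(tab)) tab$organism else
      rep(names(L_R)[1], nrow(tab))
    lr <- unname(L_R[org])
    if (any(is.na(lr[need_gamma]))) {
      bad <- unique(org[need_gamma & is.na(lr)])
      stop("No ribosome length (L_R) known for organism(s): ",
           paste(bad, collapse = ", "), ". Extend the `L_R` argument.",
           call. = FALSE)
    }
    tab$gamma_per_h[need_gamma] <- gamma_from_k(
      tab$elongation_rate_aa_per_s[need_gamma], lr[need_gamma]
    )
  }
  tibble::as_tibble(tab)
}

#' Run the growth-law analysis pipeline on a condition table
#'
#' End-to-end analysis of a growth-condition dataset: load (or accept) the
#' table, optionally smooth the degradation trend with a saturated linear fit
#' and the allocation/elongation data with polynomials, compute the
#' per-condition ribosome partition (`f_a`, `f_b`, `f_bm`, `f_bg`, mass
#' sub-fractions), estimate the null-growth bound fraction `f_b0` from the
#' slow-growth subset, fit the first growth law, and run the
#' dimensionless-demand linearity diagnostic. Outputs are deterministic
#' given the inputs.
#'
#' @param conditions A condition table (tibble or data frame in the standard
#'   schema) or a path to a condition CSV.
#' @param lambda_max Slow-growth threshold for the `f_b0` estimate, 1/h.
#' @param poly_degree Degree for the polynomial smoothing of the allocation
#'   profile (used only for the smoothed diagnostic columns).
#' @param smooth_eta If `TRUE` (default), interpolate the degradation rates
#'   with a saturated linear fit evaluated at the observed growth rates
#'   before partitioning; if `FALSE`, use them as given.
#' @param fb0_method Aggregation for [estimate_fb0()].
#' @param out_dir Optional directory: when given, the partition table, the
#'   `f_b0` report and the fit parameters are written there as CSVs.
#' @return An object of class `ribomaint_report`: a list with `partitions`,
#'   `fb0`, `growth_law`, `eta_fit` (the saturated fit or `NULL`),
#'   `linearity`, and `settings`.
#' @examples
#' gen <- generate_growth_law_dataset(n = 8, fb0 = 0.2, seed = 7)
#' rep <- run_pipeline(gen$conditions, smooth_eta = FALSE, lambda_max = Inf)
#' rep$fb0$fb0
#' @export
run_pipeline <- function(conditions, lambda_max = 0.2, poly_degree = 2,
                         smooth_eta = TRUE,
                         fb0_method = c("ratio_mean", "regression"),
                         out_dir = NULL) {
  fb0_method <- match.arg(fb0_method)
  if (is.character(conditions) && length(conditions) == 1) {
    conditions <- read_conditions(conditions)
  }
  conditions <- tibble::as_tibble(conditions)
  if (!"degradation_rate_per_h" %in% names(conditions)) {
    stop("Pipeline stage 'load': the condition table has no ",
         "`degradation_rate_per_h` column.", call. = FALSE)
  }

  eta_fit <- NULL
  work <- conditions
  if (isTRUE(smooth_eta) && nrow(conditions) >= 4) {
    eta_fit <- tryCatch(
      saturated_linear_fit(conditions),
      error = function(e) stop("Pipeline stage 'interpolate': ",
                               conditionMessage(e), call. = FALSE)
    )
    work$degradation_rate_per_h <- pmax(
      predict(eta_fit, work$growth_rate_per_h), 0
    )
  }

  partitions <- tryCatch(
    partition_ribosomes(work),
    error = function(e) stop("Pipeline stage 'partition': ",
                             conditionMessage(e), call. = FALSE)
  )
  fb0 <- tryCatch(
    estimate_fb0(work, lambda_max = lambda_max, method = fb0_method),
    error = function(e) stop("Pipeline stage 'estimate_fb0': ",
                             conditionMessage(e), call. = FALSE)
  )
  gl <- tryCatch(
    growth_law_fit(work),
    error = function(e) stop("Pipeline stage 'growth_law': ",
                             conditionMessage(e), call. = FALSE)
  )
  lin <- tryCatch(
    lambda_linearity_check(work),
    error = function(e) stop("Pipeline stage 'linearity': ",
                             conditionMessage(e), call. = FALSE)
  )

  report <- structure(
    list(partitions = partitions, fb0 = fb0, growth_law = gl,
         eta_fit = eta_fit, linearity = lin,
         settings = list(lambda_max = lambda_max, poly_degree = poly_degree,
                         smooth_eta = smooth_eta, fb0_method = fb0_method)),
    class = "ribomaint_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(partitions, file.path(out_dir, "partitions.csv"))
    fb0_est <- fb0$fb0
    fb0_sd <- fb0$sd
    fb0_n <- fb0$n_used
    fb0_row <- tibble::tibble(fb0 = fb0_est, sd = fb0_sd, n_used = fb0_n,
                              method = fb0_method, lambda_max = lambda_max)
    readr::write_csv(fb0_row, file.path(out_dir, "fb0.csv"))
    readr::write_csv(tidy(gl), file.path(out_dir, "growth_law_fit.csv"))
    if (!is.null(eta_fit)) {
      readr::write_csv(tidy(eta_fit), file.path(out_dir, "eta_fit.csv"))
    }
  }
  report
}

#' @export
print.ribomaint_report <- function(x, ...) {
  cat("<ribomaint_report>\n")
  cat("  conditions:", nrow(x$partitions), "\n")
  cat("  f_b0 estimate:", signif(x$fb0$fb0, 4), "(sd",
      signif(x$fb0$sd, 3), ", n =", x$fb0$n_used, ")\n")
  cat("  growth law: gamma_hat =", signif(x$growth_law$gamma_hat, 4),
      "/h, phi_R_min =", signif(x$growth_law$intercept, 4), "\n")
  if (!is.null(x$eta_fit)) {
    cat("  eta(lambda) breakpoint:", signif(x$eta_fit$breakpoint, 4),
        "/h, plateau:", signif(x$eta_fit$plateau, 4), "/h\n")
  }
  cat("  linearity in Lambda: slope =", signif(x$linearity$slope, 4),
      "(implied f_b =", signif(x$linearity$fb_implied, 4), ")\n")
  invisible(x)
}

#' Write a simulated mass trajectory as CSV
#'
#' @param trajectory Output of [simulate_mass_balance()].
#' @param path Output CSV path (columns `t_h`, `mass_pg`,
#'   `log_slope_per_h`).
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(trajectory, path) {
  readr::write_csv(trajectory, path)
  invisible(path)
}
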