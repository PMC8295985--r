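# broom-style accessors and print methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy the parameters of a global dispersion fit
#'
#' @param x An `rd_fit` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error` and, when
#'   Monte-Carlo errors were computed, `std_error_mc`.
#' @export
tidy.rd_fit <- function(x, ...) x$params

#' One-row summary of a global dispersion fit
#'
#' @param x An `rd_fit` object.
#' @param ... Unused.
#' @return Tibble with `chi2`, `chi2_reduced`, `n_data`, `n_params`,
#'   `n_params_total`, `n_peaks`, `converged`, `best_start`.
#' @export
glance.rd_fit <- function(x, ...) {
  tibble::tibble(
    chi2 = x$chi2, chi2_reduced = x$chi2_reduced,
    n_data = x$n_data, n_params = x$n_params,
    n_params_total = x$n_params_total,
    n_peaks = nrow(x$peaks),
    converged = x$convergence$info %in% 1:4,
    best_start = x$convergence$best_start
  )
}

#' Per-point fitted values and residuals of a dispersion fit
#'
#' @param x An `rd_fit` object.
#' @param ... Unused.
#' @return The input data with `.fitted` and `.resid` columns.
#' @export
augment.rd_fit <- function(x, ...) x$data

#' @export
print.rd_fit <- function(x, ...) {
  cat("Global two-site exchange fit (thermodynamically tied)\n")
  cat(sprintf("  %d peaks, %d data points, chi2 = %.4g (reduced %.3f)\n",
              nrow(x$peaks), x$n_data, x$chi2, x$chi2_reduced))
  cat(sprintf("  dG_act = %.0f J/mol, dG_eq = %.0f J/mol\n",
              x$params$estimate[1], x$params$estimate[2]))
  cat("  rate table:\n")
  print(as.data.frame(x$rate_table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tidy an RDC tensor fit
#'
#' @param x An `rdc_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per Saupe element.
#' @export
tidy.rdc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("Szz", "Syy_minus_Sxx", "Sxy", "Sxz", "Syz"),
    estimate = as.numeric(x$saupe)
  )
}

#' One-row summary of an RDC tensor fit
#'
#' @param x An `rdc_fit` object.
#' @param ... Unused.
#' @return Tibble with `Da_Hz`, `rhombicity`, `r_factor`, `rms_Hz`,
#'   `n`.
#' @export
glance.rdc_fit <- function(x, ...) {
  tibble::tibble(Da_Hz = x$Da_Hz, rhombicity = x$rhombicity,
                 r_factor = x$r_factor, rms_Hz = x$rms_Hz, n = x$n)
}

#' @export
print.rdc_fit <- function(x, ...) {
  cat("Alignment tensor by SVD\n")
  cat(sprintf("  Da = %.3f Hz, rhombicity = %.3f, R-factor = %.1f%% (n = %d)\n",
              x$Da_Hz, x$rhombicity, 100 * x$r_factor, x$n))
  invisible(x)
}
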