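# ps-ns timescale analysis: monoexponential decay fitting for R1/R1rho,
# tilt-angle extraction of R2, and the rotational-correlation-time
# estimate from the trimmed mean R2/R1 ratio.

#' Fit a monoexponential decay to a relaxation series
#'
#' Nonlinear least squares of `I(t) = I0 * exp(-R * t)` (Levenberg-
#' Marquardt, log-linear start). A fitted rate at or below zero is
#' flagged rather than treated as an error: flat or rising series carry
#' no decay information.
#'
#' @param series Data frame with columns `delay_s` and `intensity`
#'   (>= 3 points); an `intensity_err` column, when present and
#'   positive, weights the fit.
#' @return One-row tibble: `rate`, `rate_se`, `i0`, `i0_se`, `flag`
#'   (`"ok"` or `"no-decay"`), `n`.
#' @export
#' @examples
#' fit_exponential_decay(simulate_decay(1.2))
fit_exponential_decay <- function(series) {
  if (!all(c("delay_s", "intensity") %in% names(series)))
    abort_input("series needs delay_s and intensity columns")
  if (nrow(series) < 3) abort_input("need >= 3 delay points")
  t <- series$delay_s
  y <- series$intensity
  w <- if ("intensity_err" %in% names(series) &&
           all(series$intensity_err > 0)) 1 / series$intensity_err else
             rep(1, length(y))
  # log-linear start (positive intensities only)
  pos <- y > 0
  start <- if (sum(pos) >= 2) {
    cf <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))
    c(i0 = exp(cf[[1]]), rate = -cf[[2]])
  } else c(i0 = max(y), rate = 1)
  fit <- minpack.lm::nls.lm(
    par = c(start[["i0"]], start[["rate"]]),
    fn = function(p) (y - p[1] * exp(-p[2] * t)) * w,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  se <- tryCatch({
    dof <- max(1, length(y) - 2)
    sqrt(pmax(diag(solve(fit$hessian) * fit$deviance / dof), 0))
  }, error = function(e) c(NA_real_, NA_real_))
  # flat within round-off over the sampled window carries no rate
  span <- diff(range(t))
  no_decay <- fit$par[2] <= 0 ||
    (span > 0 && fit$par[2] * span < 1e-6)
  tibble::tibble(
    rate = fit$par[2], rate_se = se[2],
    i0 = fit$par[1], i0_se = se[1],
    flag = if (no_decay) "no-decay" else "ok",
    n = length(y)
  )
}

#' Extract R2 from R1rho and R1 with the tilt-angle correction
#'
#' `R2 = (R1rho - R1 * cos^2(theta)) / sin^2(theta)` with
#' `tan(theta) = omega1 / Omega` (spin-lock field over resonance
#' offset). On resonance (`offset_Hz = 0`, theta = 90 degrees) this
#' returns `r1rho` unchanged.
#'
#' @param r1rho Rotating-frame rate(s), 1/s.
#' @param r1 Longitudinal rate(s), 1/s.
#' @param spinlock_Hz Spin-lock field strength, Hz (> 0). Default 1000.
#' @param offset_Hz Resonance offset from the carrier, Hz.
#' @return R2 in 1/s.
#' @export
#' @examples
#' r2_from_r1rho(12, 1.5)                     # on resonance: 12
#' r2_from_r1rho(12, 1.5, 1000, 1000)         # theta = 45 deg: 2*12 - 1.5
r2_from_r1rho <- function(r1rho, r1, spinlock_Hz = 1000, offset_Hz = 0) {
  if (any(spinlock_Hz <= 0)) abort_input("spinlock_Hz must be > 0")
  sin2 <- spinlock_Hz^2 / (spinlock_Hz^2 + offset_Hz^2)
  cos2 <- 1 - sin2
  if (any(r1rho < r1 * cos2))
    abort_input("r1rho < r1*cos^2(theta): inconsistent rates")
  (r1rho - r1 * cos2) / sin2
}

#' Rotational correlation time from the mean R2/R1 ratio
#'
#' `tau_c ~ (1 / (4 * pi * nu_N)) * sqrt(6 * R2/R1 - 7)`, the standard
#' 15N-based estimate valid for slow, isotropic tumbling. Returns
#' seconds; multiply by 1e9 for ns.
#'
#' @param r2_over_r1 Mean R2/R1 ratio (must be >= 7/6; smaller ratios
#'   fall outside the approximation's regime).
#' @param nu_N_Hz 15N resonance frequency in Hz (see
#'   [nucleus_frequency_hz()]).
#' @return tau_c in seconds.
#' @export
#' @examples
#' tau_c_estimate(22.1, nucleus_frequency_hz(800, "15N")) * 1e9 # ~11 ns
tau_c_estimate <- function(r2_over_r1, nu_N_Hz) {
  if (any(nu_N_Hz <= 0)) abort_input("nu_N_Hz must be > 0")
  if (any(6 * r2_over_r1 - 7 < 0))
    abort_input("R2/R1 below 7/6: outside the slow-tumbling approximation")
  sqrt(6 * r2_over_r1 - 7) / (4 * pi * nu_N_Hz)
}

#' Trimmed mean R2/R1 ratio excluding locally flexible residues
#'
#' Residues with enhanced ps-ns local dynamics (flexible termini,
#' linkers) depress R2/R1 and would bias the tumbling estimate. The
#' rule applied here: compute the median and standard deviation of all
#' ratios once, exclude residues falling more than `n_sd` standard
#' deviations below the median, and average the rest.
#'
#' @param summary Data frame with columns `residue_id` and
#'   `r2_over_r1` (>= 3 residues).
#' @param n_sd Exclusion depth in standard deviations below the median.
#'   Default 1.5.
#' @return One-row tibble: `mean_r2_over_r1`, `n_used`, `n_excluded`,
#'   and a list-column `excluded` with the excluded residue ids.
#' @export
trimmed_mean_r2_r1 <- function(summary, n_sd = 1.5) {
  if (!all(c("residue_id", "r2_over_r1") %in% names(summary)))
    abort_input("summary needs residue_id and r2_over_r1 columns")
  if (nrow(summary) < 3) abort_input("need >= 3 residues")
  ratio <- summary$r2_over_r1
  cut <- stats::median(ratio) - n_sd * stats::sd(ratio)
  keep <- ratio >= cut
  if (!any(keep)) abort_input("exclusion rule removed every residue")
  tibble::tibble(
    mean_r2_over_r1 = mean(ratio[keep]),
    n_used = sum(keep),
    n_excluded = sum(!keep),
    excluded = list(summary$residue_id[!keep])
  )
}

#' Per-residue relaxation summary from decay series
#'
#' Fits every (residue, experiment) decay in a long-format table,
#' extracts R2 from the R1/R1rho pairs via [r2_from_r1rho()], and
#' returns per-residue rates with the R2/R1 ratio.
#'
#' @param series Long data frame with columns `residue_id`,
#'   `experiment` (`"R1"` or `"R1rho"`), `delay_s`, `intensity`, and
#'   optionally `intensity_err`, `spinlock_Hz`, `offset_Hz`,
#'   `field_MHz`.
#' @return Tibble with one row per residue: `residue_id`, `r1`,
#'   `r1_se`, `r1rho`, `r1rho_se`, `r2`, `r2_over_r1`, `field_MHz`.
#' @export
summarize_relaxation <- function(series) {
  fits <- series |>
    dplyr::group_by(.data$residue_id, .data$experiment) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_exponential_decay(d)
      f$spinlock_Hz <- if ("spinlock_Hz" %in% names(d))
        d$spinlock_Hz[1] else 1000
      f$offset_Hz <- if ("offset_Hz" %in% names(d)) d$offset_Hz[1] else 0
      f$field_MHz <- if ("field_MHz" %in% names(d)) d$field_MHz[1] else NA
      f
    }) |>
    dplyr::ungroup()
  wide <- fits |>
    tidyr::pivot_wider(id_cols = c("residue_id", "field_MHz"),
                       names_from = "experiment",
                       values_from = c("rate", "rate_se",
                                       "spinlock_Hz", "offset_Hz"))
  if (!all(c("rate_R1", "rate_R1rho") %in% names(wide)))
    abort_input("series must contain both R1 and R1rho experiments")
  if (all(wide$offset_Hz_R1rho == 0))
    message("no R1rho offsets provided: using on-resonance approximation")
  wide |>
    dplyr::mutate(
      r1 = .data$rate_R1, r1_se = .data$rate_se_R1,
      r1rho = .data$rate_R1rho, r1rho_se = .data$rate_se_R1rho,
      r2 = r2_from_r1rho(.data$rate_R1rho, .data$rate_R1,
                         .data$spinlock_Hz_R1rho, .data$offset_Hz_R1rho),
      r2_over_r1 = .data$r2 / .data$r1
    ) |>
    dplyr::select("residue_id", "field_MHz", "r1", "r1_se", "r1rho",
                  "r1rho_se", "r2", "r2_over_r1")
}
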