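# Auxiliary assay readouts: CD melting temperature by derivative
# maximum, enzymatic initial velocity by linear fit, and the
# phosphorylation mass-shift arithmetic.

#' Melting temperature from the derivative maximum of a CD melt
#'
#' Tm is located at the maximum of |d(theta)/dT| computed by central
#' differences (forward/backward at the ends), optionally after a
#' 3-point moving-average smoothing of theta. The absolute value makes
#' the result invariant to the sign convention of the ellipticity. The
#' resolution is the temperature grid step.
#'
#' Flags: `"no-transition"` when the derivative peak does not rise
#' above the curve's background derivative level (max < 3x median of
#' |d(theta)/dT|), `"multimodal"` when a second local maximum reaches
#' 50% of the global one at least two grid steps away, `"ok"`
#' otherwise.
#'
#' @param curve Data frame with columns `temperature_C` (strictly
#'   increasing, >= 4 points) and `theta_222`.
#' @param smooth Apply 3-point moving-average smoothing before
#'   differencing (useful for noisy traces). Default `FALSE`.
#' @return One-row tibble: `tm_C`, `dtheta_max`, `flag`.
#' @export
#' @examples
#' extract_tm(simulate_melt(tm_C = 54))
extract_tm <- function(curve, smooth = FALSE) {
  if (!all(c("temperature_C", "theta_222") %in% names(curve)))
    abort_input("curve needs temperature_C and theta_222 columns")
  if (nrow(curve) < 4) abort_input("need >= 4 points for a melt")
  tt <- curve$temperature_C
  if (any(diff(tt) <= 0)) abort_input("temperature_C must be strictly increasing")
  th <- curve$theta_222
  if (smooth) th <- stats::filter(th, rep(1 / 3, 3), sides = 2) |>
      as.numeric() |> (\(x) ifelse(is.na(x), curve$theta_222, x))()
  n <- length(th)
  d <- numeric(n)
  d[1] <- (th[2] - th[1]) / (tt[2] - tt[1])
  d[n] <- (th[n] - th[n - 1]) / (tt[n] - tt[n - 1])
  d[2:(n - 1)] <- (th[3:n] - th[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  ad <- abs(d)
  i_max <- which.max(ad)
  flag <- "ok"
  if (max(ad) < 3 * stats::median(ad)) flag <- "no-transition"
  # secondary local maxima at half the global height or more
  is_peak <- c(FALSE, ad[2:(n - 1)] > ad[1:(n - 2)] &
                 ad[2:(n - 1)] >= ad[3:n], FALSE)
  other <- which(is_peak & ad >= 0.5 * ad[i_max] &
                   abs(seq_len(n) - i_max) >= 2)
  if (flag == "ok" && length(setdiff(other, i_max)) > 0)
    flag <- "multimodal"
  tibble::tibble(tm_C = tt[i_max], dtheta_max = d[i_max], flag = flag)
}

#' Initial velocity from a substrate-depletion trace
#'
#' Ordinary least-squares slope of concentration versus time; the
#' initial velocity is its magnitude for a depleting trace. All
#' supplied points are used, so the caller should restrict the trace to
#' the initial linear regime (conventionally < 15% depletion). A
#' significantly increasing trace is a data-orientation error.
#'
#' @param curve Data frame with columns `time_min` and `conc_uM`
#'   (>= 3 points).
#' @return One-row tibble: `v0_uM_min`, `v0_se`, `intercept_uM`, `n`.
#' @export
#' @examples
#' initial_velocity(simulate_kinetics(v0 = 25))
initial_velocity <- function(curve) {
  if (!all(c("time_min", "conc_uM") %in% names(curve)))
    abort_input("curve needs time_min and conc_uM columns")
  if (nrow(curve) < 3) abort_input("need >= 3 points for a velocity fit")
  fit <- stats::lm(conc_uM ~ time_min, data = curve)
  cf <- stats::coef(suppressWarnings(summary(fit)))
  slope <- cf["time_min", "Estimate"]
  se <- cf["time_min", "Std. Error"]
  if (slope > 0 && slope > 2 * se)
    abort_input("concentration increases with time: check data orientation")
  tibble::tibble(
    v0_uM_min = max(-slope, 0),
    v0_se = se,
    intercept_uM = cf["(Intercept)", "Estimate"],
    n = nrow(curve)
  )
}

#' Mass shift of a single phosphorylation
#'
#' Mass of the HPO3 adduct gained on phosphorylation, from standard
#' atomic masses (average or monoisotopic), times the number of
#' adducts. The average mass (79.98 Da) rounds to the familiar +80 Da
#' shift seen in intact-mass spectra.
#'
#' @param mode `"average"` or `"monoisotopic"`.
#' @param n Number of phosphoryl adducts. Default 1.
#' @return Mass shift in Da.
#' @export
#' @examples
#' round(mass_shift_phospho())          # 80
#' mass_shift_phospho("monoisotopic")   # 79.966
mass_shift_phospho <- function(mode = c("average", "monoisotopic"),
                               n = 1) {
  mode <- match.arg(mode)
  masses <- switch(mode,
    average = c(H = 1.008, P = 30.973761998, O = 15.999),
    monoisotopic = c(H = 1.00782503207, P = 30.97376163, O = 15.9949146196))
  n * unname(masses["H"] + masses["P"] + 3 * masses["O"])
}
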