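# Seeded simulators for every input the pipeline consumes. Each forward
# model is the one the corresponding estimator inverts, so zero-noise
# round trips are exact and parameter-recovery tests need no side
# channel: the generating truth travels with the data as an attribute.

#' Default CPMG experimental design grid
#'
#' The condition grid used throughout: four temperatures (5, 10, 15,
#' 20 C), two static fields (600 and 800 MHz 1H), ten effective CPMG
#' fields between 50 and 1000 Hz, and constant-time delays of 60 ms
#' (amide 15N) or 30 ms (methyl 13C).
#'
#' @param temperatures_C,fields_MHz,nu_cpmg_Hz Numeric vectors defining
#'   the grid axes.
#' @param T_relax_s Named vector of constant-time delays (s) per nucleus.
#' @return A list with the validated grid components.
#' @export
condition_grid <- function(temperatures_C = c(5, 10, 15, 20),
                           fields_MHz = c(600, 800),
                           nu_cpmg_Hz = c(50, 100, 150, 250, 350,
                                          500, 650, 800, 900, 1000),
                           T_relax_s = c("15N" = 0.06, "13C" = 0.03)) {
  if (length(temperatures_C) == 0 || length(fields_MHz) == 0 ||
      length(nu_cpmg_Hz) == 0)
    abort_input("grid axes must be non-empty")
  if (any(nu_cpmg_Hz <= 0)) abort_input("all nu_cpmg values must be > 0")
  if (any(T_relax_s <= 0)) abort_input("T_relax must be > 0")
  list(temperatures_C = sort(temperatures_C),
       fields_MHz = sort(fields_MHz),
       nu_cpmg_Hz = sort(nu_cpmg_Hz),
       T_relax_s = T_relax_s)
}

#' Default peak table for dispersion simulations
#'
#' Five exchanging peaks: four backbone amides and one methyl group,
#' with shift differences between the exchanging states in the 1.2-3 ppm
#' range typical of a side-chain rotamer flip reshaping the local
#' environment.
#'
#' @return Tibble with columns `peak_id`, `nucleus`, `dw_ppm`,
#'   `r2_base`.
#' @export
default_peaks <- function() {
  tibble::tibble(
    peak_id = c("D167N", "A169N", "K172N", "I199N", "I199CD1"),
    nucleus = c("15N", "15N", "15N", "15N", "13C"),
    dw_ppm = c(1.5, 2.0, 2.5, 3.0, 1.2),
    r2_base = c(10, 11, 9, 12, 8)
  )
}

# deterministic intrinsic R2 per (peak, field, temperature): transverse
# relaxation grows with B0 and with tumbling time (lower T)
intrinsic_r2 <- function(r2_base, field_MHz, temperature_C) {
  r2_base * (field_MHz / 800) *
    (293.15 / celsius_to_kelvin(temperature_C))
}

#' Simulate a multi-condition relaxation-dispersion dataset
#'
#' Generates one dispersion profile per (peak, field, temperature) from
#' the Carver-Richards forward model with exchange parameters tied
#' across temperature by the Eyring equation and reaction isotherm, plus
#' additive Gaussian noise on R2eff. The generating parameters are
#' attached as `attr(, "ground_truth")`.
#'
#' @param dG_act Activation free energy controlling kex, J/mol.
#' @param dG_eq Standard free energy controlling pb, J/mol.
#' @param peaks Data frame with `peak_id`, `nucleus`, `dw_ppm` and
#'   `r2_base` columns; see [default_peaks()].
#' @param grid Condition grid from [condition_grid()].
#' @param noise_sd Gaussian noise standard deviation on R2eff, 1/s
#'   (>= 0). Default 0.2.
#' @param seed Integer seed; identical arguments give identical output.
#' @return Tibble with columns `peak_id`, `nucleus`, `field_MHz`,
#'   `temperature_C`, `T_relax_s`, `nu_cpmg_Hz`, `r2eff`, `r2eff_err`.
#' @export
#' @examples
#' rd <- simulate_dispersion(noise_sd = 0, seed = 1)
#' attr(rd, "ground_truth")$dG_act
simulate_dispersion <- function(dG_act = 50228, dG_eq = 5601,
                                peaks = default_peaks(),
                                grid = condition_grid(),
                                noise_sd = 0.2, seed = 1) {
  if (noise_sd < 0) abort_input("noise_sd must be >= 0")
  if (nrow(peaks) < 1) abort_input("need at least one peak")
  if (any(peaks$dw_ppm < 0)) abort_input("dw_ppm stored as magnitude, must be >= 0")
  if (any(peaks$r2_base <= 0)) abort_input("r2_base must be > 0")

  design <- tidyr::expand_grid(
    peaks,
    field_MHz = grid$fields_MHz,
    temperature_C = grid$temperatures_C
  ) |>
    dplyr::mutate(
      T_relax_s = unname(grid$T_relax_s[.data$nucleus]),
      r2_intrinsic = intrinsic_r2(.data$r2_base, .data$field_MHz,
                                  .data$temperature_C)
    ) |>
    tidyr::expand_grid(nu_cpmg_Hz = grid$nu_cpmg_Hz)

  temps_K <- celsius_to_kelvin(design$temperature_C)
  kex <- eyring_rate(dG_act, temps_K)
  pb <- isotherm_pb(dG_eq, temps_K)
  model <- vapply(seq_len(nrow(design)), function(i) {
    carver_richards_r2eff(
      design$nu_cpmg_Hz[i], kex[i], pb[i],
      ppm_to_rad_s(design$dw_ppm[i], design$field_MHz[i],
                   design$nucleus[i]),
      design$r2_intrinsic[i])
  }, numeric(1))

  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(length(model), 0, noise_sd))
  } else rep(0, length(model))

  out <- design |>
    dplyr::mutate(r2eff = model + noise,
                  r2eff_err = pmax(noise_sd, 1e-6)) |>
    dplyr::select("peak_id", "nucleus", "field_MHz", "temperature_C",
                  "T_relax_s", "nu_cpmg_Hz", "r2eff", "r2eff_err")
  attr(out, "ground_truth") <- list(
    dG_act = dG_act, dG_eq = dG_eq,
    peaks = tibble::as_tibble(peaks),
    r2_intrinsic = dplyr::distinct(
      design, .data$peak_id, .data$field_MHz, .data$temperature_C,
      .data$r2_intrinsic),
    noise_sd = noise_sd, seed = seed
  )
  out
}

#' Simulate a monoexponential relaxation decay
#'
#' `I(t) = i0 * exp(-rate * t) + Gaussian(0, noise_sd)`.
#'
#' @param rate Decay rate, 1/s (> 0).
#' @param delays Relaxation delays, s (non-negative). Defaults to the
#'   longitudinal-relaxation delay list 0-1.2 s.
#' @param i0 Intensity at zero delay.
#' @param noise_sd Noise standard deviation in intensity units.
#' @param seed Integer seed.
#' @param residue_id,experiment,field_MHz,spinlock_Hz,offset_Hz Metadata
#'   carried into the returned series.
#' @return Tibble with columns `residue_id`, `experiment`, `field_MHz`,
#'   `spinlock_Hz`, `offset_Hz`, `delay_s`, `intensity`,
#'   `intensity_err`.
#' @export
simulate_decay <- function(rate, delays = c(0, 0.12, 0.28, 0.44, 0.64,
                                            0.8, 1.04, 1.2),
                           i0 = 1000, noise_sd = 0, seed = 1,
                           residue_id = "res1", experiment = "R1",
                           field_MHz = 800, spinlock_Hz = 1000,
                           offset_Hz = 0) {
  if (rate <= 0) abort_input("rate must be > 0")
  if (length(delays) == 0) abort_input("delays must be non-empty")
  if (any(delays < 0)) abort_input("delays must be non-negative")
  intensity <- i0 * exp(-rate * delays)
  if (noise_sd > 0)
    intensity <- intensity +
      withr::with_seed(seed, stats::rnorm(length(delays), 0, noise_sd))
  tibble::tibble(
    residue_id = residue_id, experiment = experiment,
    field_MHz = field_MHz, spinlock_Hz = spinlock_Hz,
    offset_Hz = offset_Hz, delay_s = delays,
    intensity = intensity, intensity_err = pmax(noise_sd, 1e-9)
  )
}

#' Simulate a residual dipolar coupling set from an alignment tensor
#'
#' `D_obs = D_calc(tensor, vector) + Gaussian(0, noise_sd)` with
#' [predict_rdc()] as the forward model.
#'
#' @param tensor Alignment tensor: either the 5-vector
#'   `(Szz, Syy - Sxx, Sxy, Sxz, Syz)` in Hz or an object from
#'   [saupe_from_param()].
#' @param vectors Data frame with `residue_id`, `x`, `y`, `z` unit
#'   N-H bond vectors (norm 1 within 1e-6).
#' @param noise_sd Noise standard deviation, Hz.
#' @param seed Integer seed.
#' @return Tibble with `residue_id`, `D_obs_Hz`, `D_err_Hz`.
#' @export
simulate_rdc <- function(tensor, vectors, noise_sd = 0, seed = 1) {
  norms <- sqrt(vectors$x^2 + vectors$y^2 + vectors$z^2)
  if (any(abs(norms - 1) > 1e-6))
    abort_input("bond vectors must be unit length within 1e-6")
  if (nrow(vectors) < 1) abort_input("need at least one vector")
  d <- predict_rdc(tensor, vectors)$D_calc_Hz
  if (noise_sd > 0)
    d <- d + withr::with_seed(seed, stats::rnorm(length(d), 0, noise_sd))
  tibble::tibble(residue_id = vectors$residue_id, D_obs_Hz = d,
                 D_err_Hz = pmax(noise_sd, 1e-9))
}

#' Simulate a two-state CD thermal melt
#'
#' Ellipticity at 222 nm as a linear mix of folded and unfolded
#' baselines weighted by the two-state van't Hoff unfolded fraction
#' `fu(T) = Keq/(1+Keq)`, `Keq = exp(-(dH/R)(1/T - 1/Tm))`, so the
#' unfolded fraction is exactly 1/2 at `tm_C`.
#'
#' @param tm_C Thermodynamic midpoint, C; must lie inside `T_range`.
#' @param dH_unfold van't Hoff unfolding enthalpy, J/mol (> 0); sets the
#'   transition steepness.
#' @param baseline_folded,baseline_unfolded Length-2 vectors
#'   `(intercept, slope)` of the pre- and post-transition ellipticity
#'   baselines (millidegrees vs C).
#' @param T_range Length-2 temperature span, C.
#' @param step_C Grid step, C (> 0).
#' @param noise_sd Noise standard deviation, millidegrees.
#' @param seed Integer seed.
#' @return Tibble with `temperature_C`, `theta_222`, plus the unfolded
#'   fraction `fu` (noise-free) for reference.
#' @export
simulate_melt <- function(tm_C = 54, dH_unfold = 3e5,
                          baseline_folded = c(-25, 0.02),
                          baseline_unfolded = c(-4, 0.01),
                          T_range = c(35, 75), step_C = 1,
                          noise_sd = 0, seed = 1) {
  if (step_C <= 0) abort_input("step_C must be > 0")
  if (tm_C <= min(T_range) || tm_C >= max(T_range))
    abort_input("tm_C must lie strictly inside T_range")
  if (dH_unfold <= 0) abort_input("dH_unfold must be > 0")
  temperature_C <- seq(min(T_range), max(T_range), by = step_C)
  T_K <- celsius_to_kelvin(temperature_C)
  tm_K <- celsius_to_kelvin(tm_C)
  keq <- exp(-(dH_unfold / nmr_constants$R) * (1 / T_K - 1 / tm_K))
  fu <- keq / (1 + keq)
  theta <- (1 - fu) * (baseline_folded[1] + baseline_folded[2] * temperature_C) +
    fu * (baseline_unfolded[1] + baseline_unfolded[2] * temperature_C)
  if (noise_sd > 0)
    theta <- theta +
      withr::with_seed(seed, stats::rnorm(length(theta), 0, noise_sd))
  tibble::tibble(temperature_C = temperature_C, theta_222 = theta,
                 fu = fu)
}

#' Simulate a substrate-depletion kinetics trace
#'
#' Linear initial-regime depletion of unphosphorylated substrate:
#' `[S](t) = max(s0 - v0 * t, 0) + Gaussian(0, noise_sd)`.
#'
#' @param v0 Initial velocity, uM/min (>= 0).
#' @param s0 Starting substrate concentration, uM (> 0). Default 600.
#' @param t_points Time points, min (non-negative).
#' @param noise_sd Noise standard deviation, uM.
#' @param seed Integer seed.
#' @return Tibble with `time_min`, `conc_uM`.
#' @export
simulate_kinetics <- function(v0 = 25, s0 = 600,
                              t_points = seq(0, 10, by = 1),
                              noise_sd = 0, seed = 1) {
  if (v0 < 0) abort_input("v0 must be >= 0")
  if (s0 <= 0) abort_input("s0 must be > 0")
  if (any(t_points < 0)) abort_input("time points must be non-negative")
  conc <- pmax(s0 - v0 * t_points, 0)
  if (noise_sd > 0)
    conc <- conc +
      withr::with_seed(seed, stats::rnorm(length(conc), 0, noise_sd))
  tibble::tibble(time_min = t_points, conc_uM = conc)
}
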