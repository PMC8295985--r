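# Free-energy <-> rate/population conversions and temperature regressions.
#
# The two-site exchange a <-> b is parameterized by an activation free
# energy dG_act (controls kex = kab + kba through the Eyring equation,
# transmission coefficient 1) and a standard free energy dG_eq (controls
# the minor-state population through the reaction isotherm). All energies
# are J/mol internally; kJ appears only in presentation helpers.

#' Eyring rate from an activation free energy
#'
#' `k = (kB*T/h) * exp(-dG_act / (R*T))` with transmission coefficient 1.
#'
#' @param dG_act Activation free energy in J/mol.
#' @param temperature_K Absolute temperature(s) in K.
#' @return Rate constant(s) in 1/s.
#' @seealso [eyring_dG()] for the inverse.
#' @export
#' @examples
#' eyring_rate(50228, 278.15)
eyring_rate <- function(dG_act, temperature_K) {
  if (any(temperature_K <= 0)) abort_input("temperature_K must be > 0")
  with(nmr_constants, kB * temperature_K / h *
         exp(-dG_act / (R * temperature_K)))
}

#' Activation free energy from a rate (inverse Eyring)
#'
#' @param k Rate constant(s) in 1/s.
#' @inheritParams eyring_rate
#' @return dG_act in J/mol.
#' @export
eyring_dG <- function(k, temperature_K) {
  if (any(temperature_K <= 0)) abort_input("temperature_K must be > 0")
  if (any(k <= 0)) abort_input("k must be > 0")
  with(nmr_constants, -R * temperature_K *
         log(k * h / (kB * temperature_K)))
}

#' Minor-state population from the reaction isotherm
#'
#' `Keq = exp(-dG_eq/(R*T))`, `pb = Keq / (1 + Keq)`. A positive `dG_eq`
#' yields `pb < 0.5` (state b is the minor state).
#'
#' @param dG_eq Standard free energy of the a -> b equilibrium in J/mol.
#' @inheritParams eyring_rate
#' @return Fraction(s) in (0, 1).
#' @export
#' @examples
#' isotherm_pb(5601, 278.15) # ~0.082
isotherm_pb <- function(dG_eq, temperature_K) {
  if (any(temperature_K <= 0)) abort_input("temperature_K must be > 0")
  keq <- exp(-dG_eq / (nmr_constants$R * temperature_K))
  keq / (1 + keq)
}

#' Standard free energy from a minor-state population (inverse isotherm)
#'
#' @param pb Minor-state fraction(s), in (0, 1).
#' @inheritParams eyring_rate
#' @return dG_eq in J/mol.
#' @export
isotherm_dG <- function(pb, temperature_K) {
  if (any(pb <= 0 | pb >= 1)) abort_input("pb must lie in (0, 1)")
  -nmr_constants$R * temperature_K * log(pb / (1 - pb))
}

#' Rate table from global free energies
#'
#' Expands the two global free energies into per-temperature exchange
#' parameters: `kex` from the Eyring equation, `pb` from the isotherm,
#' and the forward/backward microscopic rates `kab = pb*kex`,
#' `kba = (1-pb)*kex` (so `kab + kba = kex` by construction).
#'
#' @param dG_act Activation free energy, J/mol.
#' @param dG_eq Standard free energy, J/mol.
#' @param temperature_K Vector of absolute temperatures.
#' @return A tibble with columns `temperature_K`, `temperature_C`, `kex`,
#'   `pb`, `kab`, `kba`.
#' @export
#' @examples
#' derive_rate_table(50228, 5601, 273.15 + c(5, 10, 15, 20))
derive_rate_table <- function(dG_act, dG_eq, temperature_K) {
  kex <- eyring_rate(dG_act, temperature_K)
  pb <- isotherm_pb(dG_eq, temperature_K)
  tibble::tibble(
    temperature_K = temperature_K,
    temperature_C = temperature_K - nmr_constants$celsius_offset,
    kex = kex, pb = pb,
    kab = pb * kex, kba = (1 - pb) * kex
  )
}

#' Eyring regression of a temperature series of rate constants
#'
#' Ordinary least squares on the linearized Eyring equation
#' `ln(k*h/(kB*T)) = -dH_act/(R*T) + dS_act/R`, yielding the activation
#' enthalpy and entropy with standard errors propagated from the
#' regression covariance.
#'
#' @param k Rate constants (1/s), one per temperature.
#' @param temperature_K Matching absolute temperatures (>= 2 distinct).
#' @return One-row tibble with `dH_act_J_mol`, `dH_act_se`,
#'   `dS_act_J_K_mol`, `dS_act_se`, `r_squared`, `n`.
#' @export
#' @examples
#' eyring_fit(c(171, 265, 406, 613), 273.15 + c(5, 10, 15, 20))
eyring_fit <- function(k, temperature_K) {
  if (length(k) != length(temperature_K))
    abort_input("k and temperature_K must have equal length")
  if (length(unique(temperature_K)) < 2)
    abort_input("need >= 2 distinct temperatures")
  if (any(k <= 0)) abort_input("rate constants must be > 0")
  y <- log(k * nmr_constants$h / (nmr_constants$kB * temperature_K))
  x <- 1 / temperature_K
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(suppressWarnings(summary(fit)))
  tibble::tibble(
    dH_act_J_mol = -cf["x", "Estimate"] * nmr_constants$R,
    dH_act_se = cf["x", "Std. Error"] * nmr_constants$R,
    dS_act_J_K_mol = cf["(Intercept)", "Estimate"] * nmr_constants$R,
    dS_act_se = cf["(Intercept)", "Std. Error"] * nmr_constants$R,
    r_squared = suppressWarnings(summary(fit))$r.squared,
    n = length(k)
  )
}

#' van't Hoff regression of a temperature series of populations
#'
#' Converts populations to equilibrium constants `Keq = pb/(1-pb)` and
#' regresses `ln Keq = -dH/(R*T) + dS/R` by ordinary least squares.
#'
#' @param pb Minor-state fractions in (0, 1), one per temperature.
#' @inheritParams eyring_fit
#' @return One-row tibble with `dH_J_mol`, `dH_se`, `dS_J_K_mol`,
#'   `dS_se`, `r_squared`, `n`.
#' @export
vant_hoff_fit <- function(pb, temperature_K) {
  if (length(pb) != length(temperature_K))
    abort_input("pb and temperature_K must have equal length")
  if (any(pb <= 0 | pb >= 1)) abort_input("pb must lie in (0, 1)")
  if (length(unique(temperature_K)) < 2)
    abort_input("need >= 2 distinct temperatures")
  y <- log(pb / (1 - pb))
  x <- 1 / temperature_K
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(suppressWarnings(summary(fit)))
  tibble::tibble(
    dH_J_mol = -cf["x", "Estimate"] * nmr_constants$R,
    dH_se = cf["x", "Std. Error"] * nmr_constants$R,
    dS_J_K_mol = cf["(Intercept)", "Estimate"] * nmr_constants$R,
    dS_se = cf["(Intercept)", "Std. Error"] * nmr_constants$R,
    r_squared = suppressWarnings(summary(fit))$r.squared,
    n = length(pb)
  )
}
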