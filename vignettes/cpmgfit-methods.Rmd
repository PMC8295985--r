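---
title: "Methods: global thermodynamic analysis of CPMG relaxation dispersion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: global thermodynamic analysis of CPMG relaxation dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmgfit)
```

## The model

A protein nucleus exchanging between two conformations a (major) and b
(minor) contributes an exchange term to its effective transverse
relaxation rate. In a constant-time CPMG experiment, R2eff measured as a
function of the refocusing frequency νCPMG traces a dispersion profile
whose shape encodes three quantities per condition: the exchange rate
constant kex = kab + kba, the minor-state population pb, and the
chemical-shift difference Δω between the states. `cpmgfit` evaluates the
profile with the Carver–Richards closed form for equal intrinsic rates
in the two states,

R2eff(ν) = R2⁰ + kex/2 − ν · acosh[ D₊ cosh(η₊) − D₋ cos(η₋) ],

with ψ = kex² − Δω², ζ = −2Δω·kex·(pa − pb),
D± = ½[±1 + (ψ + 2Δω²)/√(ψ² + ζ²)] and
η± = √(±ψ + √(ψ² + ζ²)) / (2√2·ν).

The package's central inference (`fit_dispersion()`) does not fit kex
and pb per temperature. Instead, every temperature's exchange parameters
are derived from two global free energies:

- kex(T) = (kB·T/h) · exp(−Δ‡G/(R·T))  (Eyring, transmission
  coefficient 1), and
- pb(T) = Keq/(1 + Keq) with Keq = exp(−ΔG/(R·T))  (reaction isotherm),

so that all dispersion profiles — every peak, static field and
temperature — are fit simultaneously with parameters Δ‡G, ΔG, one |Δω|
per peak, and one intrinsic rate R2⁰ per (peak, field, temperature).
For 5 peaks and 4 temperatures this reduces the exchange-parameter count
from 28 (kex, pb and Δω per peak at each temperature) to 7
(`count_parameters()`), at the cost of assuming a temperature-independent
activation heat capacity over the 5–20 °C window. The forward and
backward microscopic rates follow as kab = pb·kex and kba = (1 − pb)·kex,
and their temperature series can be re-regressed with `eyring_fit()` and
`vant_hoff_fit()` to express the same information as activation and
standard enthalpies/entropies.

The assumption of one intrinsic rate shared by states a and b mirrors
the usual practice of optimizing a single peak-specific intrinsic rate;
the two-state symmetry of the closed form (pb → 1 − pb, Δω → −Δω) makes
the states' relabeling unobservable, which is also why Δω is fitted as a
magnitude — dispersion data carry no sign information.

## The numerical oracle

`bloch_mcconnell_r2eff()` provides an independent check on the closed
form. Transverse magnetization of the two sites evolves under the 2×2
complex matrix combining relaxation, exchange and the offset Δω; ideal
180° pulses act as complex conjugation; the constant-time delay T is
divided into n = round(ν·T) blocks of two δ–180–δ echoes with
δ = T/(4n).

A propagated signal differs from the closed form in one respect: the
closed form is the decay rate of the slowly decaying eigenmode of the
echo-train propagator, whereas a single-delay signal ratio
−ln(S(T)/S(0))/T also contains the projection amplitude of the initial
condition onto that mode. The amplitude term is a genuine property of
the finite experiment; it is negligible in intermediate-to-fast exchange
but reaches a few percent of R2eff deep in slow exchange. The default
readout (`"rate"`) therefore propagates through a second identical train
and reports −ln(S(2T)/S(T))/T, which cancels the transient exactly and
isolates the steady-state rate the closed form describes; with it, the
closed form and the propagation agree to better than 0.5% (in practice,
to near machine precision) across kex ∈ [10³, 10⁴] s⁻¹, pb ∈
[0.05, 0.12], Δω ∈ [0.5, 5] ppm at both 600 and 800 MHz, and the value
is insensitive to the choice of T. The literal single-delay readout is
retained as `readout = "signal"` and its deviation is itself tested.

## Optimization

The intrinsic rates enter the model additively, so their conditional
least-squares optimum given the exchange parameters is the weighted mean
residual of each profile. `fit_dispersion()` exploits this (variable
projection): the Levenberg–Marquardt search runs only over
(Δ‡G, ΔG, Δω₁…Δωₙ), and the intrinsic rates are recovered in closed form
at every objective evaluation. This keeps a 47-parameter problem
(5 peaks × 8 conditions) in a 7-dimensional search space and makes the
fit fast enough for multistart and Monte-Carlo error estimation.

Numerical choices, all tested:

- **Bounds.** Δ‡G ∈ [30, 80] kJ/mol, ΔG ∈ [0.5, 20] kJ/mol, Δω ∈
  [1, 20] ppm for ¹⁵N (the ≥ 1 ppm restraint aids convergence and is
  configurable via `dw_lower_ppm_15N`) and [0, 20] ppm for ¹³C.
- **Multistart.** Default 10 seeded starts: the first is a heuristic
  (center of the bounds plus per-peak Δω guesses from the fast-exchange
  relation Rex ≈ pa·pb·Δω²/kex applied to the observed profile
  amplitudes), the rest randomize Δ‡G ∈ [45, 60] kJ/mol, ΔG ∈
  [2, 10] kJ/mol and jitter the Δω guesses. The best converged start by
  objective wins; ties break toward the lowest start index, so results
  are reproducible for a fixed seed.
- **Tolerances.** Relative objective tolerance 1e-10 and parameter
  tolerance 1e-8 in the optimizer.
- **Degenerate arguments.** The acosh argument is clamped at 1 with a
  warning when round-off pushes it below (flat-dispersion regime), and
  for η₊ > 350 — where cosh would overflow — the exact asymptotic
  acosh(x) → log 2x branch is used, keeping the objective finite at very
  low νCPMG.
- **Uncertainties.** Covariance-based standard errors (Gauss–Newton
  J'J inverse scaled by reduced χ²) are always reported;
  `estimate_errors()` adds parametric Monte-Carlo resampling (best-fit
  curve plus Gaussian noise at each point's σ, refit per replicate).
  Missing or non-positive σ fall back to 1 with a message.

## What the simulators emulate — and what they do not

`simulate_dispersion()` generates data under exactly the model the fit
assumes: Carver–Richards profiles on a grid of 4 temperatures (5–20 °C),
2 fields (600/800 MHz), 10 νCPMG values (50–1000 Hz), with constant-time
delays of 60 ms (¹⁵N) and 30 ms (¹³C-methyl), additive Gaussian noise on
R2eff (default σ = 0.2 s⁻¹ — a typical per-point uncertainty for
well-resolved peaks; the choice is a package default, since per-point
errors are rarely published), and intrinsic rates that grow with B₀ and
with tumbling time (lower T) through a fixed deterministic rule. The
generating parameters travel with the dataset as the `ground_truth`
attribute, so recovery tests need no side channel, and all generators
are pure functions of their arguments including the seed.

Because generator and fit share one forward model, passing recovery
tests demonstrates the correctness and conditioning of the inference,
not its robustness to real-data pathologies: peak overlap, off-resonance
and finite-pulse-width effects, temperature-dependent sample conditions,
or deviations from two-state behavior are all outside the generator's
scope. The same applies to the reported parameter uncertainties: on the
default synthetic grid they are an order of magnitude tighter than
uncertainties quoted for comparable experimental datasets, which reflect
sparser sampling and model error the generator deliberately omits.

The melt simulator uses a two-state van't Hoff population with linear
folded/unfolded baselines — the minimal model with a well-defined
thermodynamic midpoint — because the Tm readout (`extract_tm()`) is
defined as the derivative maximum, not as a fit to any unfolding model.
With ΔH_unfold = 300 kJ/mol the transition is steep enough that the
derivative maximum coincides with the midpoint to within the grid step.
The kinetics simulator produces the linear initial-regime depletion that
`initial_velocity()` inverts; curvature from substrate exhaustion is
intentionally not modeled, and truncating real traces to the initial
regime (< 15% depletion) is the caller's responsibility.

## Supporting analyses

- **Relaxation (ps–ns).** `fit_exponential_decay()` fits
  I(t) = I₀e^{−Rt} by Levenberg–Marquardt with a log-linear start;
  `r2_from_r1rho()` applies the tilt-angle correction
  R2 = (R1ρ − R1 cos²θ)/sin²θ with tanθ = ω₁/Ω, defaulting to the
  on-resonance approximation (with a notice) when offsets are absent;
  `tau_c_estimate()` evaluates τc ≈ √(6·R2/R1 − 7)/(4π·ν_N). Residues
  with enhanced local flexibility depress R2/R1, so
  `trimmed_mean_r2_r1()` excludes ratios more than 1.5 SD below the
  median (single pass) before averaging — the exclusion depth is
  configurable because no standard rule exists.
- **CSP.** `csp()` implements the weighted combination
  √((ΔδH·1)² + (ΔδN·0.154)²); `classify_significant()` applies a strict
  threshold (default 0.3 ppm). Residues missing in either state are
  skipped, never imputed. Random-coil Cα references for
  `compare_secondary_shifts()` are user-supplied per residue.
- **RDC.** The dipolar prefactor is absorbed into the Saupe elements so
  tensors are reported in Hz; `svd_fit_rdc()` solves the 5-column
  orientation design by SVD pseudoinverse (rank guarded at a 1e-8
  condition threshold), reports Da, rhombicity (|R| ≤ 2/3) and z-y-z
  Euler angles, and scores agreement with
  R = √(⟨(D_obs − D_calc)²⟩ / 2⟨D_obs²⟩). Residue matching is by id;
  unmatched entries are reported, never dropped silently.
- **Unit conventions.** °C → K uses 273.15 exactly; Δω converts from
  ppm as Δω = Δδ·10⁻⁶·2π·ν_nucleus with ν_nucleus = field × 0.10136767
  (¹⁵N) or × 0.25145002 (¹³C), fixed in `nmr_constants`; all energies
  are J/mol internally with kJ only in presentation; νCPMG = n/T_relax
  with n refocusing blocks, and non-integer n·T products are rounded
  with a warning.

## Problem sizes and reproducibility

The default synthetic study — 5 peaks × 2 fields × 4 temperatures × 10
νCPMG points (400 data) with σ = 0.2 s⁻¹ — is the scale at which all
recovery properties are asserted: the 7-parameter fit of model-true data
attains reduced χ² in [0.5, 1.5], recovers the free energies within the
reference uncertainties (±227 J/mol for Δ‡G, ±330 J/mol for ΔG), and the
median recovery error over 20 seeded replicates stays below
300/400 J/mol. `run_pipeline()` derives per-stage seeds from one global
seed through a fixed splitting rule, so stage outputs are individually
reproducible and a rerun with the same inputs is byte-identical.

## Known limitations

Three-site or multi-quantum dispersion, off-resonance R1ρ dispersion and
finite-pulse-width corrections are out of scope, as are model selection
between exchange models and full model-free analysis of the relaxation
rates. The two-state melt and linear kinetics models are deliberately
minimal (see above). Quantitative fitting of dispersion-free
(suppressed-exchange) datasets is not attempted beyond the Rex screening
threshold: such fits are degenerate and are flagged as warnings instead.
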