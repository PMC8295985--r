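# cpmgfit

Global thermodynamic analysis of CPMG relaxation-dispersion data, with
the supporting solution-NMR and biophysical readouts that accompany a
conformational-exchange study: R1/R1ρ relaxation and rotational
correlation times, chemical-shift perturbation mapping, residual
dipolar coupling (RDC) analysis by SVD, CD melting temperatures and
enzymatic initial velocities. It is written for NMR spectroscopists and
structural biologists quantifying microsecond–millisecond exchange —
for example, the rotamer flip of an active-site histidine that gates
phosphorylation — and for anyone who wants a tested, simulation-backed
reference implementation of these standard computations.

## The model

A nucleus exchanging between a major state a and a minor state b adds a
νCPMG-dependent term to its effective transverse relaxation rate. Each
dispersion profile is evaluated with the Carver–Richards closed form
(equal intrinsic rates in the two states):

    R2eff(ν) = R2⁰ + kex/2 − ν · acosh[D₊ cosh η₊ − D₋ cos η₋]

    ψ  = kex² − Δω²            ζ  = −2 Δω kex (pa − pb)
    D± = ½[±1 + (ψ + 2Δω²)/√(ψ² + ζ²)]
    η± = √(±ψ + √(ψ² + ζ²)) / (2√2 ν)

The distinctive step is the *global* fit: instead of independent
(kex, pb, Δω) at every temperature, all profiles across peaks, static
fields and temperatures are fit simultaneously with

    kex(T) = (kB T / h) · exp(−Δ‡G / RT)        (Eyring)
    pb(T)  = Keq / (1 + Keq),  Keq = exp(−ΔG / RT)   (reaction isotherm)

so the free parameters are two free energies, one |Δω| per peak, and
one intrinsic rate per (peak, field, temperature). For 5 peaks at 4
temperatures this cuts the exchange-parameter count from 28 to 7. A
numerical Bloch–McConnell propagator (`bloch_mcconnell_r2eff()`) serves
as an independent oracle for the closed form, and every estimator in
the package has a seeded simulator that generates data with known
ground truth. The methods vignette
(`vignettes/cpmgfit-methods.Rmd`) documents the model, the numerical
choices and the simulators' scope.

## Worked example

Simulate the default study — 5 exchanging peaks, 600 and 800 MHz,
5/10/15/20 °C, ten νCPMG values from 50–1000 Hz, Gaussian noise of
0.2 s⁻¹ on R2eff — and run the global fit:

```r
library(cpmgfit)

rd  <- simulate_dispersion(dG_act = 50228, dG_eq = 5601,
                           noise_sd = 0.2, seed = 42)
fit <- fit_dispersion(rd, multistart = 5, seed = 42)
fit
#> Global two-site exchange fit (thermodynamically tied)
#>   5 peaks, 400 data points, chi2 = 329.8 (reduced 0.934)
#>   dG_act = 50220 J/mol, dG_eq = 5639 J/mol
#>   rate table:
#>  temperature_K temperature_C  kex      pb   kab  kba
#>          278.1             5 2149 0.08030 172.6 1977
#>          283.1            10 3211 0.08354 268.2 2942
#>          288.1            15 4731 0.08678 410.5 4320
#>          293.1            20 6882 0.09001 619.4 6262
```

The fit recovers the generating free energies (50,228 and 5,601 J/mol)
within a few tens of J/mol; the reduced χ² near 1 says the
thermodynamic tying introduces no misfit on model-true data. The rate
table expands the two free energies into per-temperature kex and pb and
the microscopic rates kab = pb·kex, kba = (1 − pb)·kex, whose
temperature dependence `eyring_fit()`/`vant_hoff_fit()` convert to
activation and standard enthalpies and entropies. `tidy(fit)`,
`glance(fit)`, `augment(fit)` and `autoplot(fit)` give the parameter
table with uncertainties, the one-row fit summary, per-point fitted
values, and the dispersion-profile figure.

The companion readouts follow the same data-frame-in, tibble-out
pattern:

```r
extract_tm(simulate_melt(tm_C = 54))
#> # A tibble: 1 × 3
#>    tm_C dtheta_max flag
#>   <dbl>      <dbl> <chr>
#> 1    54       1.72 ok

initial_velocity(simulate_kinetics(v0 = 25, noise_sd = 5, seed = 2))
#> # A tibble: 1 × 4
#>   v0_uM_min v0_se intercept_uM     n
#>       <dbl> <dbl>        <dbl> <int>
#> 1      24.6 0.450         599.    11
```

`run_pipeline()` binds all stages (dispersion fit, relaxation/τc, CSP,
RDC/SVD, melt, kinetics) behind one seeded configuration and writes a
JSON report plus per-stage TSVs.

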