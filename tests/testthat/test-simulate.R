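test_that("zero-noise dispersion data lie exactly on the forward model", {
  rd <- simulate_dispersion(noise_sd = 0, seed = 3)
  truth <- attr(rd, "ground_truth")
  rows <- rd[c(1, 57, 200, 399), ]
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    pk <- truth$peaks[truth$peaks$peak_id == r$peak_id, ]
    r2i <- truth$r2_intrinsic
    r2i <- r2i$r2_intrinsic[r2i$peak_id == r$peak_id &
                              r2i$field_MHz == r$field_MHz &
                              r2i$temperature_C == r$temperature_C]
    T_K <- celsius_to_kelvin(r$temperature_C)
    expect_equal(
      r$r2eff,
      carver_richards_r2eff(
        r$nu_cpmg_Hz, eyring_rate(truth$dG_act, T_K),
        isotherm_pb(truth$dG_eq, T_K),
        ppm_to_rad_s(pk$dw_ppm, r$field_MHz, pk$nucleus), r2i),
      tolerance = 1e-12)
  }
})

test_that("the default design yields 5 peaks x 2 fields x 4 temperatures", {
  rd <- simulate_dispersion(dG_act = 50228, dG_eq = 5601, noise_sd = 0)
  profiles <- dplyr::distinct(rd, peak_id, field_MHz, temperature_C)
  expect_equal(nrow(profiles), 40)
  expect_equal(nrow(rd), 40 * 10)
  # generated rates are finite and positive everywhere
  expect_true(all(is.finite(rd$r2eff)) && all(rd$r2eff > 0))
})

test_that("simulators are pure functions of their seed", {
  expect_identical(simulate_dispersion(noise_sd = 0.2, seed = 11),
                   simulate_dispersion(noise_sd = 0.2, seed = 11))
  expect_false(identical(simulate_dispersion(noise_sd = 0.2, seed = 11),
                         simulate_dispersion(noise_sd = 0.2, seed = 12)))
  expect_identical(simulate_melt(noise_sd = 0.5, seed = 4),
                   simulate_melt(noise_sd = 0.5, seed = 4))
  expect_identical(simulate_decay(1, noise_sd = 5, seed = 9),
                   simulate_decay(1, noise_sd = 5, seed = 9))
  # seeded draws do not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_dispersion(noise_sd = 0.2, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("decay series follow I0*exp(-R*t) and refit exactly", {
  d <- simulate_decay(1.0, delays = c(0, 0.5, 1, 1.5, 2), i0 = 1000)
  expect_equal(d$intensity[1], 1000)
  expect_equal(d$intensity[3], 367.8794, tolerance = 1e-6)
  fit <- fit_exponential_decay(d)
  expect_equal(fit$rate, 1.0, tolerance = 1e-9)
  expect_error(simulate_decay(-1, c(0, 1)), class = "cpmgfit_input_error")
  expect_error(simulate_decay(1, numeric(0)), class = "cpmgfit_input_error")
})

test_that("RDC simulation matches the axially symmetric closed form", {
  tensor <- saupe_from_param(Da = 10, rhombicity = 0)
  v <- tibble::tibble(residue_id = 1:2, x = c(0, 1), y = c(0, 0),
                      z = c(1, 0))
  d <- simulate_rdc(tensor, v)
  expect_equal(d$D_obs_Hz[1], 2 * 10)   # theta = 0: D = 2*Da
  expect_equal(d$D_obs_Hz[2], -10)      # theta = 90 deg: D = -Da
  expect_error(
    simulate_rdc(tensor, tibble::tibble(residue_id = 1, x = 2, y = 0,
                                        z = 0)),
    class = "cpmgfit_input_error")
})

test_that("noise-free RDCs round-trip through the SVD fit", {
  tensor <- saupe_from_param(Da = 8, rhombicity = 0.4)
  v <- unit_vectors(12, seed = 5)
  fit <- svd_fit_rdc(simulate_rdc(tensor, v), v)
  expect_equal(fit$saupe, tensor, tolerance = 1e-8)
  expect_equal(fit$r_factor, 0, tolerance = 1e-8)
})

test_that("melt curves have a two-state midpoint and enthalpy-set slope", {
  m <- simulate_melt(tm_C = 54, T_range = c(35, 75), step_C = 0.5)
  expect_equal(m$fu[m$temperature_C == 54], 0.5, tolerance = 1e-12)
  expect_lt(abs(extract_tm(m)$tm_C - 54), 0.5 + 1e-9)
  steep <- function(dh) max(abs(diff(
    simulate_melt(tm_C = 54, dH_unfold = dh)$theta_222)))
  expect_gt(steep(4e5), steep(2e5))
  expect_error(simulate_melt(tm_C = 80, T_range = c(35, 75)),
               class = "cpmgfit_input_error")
})

test_that("kinetics traces deplete linearly and refit their velocity", {
  k <- simulate_kinetics(v0 = 25, s0 = 600)
  expect_equal(k$conc_uM[k$time_min == 0], 600)
  expect_equal(initial_velocity(k)$v0_uM_min, 25, tolerance = 1e-9)
  flat <- simulate_kinetics(v0 = 0)
  expect_equal(initial_velocity(flat)$v0_uM_min, 0)
  expect_error(simulate_kinetics(v0 = 25, t_points = c(-1, 0, 1)),
               class = "cpmgfit_input_error")
})
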