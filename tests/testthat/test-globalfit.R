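test_that("parameter bookkeeping reflects the thermodynamic tying", {
  expect_equal(count_parameters(5, 4, "per-temperature"), 28L)
  expect_equal(count_parameters(5, 4, "global"), 7L)
  expect_equal(count_parameters(1, 1, "global"), 3L)
  expect_equal(count_parameters(1, 1, "per-temperature"), 3L)
  expect_error(count_parameters(0, 4), class = "cpmgfit_input_error")
})

truth_dw <- c(A169N = 2.0, D167N = 1.5, I199CD1 = 1.2, I199N = 3.0,
              K172N = 2.5)

test_that("the chi-square objective has the expected structure", {
  rd <- simulate_dispersion(noise_sd = 0, seed = 2)
  truth <- attr(rd, "ground_truth")
  r2int <- truth$r2_intrinsic
  # sigma floors at 1e-6 on noise-free data, so round-off residuals are
  # amplified a millionfold; the objective is still numerically zero
  chi0 <- rd_objective(rd, truth$dG_act, truth$dG_eq, truth_dw, r2int)
  expect_lt(chi0, 1e-8)
  # moving dG_act off the truth strictly increases the objective
  expect_gt(rd_objective(rd, truth$dG_act + 500, truth$dG_eq, truth_dw,
                         r2int), chi0 + 1)
  # additivity: duplicating every data point doubles chi2
  noisy <- simulate_dispersion(noise_sd = 0.2, seed = 2)
  chi1 <- rd_objective(noisy, truth$dG_act, truth$dG_eq, truth_dw, r2int)
  chi2 <- rd_objective(dplyr::bind_rows(noisy, noisy), truth$dG_act,
                       truth$dG_eq, truth_dw, r2int)
  expect_equal(chi2, 2 * chi1, tolerance = 1e-12)
  expect_error(rd_objective(rd, 50228, 5601, truth_dw[1:2]),
               class = "cpmgfit_input_error")
})

test_that("the global fit recovers noise-free parameters to < 0.1%", {
  rd <- simulate_dispersion(noise_sd = 0, seed = 7)
  fit <- fit_dispersion(rd, multistart = 2, seed = 7)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_lt(abs(est["dG_act"] - 50228) / 50228, 1e-3)
  expect_lt(abs(est["dG_eq"] - 5601) / 5601, 1e-3)
  for (pk in names(truth_dw)) {
    expect_lt(abs(est[paste0("dw_ppm_", pk)] - truth_dw[pk]) /
                truth_dw[pk], 1e-3)
  }
  expect_lt(fit$chi2, 1e-6)
  # intrinsic rates recovered too
  truth_r2 <- attr(rd, "ground_truth")$r2_intrinsic
  merged <- dplyr::inner_join(
    fit$r2_intrinsic, truth_r2,
    by = c("peak_id", "field_MHz", "temperature_C"))
  expect_equal(merged$r2_intrinsic.x, merged$r2_intrinsic.y,
               tolerance = 1e-4)
})

test_that("noisy-data recovery sits within the reference uncertainties", {
  rd <- simulate_dispersion(noise_sd = 0.2, seed = 101)
  fit <- fit_dispersion(rd, multistart = 3, seed = 101)
  expect_lt(abs(fit$params$estimate[1] - 50228), 227)
  expect_lt(abs(fit$params$estimate[2] - 5601), 330)
  # the tying does not bias a model-true fit: reduced chi2 near 1
  expect_gt(fit$chi2_reduced, 0.5)
  expect_lt(fit$chi2_reduced, 1.5)
})

test_that("median recovery error over seeded replicates is small", {
  errs <- vapply(1:20, function(s) {
    d <- simulate_dispersion(noise_sd = 0.2, seed = 300 + s)
    f <- fit_dispersion(d, multistart = 2, seed = s)
    c(abs(f$params$estimate[1] - 50228),
      abs(f$params$estimate[2] - 5601))
  }, numeric(2))
  expect_lt(median(errs[1, ]), 300)
  expect_lt(median(errs[2, ]), 400)
})

test_that("the fit is invariant to row order", {
  rd <- simulate_dispersion(noise_sd = 0.2, seed = 13)
  shuffled <- rd[withr::with_seed(1, sample(nrow(rd))), ]
  f1 <- fit_dispersion(rd, multistart = 2, seed = 5)
  f2 <- fit_dispersion(shuffled, multistart = 2, seed = 5)
  expect_equal(f1$params$estimate, f2$params$estimate, tolerance = 1e-8)
})

test_that("a single-temperature dataset still identifies the free energies", {
  rd <- simulate_dispersion(
    noise_sd = 0, seed = 1,
    grid = condition_grid(temperatures_C = 10))
  fit <- fit_dispersion(rd, multistart = 2, seed = 1)
  expect_equal(nrow(fit$rate_table), 1)
  expect_equal(fit$rate_table$temperature_C, 10)
  expect_lt(abs(fit$params$estimate[1] - 50228) / 50228, 1e-3)
  expect_lt(abs(fit$params$estimate[2] - 5601) / 5601, 1e-3)
})

test_that("a dispersion-free dataset triggers the degenerate-fit warning", {
  rd <- simulate_dispersion(dG_eq = 19000, noise_sd = 0, seed = 1,
                            peaks = default_peaks()[1:2, ],
                            grid = condition_grid(temperatures_C = 10))
  w <- capture_warnings(try(fit_dispersion(rd, multistart = 1, seed = 1),
                            silent = TRUE))
  expect_true(any(grepl("degenerate", w)))
})

test_that("Monte-Carlo uncertainties behave like sampling errors", {
  rd <- simulate_dispersion(noise_sd = 0.2, seed = 17)
  fit <- fit_dispersion(rd, multistart = 2, seed = 17)
  mc <- estimate_errors(fit, replicates = 12, seed = 1)
  expect_true(all(mc$std_error_mc > 0))
  # quadrupling the data shrinks uncertainties about twofold
  rd4 <- dplyr::bind_rows(lapply(0:3, function(k)
    simulate_dispersion(noise_sd = 0.2, seed = 17 + 1000 * k)))
  fit4 <- fit_dispersion(rd4, multistart = 2, seed = 17)
  mc4 <- estimate_errors(fit4, replicates = 12, seed = 1)
  ratio <- mc$std_error_mc[1:2] / mc4$std_error_mc[1:2]
  expect_true(all(ratio > 1.3 & ratio < 3.1))
  # zero-noise data yield (near-)zero uncertainties
  rd0 <- simulate_dispersion(noise_sd = 0, seed = 17)
  rd0$r2eff_err <- 1e-6
  fit0 <- fit_dispersion(rd0, multistart = 1, seed = 17)
  mc0 <- estimate_errors(fit0, replicates = 5, seed = 1)
  expect_lt(max(mc0$std_error_mc[1:2]), 1)
  expect_warning(estimate_errors(fit, replicates = 1), "disabled")
})

test_that("broom-style accessors expose the fit", {
  rd <- simulate_dispersion(noise_sd = 0, seed = 7)
  fit <- fit_dispersion(rd, multistart = 1, seed = 7)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std_error"))
  expect_equal(nrow(td), 7)
  gl <- glance(fit)
  expect_equal(gl$n_params, 7L)
  expect_equal(gl$n_params_total, 7L + 40L)
  expect_equal(gl$n_data, 400L)
  au <- augment(fit)
  expect_true(all(c(".fitted", ".resid") %in% names(au)))
  expect_equal(au$r2eff - au$.resid, au$.fitted, tolerance = 1e-12)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
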