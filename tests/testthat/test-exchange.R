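dw_2ppm_800 <- ppm_to_rad_s(2, 800, "15N")

test_that("Carver-Richards reduces to the intrinsic rate without exchange", {
  nu <- c(50, 200, 1000)
  expect_equal(carver_richards_r2eff(nu, 3000, 0, dw_2ppm_800, 10),
               rep(10, 3))
  expect_equal(carver_richards_r2eff(nu, 3000, 0.08, 0, 10), rep(10, 3))
})

test_that("Carver-Richards matches frozen Bloch-McConnell values", {
  # kex = 3162/s, pb = 0.084, dw = 2 ppm 15N at 800 MHz, R2 = 10/s
  cr <- carver_richards_r2eff(c(50, 1000), 3162, 0.084, dw_2ppm_800, 10)
  expect_equal(cr[1], 32.29963, tolerance = 1e-6)
  expect_equal(cr[2], 14.18898, tolerance = 1e-6)
  # low-nu exchange contribution near the fast-exchange estimate
  # pa*pb*dw^2/kex = 25.27/s (kex/dw ~ 3: moderately fast regime)
  expect_equal(cr[1] - 10, 25.27, tolerance = 0.15)
  # high-nu residual nearly refocused
  expect_lt(cr[2] - 10, 5)
})

test_that("R2eff never increases with the CPMG field in the fitted regime", {
  # in deep slow exchange (kex well below dw) dispersion profiles are
  # genuinely non-monotone; the invariant applies to the intermediate
  # regime the fits inhabit
  grid <- expand.grid(kex = c(2117, 3162, 6859),
                      pb = c(0.05, 0.09, 0.12),
                      dw_ppm = c(0.5, 2, 3, 5))
  nu <- seq(25, 2000, by = 25)
  for (i in seq_len(nrow(grid))) {
    r <- carver_richards_r2eff(
      nu, grid$kex[i], grid$pb[i],
      ppm_to_rad_s(grid$dw_ppm[i], 800, "15N"), 10)
    expect_true(all(diff(r) <= 1e-9))
    expect_true(all(r >= 10 - 1e-9))
  }
})

test_that("R2eff is symmetric under state relabeling", {
  nu <- c(50, 150, 500, 1000)
  expect_equal(
    carver_richards_r2eff(nu, 3162, 0.084, dw_2ppm_800, 10),
    carver_richards_r2eff(nu, 3162, 1 - 0.084, -dw_2ppm_800, 10),
    tolerance = 1e-12)
})

test_that("Rex scales quadratically with dw in fast exchange", {
  rex0 <- function(dw, kex)
    carver_richards_r2eff(10, kex, 0.1, dw, 10) -
      carver_richards_r2eff(1e5, kex, 0.1, dw, 10)
  ratio <- rex0(2000, 20000) / rex0(1000, 20000)
  expect_equal(ratio, 4.0, tolerance = 0.02)
})

test_that("extreme low-nu evaluation stays finite (overflow guard)", {
  r <- carver_richards_r2eff(c(0.5, 1, 2), 10000, 0.1,
                             ppm_to_rad_s(5, 800, "15N"), 10)
  expect_true(all(is.finite(r)))
})

test_that("Bloch-McConnell propagation reproduces the closed form", {
  # oracle-equivalence over the fitted-parameter box, both fields
  worst <- 0
  for (kex in c(1000, 3162, 10000)) {
    for (pb in c(0.05, 0.12)) {
      for (dw_ppm in c(0.5, 2, 5)) {
        for (field in c(600, 800)) {
          dw <- ppm_to_rad_s(dw_ppm, field, "15N")
          for (nu in c(50, 100, 250, 500, 1000)) {
            cr <- carver_richards_r2eff(nu, kex, pb, dw, 10)
            bm <- bloch_mcconnell_r2eff(nu, kex, pb, dw, 10, 0.06)
            worst <- max(worst, abs(cr - bm) / bm)
          }
        }
      }
    }
  }
  expect_lt(worst, 0.005)
})

test_that("Bloch-McConnell limits and invariances hold", {
  expect_equal(bloch_mcconnell_r2eff(100, 3000, 0, 1000, 12.5, 0.06),
               12.5, tolerance = 1e-10)
  # rate readout is insensitive to the constant-time delay
  a <- bloch_mcconnell_r2eff(100, 2117, 0.08, dw_2ppm_800, 10, 0.06)
  b <- bloch_mcconnell_r2eff(100, 2117, 0.08, dw_2ppm_800, 10, 0.12)
  expect_lt(abs(a - b) / a, 0.001)
  # the single-delay signal readout carries the echo-train transient:
  # close to, but measurably different from, the steady-state rate
  s <- bloch_mcconnell_r2eff(100, 2117, 0.08, dw_2ppm_800, 10, 0.06,
                             readout = "signal")
  expect_lt(abs(s - a) / a, 0.025)
  expect_gt(abs(s - a), 0)
  expect_error(bloch_mcconnell_r2eff(5, 3000, 0.08, 1000, 10, 0.06),
               class = "cpmgfit_input_error")
  expect_warning(bloch_mcconnell_r2eff(55, 3000, 0.08, 1000, 10, 0.06),
                 "rounded")
})

test_that("intensity conversion matches its closed form", {
  expect_equal(r2eff_from_intensities(100, 100, 0.06), 0)
  expect_equal(r2eff_from_intensities(exp(-1) * 50, 50, 0.06),
               16.66667, tolerance = 1e-6)
  expect_equal(r2eff_from_intensities(0.5, 1, 0.03), 23.10491,
               tolerance = 1e-6)
  expect_error(r2eff_from_intensities(-1, 100, 0.06),
               class = "cpmgfit_input_error")
})

test_that("Rex amplitude and dispersing-peak selection work per profile", {
  flat <- tibble::tibble(peak_id = "A", nucleus = "15N", field_MHz = 800,
                         temperature_C = 10,
                         nu_cpmg_Hz = c(50, 500, 1000),
                         r2eff = c(12, 12, 12))
  expect_equal(rex_amplitude(flat)$rex, 0)
  expect_error(rex_amplitude(flat[1, ]), class = "cpmgfit_input_error")

  rex_map <- tibble::tibble(peak_id = c("A", "B", "C"),
                            rex = c(7.1, 4.9, 12.0))
  expect_equal(select_dispersing(rex_map)$peak_id, c("A", "C"))
  expect_equal(nrow(select_dispersing(
    tibble::tibble(peak_id = letters[1:4], rex = rep(0, 4)))), 0)

  # residue-resolved map: only the four sites flanking the active-site
  # histidine rise above the 5/s cutoff
  resmap <- tibble::tibble(
    peak_id = c("Asp167", "Ala169", "Lys172", "Gly180", "Ile199",
                "Val210"),
    rex = c(18, 9.5, 6.2, 1.1, 22.4, 3.0))
  expect_equal(select_dispersing(resmap)$peak_id,
               c("Asp167", "Ala169", "Lys172", "Ile199"))
})
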