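test_that("couplings difference and R-factor closed forms hold", {
  expect_equal(rdc_from_couplings(-93, -93), 0)
  expect_equal(rdc_from_couplings(-85.2, -93), 7.8)
  expect_equal(rdc_from_couplings(3, 10), -rdc_from_couplings(10, 3))
  obs <- c(5, -3, 8, -1)
  expect_equal(r_factor(obs, obs), 0)
  expect_equal(r_factor(obs, rep(0, 4)), 1 / sqrt(2))
  expect_equal(r_factor(obs * 3.7, obs * 3.7 * 0.5),
               r_factor(obs, obs * 0.5))
  expect_error(r_factor(rep(0, 3), c(1, 2, 3)),
               class = "cpmgfit_input_error")
  expect_error(r_factor(1:3, 1:4), class = "cpmgfit_input_error")
})

test_that("SVD fit recovers a known tensor exactly and optimally", {
  tensor <- saupe_from_param(Da = 10, rhombicity = 0.3)
  v <- unit_vectors(15, seed = 3)
  d <- simulate_rdc(tensor, v)
  fit <- svd_fit_rdc(d, v)
  expect_equal(fit$saupe, tensor, tolerance = 1e-8)
  expect_equal(fit$r_factor, 0, tolerance = 1e-8)
  expect_equal(fit$Da_Hz, 10, tolerance = 1e-8)
  expect_equal(abs(fit$rhombicity), 0.3, tolerance = 1e-8)
  # traceless within numerical precision
  expect_lt(abs(sum(eigen(fit$saupe_matrix)$values)), 1e-10)
  # least-squares optimality: no random tensor scores a lower R-factor
  noisy <- simulate_rdc(tensor, v, noise_sd = 1, seed = 4)
  best <- svd_fit_rdc(noisy, v)
  for (s in 1:10) {
    rand_t <- withr::with_seed(s, best$saupe + rnorm(5, 0, 2))
    r_rand <- r_factor(noisy$D_obs_Hz, predict_rdc(rand_t, v)$D_calc_Hz)
    expect_gte(r_rand, best$r_factor)
  }
})

test_that("the tensor fit is rotation-covariant", {
  tensor <- saupe_from_param(Da = 8, rhombicity = 0.2)
  v <- unit_vectors(20, seed = 6)
  d <- simulate_rdc(tensor, v)
  rot <- random_rotation(seed = 11)
  vr <- as.matrix(v[c("x", "y", "z")]) %*% t(rot)
  v2 <- tibble::tibble(residue_id = v$residue_id, x = vr[, 1],
                       y = vr[, 2], z = vr[, 3])
  f1 <- svd_fit_rdc(d, v)
  f2 <- svd_fit_rdc(d, v2)
  expect_equal(f2$r_factor, f1$r_factor, tolerance = 1e-10)
  expect_equal(sort(eigen(f2$saupe_matrix)$values),
               sort(eigen(f1$saupe_matrix)$values), tolerance = 1e-8)
})

test_that("noise drives the R-factor to the expected level", {
  tensor <- saupe_from_param(Da = 10, rhombicity = 0.25)
  v <- unit_vectors(30, seed = 12)
  clean <- simulate_rdc(tensor, v)
  sigma <- 0.1 * sqrt(mean(clean$D_obs_Hz^2))
  rf <- vapply(1:50, function(s)
    svd_fit_rdc(simulate_rdc(tensor, v, noise_sd = sigma, seed = s),
                v)$r_factor,
    numeric(1))
  expect_gt(mean(rf), 0.04)
  expect_lt(mean(rf), 0.10)
})

test_that("degenerate inputs are rejected", {
  v <- unit_vectors(4, seed = 1)
  d <- simulate_rdc(saupe_from_param(5), v)
  expect_error(svd_fit_rdc(d, v), class = "cpmgfit_input_error")
  # rank-deficient: all bonds parallel
  vpar <- tibble::tibble(residue_id = 1:6, x = 1, y = 0, z = 0)
  dpar <- tibble::tibble(residue_id = 1:6, D_obs_Hz = c(1, 2, 1, 3, 2, 1))
  expect_error(svd_fit_rdc(dpar, vpar), class = "cpmgfit_input_error")
})

test_that("N-H vectors are extracted from PDB coordinates", {
  skip_if_not_installed("bio3d")
  path <- withr::local_tempfile(fileext = ".pdb")
  # axis-aligned N->H bonds plus one proline-like residue without H
  res <- tibble::tibble(
    resno = 1:4, resn = c("ALA", "GLY", "LEU", "PRO"), chain = "A",
    n_x = c(0, 10, 20, 30), n_y = 0, n_z = 0,
    h_x = c(1, 10, 20, NA), h_y = c(0, 1, 0, NA),
    h_z = c(0, 0, 1, NA))
  write_mini_pdb(path, res)
  expect_message(vec <- extract_nh_vectors(path), "without amide H")
  expect_equal(vec$residue_id, 1:3)   # proline absent
  expect_equal(unlist(vec[1, c("x", "y", "z")]), c(x = 1, y = 0, z = 0))
  expect_equal(unlist(vec[2, c("x", "y", "z")]), c(x = 0, y = 1, z = 0))
  expect_equal(unlist(vec[3, c("x", "y", "z")]), c(x = 0, y = 0, z = 1))
  expect_equal(sqrt(vec$x^2 + vec$y^2 + vec$z^2), rep(1, 3),
               tolerance = 1e-6)
  expect_error(extract_nh_vectors(path, chain = "B"),
               class = "cpmgfit_input_error")
  expect_error(extract_nh_vectors("no-such-file.pdb"),
               class = "cpmgfit_input_error")
})

test_that("tensor accessors summarize the fit", {
  tensor <- saupe_from_param(Da = 10, rhombicity = 0.3)
  v <- unit_vectors(15, seed = 3)
  fit <- svd_fit_rdc(simulate_rdc(tensor, v), v)
  expect_equal(nrow(tidy(fit)), 5)
  expect_equal(glance(fit)$n, 15)
  expect_s3_class(autoplot(fit), "ggplot")
})
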