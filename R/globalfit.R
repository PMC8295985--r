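# Global thermodynamic fit of relaxation-dispersion data.
#
# All profiles (peaks x fields x temperatures) are fit simultaneously to
# the Carver-Richards model with kex and pb at every temperature derived
# from two global free energies (Eyring equation + reaction isotherm).
# Free parameters: dG_act, dG_eq, one |dw| per peak, and one intrinsic
# R2 per (peak, field, temperature). Because the intrinsic rate enters
# the model additively, it is profiled out in closed form at each
# objective evaluation (its weighted-least-squares optimum is the
# weighted mean residual of the profile), so the nonlinear search runs
# in only 2 + n_peaks dimensions.

PROFILE_KEYS <- c("peak_id", "nucleus", "field_MHz", "temperature_C",
                  "T_relax_s")

#' Count optimized exchange parameters under a tying scheme
#'
#' Bookkeeping for the thermodynamic tying argument: fitting kex, pb and
#' one dw per peak independently at every temperature costs
#' `(2 + n_peaks) * n_temps` parameters, while tying all temperatures
#' through the two free energies costs `2 + n_peaks`. Intrinsic rates
#' are excluded from both counts (they appear in either scheme).
#'
#' @param n_peaks Number of exchanging peaks (>= 1).
#' @param n_temps Number of temperatures (>= 1).
#' @param tying `"global"` (free energies shared across temperature) or
#'   `"per-temperature"` (independent kex, pb at each temperature).
#' @return Integer parameter count.
#' @export
#' @examples
#' count_parameters(5, 4, "per-temperature") # 28
#' count_parameters(5, 4, "global")          # 7
count_parameters <- function(n_peaks, n_temps,
                             tying = c("global", "per-temperature")) {
  tying <- match.arg(tying)
  if (n_peaks < 1 || n_temps < 1) abort_input("n_peaks and n_temps must be >= 1")
  if (tying == "global") 2L + as.integer(n_peaks)
  else (2L + as.integer(n_peaks)) * as.integer(n_temps)
}

# canonical ordering + validation of a dispersion dataset
prepare_rd_data <- function(data) {
  need <- c(PROFILE_KEYS, "nu_cpmg_Hz", "r2eff")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0)
    abort_input(paste("missing columns:", paste(missing, collapse = ", ")))
  if (!"r2eff_err" %in% names(data)) {
    message("no r2eff_err column; using sigma = 1 for all points")
    data$r2eff_err <- 1
  }
  if (any(is.na(data$r2eff_err)) || any(data$r2eff_err <= 0)) {
    message("non-positive or missing r2eff_err replaced by sigma = 1")
    data$r2eff_err[is.na(data$r2eff_err) | data$r2eff_err <= 0] <- 1
  }
  data |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$peak_id, .data$nucleus, .data$field_MHz,
                   .data$temperature_C, .data$nu_cpmg_Hz)
}

# exchange contribution (R2eff minus intrinsic rate) for a vector of rows
# sharing one parameter set
exchange_contribution <- function(nu, kex, pb, dw_rad) {
  carver_richards_r2eff(nu, kex, pb, dw_rad, r2_intrinsic = 1) - 1
}

#' Chi-square objective of the global dispersion model
#'
#' `chi2 = sum(((r2eff_obs - r2eff_model) / sigma)^2)` over every point
#' in the dataset, with the model built from the two global free
#' energies, per-peak shift differences, and per-(peak, field,
#' temperature) intrinsic rates. When `r2_intrinsic` is `NULL` the
#' intrinsic rates are set to their conditional weighted-least-squares
#' optimum (the value [fit_dispersion()] would assign).
#'
#' @param data Dispersion dataset (see [simulate_dispersion()] for the
#'   column layout); a missing `r2eff_err` column falls back to
#'   sigma = 1 with a message.
#' @param dG_act,dG_eq Global free energies, J/mol.
#' @param dw_ppm Named numeric vector of shift-difference magnitudes,
#'   ppm, with one entry per `peak_id` in `data`.
#' @param r2_intrinsic Optional data frame with columns `peak_id`,
#'   `field_MHz`, `temperature_C`, `r2_intrinsic` giving the intrinsic
#'   rates; `NULL` profiles them out.
#' @return The chi-square value (numeric scalar).
#' @export
rd_objective <- function(data, dG_act, dG_eq, dw_ppm,
                         r2_intrinsic = NULL) {
  data <- prepare_rd_data(data)
  miss <- setdiff(unique(data$peak_id), names(dw_ppm))
  if (length(miss) > 0)
    abort_input(paste("dw_ppm missing peaks:", paste(miss, collapse = ", ")))
  res <- rd_residuals(data, dG_act, dG_eq, dw_ppm, r2_intrinsic)
  sum(res^2)
}

# weighted residual vector; profiles out intrinsic rates unless supplied
rd_residuals <- function(data, dG_act, dG_eq, dw_ppm,
                         r2_intrinsic = NULL) {
  key <- interaction(data$peak_id, data$nucleus, data$field_MHz,
                     data$temperature_C, drop = TRUE)
  temps_K <- celsius_to_kelvin(data$temperature_C)
  kex <- eyring_rate(dG_act, temps_K)
  pb <- isotherm_pb(dG_eq, temps_K)
  dw_rad <- ppm_to_rad_s(unname(dw_ppm[data$peak_id]), data$field_MHz,
                         data$nucleus)
  g <- numeric(nrow(data))
  for (idx in split(seq_len(nrow(data)), key)) {
    g[idx] <- exchange_contribution(data$nu_cpmg_Hz[idx], kex[idx[1]],
                                    pb[idx[1]], dw_rad[idx[1]])
  }
  w <- 1 / data$r2eff_err^2
  partial <- data$r2eff - g
  if (is.null(r2_intrinsic)) {
    r2hat <- stats::ave(seq_len(nrow(data)), key, FUN = function(idx)
      sum(partial[idx] * w[idx]) / sum(w[idx]))
  } else {
    lk <- dplyr::left_join(
      data[c("peak_id", "field_MHz", "temperature_C")], r2_intrinsic,
      by = c("peak_id", "field_MHz", "temperature_C"))
    if (any(is.na(lk$r2_intrinsic)))
      abort_input("r2_intrinsic table does not cover every condition")
    r2hat <- lk$r2_intrinsic
  }
  (partial - r2hat) / data$r2eff_err
}

#' Globally fit relaxation-dispersion profiles with thermodynamic tying
#'
#' Bound-constrained Levenberg-Marquardt minimization of
#' [rd_objective()] with multistart initialization. Shift differences of
#' 15N peaks are restrained to at least `dw_lower_ppm_15N` (default
#' 1 ppm) to aid convergence; 13C shifts are bounded below at 0.
#'
#' @param data Dispersion dataset with columns `peak_id`, `nucleus`,
#'   `field_MHz`, `temperature_C`, `T_relax_s`, `nu_cpmg_Hz`, `r2eff`
#'   and (recommended) `r2eff_err`.
#' @param dw_lower_ppm_15N Lower bound on 15N shift differences, ppm.
#' @param multistart Number of seeded starting points (>= 1).
#' @param seed Integer seed for start generation.
#' @param mc_replicates Monte-Carlo replicates for parameter
#'   uncertainties (0 disables; see [estimate_errors()]). Covariance
#'   based uncertainties are always reported.
#' @param ftol,ptol Relative objective and parameter convergence
#'   tolerances for the optimizer.
#' @return An object of class `rd_fit`: a list with elements `params`
#'   (tibble of dG_act, dG_eq and per-peak dw with uncertainties),
#'   `r2_intrinsic`, `rate_table`, `chi2`, `chi2_reduced`, `n_data`,
#'   `n_params` (thermodynamic bookkeeping: 2 + n_peaks),
#'   `n_params_total`, `data` (input with `.fitted` and `.resid`),
#'   `convergence` and `starts`. Methods: [tidy.rd_fit()],
#'   [glance.rd_fit()], [augment.rd_fit()], [autoplot.rd_fit()].
#' @export
#' @examples
#' rd <- simulate_dispersion(noise_sd = 0, seed = 7)
#' fit <- fit_dispersion(rd, multistart = 2)
#' glance(fit)
fit_dispersion <- function(data, dw_lower_ppm_15N = 1, multistart = 10,
                           seed = 1, mc_replicates = 0,
                           ftol = 1e-10, ptol = 1e-8) {
  data <- prepare_rd_data(data)
  peaks <- data |>
    dplyr::distinct(.data$peak_id, .data$nucleus) |>
    dplyr::arrange(.data$peak_id)
  if (any(duplicated(peaks$peak_id)))
    abort_input("a peak_id maps to more than one nucleus")
  n_peaks <- nrow(peaks)

  rex <- rex_amplitude(data)
  if (max(rex$rex) < 0.5)
    warning("no dispersing profile (all Rex < 0.5 /s); fit is degenerate")

  lower <- c(30000, 500, ifelse(peaks$nucleus == "15N",
                                dw_lower_ppm_15N, 0))
  upper <- c(80000, 20000, rep(20, n_peaks))

  # per-peak dw guess from the fast-exchange relation Rex ~ pa*pb*dw^2/kex
  dw_guess <- function(dG_act0, dG_eq0) {
    t_mid <- celsius_to_kelvin(mean(unique(data$temperature_C)))
    kex0 <- eyring_rate(dG_act0, t_mid)
    pb0 <- isotherm_pb(dG_eq0, t_mid)
    vapply(seq_len(n_peaks), function(i) {
      r <- rex |> dplyr::filter(.data$peak_id == peaks$peak_id[i])
      rx <- max(mean(r$rex), 0.5)
      f <- max(r$field_MHz)
      dw_rad <- sqrt(rx * kex0 / (pb0 * (1 - pb0)))
      dw_rad / (1e-6 * 2 * pi * nucleus_frequency_hz(f, peaks$nucleus[i]))
    }, numeric(1))
  }

  starts <- withr::with_seed(seed, {
    lapply(seq_len(max(1, multistart)), function(s) {
      if (s == 1) {
        th <- c(52000, 6000, dw_guess(52000, 6000))
      } else {
        dga <- stats::runif(1, 45000, 60000)
        dge <- stats::runif(1, 2000, 10000)
        th <- c(dga, dge,
                dw_guess(dga, dge) * stats::runif(n_peaks, 0.7, 1.4))
      }
      pmin(pmax(th, lower), upper)
    })
  })

  dw_named <- function(theta) stats::setNames(theta[-(1:2)], peaks$peak_id)
  resid_fn <- function(theta)
    rd_residuals(data, theta[1], theta[2], dw_named(theta))

  fits <- lapply(starts, function(th) {
    tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = th, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          ftol = ftol, ptol = ptol, maxiter = 500))),
      error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1)) &
    vapply(fits, function(f) f$info %in% 1:4, logical(1))
  if (!any(ok))
    stop(structure(
      class = c("cpmgfit_fit_failure", "error", "condition"),
      list(message = paste(
        "optimizer failed to converge from every start;",
        "info codes:", paste(vapply(
          fits, function(f) if (is.null(f)) NA_integer_ else f$info,
          integer(1)), collapse = ", ")),
        call = sys.call(-1))))
  dev <- vapply(fits, function(f)
    if (is.null(f)) Inf else f$deviance, numeric(1))
  dev[!ok] <- Inf
  best_i <- which.min(dev)           # which.min takes the first: ties
  best <- fits[[best_i]]             # break toward the lowest start index
  theta <- best$par

  # covariance-based uncertainties (J'J inverse scaled by reduced chi2)
  n_data <- nrow(data)
  n_profiles <- nrow(dplyr::distinct(
    data, .data$peak_id, .data$field_MHz, .data$temperature_C))
  dof <- max(1, n_data - (2 + n_peaks + n_profiles))
  se <- rep(NA_real_, length(theta))
  cov_try <- tryCatch(solve(best$hessian) * best$deviance / dof,
                      error = function(e) NULL)
  if (!is.null(cov_try)) se <- sqrt(pmax(diag(cov_try), 0))

  params <- tibble::tibble(
    term = c("dG_act", "dG_eq", paste0("dw_ppm_", peaks$peak_id)),
    estimate = theta, std_error = se
  )

  # intrinsic rates at the optimum
  resid <- resid_fn(theta)
  fitted <- data$r2eff - resid * data$r2eff_err
  key_df <- data[PROFILE_KEYS]
  g <- fitted  # reconstruct r2hat = fitted - exchange contribution
  temps_K <- celsius_to_kelvin(data$temperature_C)
  kex_v <- eyring_rate(theta[1], temps_K)
  pb_v <- isotherm_pb(theta[2], temps_K)
  dwv <- stats::setNames(theta[-(1:2)], peaks$peak_id)
  dw_rad <- ppm_to_rad_s(unname(dwv[data$peak_id]), data$field_MHz,
                         data$nucleus)
  key <- interaction(data$peak_id, data$field_MHz, data$temperature_C,
                     drop = TRUE)
  gc_ <- numeric(n_data)
  for (idx in split(seq_len(n_data), key))
    gc_[idx] <- exchange_contribution(data$nu_cpmg_Hz[idx], kex_v[idx[1]],
                                      pb_v[idx[1]], dw_rad[idx[1]])
  r2int <- dplyr::bind_cols(key_df, r2_intrinsic = fitted - gc_) |>
    dplyr::distinct(.data$peak_id, .data$nucleus, .data$field_MHz,
                    .data$temperature_C, .keep_all = TRUE) |>
    dplyr::select(-"T_relax_s")

  out <- structure(list(
    params = params,
    r2_intrinsic = r2int,
    rate_table = derive_rate_table(
      theta[1], theta[2],
      celsius_to_kelvin(sort(unique(data$temperature_C)))),
    chi2 = best$deviance,
    chi2_reduced = best$deviance / dof,
    n_data = n_data,
    n_params = 2L + n_peaks,
    n_params_total = 2L + n_peaks + n_profiles,
    data = dplyr::mutate(data, .fitted = fitted,
                         .resid = data$r2eff - fitted),
    convergence = list(info = best$info, message = best$message,
                       niter = best$niter, best_start = best_i),
    starts = tibble::tibble(start = seq_along(dev), deviance = dev,
                            converged = ok),
    peaks = peaks,
    seed = seed
  ), class = "rd_fit")

  if (mc_replicates >= 2) {
    mc <- estimate_errors(out, replicates = mc_replicates, seed = seed)
    out$params <- dplyr::left_join(out$params, mc, by = "term")
  } else if (mc_replicates != 0) {
    warning("mc_replicates < 2: Monte-Carlo uncertainties disabled")
  }
  out
}

#' Monte-Carlo parameter uncertainties for a global dispersion fit
#'
#' Parametric residual resampling: replicate datasets are built as
#' best-fit curve plus Gaussian noise drawn at each point's reported
#' sigma, refit from the best-fit parameters, and the standard
#' deviation of each parameter over replicates is reported.
#'
#' @param fit An `rd_fit` object from [fit_dispersion()].
#' @param replicates Number of replicates (>= 2).
#' @param seed Integer seed.
#' @return Tibble with columns `term` and `std_error_mc`.
#' @export
estimate_errors <- function(fit, replicates = 50, seed = 1) {
  if (!inherits(fit, "rd_fit")) abort_input("fit must be an rd_fit object")
  if (replicates < 2) {
    warning("replicates < 2: Monte-Carlo error estimation disabled")
    return(tibble::tibble(term = character(), std_error_mc = numeric()))
  }
  data <- fit$data
  peaks <- fit$peaks
  theta0 <- fit$params$estimate
  lower <- c(30000, 500, ifelse(peaks$nucleus == "15N", 1, 0))
  upper <- c(80000, 20000, rep(20, nrow(peaks)))
  dw_named <- function(theta) stats::setNames(theta[-(1:2)], peaks$peak_id)
  draws <- withr::with_seed(seed, {
    replicate(replicates,
              stats::rnorm(nrow(data), 0, data$r2eff_err),
              simplify = FALSE)
  })
  ests <- vapply(draws, function(eps) {
    d <- data
    d$r2eff <- data$.fitted + eps
    rf <- function(theta)
      rd_residuals(d, theta[1], theta[2], dw_named(theta))
    f <- tryCatch(suppressWarnings(minpack.lm::nls.lm(
      par = theta0, fn = rf, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(f)) rep(NA_real_, length(theta0)) else f$par
  }, numeric(length(theta0)))
  tibble::tibble(
    term = fit$params$term,
    std_error_mc = apply(ests, 1, stats::sd, na.rm = TRUE)
  )
}
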