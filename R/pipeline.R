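# End-to-end orchestration: runs whichever analysis stages the
# configuration provides inputs for and writes a machine-readable
# report. Stages are independent; one failing stage never aborts the
# others.

# derive a per-stage seed from the global one (kept within 32-bit range)
stage_seed <- function(seed, stage_index) {
  (seed * 131L + stage_index * 7919L) %% 2147483647L
}

#' Run the full analysis pipeline from a configuration
#'
#' The configuration is a named list (or the path to a YAML file
#' holding one) with any subset of the stage blocks below; stages
#' without inputs are marked `"skipped"` in the report.
#'
#' \describe{
#'   \item{rd}{`list(path, dw_lower_ppm_15N, multistart, mc_replicates,
#'     rex_threshold_s)` -- global dispersion fit on [read_rd_tsv()]
#'     data.}
#'   \item{relaxation}{`list(path)` -- decay fits, R2 extraction, and
#'     the tau_c estimate.}
#'   \item{shifts}{`list(path_a, path_b, csp_threshold_ppm)` -- CSP map
#'     and significance classing.}
#'   \item{rdc}{`list(rdc_path, pdb_path, chain, model)` -- SVD tensor
#'     fit against structure coordinates.}
#'   \item{melt}{`list(path, smooth)` -- Tm extraction.}
#'   \item{kinetics}{`list(path)` -- initial-velocity fit.}
#' }
#'
#' Top-level fields: `out_dir` (required), `seed` (default 1).
#'
#' @param config Named list or path to a YAML file.
#' @return The report, invisibly: a named list with one entry per
#'   stage (`status` plus stage-specific results), also written to
#'   `<out_dir>/report.json` with per-stage TSVs alongside.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) abort_input("config$out_dir is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  report <- list(schema = "cpmgfit-report/1", seed = seed)
  run_stage <- function(name, idx, fun) {
    block <- config[[name]]
    if (is.null(block)) return(list(status = "skipped"))
    tryCatch(c(list(status = "ok"), fun(block, stage_seed(seed, idx))),
             error = function(e) list(status = "failed",
                                      error = conditionMessage(e)))
  }

  report$rd <- run_stage("rd", 1L, function(b, s) {
    data <- read_rd_tsv(b$path)
    fit <- fit_dispersion(
      data,
      dw_lower_ppm_15N = b$dw_lower_ppm_15N %||% 1,
      multistart = b$multistart %||% 10,
      seed = s,
      mc_replicates = b$mc_replicates %||% 0)
    rex <- rex_amplitude(data)
    disp <- select_dispersing(
      rex |> dplyr::group_by(.data$peak_id) |>
        dplyr::summarise(rex = max(.data$rex), .groups = "drop"),
      threshold_s = b$rex_threshold_s %||% 5)
    readr::write_tsv(fit$rate_table,
                     file.path(config$out_dir, "rate_table.tsv"))
    readr::write_tsv(tidy(fit),
                     file.path(config$out_dir, "rd_parameters.tsv"))
    readr::write_tsv(augment(fit),
                     file.path(config$out_dir, "rd_fitted.tsv"))
    list(params = as.list(stats::setNames(fit$params$estimate,
                                          fit$params$term)),
         chi2 = fit$chi2, chi2_reduced = fit$chi2_reduced,
         n_data = fit$n_data, n_params = fit$n_params,
         dispersing_peaks = disp$peak_id,
         rate_table = lapply(seq_len(nrow(fit$rate_table)), function(i)
           as.list(fit$rate_table[i, ])))
  })

  report$relaxation <- run_stage("relaxation", 2L, function(b, s) {
    series <- read_relaxation_tsv(b$path)
    summ <- summarize_relaxation(series)
    trimmed <- trimmed_mean_r2_r1(summ)
    field <- summ$field_MHz[1]
    tau <- if (!is.na(field))
      tau_c_estimate(trimmed$mean_r2_over_r1,
                     nucleus_frequency_hz(field, "15N")) else NA_real_
    readr::write_tsv(summ,
                     file.path(config$out_dir, "relaxation_summary.tsv"))
    list(mean_r2_over_r1 = trimmed$mean_r2_over_r1,
         excluded_residues = trimmed$excluded[[1]],
         tau_c_ns = tau * 1e9)
  })

  report$shifts <- run_stage("shifts", 3L, function(b, s) {
    a <- read_shift_tsv(b$path_a)
    bb <- read_shift_tsv(b$path_b)
    map <- csp_table(a, bb)
    sig <- classify_significant(map, b$csp_threshold_ppm %||% 0.3)
    readr::write_tsv(map, file.path(config$out_dir, "csp_map.tsv"))
    list(n_residues = nrow(map), significant = sig$residue_id)
  })

  report$rdc <- run_stage("rdc", 4L, function(b, s) {
    rdc <- read_rdc_tsv(b$rdc_path)
    vecs <- extract_nh_vectors(b$pdb_path, chain = b$chain,
                               model = b$model %||% 1)
    fit <- svd_fit_rdc(rdc, vecs)
    readr::write_tsv(fit$predictions,
                     file.path(config$out_dir, "rdc_predictions.tsv"))
    list(Da_Hz = fit$Da_Hz, rhombicity = fit$rhombicity,
         r_factor = fit$r_factor, n = fit$n,
         saupe = as.numeric(fit$saupe),
         euler_deg = as.list(fit$euler_deg))
  })

  report$melt <- run_stage("melt", 5L, function(b, s) {
    tm <- extract_tm(read_curve_tsv(b$path), smooth = b$smooth %||% FALSE)
    list(tm_C = tm$tm_C, flag = tm$flag)
  })

  report$kinetics <- run_stage("kinetics", 6L, function(b, s) {
    v <- initial_velocity(read_curve_tsv(b$path))
    list(v0_uM_min = v$v0_uM_min, v0_se = v$v0_se)
  })

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
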