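# Tab-separated interchange formats. All files are UTF-8 TSV with a
# header row and '#' comment lines; column names carry units.

read_tsv_checked <- function(path, required, label) {
  if (!file.exists(path)) abort_input(paste(label, "file not found:", path))
  out <- tryCatch(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE),
    error = function(e) abort_input(paste("cannot parse", label, "file:",
                                          conditionMessage(e))))
  if (nrow(out) == 0) abort_input(paste(label, "file is empty:", path))
  missing <- setdiff(required, names(out))
  if (length(missing) > 0)
    abort_input(paste0(label, " file missing column(s): ",
                       paste(missing, collapse = ", ")))
  probs <- readr::problems(out)
  if (nrow(probs) > 0)
    abort_input(paste0("non-numeric or malformed cell(s) in ", label,
                       " file, first at line ", probs$row[1] + 1))
  out
}

#' Read a relaxation-dispersion TSV
#'
#' Expected columns: `peak_id`, `nucleus`, `field_MHz`,
#' `temperature_C`, `T_relax_s`, `nu_cpmg_Hz`, `r2eff`, and optionally
#' `r2eff_err`. Rows are returned sorted by profile and ascending
#' `nu_cpmg_Hz`.
#'
#' @param path File path.
#' @return Tibble in the [simulate_dispersion()] layout.
#' @export
read_rd_tsv <- function(path) {
  out <- read_tsv_checked(
    path, c("peak_id", "nucleus", "field_MHz", "temperature_C",
            "T_relax_s", "nu_cpmg_Hz", "r2eff"), "dispersion")
  prepare_rd_data(out)
}

#' Write a relaxation-dispersion TSV
#'
#' @param data Dispersion dataset.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rd_tsv <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' Read a relaxation decay-series TSV
#'
#' Expected columns: `residue_id`, `experiment`, `delay_s`,
#' `intensity`; optional `intensity_err`, `spinlock_Hz`, `offset_Hz`,
#' `field_MHz`.
#'
#' @param path File path.
#' @return Tibble of decay series.
#' @export
read_relaxation_tsv <- function(path) {
  read_tsv_checked(path, c("residue_id", "experiment", "delay_s",
                           "intensity"), "relaxation")
}

#' Read a chemical-shift TSV
#'
#' Expected columns: `residue_id`, `dH`, `dN`; optional `dCa`.
#'
#' @param path File path.
#' @return Tibble of shifts.
#' @export
read_shift_tsv <- function(path) {
  read_tsv_checked(path, c("residue_id", "dH", "dN"), "shift")
}

#' Read an RDC TSV
#'
#' Expected columns: `residue_id`, `D_obs_Hz`; optional `D_err_Hz`.
#'
#' @param path File path.
#' @return Tibble of couplings.
#' @export
read_rdc_tsv <- function(path) {
  read_tsv_checked(path, c("residue_id", "D_obs_Hz"), "RDC")
}

#' Read an assay-curve TSV
#'
#' Two-column trace: melts carry `temperature_C` + `theta_222`,
#' kinetics traces `time_min` + `conc_uM`. The kind is inferred from
#' the columns present.
#'
#' @param path File path.
#' @return Tibble with an added `kind` attribute (`"melt"` or
#'   `"kinetics"`).
#' @export
read_curve_tsv <- function(path) {
  out <- read_tsv_checked(path, character(), "assay curve")
  if (all(c("temperature_C", "theta_222") %in% names(out))) {
    attr(out, "kind") <- "melt"
  } else if (all(c("time_min", "conc_uM") %in% names(out))) {
    attr(out, "kind") <- "kinetics"
  } else {
    abort_input(paste("assay curve file must carry temperature_C/theta_222",
                      "or time_min/conc_uM columns"))
  }
  out
}
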