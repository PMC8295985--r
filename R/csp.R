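# Chemical-shift comparisons between two states: weighted 1H/15N
# perturbations, significance classification, and secondary-Calpha
# shift correlation.

#' Weighted combined 1H/15N chemical-shift perturbation
#'
#' `sqrt((ddH * wH)^2 + (ddN * wN)^2)` with the conventional amide
#' weights wH = 1 and wN = 0.154 that put the 15N dispersion on the
#' 1H ppm scale.
#'
#' @param dH_a,dH_b 1H shifts (ppm) of states a and b. Vectorized.
#' @param dN_a,dN_b 15N shifts (ppm) of states a and b.
#' @param wH,wN Weighting factors; defaults 1 and 0.154.
#' @return Perturbation in ppm (>= 0).
#' @export
#' @examples
#' csp(8.30, 8.25, 118.5, 118.0) # 0.0918 ppm
csp <- function(dH_a, dH_b, dN_a, dN_b, wH = 1, wN = 0.154) {
  sqrt(((dH_a - dH_b) * wH)^2 + ((dN_a - dN_b) * wN)^2)
}

#' Per-residue CSP table from two state shift tables
#'
#' Joins two shift tables by residue and computes [csp()] for every
#' residue present with finite 1H and 15N shifts in both states;
#' residues missing from either state are skipped with a message, never
#' imputed.
#'
#' @param state_a,state_b Data frames with columns `residue_id`, `dH`,
#'   `dN`.
#' @inheritParams csp
#' @return Tibble with `residue_id` and `csp_ppm`.
#' @export
csp_table <- function(state_a, state_b, wH = 1, wN = 0.154) {
  need <- c("residue_id", "dH", "dN")
  if (!all(need %in% names(state_a)) || !all(need %in% names(state_b)))
    abort_input("shift tables need residue_id, dH, dN columns")
  joined <- dplyr::inner_join(state_a[need], state_b[need],
                              by = "residue_id",
                              suffix = c("_a", "_b"))
  complete <- stats::complete.cases(
    joined[c("dH_a", "dN_a", "dH_b", "dN_b")])
  n_all <- length(union(state_a$residue_id, state_b$residue_id))
  if (sum(complete) < n_all)
    message(n_all - sum(complete),
            " residue(s) without shifts in both states skipped")
  joined <- joined[complete, ]
  tibble::tibble(
    residue_id = joined$residue_id,
    csp_ppm = csp(joined$dH_a, joined$dH_b, joined$dN_a, joined$dN_b,
                  wH, wN)
  )
}

#' Residues with significant chemical-shift perturbation
#'
#' Keeps residues whose perturbation strictly exceeds the threshold
#' (default 0.3 ppm, the usual cutoff for perturbations localized
#' around a modification site).
#'
#' @param csp_map Data frame with columns `residue_id` and `csp_ppm`.
#' @param threshold_ppm Cutoff, ppm (> 0).
#' @return Tibble of rows with `csp_ppm > threshold_ppm`, input order
#'   preserved.
#' @export
classify_significant <- function(csp_map, threshold_ppm = 0.3) {
  if (threshold_ppm <= 0) abort_input("threshold_ppm must be > 0")
  if (!all(c("residue_id", "csp_ppm") %in% names(csp_map)))
    abort_input("csp_map needs residue_id and csp_ppm columns")
  tibble::as_tibble(
    csp_map[csp_map$csp_ppm > threshold_ppm, , drop = FALSE])
}

#' Correlate secondary Calpha shifts between two states
#'
#' Secondary shifts (observed minus random-coil Calpha shift) probe
#' secondary structure; identical structure in two states yields a
#' unit-slope, high-correlation line. Least-squares regression of state
#' a's secondary shifts (y) on state b's (x) plus the Pearson
#' correlation.
#'
#' @param table_a,table_b Data frames with columns `residue_id` and
#'   `dCa` (ppm).
#' @param random_coil Data frame with columns `residue_id` and
#'   `dCa_coil` (ppm).
#' @return One-row tibble: `slope`, `intercept`, `r`, `n`.
#' @export
compare_secondary_shifts <- function(table_a, table_b, random_coil) {
  for (tb in list(table_a, table_b))
    if (!all(c("residue_id", "dCa") %in% names(tb)))
      abort_input("shift tables need residue_id and dCa columns")
  if (!all(c("residue_id", "dCa_coil") %in% names(random_coil)))
    abort_input("random_coil needs residue_id and dCa_coil columns")
  joined <- table_a |>
    dplyr::inner_join(table_b, by = "residue_id",
                      suffix = c("_a", "_b")) |>
    dplyr::inner_join(random_coil, by = "residue_id") |>
    dplyr::filter(stats::complete.cases(.data$dCa_a, .data$dCa_b,
                                        .data$dCa_coil))
  if (nrow(joined) < 3)
    abort_input("need >= 3 residues with Calpha shifts in both states")
  y <- joined$dCa_a - joined$dCa_coil
  x <- joined$dCa_b - joined$dCa_coil
  fit <- stats::lm(y ~ x)
  tibble::tibble(
    slope = stats::coef(fit)[["x"]],
    intercept = stats::coef(fit)[["(Intercept)"]],
    r = stats::cor(x, y),
    n = nrow(joined)
  )
}
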