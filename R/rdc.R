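# Residual dipolar coupling analysis: couplings -> RDCs, N-H bond
# vectors from structure coordinates, alignment-tensor determination by
# singular value decomposition, prediction, and R-factor scoring.
#
# The dipolar prefactor is absorbed into the Saupe elements, so the
# tensor is expressed directly in Hz (the axial magnitude Da is the Hz
# value familiar from D(theta) = Da*(3cos^2(theta)-1) for an axially
# symmetric tensor). Five independent elements are carried in the order
# (Szz, Syy - Sxx, Sxy, Sxz, Syz), in the frame of the input structure.

#' RDC from scalar couplings in aligned and isotropic media
#'
#' `D = J_aligned - J_iso`.
#'
#' @param J_aligned,J_iso 1J(NH) splittings, Hz. Vectorized.
#' @return Coupling(s) in Hz.
#' @export
rdc_from_couplings <- function(J_aligned, J_iso) {
  J_aligned - J_iso
}

#' Extract N-H bond unit vectors from a PDB file
#'
#' Reads backbone N and amide H (atom name `H` or `HN`) coordinates and
#' returns normalized N->H vectors per residue. Residues without an
#' amide proton (prolines, N-terminus) are skipped with a message.
#'
#' @param pdb_path Path to a PDB file.
#' @param chain Optional chain identifier; default uses all chains.
#' @param model Model number for multi-model (NMR) files; default 1.
#' @return Tibble with `residue_id`, `x`, `y`, `z` (unit vectors).
#' @export
extract_nh_vectors <- function(pdb_path, chain = NULL, model = 1) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    abort_input("extract_nh_vectors requires the bio3d package")
  if (!file.exists(pdb_path)) abort_input("PDB file not found")
  pdb <- bio3d::read.pdb(pdb_path, multi = TRUE)
  at <- pdb$atom
  if (length(dim(pdb$xyz)) == 2 && nrow(pdb$xyz) >= model) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  } else if (model != 1) {
    abort_input("requested model not present in file")
  }
  if (!is.null(chain)) {
    at <- at[at$chain %in% chain, ]
    if (nrow(at) == 0) abort_input("requested chain not present in file")
  }
  nn <- at[at$elety == "N", ]
  hh <- at[at$elety %in% c("H", "HN"), ]
  key <- function(d) paste(d$chain, d$resno)
  m <- match(key(nn), key(hh))
  skipped <- nn$resno[is.na(m)]
  if (length(skipped) > 0)
    message("residue(s) without amide H skipped: ",
            paste(skipped, collapse = ", "))
  nn <- nn[!is.na(m), ]
  hh <- hh[m[!is.na(m)], ]
  v <- cbind(hh$x - nn$x, hh$y - nn$y, hh$z - nn$z)
  nrm <- sqrt(rowSums(v^2))
  zero <- nrm < 1e-9
  if (any(zero)) {
    warning("zero-length N-H vector(s) skipped: ",
            paste(nn$resno[zero], collapse = ", "))
    nn <- nn[!zero, ]; v <- v[!zero, , drop = FALSE]
    nrm <- nrm[!zero]
  }
  tibble::tibble(residue_id = nn$resno,
                 x = v[, 1] / nrm, y = v[, 2] / nrm, z = v[, 3] / nrm)
}

# 5-column orientation design matrix for unit vectors; with s =
# (Szz, Syy - Sxx, Sxy, Sxz, Syz), D = A %*% s
rdc_design_matrix <- function(vectors) {
  with(vectors, cbind(
    (3 * z^2 - 1) / 2,
    (y^2 - x^2) / 2,
    2 * x * y,
    2 * x * z,
    2 * y * z
  ))
}

# 3x3 traceless symmetric matrix from the 5-element parameterization
saupe_matrix <- function(s) {
  szz <- s[1]; d <- s[2]
  sxx <- (-szz - d) / 2
  syy <- (-szz + d) / 2
  matrix(c(sxx, s[3], s[4],
           s[3], syy, s[5],
           s[4], s[5], szz), nrow = 3)
}

#' Build an alignment tensor from axial magnitude and rhombicity
#'
#' Constructs the 5-element Saupe parameterization of a tensor with
#' axial magnitude `Da` (Hz), rhombicity `R` (|R| <= 2/3) and principal
#' axes aligned with the coordinate frame: eigenvalues
#' `(Da*(-1 + 1.5R), Da*(-1 - 1.5R), 2*Da)` for (x, y, z).
#'
#' @param Da Axial magnitude, Hz.
#' @param rhombicity Rhombicity R; default 0 (axially symmetric).
#' @return Numeric 5-vector `(Szz, Syy - Sxx, Sxy, Sxz, Syz)`.
#' @export
#' @examples
#' saupe_from_param(10)      # axially symmetric, D(z) = 20 Hz
saupe_from_param <- function(Da, rhombicity = 0) {
  if (abs(rhombicity) > 2 / 3)
    abort_input("|rhombicity| must be <= 2/3")
  sxx <- Da * (-1 + 1.5 * rhombicity)
  syy <- Da * (-1 - 1.5 * rhombicity)
  c(2 * Da, syy - sxx, 0, 0, 0)
}

#' Predict RDCs from an alignment tensor and bond vectors
#'
#' `D(v) = v' S v` with the 3x3 Saupe reconstruction of the tensor in
#' Hz units.
#'
#' @param tensor 5-vector `(Szz, Syy - Sxx, Sxy, Sxz, Syz)` in Hz, or
#'   an `rdc_fit` object.
#' @param vectors Data frame with `residue_id`, `x`, `y`, `z`.
#' @return Tibble with `residue_id` and `D_calc_Hz`.
#' @export
predict_rdc <- function(tensor, vectors) {
  if (inherits(tensor, "rdc_fit")) tensor <- tensor$saupe
  if (length(tensor) != 5) abort_input("tensor must have 5 elements")
  tibble::tibble(
    residue_id = vectors$residue_id,
    D_calc_Hz = drop(rdc_design_matrix(vectors) %*% tensor)
  )
}

#' Quality R-factor for observed versus back-calculated RDCs
#'
#' `R = sqrt(mean((D_obs - D_calc)^2) / (2 * mean(D_obs^2)))`: zero for
#' perfect agreement, 1/sqrt(2) for predictions of zero, invariant to a
#' common rescaling of both inputs.
#'
#' @param D_obs,D_calc Equal-length coupling vectors, Hz.
#' @return R-factor (fraction; multiply by 100 for percent).
#' @export
r_factor <- function(D_obs, D_calc) {
  if (length(D_obs) != length(D_calc) || length(D_obs) == 0)
    abort_input("D_obs and D_calc must be equal-length and non-empty")
  if (all(D_obs == 0)) abort_input("all-zero D_obs: R-factor undefined")
  sqrt(mean((D_obs - D_calc)^2) / (2 * mean(D_obs^2)))
}

#' Fit an alignment tensor to RDCs by singular value decomposition
#'
#' Solves the linear least-squares problem `D_obs = A s` for the five
#' independent Saupe elements through the SVD pseudoinverse of the
#' orientation design matrix `A`, then diagonalizes the reconstructed
#' tensor for the axial magnitude, rhombicity and principal-axis
#' orientation (z-y-z Euler angles).
#'
#' @param rdc Data frame with `residue_id`, `D_obs_Hz` and optionally
#'   `D_err_Hz`.
#' @param vectors Data frame with `residue_id`, `x`, `y`, `z` unit
#'   bond vectors. At least 5 residues must match `rdc`; unmatched
#'   entries on either side are reported in the result.
#' @return Object of class `rdc_fit`: list with `saupe` (5-vector),
#'   `saupe_matrix`, `Da_Hz`, `rhombicity`, `euler_deg`, `predictions`
#'   (tibble `residue_id`, `D_obs_Hz`, `D_calc_Hz`), `r_factor`, `rms_Hz`,
#'   `n`, `unmatched_rdc`, `unmatched_vectors`.
#' @export
#' @examples
#' v <- tibble::tibble(residue_id = 1:8,
#'                     x = c(1, 0, 0, 1, 0, 1, -1, 0.5) /
#'                       sqrt(c(1, 1, 1, 2, 2, 2, 3, 1.25)),
#'                     y = c(0, 1, 0, 1, 1, 0, 1, 1) /
#'                       sqrt(c(1, 1, 1, 2, 2, 2, 3, 1.25)),
#'                     z = c(0, 0, 1, 0, 1, 1, 1, 0) /
#'                       sqrt(c(1, 1, 1, 2, 2, 2, 3, 1.25)))
#' d <- simulate_rdc(saupe_from_param(10, 0.2), v)
#' fit <- svd_fit_rdc(d, v)
#' fit$r_factor
svd_fit_rdc <- function(rdc, vectors) {
  if (!all(c("residue_id", "D_obs_Hz") %in% names(rdc)))
    abort_input("rdc needs residue_id and D_obs_Hz columns")
  if (!all(c("residue_id", "x", "y", "z") %in% names(vectors)))
    abort_input("vectors needs residue_id, x, y, z columns")
  matched <- dplyr::inner_join(rdc, vectors, by = "residue_id")
  unmatched_rdc <- setdiff(rdc$residue_id, matched$residue_id)
  unmatched_vec <- setdiff(vectors$residue_id, matched$residue_id)
  if (length(unmatched_rdc) + length(unmatched_vec) > 0)
    message(length(unmatched_rdc), " RDC row(s) and ",
            length(unmatched_vec),
            " vector row(s) had no partner and were not fit")
  if (nrow(matched) < 5)
    abort_input("need >= 5 residues with both an RDC and a bond vector")

  A <- rdc_design_matrix(matched)
  sv <- svd(A)
  if (min(sv$d) / max(sv$d) < 1e-8)
    abort_input("rank-deficient orientation design: geometry unfittable")
  s <- sv$v %*% ((crossprod(sv$u, matched$D_obs_Hz)) / sv$d)
  s <- drop(s)

  S <- saupe_matrix(s)
  eg <- eigen(S, symmetric = TRUE)
  ord <- order(abs(eg$values))          # |Sxx| <= |Syy| <= |Szz|
  vals <- eg$values[ord]                # (x, y, z) principal values
  vecs <- eg$vectors[, ord]
  if (det(vecs) < 0) vecs[, 1] <- -vecs[, 1]
  Da <- vals[3] / 2
  rhomb <- (vals[1] - vals[2]) / (3 * Da)
  # z-y-z Euler angles of the rotation molecular frame -> principal frame
  beta <- acos(pmin(pmax(vecs[3, 3], -1), 1))
  if (abs(sin(beta)) > 1e-8) {
    alpha <- atan2(vecs[2, 3], vecs[1, 3])
    gamma <- atan2(vecs[3, 2], -vecs[3, 1])
  } else {
    alpha <- atan2(vecs[2, 1], vecs[1, 1])
    gamma <- 0
  }
  d_calc <- drop(A %*% s)

  structure(list(
    saupe = s,
    saupe_matrix = S,
    Da_Hz = Da,
    rhombicity = rhomb,
    euler_deg = c(alpha = alpha, beta = beta, gamma = gamma) * 180 / pi,
    predictions = tibble::tibble(residue_id = matched$residue_id,
                                 D_obs_Hz = matched$D_obs_Hz,
                                 D_calc_Hz = d_calc),
    r_factor = r_factor(matched$D_obs_Hz, d_calc),
    rms_Hz = sqrt(mean((matched$D_obs_Hz - d_calc)^2)),
    n = nrow(matched),
    unmatched_rdc = unmatched_rdc,
    unmatched_vectors = unmatched_vec
  ), class = "rdc_fit")
}
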