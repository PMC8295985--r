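# Shared fixture builders: everything is generated in code at test time.

# minimal PDB writer for backbone N/H (and CA for realism) atoms
write_mini_pdb <- function(path, residues) {
  # residues: data frame with resno, resn, chain, and named coordinate
  # columns n_x..n_z, h_x..h_z (h_* may be NA for proline-like residues)
  lines <- character(0)
  serial <- 1
  fmt <- function(serial, name, resn, chain, resno, x, y, z) {
    sprintf("ATOM  %5d  %-3s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            serial, name, resn, chain, resno, x, y, z, 1, 0)
  }
  for (i in seq_len(nrow(residues))) {
    r <- residues[i, ]
    lines <- c(lines, fmt(serial, "N", r$resn, r$chain, r$resno,
                          r$n_x, r$n_y, r$n_z))
    serial <- serial + 1
    if (!is.na(r$h_x)) {
      lines <- c(lines, fmt(serial, "H", r$resn, r$chain, r$resno,
                            r$h_x, r$h_y, r$h_z))
      serial <- serial + 1
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# n roughly uniformly oriented unit vectors (deterministic)
unit_vectors <- function(n, seed = 1) {
  withr::with_seed(seed, {
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    tibble::tibble(residue_id = seq_len(n),
                   x = v[, 1], y = v[, 2], z = v[, 3])
  })
}

# random 3D rotation matrix (deterministic)
random_rotation <- function(seed = 1) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}
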