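# shared fixture builders and oracles

# write a minimal CIF text and return its path
write_cif_text <- function(lines, path = tempfile(fileext = ".cif")) {
  writeLines(lines, path)
  path
}

cubic_one_atom_cif <- function(a = 10, frac = "0.500000", occ = "1.0",
                               extra = character(0)) {
  write_cif_text(c(
    "data_test",
    sprintf("_cell_length_a %.4f", a),
    sprintf("_cell_length_b %.4f", a),
    sprintf("_cell_length_c %.4f", a),
    "_cell_angle_alpha 90",
    "_cell_angle_beta 90",
    "_cell_angle_gamma 90",
    extra,
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    sprintf("C1 C %s %s %s %s", frac, frac, frac, occ)
  ))
}

# brute-force oracle: squared distance from a Cartesian point to the nearest
# atom over an exhaustive 27-neighbor-cell enumeration
oracle_nearest_d2 <- function(cell, point_frac, atoms_frac) {
  best <- Inf
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    img <- sweep(atoms_frac, 2, c(sx, sy, sz), "+")
    d <- frac_to_cart(cell, img) -
      matrix(drop(frac_to_cart(cell, point_frac)), nrow(img), 3, byrow = TRUE)
    best <- min(best, min(rowSums(d^2)))
  }
  best
}

# brute-force point-in-union classification over 27 neighbor cells
oracle_in_union <- function(cell, point_frac, atoms_frac, radii) {
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    img <- sweep(atoms_frac, 2, c(sx, sy, sz), "+")
    d2 <- rowSums((frac_to_cart(cell, img) -
      matrix(drop(frac_to_cart(cell, point_frac)), nrow(img), 3, byrow = TRUE))^2)
    if (any(d2 <= radii^2)) return(TRUE)
  }
  FALSE
}

# a small molecular-looking P1 structure: C-H pair plus an O, in a
# triclinic cell
triclinic_chx_structure <- function(ch_dist = 0.95) {
  cell <- unit_cell(7, 8, 9, 80, 95, 103)
  c_frac <- c(0.3, 0.4, 0.5)
  # place H at ch_dist along a fixed Cartesian direction
  u <- c(1, 2, 2) / 3
  h_cart <- drop(frac_to_cart(cell, c_frac)) + u * ch_dist
  h_frac <- drop(cart_to_frac(cell, h_cart))
  crystal_structure(
    cell,
    tibble::tibble(
      label = c("C1", "H1", "O1"),
      element = c("C", "H", "O"),
      fx = c(c_frac[1], h_frac[1], 0.8),
      fy = c(c_frac[2], h_frac[2], 0.1),
      fz = c(c_frac[3], h_frac[3], 0.2)
    )
  )
}
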