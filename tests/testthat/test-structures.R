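test_that("unit cell volume matches the closed-form triclinic expression", {
  cases <- list(
    c(10, 10, 10, 90, 90, 90),
    c(5.4, 7.1, 9.3, 90, 101.2, 90),
    c(6.2, 7.8, 8.1, 80.5, 95.3, 103.1)
  )
  for (p in cases) {
    cell <- unit_cell(p[1], p[2], p[3], p[4], p[5], p[6])
    ca <- cos(p[4] * pi / 180); cb <- cos(p[5] * pi / 180); cg <- cos(p[6] * pi / 180)
    v_ref <- p[1] * p[2] * p[3] * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
    expect_equal(cell$volume, v_ref, tolerance = 1e-9)
    # the orthogonalization transform must reproduce the same volume
    expect_equal(abs(det(cell$ortho)), v_ref, tolerance = 1e-9)
  }
  expect_error(unit_cell(10, 10, 10, alpha = 0), "angles")
  expect_error(unit_cell(-1, 10, 10), "positive")
})

test_that("read_cif parses cell, coordinates, su values and Z", {
  path <- cubic_one_atom_cif(a = 10, extra = "_cell_formula_units_Z 4")
  s <- read_cif(path)
  expect_s3_class(s, "crystal_structure")
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$cell$volume, 1000)
  expect_equal(s$Z, 4)

  # parenthesis su notation
  path2 <- cubic_one_atom_cif(frac = "0.1234(5)")
  s2 <- read_cif(path2)
  expect_equal(s2$atoms$fx, 0.1234)
  expect_equal(s2$atoms$su_x, 0.0005)

  expect_equal(parse_cif_number("10.53(12)"), c(10.53, 0.12))
  expect_equal(parse_cif_number("-0.25"), c(-0.25, 0))
  expect_true(is.na(parse_cif_number(".")[1]))
})

test_that("read_cif applies the disorder curation policy", {
  path <- cubic_one_atom_cif(occ = "0.5")
  expect_error(read_cif(path, strict = TRUE), "disorder")
  # permissive mode: a lone partial site belongs to no ordered component
  # only when its disorder group is set; occupancy < 1 alone keeps the site
  expect_warning(s <- read_cif(path, strict = FALSE), "disorder")
  expect_equal(s$atoms$occ, 1)
})

test_that("read_cif rejects files without coordinates or cell", {
  path <- write_cif_text(c(
    "data_x", "_cell_length_a 10", "_cell_length_b 10", "_cell_length_c 10",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90"
  ))
  expect_error(read_cif(path), "no coordinates")
  path2 <- write_cif_text(c("data_x", "_cell_length_a 10"))
  expect_error(read_cif(path2), "missing|format")
  expect_error(read_cif(tempfile()), "not found")
})

test_that("symmetry operators parse, including fractions and coefficients", {
  op <- voidpart:::parse_symop("-x, y+1/2, 1/2-z")
  expect_equal(op$rot, matrix(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), 3, byrow = TRUE))
  expect_equal(op$tra, c(0, 0.5, 0.5))
  expect_error(voidpart:::parse_symop("x, y"), "parse")
})

test_that("expand_to_cell honours identity, centering and special positions", {
  cell <- unit_cell(10, 10, 10)
  at <- tibble::tibble(label = "C1", element = "C", fx = 0.1, fy = 0.2, fz = 0.3)

  # P1: unchanged
  s <- crystal_structure(cell, at)
  expect_equal(expand_to_cell(s)$atoms[, c("fx", "fy", "fz")],
               s$atoms[, c("fx", "fy", "fz")])

  # body centering doubles the count
  s2 <- crystal_structure(cell, at, symops = c("x, y, z", "x+1/2, y+1/2, z+1/2"))
  e2 <- expand_to_cell(s2)
  expect_equal(nrow(e2$atoms), 2)

  # an atom on an inversion center collapses back to one site under P-1
  s3 <- crystal_structure(
    cell,
    tibble::tibble(label = "C1", element = "C", fx = 0, fy = 0, fz = 0),
    symops = c("x, y, z", "-x, -y, -z")
  )
  expect_equal(nrow(expand_to_cell(s3)$atoms), 1)

  # general position under P-1 gives two atoms, verified against brute force
  s4 <- crystal_structure(at = at, cell = cell, symops = c("x, y, z", "-x, -y, -z"))
  e4 <- expand_to_cell(s4)
  expect_equal(nrow(e4$atoms), 2)
  brute <- rbind(c(0.1, 0.2, 0.3), voidpart:::wrap_frac(-c(0.1, 0.2, 0.3)))
  got <- as.matrix(e4$atoms[, c("fx", "fy", "fz")])
  expect_equal(got[order(got[, 1]), ], brute[order(brute[, 1]), ],
               ignore_attr = TRUE)
})

test_that("expansion is idempotent", {
  cell <- unit_cell(8, 9, 10, 85, 92, 95)
  s <- crystal_structure(
    cell,
    tibble::tibble(label = c("C1", "N1"), element = c("C", "N"),
                   fx = c(0.12, 0.77), fy = c(0.33, 0.05), fz = c(0.91, 0.48)),
    symops = c("x, y, z", "-x, y+1/2, -z+1/2")
  )
  once <- expand_to_cell(s)
  twice <- expand_to_cell(once)
  expect_identical(once$atoms, twice$atoms)
})

test_that("normalize_xh rescales the bond along the same direction", {
  s <- triclinic_chx_structure(ch_dist = 0.95)
  before <- s$atoms
  out <- normalize_xh(s)
  # heavy atoms bit-identical
  expect_identical(out$atoms[c(1, 3), ], before[c(1, 3), ])
  cell <- s$cell
  v_before <- voidpart:::min_image_vec(cell, as.numeric(before[1, c("fx", "fy", "fz")]),
                                       as.numeric(before[2, c("fx", "fy", "fz")]))
  v_after <- voidpart:::min_image_vec(cell, as.numeric(out$atoms[1, c("fx", "fy", "fz")]),
                                      as.numeric(out$atoms[2, c("fx", "fy", "fz")]))
  d_after <- sqrt(sum(v_after^2))
  expect_equal(d_after, 1.089, tolerance = 1e-9)
  # unit direction preserved
  expect_equal(v_after / d_after, v_before / sqrt(sum(v_before^2)), tolerance = 1e-12)

  # idempotence: a bond already at the table distance is untouched
  again <- normalize_xh(out)
  expect_equal(as.matrix(again$atoms[, c("fx", "fy", "fz")]),
               as.matrix(out$atoms[, c("fx", "fy", "fz")]), tolerance = 1e-9)

  # structures without hydrogen pass through unchanged
  noh <- make_structure("single_sphere")
  expect_identical(normalize_xh(noh)$atoms, noh$atoms)
})

test_that("a hydrogen with no bonded heavy atom is left in place with a warning", {
  cell <- unit_cell(10, 10, 10)
  s <- crystal_structure(cell, tibble::tibble(
    label = c("C1", "H1"), element = c("C", "H"),
    fx = c(0.1, 0.6), fy = 0.1, fz = 0.1
  ))
  expect_warning(out <- normalize_xh(s), "no bonded heavy atom")
  expect_identical(out$atoms, s$atoms)
})

test_that("assign_radii fills from the table and errors on missing elements", {
  cell <- unit_cell(10, 10, 10)
  s <- crystal_structure(cell, tibble::tibble(
    label = c("C1", "C2"), element = "C", fx = c(0.1, 0.5), fy = 0.5, fz = 0.5
  ))
  out <- assign_radii(s)
  expect_equal(out$atoms$r_vdw, rep(vdw_radii()$r_vdw[vdw_radii()$element == "C"], 2))

  mixed <- crystal_structure(cell, tibble::tibble(
    label = c("C1", "H1", "N1", "O1"), element = c("C", "H", "N", "O"),
    fx = c(0.1, 0.2, 0.3, 0.4), fy = 0.5, fz = 0.5
  ))
  r <- assign_radii(mixed)$atoms$r_vdw
  expect_equal(length(unique(r)), 4)

  truncated <- vdw_radii()[vdw_radii()$element == "H", ]
  expect_error(assign_radii(mixed, truncated), "C.*N.*O")
})

test_that("padded_atom_list adds exactly the images that can reach the cell", {
  # atom at the cell center with a small radius: no image qualifies
  s <- make_structure("single_sphere", r = 0.5, a = 20)
  expect_equal(nrow(padded_atom_list(s)), 1)

  # atom at the origin of a cubic cell: 7 additional corner images
  cell <- unit_cell(10, 10, 10)
  s2 <- crystal_structure(cell, tibble::tibble(
    label = "C1", element = "C", fx = 0, fy = 0, fz = 0, r_vdw = 1.7
  ))
  expect_equal(nrow(padded_atom_list(s2)), 8)
})

test_that("padded list classification matches the 27-cell brute force", {
  set.seed(11)
  for (rep in 1:3) {
    cell <- unit_cell(6 + runif(1), 7 + runif(1), 8 + runif(1),
                      80 + runif(1, 0, 20), 85 + runif(1, 0, 10), 95 + runif(1, 0, 15))
    n_at <- 4
    afrac <- matrix(runif(3 * n_at), ncol = 3)
    radii <- runif(n_at, 1.2, 2.0)
    s <- crystal_structure(cell, tibble::tibble(
      label = paste0("C", 1:n_at), element = "C",
      fx = afrac[, 1], fy = afrac[, 2], fz = afrac[, 3], r_vdw = radii
    ))
    padded <- padded_atom_list(s)
    pts <- matrix(runif(3 * 150), ncol = 3)
    mask <- voidpart:::classify_points_mask(pts, padded, cell)
    oracle <- vapply(seq_len(nrow(pts)), function(i) {
      oracle_in_union(cell, pts[i, ], afrac, radii)
    }, logical(1))
    expect_identical(mask, oracle)
  }
})
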