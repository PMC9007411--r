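test_that("classify_points handles the degenerate and closed-form cases", {
  s <- make_structure("single_sphere", r = 1.7, a = 10)
  padded <- padded_atom_list(s)
  # point at the atom center and a far point
  expect_equal(classify_points(rbind(c(0.5, 0.5, 0.5)), padded, s$cell), 1)
  expect_equal(classify_points(rbind(c(0.01, 0.01, 0.01)), padded, s$cell), 0)

  # fraction of hits vs the analytic volume fraction, within 3 binomial sigma
  n <- 1e4
  set.seed(21)
  pts <- matrix(runif(3 * n), ncol = 3)
  frac_hit <- classify_points(pts, padded, s$cell) / n
  p_true <- (4 / 3) * pi * 1.7^3 / 1000
  expect_lt(abs(frac_hit - p_true), 3 * sqrt(p_true * (1 - p_true) / n))

  # empty atom list: everything is void, with a warning
  empty <- crystal_structure(s$cell, s$atoms[0, ])
  expect_warning(n0 <- classify_points(pts, empty$atoms, s$cell), "empty")
  expect_equal(n0, 0)
})

test_that("run_volume recovers closed-form sphere-union volumes", {
  cfg <- sampler_config(n_points = 1e5, seed = 101, max_runs = 5)

  s1 <- make_structure("single_sphere", r = 1.7, a = 10)
  r1 <- suppressWarnings(run_volume(s1, cfg))
  expect_lt(abs(r1$v_net - attr(s1, "analytic_v_net")), 3 * r1$sigma_net)

  s2 <- make_structure("sphere_pair", r = 1.5, d = 2, a = 12)
  r2 <- suppressWarnings(run_volume(s2, cfg))
  expect_equal(attr(s2, "analytic_v_net"), 26.180, tolerance = 1e-4)
  expect_lt(abs(r2$v_net - attr(s2, "analytic_v_net")), 3 * r2$sigma_net)
})

test_that("volume results conserve the cell volume exactly", {
  s <- make_structure("fcc_touching", r = 1.5)
  r <- suppressWarnings(run_volume(s, sampler_config(n_points = 2e4, seed = 5, max_runs = 3,
                                                     target_rel_sigma = Inf)))
  expect_identical(r$v_net + r$v_void, r$v_cell)
  expect_equal(r$v_net, mean(r$per_run_v_net), tolerance = 1e-12)
  expect_gte(r$sigma_net, 0)
  expect_true(r$v_net >= 0 && r$v_net <= r$v_cell)
})

test_that("identical seed and config give bit-identical runs", {
  s <- make_structure("sphere_pair", r = 1.5, d = 2, a = 12)
  cfg <- sampler_config(n_points = 2e4, seed = 77, max_runs = 4, target_rel_sigma = Inf)
  a <- suppressWarnings(run_volume(s, cfg))
  b <- suppressWarnings(run_volume(s, cfg))
  expect_identical(a$per_run_v_net, b$per_run_v_net)
})

test_that("adding an atom never decreases the network volume", {
  cell <- unit_cell(12, 12, 12)
  base <- crystal_structure(cell, tibble::tibble(
    label = "C1", element = "C", fx = 0.4, fy = 0.5, fz = 0.5, r_vdw = 1.7
  ))
  bigger <- crystal_structure(cell, tibble::tibble(
    label = c("C1", "C2"), element = "C", fx = c(0.4, 0.6), fy = 0.5, fz = 0.5,
    r_vdw = 1.7
  ))
  cfg <- sampler_config(n_points = 2e4, seed = 9, min_runs = 2, max_runs = 2,
                        target_rel_sigma = Inf)
  va <- run_volume(base, cfg)$v_net
  vb <- run_volume(bigger, cfg)$v_net
  expect_gte(vb, va)
})

test_that("the sampler warns and reports non-convergence when the target is unreachable", {
  s <- make_structure("single_sphere", r = 1.7, a = 10)
  cfg <- sampler_config(n_points = 1000, target_rel_sigma = 1e-4, max_runs = 3)
  expect_warning(r <- run_volume(s, cfg), "not reached")
  expect_false(r$converged)
  expect_equal(r$n_runs, 3)
})

test_that("sampler_config validates its bounds", {
  expect_error(sampler_config(n_points = 0), "n_points")
  expect_error(sampler_config(min_runs = 1), "min_runs")
  expect_error(sampler_config(min_runs = 5, max_runs = 3), "max_runs")
})

test_that("coordinate-uncertainty propagation behaves like the MC spread when su = 0", {
  s <- make_structure("sphere_pair", r = 1.5, d = 2, a = 12, su = 0)
  cfg <- sampler_config(n_points = 2e4)
  expect_message(
    pr <- propagate_uncertainty(s, cfg, n_models = 12, seed = 31),
    "Monte Carlo reproducibility"
  )
  mc <- suppressWarnings(run_volume(s, sampler_config(
    n_points = 2e4, seed = 32, min_runs = 12, max_runs = 12, target_rel_sigma = 0
  )))
  expect_lt(pr$sigma_net, 2 * mc$sigma_net)
  expect_gt(pr$sigma_net, mc$sigma_net / 2)
})

test_that("coordinate uncertainty inflates the volume spread", {
  exact <- make_structure("sphere_pair", r = 1.5, d = 2, a = 12, su = 0)
  fuzzy <- make_structure("sphere_pair", r = 1.5, d = 2, a = 12, su = 0.02)
  cfg <- sampler_config(n_points = 5e4)
  p0 <- suppressMessages(propagate_uncertainty(exact, cfg, n_models = 20, seed = 41))
  p1 <- propagate_uncertainty(fuzzy, cfg, n_models = 20, seed = 41)
  expect_gt(p1$sigma_net, p0$sigma_net)
  expect_error(propagate_uncertainty(exact, cfg, n_models = 1), "n_models")
})

test_that("fragment volumes reproduce isolated-union closed forms", {
  cfg <- sampler_config(n_points = 5e4, seed = 51, max_runs = 3, target_rel_sigma = Inf)

  # whole cell contents of a fully interior sphere = periodic network volume
  s <- make_structure("single_sphere", r = 1.7, a = 10)
  rv <- run_volume(s, sampler_config(n_points = 5e4, seed = 52, max_runs = 3,
                                     target_rel_sigma = Inf))
  fv <- fragment_volume(s, list(1), cfg)
  expect_lt(abs(fv$v_molecule - rv$v_net), 3 * sqrt(fv$sigma^2 + rv$sigma_net^2))

  # two disjoint molecules: per-molecule volume = single-sphere volume
  sp <- make_structure("sphere_pair", r = 1.5, d = 6, a = 20)
  f2 <- fragment_volume(sp, list(1, 2), cfg)
  expect_lt(abs(f2$v_molecule - (4 / 3) * pi * 1.5^3), 3 * f2$sigma + 0.05)

  # overlapping molecules: per-molecule volume below the isolated volume
  so <- make_structure("sphere_pair", r = 1.5, d = 2, a = 20)
  f3 <- fragment_volume(so, list(1, 2), cfg)
  expect_lt(f3$v_molecule, (4 / 3) * pi * 1.5^3 - 3 * f3$sigma)

  expect_error(fragment_volume(s, list(), cfg), "empty")
})

test_that("packing coefficient is the occupied cell fraction with scaled sigma", {
  r <- voidpart:::new_volume_result(
    v_cell = 1000, v_net = 750, sigma_net = 10, n_points = 1, n_runs = 3,
    converged = TRUE, per_run_v_net = c(750, 750, 750)
  )
  pc <- packing_coefficient(r)
  expect_equal(pc$x, 0.75)
  expect_equal(pc$sigma_x, 0.01)

  r0 <- voidpart:::new_volume_result(1000, 0, 0, 1, 3, TRUE, c(0, 0, 0))
  expect_equal(packing_coefficient(r0)$x, 0)
})

test_that("occupancy maps round-trip and match the analytic fraction", {
  s <- make_structure("single_sphere", r = 1.7, a = 10)
  path <- tempfile(fileext = ".cube")
  export_occupancy_map(s, grid = c(40, 40, 40), path = path)
  m <- voidpart:::read_occupancy_map(path)
  expect_equal(m$grid, c(40, 40, 40))
  frac <- mean(m$values)
  expect_lt(abs(frac - attr(s, "analytic_v_net") / 1000), 0.002)

  # round trip is exact
  path2 <- tempfile(fileext = ".cube")
  export_occupancy_map(s, grid = c(40, 40, 40), path = path2)
  m2 <- voidpart:::read_occupancy_map(path2)
  expect_identical(m$values, m2$values)

  # empty structure gives an all-zero grid
  empty <- crystal_structure(s$cell, s$atoms[0, ])
  path3 <- tempfile(fileext = ".cube")
  export_occupancy_map(empty, grid = c(4, 4, 4), path = path3)
  expect_true(all(voidpart:::read_occupancy_map(path3)$values == 0))

  expect_error(export_occupancy_map(s, grid = c(1, 4, 4), path = tempfile()), "voxels")
})
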