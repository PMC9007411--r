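#' Sampler configuration
#'
#' Controls the Monte Carlo volume estimation: points per run, the target
#' relative precision of the network volume, and the run-count bounds. The
#' defaults (one million points, target sigma(V_net)/V_net of 0.1%, three to
#' ten runs) reach the target within three runs for typical molecular
#' crystals.
#'
#' @param n_points Random points per run.
#' @param target_rel_sigma Convergence target for the population relative
#'   standard deviation of the per-run network volumes.
#' @param min_runs Minimum number of runs (at least 2; a population standard
#'   deviation needs two values).
#' @param max_runs Maximum number of runs.
#' @param seed Optional integer master seed. Per-run substreams are derived
#'   from it, so results are reproducible regardless of when convergence
#'   stops the loop.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_points = 1e6, target_rel_sigma = 0.001,
                           min_runs = 3, max_runs = 10, seed = NULL) {
  if (n_points < 1) abort("n_points must be at least 1")
  if (min_runs < 2) abort("min_runs must be at least 2")
  if (max_runs < min_runs) abort("max_runs must be >= min_runs")
  structure(
    list(
      n_points = as.integer(n_points),
      target_rel_sigma = target_rel_sigma,
      min_runs = as.integer(min_runs),
      max_runs = as.integer(max_runs),
      seed = seed
    ),
    class = "sampler_config"
  )
}

# derive k reproducible substream seeds from a master seed without
# disturbing the caller's RNG state when a seed is given
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(sample.int(2147483646L, k))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(2147483646L, k)
}

# population standard deviation (divide by n, not n - 1): the per-run scatter
# is the quantity of interest, not the uncertainty of its mean
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Classify sample points as network or void
#'
#' A point belongs to the network when its Cartesian distance to any atom in
#' the padded list is less than or equal to that atom's van der Waals radius
#' (points exactly on a sphere surface count as network); otherwise it
#' belongs to the voids.
#'
#' @param points An n x 3 matrix of fractional coordinates in `[0, 1)`.
#' @param atoms A padded atom tibble from [padded_atom_list()].
#' @param cell The [unit_cell()].
#' @return The number of network points.
#' @export
classify_points <- function(points, atoms, cell) {
  sum(classify_points_mask(points, atoms, cell))
}

classify_points_mask <- function(points, atoms, cell) {
  pts <- rbind_coords(points)
  n <- nrow(pts)
  if (is.null(atoms) || !nrow(atoms)) {
    warn("empty atom list: all points classified as void")
    return(logical(n))
  }
  cart <- frac_to_cart(cell, pts)
  px <- cart[, 1]; py <- cart[, 2]; pz <- cart[, 3]
  acart <- frac_to_cart(cell, as.matrix(atoms[, c("fx", "fy", "fz")]))
  r2 <- atoms$r_vdw^2
  inside <- logical(n)
  rem <- seq_len(n)
  for (j in seq_len(nrow(acart))) {
    if (!length(rem)) break
    dx <- px[rem] - acart[j, 1]
    dy <- py[rem] - acart[j, 2]
    dz <- pz[rem] - acart[j, 3]
    hit <- dx * dx + dy * dy + dz * dz <= r2[j]
    if (any(hit)) {
      inside[rem[hit]] <- TRUE
      rem <- rem[!hit]
    }
  }
  inside
}

#' Monte Carlo network and void volumes
#'
#' Uniform random points are thrown into the unit cell; the fraction landing
#' inside the union of van der Waals spheres (including spheres of periodic
#' images overlapping the cell) estimates `V_net = (n_net/n) V`, with
#' `V_void = V - V_net` by subtraction. Independent runs repeat until the
#' population relative standard deviation of the per-run network volumes
#' drops below the target (earliest after `min_runs` runs); if `max_runs`
#' is reached without convergence the result is returned with
#' `converged = FALSE` and a warning suggesting a larger `n_points`.
#'
#' @param structure A [crystal_structure()] with radii assigned (expand the
#'   cell first for non-P1 structures).
#' @param config A [sampler_config()].
#' @return An object of class `volume_result` with fields `v_cell`, `v_net`,
#'   `v_void` (all cubic angstroms; `v_net + v_void == v_cell` exactly),
#'   `sigma_net`, `n_points`, `n_runs`, `converged` and `per_run_v_net`.
#' @export
#' @examples
#' s <- make_structure("single_sphere", r = 1.7, a = 10)
#' run_volume(s, sampler_config(n_points = 1e4, seed = 1))
run_volume <- function(structure, config = sampler_config()) {
  stopifnot(inherits(structure, "crystal_structure"))
  padded <- padded_atom_list(structure)
  run_volume_padded(padded, structure$cell, config)
}

run_volume_padded <- function(padded, cell, config) {
  seeds <- derive_seeds(config$seed, config$max_runs)
  v_cell <- cell$volume
  per_run <- numeric(0)
  converged <- FALSE
  for (i in seq_len(config$max_runs)) {
    set.seed(seeds[i])
    pts <- matrix(runif(3 * config$n_points), ncol = 3)
    n_net <- classify_points(pts, padded, cell)
    per_run <- c(per_run, n_net / config$n_points * v_cell)
    if (i >= config$min_runs) {
      s <- pop_sd(per_run)
      if (s / mean(per_run) < config$target_rel_sigma) {
        converged <- TRUE
        break
      }
    }
  }
  v_net <- mean(per_run)
  if (!converged) {
    warn(sprintf(
      "target sigma(V_net)/V_net = %g not reached after %d runs (achieved %.3g); repeat with larger n_points",
      config$target_rel_sigma, length(per_run),
      if (v_net > 0) pop_sd(per_run) / v_net else NA_real_
    ))
  }
  new_volume_result(
    v_cell = v_cell, v_net = v_net, sigma_net = pop_sd(per_run),
    n_points = config$n_points, n_runs = length(per_run),
    converged = converged, per_run_v_net = per_run
  )
}

new_volume_result <- function(v_cell, v_net, sigma_net, n_points, n_runs,
                              converged, per_run_v_net) {
  structure(
    list(
      v_cell = v_cell, v_net = v_net, v_void = v_cell - v_net,
      sigma_net = sigma_net, n_points = n_points, n_runs = n_runs,
      converged = converged, per_run_v_net = per_run_v_net
    ),
    class = "volume_result"
  )
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf(
    "<volume_result> V=%.3f  V_net=%.3f(%.3f)  V_void=%.3f A^3  x=%.4f  [%d x %g pts, %s]\n",
    x$v_cell, x$v_net, x$sigma_net, x$v_void, x$v_net / x$v_cell,
    x$n_runs, x$n_points, if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Propagate coordinate uncertainty into the volume estimate
#'
#' A second Monte Carlo layer: `n_models` structural models are generated by
#' perturbing every fractional coordinate with an independent Gaussian
#' deviate of standard deviation equal to its standard uncertainty
#' ([perturb_models()]); one volume run is performed per model, and the mean
#' and population standard deviation of the resulting network-volume
#' distribution — which reflects both the coordinate precision and the
#' sampler's own reproducibility — are reported as `v_net` and `sigma_net`.
#'
#' @inheritParams run_volume
#' @param n_models Number of perturbed models (at least 2).
#' @param seed Master seed for both the perturbations and the per-model runs
#'   (overrides `config$seed`).
#' @return A `volume_result`; `per_run_v_net` holds the per-model values and
#'   `n_runs` equals `n_models`.
#' @export
propagate_uncertainty <- function(structure, config = sampler_config(),
                                  n_models = 100, seed = config$seed) {
  stopifnot(inherits(structure, "crystal_structure"))
  if (n_models < 2) abort("n_models must be at least 2 to estimate a standard deviation")
  su <- unlist(structure$atoms[, c("su_x", "su_y", "su_z")])
  if (all(su == 0)) {
    inform("all coordinate su values are zero: spread reflects Monte Carlo reproducibility only")
  }
  seeds <- derive_seeds(seed, n_models + 1L)
  models <- perturb_models(structure, n_models, seed = seeds[n_models + 1L])
  # a single sampling pass per model: the model-to-model spread already
  # carries the MC scatter, so no inner convergence loop is needed
  per_model <- vapply(seq_len(n_models), function(i) {
    padded <- padded_atom_list(models[[i]])
    set.seed(seeds[i])
    pts <- matrix(runif(3 * config$n_points), ncol = 3)
    classify_points(pts, padded, structure$cell) / config$n_points * structure$cell$volume
  }, numeric(1))
  new_volume_result(
    v_cell = structure$cell$volume, v_net = mean(per_model),
    sigma_net = pop_sd(per_model), n_points = config$n_points,
    n_runs = n_models, converged = TRUE, per_run_v_net = per_model
  )
}

#' Volume of isolated structural fragments
#'
#' Computes the Monte Carlo volume of the van der Waals sphere union of an
#' atom subset treated as an isolated (non-periodic) fragment, sampled in
#' the Cartesian bounding box of the subset's spheres, and scales it to the
#' number of molecules in the subset. Because sphere surfaces of neighboring
#' molecules overlap, the per-molecule volume of an interacting subset is
#' smaller than that of an isolated molecule.
#'
#' @inheritParams run_volume
#' @param groups A list of integer vectors indexing `structure$atoms`, one
#'   per molecule (a single vector is taken as one molecule). Molecules must
#'   be geometrically whole in the stored coordinates.
#' @return A tibble with one row: `v_molecule` (cubic angstroms per
#'   molecule), `sigma` (population sd over runs, per molecule),
#'   `n_molecules`, `n_runs`, `converged`.
#' @export
fragment_volume <- function(structure, groups, config = sampler_config()) {
  stopifnot(inherits(structure, "crystal_structure"))
  if (!is.list(groups)) groups <- list(groups)
  idx <- unlist(groups)
  if (!length(idx)) abort("empty subset")
  at <- structure$atoms[idx, , drop = FALSE]
  if (anyNA(at$r_vdw)) abort("assign radii before computing fragment volumes")
  n_mol <- length(groups)
  cart <- frac_to_cart(structure$cell, as.matrix(at[, c("fx", "fy", "fz")]))
  lo <- apply(cart - at$r_vdw, 2, min)
  hi <- apply(cart + at$r_vdw, 2, max)
  box_v <- prod(hi - lo)
  r2 <- at$r_vdw^2
  seeds <- derive_seeds(config$seed, config$max_runs)
  per_run <- numeric(0)
  converged <- FALSE
  for (i in seq_len(config$max_runs)) {
    set.seed(seeds[i])
    pts <- cbind(
      runif(config$n_points, lo[1], hi[1]),
      runif(config$n_points, lo[2], hi[2]),
      runif(config$n_points, lo[3], hi[3])
    )
    inside <- logical(config$n_points)
    rem <- seq_len(config$n_points)
    for (j in seq_len(nrow(cart))) {
      if (!length(rem)) break
      d2 <- (pts[rem, 1] - cart[j, 1])^2 + (pts[rem, 2] - cart[j, 2])^2 +
        (pts[rem, 3] - cart[j, 3])^2
      hit <- d2 <= r2[j]
      inside[rem[hit]] <- TRUE
      rem <- rem[!hit]
    }
    per_run <- c(per_run, sum(inside) / config$n_points * box_v)
    if (i >= config$min_runs) {
      if (pop_sd(per_run) / mean(per_run) < config$target_rel_sigma) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    warn("fragment volume did not reach the target precision; increase n_points")
  }
  tibble(
    v_molecule = mean(per_run) / n_mol,
    sigma = pop_sd(per_run) / n_mol,
    n_molecules = n_mol,
    n_runs = length(per_run),
    converged = converged
  )
}

#' Packing coefficient
#'
#' The fraction of the unit cell occupied by atoms, `x = V_net / V`, with
#' standard deviation `sigma_net / V`. Typical molecular crystals fall in
#' 0.6-0.8 at ambient pressure.
#'
#' @param result A `volume_result`.
#' @return A tibble with columns `x` and `sigma_x`.
#' @export
packing_coefficient <- function(result) {
  stopifnot(inherits(result, "volume_result"))
  if (result$v_cell <= 0) abort("v_cell must be positive")
  tibble(x = result$v_net / result$v_cell, sigma_x = result$sigma_net / result$v_cell)
}

#' Export a volumetric occupancy map
#'
#' Writes a regular grid over fractional coordinates with value 1 where the
#' voxel center lies inside the van der Waals union (network) and 0 in the
#' voids, as a Gaussian cube file (text) readable by standard volumetric
#' viewers.
#'
#' @inheritParams run_volume
#' @param grid Integer vector of three voxel counts (each at least 2).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_occupancy_map <- function(structure, grid, path) {
  stopifnot(inherits(structure, "crystal_structure"))
  grid <- as.integer(grid)
  if (length(grid) != 3 || any(grid < 2)) abort("grid must give at least 2 voxels per axis")
  padded <- padded_atom_list(structure)
  centers <- as.matrix(expand.grid(
    fx = (seq_len(grid[1]) - 0.5) / grid[1],
    fy = (seq_len(grid[2]) - 0.5) / grid[2],
    fz = (seq_len(grid[3]) - 0.5) / grid[3]
  ))
  occ <- if (nrow(structure$atoms)) {
    as.integer(classify_points_mask(centers, padded, structure$cell))
  } else rep(0L, nrow(centers))
  # cube order: x outer, z fastest
  arr <- array(occ, dim = grid)  # filled with fx fastest from expand.grid
  m <- structure$cell$ortho
  lines <- c(
    "voidpart occupancy map (1 = network, 0 = void)",
    "fractional grid over one unit cell, voxel-center sampling",
    sprintf("%5d %11.6f %11.6f %11.6f", 0L, 0, 0, 0),
    sprintf("%5d %11.6f %11.6f %11.6f", grid[1], m[1, 1] / grid[1], m[2, 1] / grid[1], m[3, 1] / grid[1]),
    sprintf("%5d %11.6f %11.6f %11.6f", grid[2], m[1, 2] / grid[2], m[2, 2] / grid[2], m[3, 2] / grid[2]),
    sprintf("%5d %11.6f %11.6f %11.6f", grid[3], m[1, 3] / grid[3], m[2, 3] / grid[3], m[3, 3] / grid[3])
  )
  vals <- character(0)
  for (ix in seq_len(grid[1])) {
    for (iy in seq_len(grid[2])) {
      row <- arr[ix, iy, ]
      chunks <- split(row, ceiling(seq_along(row) / 6))
      vals <- c(vals, vapply(chunks, function(ch) paste(sprintf("%13.5e", ch), collapse = " "), character(1)))
    }
  }
  writeLines(c(lines, vals), path)
  invisible(path)
}

# read back a cube file written by export_occupancy_map (round-trip checks)
read_occupancy_map <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[3:6]), "\\s+")
  natoms <- as.integer(hdr[[1]][1])
  grid <- vapply(hdr[2:4], function(h) as.integer(h[1]), integer(1))
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:(6 + natoms))]), "\\s+")))
  # file order is x outer / z fastest; restore R's column-major layout
  arr <- aperm(array(vals, dim = rev(grid)), 3:1)
  list(grid = grid, values = arr)
}
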