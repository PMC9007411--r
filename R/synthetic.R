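#' Analytic sphere-packing fixture structures
#'
#' Generates small P1 "crystals" whose network volume is known in closed
#' form, so the Monte Carlo sampler can be validated without any external
#' structure:
#'
#' * `single_sphere`: one atom of radius `r` centered in a cubic cell of
#'   edge `a`; `V_net = (4/3) pi r^3`.
#' * `sphere_pair`: two atoms of radii `r1`, `r2` with centers `d` apart
#'   along x in a cubic cell; union volume from the closed-form lens
#'   subtraction (disjoint spheres simply add).
#' * `fcc_touching`: four touching spheres of radius `r` on a face-centered
#'   cubic cell (`a = 2 sqrt(2) r`); packing fraction `pi / sqrt(18)`.
#' * `random_atoms`: `n` atoms of radius `r` uniform in a cubic cell (no
#'   analytic volume; useful for oracle-equivalence tests).
#'
#' Distinct radii are mapped to distinct element labels with the radius
#' stored directly on the atoms, so the fixtures are self-contained; use
#' [fixture_radii_table()] when round-tripping through CIF.
#'
#' @param kind Fixture kind (see above).
#' @param r,r1,r2 Sphere radii in angstroms.
#' @param a Cubic cell edge in angstroms (ignored for `fcc_touching`).
#' @param d Center separation for `sphere_pair`.
#' @param n Atom count for `random_atoms`.
#' @param su Fractional coordinate standard uncertainty applied to every
#'   coordinate (default 0).
#' @param seed Seed for `random_atoms`.
#' @return A [crystal_structure()] with radii assigned; for kinds with a
#'   closed-form network volume the value is stored in attribute
#'   `analytic_v_net`.
#' @export
#' @examples
#' s <- make_structure("single_sphere", r = 1.7, a = 10)
#' attr(s, "analytic_v_net")  # 20.58 A^3
make_structure <- function(kind = c("single_sphere", "sphere_pair", "fcc_touching", "random_atoms"),
                           r = 1.7, a = 10, r1 = r, r2 = r, d = 2, n = 5,
                           su = 0, seed = NULL) {
  kind <- match.arg(kind)
  elements <- c("C", "N", "O", "S", "P", "F", "Cl")
  analytic <- NA_real_
  if (kind == "single_sphere") {
    stopifnot(r > 0, a > 0)
    atoms <- tibble(
      label = "C1", element = "C", fx = 0.5, fy = 0.5, fz = 0.5,
      su_x = su, su_y = su, su_z = su, occ = 1, r_vdw = r
    )
    cell <- unit_cell(a, a, a)
    analytic <- 4 / 3 * pi * r^3
  } else if (kind == "sphere_pair") {
    stopifnot(r1 > 0, r2 > 0, d > 0, a > 0)
    atoms <- tibble(
      label = c("C1", "N1"), element = c("C", "N"),
      fx = 0.5 + c(-d / 2, d / 2) / a, fy = 0.5, fz = 0.5,
      su_x = su, su_y = su, su_z = su, occ = 1, r_vdw = c(r1, r2)
    )
    cell <- unit_cell(a, a, a)
    analytic <- sphere_union_volume(r1, r2, d)
    if (d >= r1 + r2) inform("sphere_pair is disjoint: union volume is the simple sum")
  } else if (kind == "fcc_touching") {
    stopifnot(r > 0)
    a <- 2 * sqrt(2) * r
    f <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
    atoms <- tibble(
      label = paste0("C", 1:4), element = "C",
      fx = f[, 1], fy = f[, 2], fz = f[, 3],
      su_x = su, su_y = su, su_z = su, occ = 1, r_vdw = r
    )
    cell <- unit_cell(a, a, a)
    analytic <- 4 * (4 / 3) * pi * r^3  # touching spheres: no overlap
  } else {
    stopifnot(n >= 1, r > 0, a > 0)
    seeds <- derive_seeds(seed, 1)
    set.seed(seeds[1])
    f <- matrix(runif(3 * n), ncol = 3)
    atoms <- tibble(
      label = paste0("C", seq_len(n)), element = "C",
      fx = f[, 1], fy = f[, 2], fz = f[, 3],
      su_x = su, su_y = su, su_z = su, occ = 1, r_vdw = r
    )
    cell <- unit_cell(a, a, a)
  }
  s <- crystal_structure(cell, atoms, id = paste0("synthetic_", kind))
  attr(s, "analytic_v_net") <- analytic
  s
}

#' Closed-form volume of a union of two spheres
#'
#' `V = V1 + V2 - V_lens`, with the lens volume of two overlapping spheres
#' of radii `r1`, `r2` at center distance `d`; for equal radii this reduces
#' to `(pi/12)(4r + d)(2r - d)^2`.
#'
#' @param r1,r2 Sphere radii.
#' @param d Center separation.
#' @return Union volume.
#' @export
sphere_union_volume <- function(r1, r2, d) {
  v1 <- 4 / 3 * pi * r1^3
  v2 <- 4 / 3 * pi * r2^3
  if (d >= r1 + r2) return(v1 + v2)
  if (d <= abs(r1 - r2)) return(max(v1, v2))
  lens <- pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
  v1 + v2 - lens
}

#' Radius table for a fixture structure
#'
#' When a synthetic fixture is written to CIF the radii are not carried by
#' the file; this emits the matching element-to-radius table (one row per
#' element) for use with [assign_radii()].
#'
#' @param structure A fixture from [make_structure()].
#' @param path Optional CSV path to write.
#' @return A tibble `element`, `r_vdw` (written to `path` when given).
#' @export
fixture_radii_table <- function(structure, path = NULL) {
  at <- structure$atoms
  tbl <- dplyr::distinct(tibble(element = at$element, r_vdw = at$r_vdw))
  if (anyNA(tbl$r_vdw)) abort("fixture has unassigned radii")
  if (any(duplicated(tbl$element))) {
    abort("fixture assigns different radii to the same element; cannot emit a table")
  }
  if (!is.null(path)) write.csv(tbl, path, row.names = FALSE)
  tbl
}

#' Synthetic pressure series from stated equations of state
#'
#' Generates a [pressure_series()] whose network and void volumes follow
#' stated EoS parameter sets exactly (plus optional Gaussian noise), so the
#' fitting layer can be validated by round trip. `two_phase_series` joins
#' two parameter sets at a break pressure: the second segment's `v0` is
#' solved so its volume at the break equals the first segment's minus the
#' requested step (all families scale as `V(P) = V0 h(P)`, so this is a
#' direct rescaling).
#'
#' @param kind `"eos_series"` or `"two_phase_series"`.
#' @param pressures Strictly increasing pressure grid, GPa.
#' @param net,void Lists `list(family =, v0 =, k0 =, kprime =)` describing
#'   the per-formula-unit component volumes (kprime defaults to 4).
#' @param net2,void2 Second-segment parameters `list(family =, k0 =,
#'   kprime =)` for `two_phase_series` (their `v0` is derived from
#'   continuity minus the step).
#' @param break_p Break pressure for `two_phase_series`.
#' @param step_net,step_void Volume drop (cubic angstroms per formula unit)
#'   of each component at the break (positive = volume decreases).
#' @param noise_sd Gaussian noise sd added independently to the network and
#'   void volumes, cubic angstroms.
#' @param Z Formula units per cell; generated volumes are multiplied by `Z`
#'   and the column recorded, so [scale_to_Z()] recovers the per-formula
#'   values.
#' @param seed Seed for the noise.
#' @param id Series identifier.
#' @return A [pressure_series()]; the generating parameters are stored in
#'   attribute `generator`.
#' @export
make_series <- function(kind = c("eos_series", "two_phase_series"),
                        pressures = seq(0, 8, length.out = 9),
                        net = list(family = "bm3", v0 = 200, k0 = 100, kprime = 6),
                        void = list(family = "vinet", v0 = 70, k0 = 3.5, kprime = 8),
                        net2 = NULL, void2 = NULL, break_p = NULL,
                        step_net = 0, step_void = 0,
                        noise_sd = 0, Z = 1, seed = NULL, id = kind) {
  kind <- match.arg(kind)
  p <- as.numeric(pressures)
  if (any(diff(p) <= 0)) abort("pressures must be strictly increasing")
  if (any(duplicated(p))) abort("duplicate pressures")
  comp_volumes <- function(par, par2, step) {
    par$kprime <- par$kprime %||% 4
    if (kind == "eos_series" || is.null(par2)) {
      return(eos_volume(par$family, p, par$v0, par$k0, par$kprime))
    }
    if (is.null(break_p)) abort("two_phase_series needs break_p")
    par2$kprime <- par2$kprime %||% 4
    v_at_break <- eos_volume(par$family, break_p, par$v0, par$k0, par$kprime)
    target <- v_at_break - step
    # V(P) = v0 * h(P): solve v0 of segment 2 from its unit-v0 volume
    h2 <- eos_volume(par2$family, break_p, 1, par2$k0, par2$kprime)
    v0_2 <- target / h2
    lo <- p < break_p
    out <- numeric(length(p))
    out[lo] <- eos_volume(par$family, p[lo], par$v0, par$k0, par$kprime)
    out[!lo] <- eos_volume(par2$family, p[!lo], v0_2, par2$k0, par2$kprime)
    out
  }
  v_net <- comp_volumes(net, net2, step_net)
  v_void <- comp_volumes(void, void2, step_void)
  if (noise_sd > 0) {
    seeds <- derive_seeds(seed, 1)
    set.seed(seeds[1])
    v_net <- v_net + rnorm(length(p), 0, noise_sd)
    v_void <- v_void + rnorm(length(p), 0, noise_sd)
  }
  df <- tibble(
    pressure = p,
    v_net = v_net * Z,
    v_void = v_void * Z,
    sigma = noise_sd * Z,
    Z = as.integer(Z)
  )
  out <- pressure_series(df, id = id)
  attr(out, "generator") <- list(
    kind = kind, net = net, void = void, net2 = net2, void2 = void2,
    break_p = break_p, step_net = step_net, step_void = step_void,
    noise_sd = noise_sd, Z = Z, seed = seed
  )
  out
}

#' Perturbed structural models from coordinate uncertainties
#'
#' Each model perturbs every fractional coordinate independently by a
#' Gaussian deviate with standard deviation equal to that coordinate's
#' standard uncertainty (zero su leaves the coordinate untouched).
#'
#' @param structure A [crystal_structure()].
#' @param n_models Number of models.
#' @param seed Optional seed; the same seed reproduces the same model list.
#' @return A list of `n_models` crystal structures.
#' @export
perturb_models <- function(structure, n_models, seed = NULL) {
  stopifnot(inherits(structure, "crystal_structure"), n_models >= 1)
  at <- structure$atoms
  n <- nrow(at)
  seeds <- derive_seeds(seed, 1)
  set.seed(seeds[1])
  lapply(seq_len(n_models), function(i) {
    z <- matrix(rnorm(3 * n), ncol = 3)
    out <- structure
    out$atoms$fx <- wrap_frac(at$fx + at$su_x * z[, 1])
    out$atoms$fy <- wrap_frac(at$fy + at$su_y * z[, 2])
    out$atoms$fz <- wrap_frac(at$fz + at$su_z * z[, 3])
    out
  })
}
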