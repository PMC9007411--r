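#' Construct a crystal structure
#'
#' The central container: a unit cell plus a tibble of atoms in fractional
#' coordinates. Atom coordinates are wrapped into `[0, 1)` on construction.
#' Symmetry operators are kept as the raw `x,y,z`-style strings read from the
#' CIF; [expand_to_cell()] applies them.
#'
#' @param cell A [unit_cell()].
#' @param atoms A data frame with columns `label`, `element`, `fx`, `fy`,
#'   `fz`; optional `su_x`, `su_y`, `su_z` (fractional standard
#'   uncertainties, default 0), `occ` (occupancy, default 1) and `r_vdw`
#'   (van der Waals radius in angstroms, default `NA` until
#'   [assign_radii()]).
#' @param symops Character vector of symmetry operators (`"x, y, z"` style).
#' @param Z Formula units per cell (may be `NA`).
#' @param pressure Pressure in GPa (may be `NA`).
#' @param id Identifier string.
#'
#' @return An object of class `crystal_structure`.
#' @export
crystal_structure <- function(cell, atoms, symops = "x, y, z",
                              Z = NA_real_, pressure = NA_real_, id = "") {
  stopifnot(inherits(cell, "unit_cell"))
  atoms <- as_tibble(atoms)
  need <- c("label", "element", "fx", "fy", "fz")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) abort(paste0("atoms is missing columns: ", paste(miss, collapse = ", ")))
  for (col in c("su_x", "su_y", "su_z")) {
    if (!col %in% names(atoms)) atoms[[col]] <- 0
  }
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"r_vdw" %in% names(atoms)) atoms$r_vdw <- NA_real_
  atoms$fx <- wrap_frac(atoms$fx)
  atoms$fy <- wrap_frac(atoms$fy)
  atoms$fz <- wrap_frac(atoms$fz)
  structure(
    list(cell = cell, atoms = atoms, symops = symops,
         Z = Z, pressure = pressure, id = id),
    class = "crystal_structure"
  )
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf(
    "<crystal_structure> %s: %d atoms, %d symop(s), V=%.3f A^3%s\n",
    if (nzchar(x$id)) x$id else "(unnamed)",
    nrow(x$atoms), length(x$symops), x$cell$volume,
    if (is.finite(x$pressure)) sprintf(", P=%.3g GPa", x$pressure) else ""
  ))
  invisible(x)
}

# ---- symmetry operators ------------------------------------------------

# parse one "x, y, z"-style operator into a 3x3 rotation and a translation
parse_symop <- function(op) {
  parts <- strsplit(gsub("[ '\"]", "", tolower(op)), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3) abort(paste0("cannot parse symmetry operator: ", op))
  rot <- matrix(0, 3, 3)
  tra <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # split into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (term in terms) {
      sgn <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      axis <- regmatches(body, regexpr("[xyz]", body))
      if (length(axis) == 1) {
        coefstr <- sub("[xyz]", "", body)
        coefstr <- gsub("\\*", "", coefstr)
        coef <- if (coefstr == "") 1 else parse_fraction(coefstr, op)
        j <- match(axis, c("x", "y", "z"))
        rot[i, j] <- rot[i, j] + sgn * coef
      } else {
        tra[i] <- tra[i] + sgn * parse_fraction(body, op)
      }
    }
  }
  list(rot = rot, tra = tra)
}

parse_fraction <- function(s, op) {
  if (grepl("^\\d+/\\d+$", s)) {
    ab <- as.numeric(strsplit(s, "/", fixed = TRUE)[[1]])
    return(ab[1] / ab[2])
  }
  # forms like "x/2" arrive here with the axis stripped: "/2"
  if (grepl("^/\\d+$", s)) {
    return(1 / as.numeric(sub("/", "", s)))
  }
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) abort(paste0("cannot parse symmetry operator: ", op))
  v
}

#' Expand symmetry to the full unit cell
#'
#' Applies every symmetry operator to every atom, wraps all images into the
#' cell and removes duplicates closer than `dup_tol` (minimum-image Cartesian
#' distance). When `Z` is recorded the expanded atom count is checked for
#' consistency with `Z x` (atoms per asymmetric contribution) and a message
#' is emitted when they disagree.
#'
#' @param structure A [crystal_structure()].
#' @param dup_tol Duplicate-atom tolerance in angstroms (default 0.05).
#' @return The structure with its `atoms` tibble replaced by the symmetry
#'   expansion and `symops` reset to the identity.
#' @export
expand_to_cell <- function(structure, dup_tol = 0.05) {
  stopifnot(inherits(structure, "crystal_structure"))
  ops <- lapply(structure$symops, parse_symop)
  at <- structure$atoms
  frac <- as.matrix(at[, c("fx", "fy", "fz")])
  images <- purrr::map(ops, function(op) {
    f <- frac %*% t(op$rot)
    f <- sweep(f, 2, op$tra, "+")
    f - floor(f)
  })
  all_frac <- do.call(rbind, images)
  all_idx <- rep(seq_len(nrow(at)), times = length(ops))
  # dedup: first occurrence wins; minimum-image distance below tolerance
  keep <- dedup_sites(structure$cell, all_frac, dup_tol)
  out <- at[all_idx[keep], , drop = FALSE]
  out$fx <- wrap_frac(all_frac[keep, 1])
  out$fy <- wrap_frac(all_frac[keep, 2])
  out$fz <- wrap_frac(all_frac[keep, 3])
  res <- structure
  res$atoms <- out
  res$symops <- "x, y, z"
  if (is.finite(structure$Z) && structure$Z >= 1) {
    n_asym <- nrow(at)
    expected <- n_asym * length(ops)
    if (nrow(out) %% n_asym != 0 && nrow(out) != expected) {
      inform(sprintf(
        "expanded atom count %d is not a multiple of the %d input sites (Z = %g); check for special positions or missing operators",
        nrow(out), n_asym, structure$Z
      ))
    }
  }
  res
}

# indices of rows to keep after duplicate removal at tol (angstrom)
dedup_sites <- function(cell, frac, tol) {
  n <- nrow(frac)
  keep <- logical(n)
  kept <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(n)) {
    if (nrow(kept) == 0) {
      keep[i] <- TRUE
      kept <- frac[i, , drop = FALSE]
      next
    }
    v <- min_image_vec(cell, frac[i, ], kept)
    if (min(sqrt(rowSums(v^2))) >= tol) {
      keep[i] <- TRUE
      kept <- rbind(kept, frac[i, ])
    }
  }
  which(keep)
}

#' Normalize X-H distances to neutron values
#'
#' X-ray refinement places hydrogen at the centroid of its bonding electron
#' density, foreshortening X-H bonds by roughly 0.1 angstrom. Each hydrogen
#' bonded to a heavy atom (separation below `bond_factor` times the sum of
#' covalent radii) is moved along the existing X->H direction so the bond
#' length equals the table value for the heavy element. Heavy atoms are never
#' moved; hydrogens with no plausible bonded neighbor are left in place with
#' a warning.
#'
#' @param structure A [crystal_structure()] (typically already expanded).
#' @param table X-H distance table as from [xh_distances()].
#' @param cov Covalent-radius table as from [covalent_radii()], used only for
#'   bond detection.
#' @param bond_factor Bond-detection multiplier on the covalent-radius sum.
#' @return The structure with hydrogen positions updated.
#' @export
normalize_xh <- function(structure, table = xh_distances(),
                         cov = covalent_radii(), bond_factor = 1.2) {
  stopifnot(inherits(structure, "crystal_structure"))
  at <- structure$atoms
  is_h <- at$element %in% c("H", "D")
  if (!any(is_h)) return(structure)
  rc <- table_lookup(cov, "r_cov")
  dt <- table_lookup(table, "d_xh")
  if (!"H" %in% names(rc)) abort("covalent table must contain H")
  heavy_idx <- which(!is_h)
  if (!length(heavy_idx)) {
    warn("structure contains only hydrogen; nothing to normalize against")
    return(structure)
  }
  frac <- as.matrix(at[, c("fx", "fy", "fz")])
  cell <- structure$cell
  for (i in which(is_h)) {
    hv <- min_image_vec(cell, frac[i, ], frac[heavy_idx, , drop = FALSE])
    d <- sqrt(rowSums(hv^2))
    el <- at$element[heavy_idx]
    rcx <- rc[el]
    ok <- is.finite(rcx) & d < bond_factor * (rcx + rc[["H"]]) & d > 1e-6
    if (!any(ok)) {
      warn(sprintf("hydrogen %s has no bonded heavy atom; left in place", at$label[i]))
      next
    }
    j <- which(ok)[which.min(d[ok])]
    target <- dt[el[j]]
    if (is.na(target)) next  # no normalization defined for this X element
    # X -> H unit vector from the minimum image; hv is H -> X so negate
    u <- -hv[j, ] / d[j]
    x_cart <- frac_to_cart(cell, frac[heavy_idx[j], ])
    # honour periodicity: place H relative to the image of X nearest to H
    x_near <- frac_to_cart(cell, frac[i, ]) + hv[j, ]
    new_cart <- x_near + u * unname(target)
    newf <- wrap_frac(drop(cart_to_frac(cell, new_cart)))
    frac[i, ] <- newf
    at$fx[i] <- newf[1]; at$fy[i] <- newf[2]; at$fz[i] <- newf[3]
  }
  out <- structure
  out$atoms <- at
  out
}

#' Assign van der Waals radii
#'
#' @param structure A [crystal_structure()].
#' @param radii Radius table as from [vdw_radii()].
#' @return The structure with the `r_vdw` column filled. An element absent
#'   from the table is an error (a silent default radius would bias every
#'   volume computed downstream).
#' @export
assign_radii <- function(structure, radii = vdw_radii()) {
  stopifnot(inherits(structure, "crystal_structure"))
  lut <- table_lookup(radii, "r_vdw")
  el <- structure$atoms$element
  r <- lut[el]
  if (anyNA(r)) {
    missing <- sort(unique(el[is.na(r)]))
    abort(paste0(
      "no van der Waals radius for element(s): ", paste(missing, collapse = ", "),
      "; extend the radii table"
    ))
  }
  out <- structure
  out$atoms$r_vdw <- unname(r)
  out
}

#' Padded atom list for the point sampler
#'
#' Returns the full-cell atoms plus every periodic image lying within a slab
#' of width `R_max` (the largest van der Waals radius present) around the
#' cell, so that any sample point inside the cell sees every atom whose
#' sphere could contain it. The slab is measured against the perpendicular
#' cell heights computed from the reciprocal axes, which reduces to the
#' fractional criterion `|x| < R_max/a` (etc.) for orthogonal cells and
#' remains correct for oblique ones.
#'
#' @param structure A [crystal_structure()] with radii assigned.
#' @return A tibble of atoms; image coordinates lie outside `[0, 1)`.
#' @export
padded_atom_list <- function(structure) {
  stopifnot(inherits(structure, "crystal_structure"))
  at <- structure$atoms
  if (anyNA(at$r_vdw)) abort("assign radii before building the padded list")
  if (!nrow(at)) return(at)
  r_max <- max(at$r_vdw)
  delta <- r_max / cell_heights(structure$cell)
  s <- pmax(1L, ceiling(delta))
  shifts <- as.matrix(expand.grid(
    sx = -s[1]:s[1], sy = -s[2]:s[2], sz = -s[3]:s[3]
  ))
  frac <- as.matrix(at[, c("fx", "fy", "fz")])
  pieces <- vector("list", nrow(shifts))
  for (k in seq_len(nrow(shifts))) {
    sh <- shifts[k, ]
    f <- sweep(frac, 2, sh, "+")
    inside <- f[, 1] > -delta[1] & f[, 1] < 1 + delta[1] &
      f[, 2] > -delta[2] & f[, 2] < 1 + delta[2] &
      f[, 3] > -delta[3] & f[, 3] < 1 + delta[3]
    if (!any(inside)) next
    p <- at[inside, , drop = FALSE]
    p$fx <- f[inside, 1]; p$fy <- f[inside, 2]; p$fz <- f[inside, 3]
    pieces[[k]] <- p
  }
  dplyr::bind_rows(pieces)
}
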