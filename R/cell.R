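#' Construct a unit cell
#'
#' A triclinic unit cell described by its six lattice parameters, the derived
#' cell volume and the orthogonalization matrix that maps fractional to
#' Cartesian coordinates (in angstroms).
#'
#' @param a,b,c Cell edge lengths in angstroms.
#' @param alpha,beta,gamma Cell angles in degrees, each strictly inside
#'   (0, 180).
#'
#' @return An object of class `unit_cell`: a list with the six parameters,
#'   `volume` (cubic angstroms) and `ortho`, the 3x3 fractional-to-Cartesian
#'   transform whose columns are the cell vectors.
#' @export
#' @examples
#' cell <- unit_cell(10, 10, 10)
#' cell$volume  # 1000
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = a, b = b, c = c)
  if (any(!is.finite(p)) || any(p <= 0)) {
    abort("unit cell lengths must be positive and finite")
  }
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180)) {
    abort("unit cell angles must lie strictly between 0 and 180 degrees")
  }
  ca <- cos(alpha * pi / 180)
  cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  # squared factor in the closed-form triclinic volume; must be positive for
  # a realizable metric
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) {
    abort("unit cell angles do not define a positive-volume metric")
  }
  v <- sqrt(v2)
  ortho <- matrix(
    c(
      a, b * cg, c * cb,
      0, b * sg, c * (ca - cb * cg) / sg,
      0, 0, c * v / sg
    ),
    nrow = 3, byrow = TRUE
  )
  structure(
    list(
      a = a, b = b, c = c,
      alpha = alpha, beta = beta, gamma = gamma,
      volume = a * b * c * v,
      ortho = ortho
    ),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf(
    "<unit_cell> a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.3f A^3\n",
    x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume
  ))
  invisible(x)
}

#' Convert fractional to Cartesian coordinates
#'
#' @param cell A [unit_cell()].
#' @param frac Numeric matrix (n x 3) or length-3 vector of fractional
#'   coordinates.
#' @return An n x 3 matrix of Cartesian coordinates in angstroms.
#' @export
frac_to_cart <- function(cell, frac) {
  m <- rbind_coords(frac)
  m %*% t(cell$ortho)
}

#' Convert Cartesian to fractional coordinates
#'
#' @inheritParams frac_to_cart
#' @param cart Numeric matrix (n x 3) or length-3 vector of Cartesian
#'   coordinates in angstroms.
#' @return An n x 3 matrix of fractional coordinates (not wrapped).
#' @export
cart_to_frac <- function(cell, cart) {
  m <- rbind_coords(cart)
  m %*% t(solve(cell$ortho))
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  storage.mode(x) <- "double"
  x
}

# wrap fractional coordinates into [0, 1); tolerance keeps values that are
# numerically 1 from surviving as 0.9999999...
wrap_frac <- function(x, eps = 1e-12) {
  y <- x - floor(x)
  y[abs(y - 1) < eps] <- 0
  y
}

# perpendicular cell heights: distance between opposite cell faces along each
# axis. Row i of solve(ortho) is the gradient of fractional coordinate i with
# respect to Cartesian position, so the height is 1 / ||row_i||.
cell_heights <- function(cell) {
  inv <- solve(cell$ortho)
  1 / sqrt(rowSums(inv^2))
}

# minimum-image separation vectors (Cartesian) from atom a to atom b
min_image_vec <- function(cell, frac_a, frac_b) {
  d <- rbind_coords(frac_b) - matrix(frac_a, nrow = NROW(rbind_coords(frac_b)), ncol = 3, byrow = TRUE)
  d <- d - round(d)
  d %*% t(cell$ortho)
}
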