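#' Unit cell
#'
#' Construct a crystallographic unit cell from the six cell constants.
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#'
#' @return An object of class `unit_cell`: a list with the six constants and
#'   the orthogonalization (`orth`) and deorthogonalization (`frac`) matrices
#'   used by [frac_to_cart()] and [cart_to_frac()].
#' @examples
#' cl <- unit_cell(4.84, 42.425, 22.256, 90, 94.57, 90)
#' p <- c(0.1, 0.2, 0.3)
#' cart_to_frac(frac_to_cart(p, cl), cl)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (!all(is.finite(c(a, b, c, alpha, beta, gamma)))) {
    stop("unit_cell: non-finite cell constant")
  }
  if (any(c(a, b, c) <= 0)) stop("unit_cell: cell edges must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180)) {
    stop("unit_cell: cell angles must lie in (0, 180) degrees")
  }
  ca <- cos(alpha * pi / 180)
  cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  # standard PDB orthogonalization: a along x, b in the x-y plane
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0, c * v / sg
  ), nrow = 3, byrow = TRUE)
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         orth = orth, frac = solve(orth)),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Fractional / Cartesian conversion
#'
#' Convert coordinates between the fractional basis of a [unit_cell()] and
#' Cartesian Angstrom. Inputs may be a length-3 vector or an n x 3 matrix.
#'
#' @param x Coordinates (vector of length 3 or n x 3 matrix).
#' @param cell A `unit_cell`.
#' @return Coordinates in the target basis, same shape as the input.
#' @export
frac_to_cart <- function(x, cell) .apply_basis(x, cell$orth)

#' @rdname frac_to_cart
#' @export
cart_to_frac <- function(x, cell) .apply_basis(x, cell$frac)

.apply_basis <- function(x, m) {
  if (is.matrix(x)) t(m %*% t(x)) else as.numeric(m %*% x)
}
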