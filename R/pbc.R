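#' Minimum-image displacement between two points
#'
#' Returns the shortest periodic image of `q - p` in an orthorhombic box.
#' Each component of the result lies in `[-L/2, L/2)`.
#'
#' @param p,q Numeric 3-vectors, or n x 3 matrices of paired points (Angstrom).
#' @param box A [cg_box()] or numeric 3-vector of edge lengths.
#' @return The displacement(s) `q - p` under the minimum image convention,
#'   same shape as the inputs.
#' @export
#' @examples
#' minimum_image_displacement(c(1, 1, 1), c(9, 9, 9), cg_box(10, 10, 10))
minimum_image_displacement <- function(p, q, box) {
  box <- as.numeric(box)
  if (is.matrix(p) || is.matrix(q)) {
    p <- matrix(as.numeric(p), ncol = 3)
    q <- matrix(as.numeric(q), ncol = 3)
    d <- q - p
    for (k in 1:3) d[, k] <- d[, k] - box[k] * floor(d[, k] / box[k] + 0.5)
    d
  } else {
    d <- as.numeric(q) - as.numeric(p)
    d - box * floor(d / box + 0.5)
  }
}

#' Wrap coordinates into the primary periodic cell
#'
#' @param coords Numeric n x 3 matrix (or 3-vector) of coordinates, Angstrom.
#' @param box A [cg_box()] or numeric 3-vector.
#' @return Coordinates wrapped into `[0, L)` per axis.
#' @export
wrap_coords <- function(coords, box) {
  box <- as.numeric(box)
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3)
  for (k in 1:3) coords[, k] <- coords[, k] - box[k] * floor(coords[, k] / box[k])
  coords
}

# all-pairs minimum-image distance matrix (small n only)
minimum_image_dist <- function(a, b, box) {
  box <- as.numeric(box)
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], `-`)
    dk <- dk - box[k] * floor(dk / box[k] + 0.5)
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}
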