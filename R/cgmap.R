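#' Map atomistic coordinates to coarse-grained bead positions
#'
#' Each bead is placed at the center of geometry (unweighted mean) of its
#' constituent atoms, the standard way an all-atom trajectory is projected onto
#' a coarse-grained mapping for comparison with a CG model.
#'
#' @param atom_coords Numeric n x 3 matrix of atom coordinates.
#' @param mapping List of integer vectors, one per bead, giving the atom
#'   indices that map to that bead. Sets may overlap (virtual-site style
#'   mappings) but must be non-empty and in range.
#' @return Numeric length(mapping) x 3 matrix of bead coordinates.
#' @export
#' @examples
#' atoms <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1, 0))
#' map_atomistic_to_cg(atoms, list(1:2, 3))
map_atomistic_to_cg <- function(atom_coords, mapping) {
  atom_coords <- as.matrix(atom_coords)
  if (ncol(atom_coords) != 3) stop("atom_coords must be n x 3", call. = FALSE)
  n <- nrow(atom_coords)
  empty <- which(!vapply(mapping, length, integer(1)))
  if (length(empty)) {
    stop("mapping error: bead ", empty[1], " has an empty atom set", call. = FALSE)
  }
  out <- matrix(0, length(mapping), 3)
  for (i in seq_along(mapping)) {
    idx <- as.integer(mapping[[i]])
    if (any(idx < 1 | idx > n)) {
      stop("index error: bead ", i, " references atoms outside 1..", n, call. = FALSE)
    }
    out[i, ] <- colMeans(atom_coords[idx, , drop = FALSE])
  }
  out
}
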