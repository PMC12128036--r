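# subset a mesh to the faces of selected components, re-wrapped as its own mesh
.component_submesh <- function(mesh, comp_id) {
  sel <- mesh$component %in% comp_id
  faces <- mesh$faces[sel, , drop = FALSE]
  keep <- sort(unique(as.vector(faces)))
  remap <- match(faces, keep)
  surface_mesh(mesh$vertices[keep, , drop = FALSE],
               matrix(remap, ncol = 3),
               box = mesh$box,
               face_shift = mesh$face_shift[sel, , drop = FALSE])
}

#' Split a bilayer surface into its two leaflets
#'
#' A box-percolating bilayer yields one Willard-Chandler component per
#' leaflet; the isosurface extraction does not label them, so leaflets are
#' identified by mesh connectivity: the two largest components by area,
#' returned in (upper, lower) order by mean vertex z. Additional small
#' components (e.g. a coexisting micelle) trigger a warning.
#'
#' @param mesh A [surface_mesh()] from a lamellar frame.
#' @return List with `upper` and `lower` (each a [surface_mesh()]) and
#'   `n_extra_components`.
#' @export
split_bilayer_leaflets <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (mesh$n_components < 2) {
    stop("not-a-bilayer error: surface has fewer than two connected components",
         call. = FALSE)
  }
  ord <- order(mesh$component_area, decreasing = TRUE)
  n_extra <- mesh$n_components - 2L
  if (n_extra > 0) {
    warning(sprintf("bilayer surface has %d extra component(s) beyond the two leaflets",
                    n_extra))
  }
  two <- lapply(ord[1:2], function(ci) .component_submesh(mesh, ci))
  mean_z <- vapply(two, function(m) mean(m$vertices[, 3]), numeric(1))
  up <- which.max(mean_z)
  list(upper = two[[up]], lower = two[[3 - up]], n_extra_components = n_extra)
}

#' Bilayer thickness distribution
#'
#' For every vertex of each leaflet surface, the minimum-image distance to the
#' nearest vertex of the other surface; the two directions are pooled, so the
#' result is symmetric in (upper, lower).
#'
#' @param upper,lower Leaflet meshes from [split_bilayer_leaflets()].
#' @return List: `distances` (pooled, Angstrom), `mean`, `sd`.
#' @export
bilayer_thickness <- function(upper, lower) {
  vu <- upper$vertices
  vl <- lower$vertices
  if (!nrow(vu) || !nrow(vl)) stop("empty leaflet vertex set", call. = FALSE)
  box <- upper$box
  pooled <- c(.nn_dist(vu, vl, box), .nn_dist(vl, vu, box))
  list(distances = pooled, mean = mean(pooled), sd = stats::sd(pooled))
}

# exact nearest-neighbor minimum-image distances from each row of a to the
# point set b: chunked squared-distance scan with C-level row minima
.nn_dist <- function(a, b, box) {
  n <- nrow(a)
  out <- numeric(n)
  step <- max(1L, as.integer(4e6 / nrow(b)))
  for (i0 in seq(1L, n, by = step)) {
    rows <- i0:min(n, i0 + step - 1L)
    d2 <- matrix(0, length(rows), nrow(b))
    for (k in 1:3) {
      dk <- outer(a[rows, k], b[, k], `-`)
      dk <- dk - box[k] * floor(dk / box[k] + 0.5)
      d2 <- d2 + dk * dk
    }
    out[rows] <- sqrt(d2[cbind(seq_along(rows), max.col(-d2, "first"))])
  }
  out
}

#' Isocontour offset of a uniform slab under the Willard-Chandler convention
#'
#' The isosurface of a uniform density slab of thickness `T` smoothed with a
#' Gaussian kernel of bandwidth `h` does not sit on the slab face: the level
#' `iso_fraction * rho_max` is crossed a distance `delta` outside it
#' (`delta ~ 0.44 h` for the 1/3 fraction). The measured surface-to-surface
#' thickness of an ideal bilayer of nominal (bead-span) thickness `T` is
#' therefore `T + 2 delta`. Solved from the closed-form slab profile
#' `rho(z) = Phi((T/2 - z)/h) - Phi((-T/2 - z)/h)`.
#'
#' @param thickness Nominal slab thickness `T`, Angstrom.
#' @param params A [wc_params()] (bandwidth and iso fraction are used).
#' @return The one-sided offset `delta`, Angstrom.
#' @export
#' @examples
#' wc_slab_offset(20)  # ~1.77
wc_slab_offset <- function(thickness, params = wc_params()) {
  h <- params$bandwidth
  t2 <- thickness / 2
  prof <- function(z) stats::pnorm((t2 - z) / h) - stats::pnorm((-t2 - z) / h)
  target <- params$iso_fraction * prof(0)
  stats::uniroot(function(d) prof(t2 + d) - target,
                 lower = 0, upper = 10 * h)$root
}

#' Area per headgroup of a bilayer
#'
#' Combined area of the two leaflet surfaces divided by the number of
#' surfactants in the bilayer.
#'
#' @param upper,lower Leaflet meshes.
#' @param n Number of surfactants (>= 1).
#' @return Area per headgroup, Angstrom^2.
#' @export
area_per_headgroup <- function(upper, lower, n) {
  if (n < 1) stop("surfactant count must be >= 1", call. = FALSE)
  (sum(upper$component_area) + sum(lower$component_area)) / n
}
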