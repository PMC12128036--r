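# Isosurface triangulation on a periodic grid.
#
# The level set is extracted by marching tetrahedra on a Kuhn (6-tetrahedron)
# subdivision of each grid cell. The Kuhn subdivision is translation-
# consistent, so faces of adjacent cells are split along the same diagonal and
# the resulting mesh is a closed 2-manifold (every edge shared by exactly two
# triangles) even across the periodic seam, where vertices are identified by
# wrapped grid-edge keys. Triangles are oriented outward from the dense phase
# (density >= isovalue).

.kuhn_tets <- rbind(
  c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L), c(0L, 2L, 3L, 7L),
  c(0L, 2L, 6L, 7L), c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L)
)  # corner bit index: x + 2y + 4z

.row_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# core marcher: values (periodic 3-d array), box lengths, isovalue.
# Returns vertices (canonical coords), faces, face_shift (nf x 9 lattice
# shifts: per face vertex, per axis), box.
marching_tetrahedra <- function(values, box, iso) {
  nd <- dim(values)
  eff <- box / nd
  roll <- function(a, s) {
    # shift array by s = c(dx,dy,dz) with periodic wrap: corner value array
    idx <- lapply(1:3, function(k) {
      if (s[k] == 0) seq_len(nd[k]) else c(2:nd[k], 1L)
    })
    a[idx[[1]], idx[[2]], idx[[3]]]
  }
  corner_off <- cbind(x = bitwAnd(0:7, 1L),
                      y = bitwAnd(0:7 %/% 2L, 1L),
                      z = bitwAnd(0:7 %/% 4L, 1L))
  cv <- lapply(1:8, function(c) roll(values, corner_off[c, ]))
  cmin <- Reduce(pmin, cv)
  cmax <- Reduce(pmax, cv)
  active <- which(cmax >= iso & cmin < iso)
  empty <- list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3),
                face_shift = matrix(0L, 0, 9), box = box)
  if (!length(active)) return(empty)

  ai <- arrayInd(active, nd) - 1L             # 0-based cell indices
  nA <- nrow(ai)
  V8 <- vapply(1:8, function(c) cv[[c]][active], numeric(nA))
  if (nA == 1) V8 <- matrix(V8, 1, 8)
  # global node ids and local (unwrapped) coordinates per corner
  nid8 <- matrix(0L, nA, 8)
  px8 <- py8 <- pz8 <- matrix(0, nA, 8)
  for (c in 1:8) {
    gx <- ai[, 1] + corner_off[c, 1]
    gy <- ai[, 2] + corner_off[c, 2]
    gz <- ai[, 3] + corner_off[c, 3]
    nid8[, c] <- (gx %% nd[1]) + nd[1] * ((gy %% nd[2]) + nd[2] * (gz %% nd[3]))
    px8[, c] <- gx * eff[1]; py8[, c] <- gy * eff[2]; pz8[, c] <- gz * eff[3]
  }

  keys <- character(0)
  coords <- list()
  n_face <- 0L
  face_keys <- list()
  face_coords <- list()

  emit <- function(rows, tc, e1, e2, e3, dir) {
    # one triangle per row; e* = c(from_corner, to_corner) within tet corners
    # (local indices 1..4), interpolating from the "from" to the "to" corner.
    ep <- function(e) {
      a <- tc[e[1]]; b <- tc[e[2]]
      va <- V8[rows, a]; vb <- V8[rows, b]
      t <- (iso - va) / (vb - va)
      p <- cbind(px8[rows, a] + t * (px8[rows, b] - px8[rows, a]),
                 py8[rows, a] + t * (py8[rows, b] - py8[rows, a]),
                 pz8[rows, a] + t * (pz8[rows, b] - pz8[rows, a]))
      ka <- nid8[rows, a]; kb <- nid8[rows, b]
      list(p = p, key = paste0(pmin(ka, kb), "_", pmax(ka, kb)))
    }
    p1 <- ep(e1); p2 <- ep(e2); p3 <- ep(e3)
    nrm <- .row_cross(p2$p - p1$p, p3$p - p1$p)
    flip <- rowSums(nrm * dir) < 0
    if (any(flip)) {
      tmp <- p2$p[flip, , drop = FALSE]
      p2$p[flip, ] <- p3$p[flip, , drop = FALSE]
      p3$p[flip, ] <- tmp
      tmpk <- p2$key[flip]
      p2$key[flip] <- p3$key[flip]
      p3$key[flip] <- tmpk
    }
    n_face <<- n_face + 1L
    face_keys[[n_face]] <<- cbind(p1$key, p2$key, p3$key)
    face_coords[[n_face]] <<- cbind(p1$p, p2$p, p3$p)
    invisible(NULL)
  }

  corner_mean <- function(rows, tcs) {
    px <- py <- pz <- 0
    for (a in tcs) {
      px <- px + px8[rows, a]; py <- py + py8[rows, a]; pz <- pz + pz8[rows, a]
    }
    cbind(px, py, pz) / length(tcs)
  }

  for (t in 1:6) {
    tc <- .kuhn_tets[t, ] + 1L
    m <- V8[, tc, drop = FALSE] >= iso
    code <- as.integer(m %*% c(1L, 2L, 4L, 8L))
    for (cd in sort(unique(code))) {
      if (cd == 0L || cd == 15L) next
      rows <- which(code == cd)
      inside <- which(bitwAnd(cd, c(1L, 2L, 4L, 8L)) > 0L)
      outside <- setdiff(1:4, inside)
      if (length(inside) == 1L) {
        A <- inside; BCD <- outside
        dir <- corner_mean(rows, tc[BCD]) - corner_mean(rows, tc[A])
        emit(rows, tc, c(A, BCD[1]), c(A, BCD[2]), c(A, BCD[3]), dir)
      } else if (length(inside) == 3L) {
        D <- outside
        dir <- corner_mean(rows, tc[D]) - corner_mean(rows, tc[inside])
        emit(rows, tc, c(inside[1], D), c(inside[2], D), c(inside[3], D), dir)
      } else {
        A <- inside[1]; B <- inside[2]; C <- outside[1]; D <- outside[2]
        dir <- corner_mean(rows, tc[outside]) - corner_mean(rows, tc[inside])
        # quad on edges AC, AD, BD, BC (cyclic), split into two triangles
        emit(rows, tc, c(A, C), c(A, D), c(B, D), dir)
        emit(rows, tc, c(A, C), c(B, D), c(B, C), dir)
      }
    }
  }
  if (!n_face) return(empty)

  all_keys <- do.call(rbind, face_keys)
  all_coords <- do.call(rbind, face_coords)
  kvec <- as.vector(t(all_keys))                         # 3 per face, in order
  cmat <- matrix(t(all_coords), ncol = 3, byrow = TRUE)  # matching coords
  uk <- unique(kvec)
  vid <- match(kvec, uk)
  vertices <- cmat[match(uk, kvec), , drop = FALSE]
  shift <- round((cmat - vertices[vid, , drop = FALSE]) /
                   matrix(box, nrow(cmat), 3, byrow = TRUE))
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  # face_shift columns: v1x v1y v1z v2x v2y v2z v3x v3y v3z
  face_shift <- matrix(0L, nrow(faces), 9)
  idx <- rep(seq_len(nrow(faces)), each = 3)
  within <- rep(1:3, nrow(faces))
  for (k in 1:3) face_shift[cbind(idx, (within - 1) * 3 + k)] <- as.integer(shift[, k])
  list(vertices = vertices, faces = faces, face_shift = face_shift, box = box)
}

#' Construct a triangulated surface mesh
#'
#' Wraps a vertex/face soup into the mesh container used by the surface
#' metrics, labelling connected components by shared edges and computing
#' per-component area and signed enclosed volume. Meshes from
#' [willard_chandler_surface()] carry per-face lattice shifts so that
#' components crossing the periodic seam stay contiguous.
#'
#' @param vertices Numeric nv x 3 matrix.
#' @param faces Integer nf x 3 matrix of vertex indices, outward-oriented.
#' @param box Periodic box (defaults to an effectively aperiodic huge box).
#' @param face_shift Optional nf x 9 integer lattice shifts
#'   (v1x v1y v1z v2x ... v3z).
#' @return A list with class `"surface_mesh"`: vertices, faces, face_shift,
#'   box, `component` (per-face label), `component_area`,
#'   `component_volume` (signed), `component_percolating` (per component,
#'   3-column logical by axis), `n_components`.
#' @export
surface_mesh <- function(vertices, faces, box = rep(1e9, 3), face_shift = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  box <- as.numeric(box)
  if (is.null(face_shift)) face_shift <- matrix(0L, nrow(faces), 9)
  mesh <- list(vertices = vertices, faces = faces,
               face_shift = face_shift, box = box)
  .label_components(mesh)
}

# per-face vertex coordinate blocks in the face's own (cell-local) frame
.face_geometry <- function(mesh, extra_shift = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  b <- mesh$box
  out <- vector("list", 3)
  for (k in 1:3) {
    sh <- mesh$face_shift[, (k - 1) * 3 + (1:3), drop = FALSE]
    if (!is.null(extra_shift)) sh <- sh + extra_shift
    out[[k]] <- v[f[, k], , drop = FALSE] +
      sh * matrix(b, nrow(f), 3, byrow = TRUE)
  }
  out
}

.face_edge_keys <- function(faces) {
  ek <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  cbind(ek(faces[, 1], faces[, 2]),
        ek(faces[, 2], faces[, 3]),
        ek(faces[, 3], faces[, 1]))
}

# label connected components, compute areas and unfolded signed volumes
.label_components <- function(mesh) {
  nf <- nrow(mesh$faces)
  if (!nf) stop("no-surface error: mesh has no faces", call. = FALSE)
  ekeys <- .face_edge_keys(mesh$faces)
  ekeys_v <- as.vector(ekeys)
  uk <- unique(ekeys_v)
  eid <- matrix(match(ekeys_v, uk), nf, 3)       # face -> its 3 edge ids
  edge_faces <- split(rep(seq_len(nf), 3), as.vector(eid))
  # one shared vertex id per edge (recovered from any face holding it)
  vmin <- c(pmin(mesh$faces[, 1], mesh$faces[, 2]),
            pmin(mesh$faces[, 2], mesh$faces[, 3]),
            pmin(mesh$faces[, 3], mesh$faces[, 1]))
  edge_vertex <- vmin[match(seq_along(uk), as.vector(eid))]
  pairs <- do.call(rbind, lapply(edge_faces, function(fs) {
    if (length(fs) < 2) return(NULL)
    cbind(fs[1], fs[-1])
  }))
  if (is.null(pairs)) pairs <- cbind(integer(0), integer(0))
  root <- union_find_components(nf, pairs)
  comp <- match(root, unique(root))
  ncomp <- max(comp)

  geom <- .face_geometry(mesh)
  cr <- .row_cross(geom[[2]] - geom[[1]], geom[[3]] - geom[[1]])
  f_area <- 0.5 * sqrt(rowSums(cr^2))
  area <- as.numeric(rowsum(f_area, comp))

  # unfold each component (consistent lattice shifts face by face); a
  # conflicting shift marks percolation along that axis
  perc <- matrix(FALSE, ncomp, 3)
  face_offset <- matrix(0L, nf, 3)
  seen <- rep(FALSE, nf)
  queue <- integer(nf)
  for (ci in seq_len(ncomp)) {
    fs <- which(comp == ci)
    seen[fs[1]] <- TRUE
    queue[1] <- fs[1]
    head_i <- 1L; tail_i <- 1L
    while (head_i <= tail_i) {
      f <- queue[head_i]; head_i <- head_i + 1L
      for (e in eid[f, ]) {
        for (g in edge_faces[[e]]) {
          if (g == f) next
          # the edge's shared vertex determines g's offset relative to f
          a <- edge_vertex[e]
          kf <- which(mesh$faces[f, ] == a)[1]
          kg <- which(mesh$faces[g, ] == a)[1]
          sf <- mesh$face_shift[f, (kf - 1) * 3 + (1:3)] + face_offset[f, ]
          sg <- mesh$face_shift[g, (kg - 1) * 3 + (1:3)]
          og <- sf - sg
          if (!seen[g]) {
            face_offset[g, ] <- og
            seen[g] <- TRUE
            tail_i <- tail_i + 1L
            queue[tail_i] <- g
          } else if (any(face_offset[g, ] != og)) {
            perc[ci, face_offset[g, ] != og] <- TRUE
          }
        }
      }
    }
  }
  # signed volume from z-flux of the unfolded geometry; valid for any
  # component that does not percolate in z
  geo <- .face_geometry(mesh, extra_shift = face_offset)
  crz <- .row_cross(geo[[2]] - geo[[1]], geo[[3]] - geo[[1]])[, 3] / 2
  zbar <- (geo[[1]][, 3] + geo[[2]][, 3] + geo[[3]][, 3]) / 3
  vol <- as.numeric(rowsum(crz * zbar, comp))
  vol[perc[, 3]] <- NA_real_

  mesh$component <- comp
  mesh$n_components <- ncomp
  mesh$component_area <- area
  mesh$component_volume <- vol
  mesh$component_percolating <- perc
  mesh$face_offset <- face_offset
  mesh$edge_counts <- lengths(edge_faces)
  class(mesh) <- "surface_mesh"
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d vertices, %d faces, %d component(s), area %.1f A^2>\n",
              nrow(x$vertices), nrow(x$faces), x$n_components,
              sum(x$component_area)))
  invisible(x)
}

#' Willard-Chandler isosurface of a density field
#'
#' Extracts the level set of the Gaussian-smoothed bead density at
#' `iso_fraction * rho_max` over the central box, with vertices linearly
#' interpolated along grid edges and triangles stitched across the periodic
#' seam so that components wrapping the boundary (including box-percolating
#' bilayers) remain contiguous and closed.
#'
#' @param field A [gaussian_density_grid()] result.
#' @param params The [wc_params()] (for the iso fraction).
#' @return A [surface_mesh()].
#' @export
willard_chandler_surface <- function(field, params = wc_params()) {
  stopifnot(inherits(field, "density_field"))
  if (field$rho_max <= 0 || diff(range(field$values)) == 0) {
    stop("no-surface error: density field is constant", call. = FALSE)
  }
  iso <- params$iso_fraction * field$rho_max
  raw <- marching_tetrahedra(field$values, field$box, iso)
  if (!nrow(raw$faces)) {
    stop("no-surface error: level set is empty at this isovalue", call. = FALSE)
  }
  surface_mesh(raw$vertices, raw$faces, box = raw$box,
               face_shift = raw$face_shift)
}

#' Total area and material volume of a closed mesh
#'
#' Area is the sum of triangle areas. Volume is the absolute value of the sum
#' of per-component signed volumes computed by the divergence theorem with
#' faces oriented outward from the dense phase, so a nested inner surface
#' (e.g. a vesicle lumen) subtracts the cavity it encloses, leaving the
#' material (shell) volume.
#'
#' @param mesh A [surface_mesh()].
#' @return List: `area` (Angstrom^2), `volume` (material, Angstrom^3),
#'   `component_area`, `component_volume` (signed), `outer_volume` (largest
#'   single-component enclosed volume, lumen-inclusive for a vesicle).
#' @export
mesh_area_volume <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  holes <- sum(mesh$edge_counts != 2)
  if (holes > 0) {
    stop(sprintf("open-mesh error: %d boundary/non-manifold edges", holes),
         call. = FALSE)
  }
  vols <- mesh$component_volume
  if (anyNA(vols)) {
    warning("component percolating in z: enclosed volume is undefined for it")
  }
  list(area = sum(mesh$component_area),
       volume = abs(sum(vols, na.rm = TRUE)),
       component_area = mesh$component_area,
       component_volume = vols,
       outer_volume = if (all(is.na(vols))) NA_real_ else max(abs(vols), na.rm = TRUE))
}

#' Per-surfactant surface metrics
#'
#' @param area Surface area (Angstrom^2).
#' @param volume Enclosed material volume (Angstrom^3), positive.
#' @param n Aggregation number (>= 1).
#' @return List: `area_per_surfactant`, `volume_per_surfactant`,
#'   `sa_to_volume`.
#' @export
per_surfactant_metrics <- function(area, volume, n) {
  if (n < 1) stop("aggregation number must be >= 1", call. = FALSE)
  if (!is.finite(volume) || volume <= 0) {
    stop("degenerate-surface error: enclosed volume is not positive", call. = FALSE)
  }
  list(area_per_surfactant = area / n,
       volume_per_surfactant = volume / n,
       sa_to_volume = area / volume)
}

#' Subdivided icosahedral sphere mesh
#'
#' A validation fixture: each subdivision level splits every triangle in four
#' and reprojects vertices to the sphere, converging on area `4 pi r^2` and
#' volume `4/3 pi r^3`.
#'
#' @param radius Sphere radius.
#' @param depth Subdivision depth (0 = icosahedron).
#' @param center Sphere center.
#' @return A [surface_mesh()] with outward-oriented faces.
#' @export
icosphere <- function(radius = 1, depth = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (d in seq_len(depth)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newf <- matrix(0L, 0, 3)
    vlist <- list(v)
    midpoint <- function(a, b) {
      key <- paste0(min(a, b), "_", max(a, b))
      got <- mid_cache[[key]]
      if (!is.null(got)) return(got)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- m
      mid_cache[[key]] <- nv
      nv
    }
    fl <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      fl[[i]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, vlist[-1]))
    f <- do.call(rbind, fl)
  }
  surface_mesh(sweep(v * radius, 2, center, `+`), f)
}

#' Export a mesh to ASCII PLY
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices", "end_header",
    sprintf("%.6f %.6f %.6f", mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]),
    sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L)
  ), con)
  invisible(path)
}

#' Export a mesh to Wavefront OBJ
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]),
    sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  ), con)
  invisible(path)
}
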