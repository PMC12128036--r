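# Deterministic generators for synthetic self-assembled structures with known
# ground truth: ellipsoidal micelles, bilayer vesicles, disc-like bicelles,
# box-percolating lamellae and dispersed monomers. Surfactants are ideal
# head-to-tail chains anchored at an interface with tails pointing into the
# hydrophobic region; isotropic Gaussian positional noise emulates thermal
# jitter.

#' Default synthetic surfactant topology
#'
#' A double-tailed surfactant reduced to a single chain: two head beads
#' (small size class) followed by four tail beads. Tail beads default to the
#' regular size class, giving the 5.875 Angstrom clustering cutoff.
#'
#' @param tail_size_class Size class of the tail beads.
#' @param head_size_class Size class of the head beads.
#' @return A [cg_topology()] named `"SURF"`.
#' @export
synthetic_surfactant_topology <- function(tail_size_class = "R",
                                          head_size_class = "S") {
  cg_topology("SURF", c(
    lapply(1:2, function(i) bead_spec(paste0("H", i), head_size_class, "head")),
    lapply(1:4, function(i) bead_spec(paste0("T", i), tail_size_class, "tail"))
  ))
}

# place one surfactant chain: bead i at anchor + (i-1) * step * dir
.chain_coords <- function(anchor, dir, step, n_beads) {
  t(anchor + outer(dir, (0:(n_beads - 1)) * step))
}

# micelle-style chain: beads walk radially inward from surface anchor toward
# the aggregate center, clamped so they never overshoot it
.radial_chain <- function(anchor, step, n_beads, floor_frac = 0.06) {
  r <- sqrt(sum(anchor^2))
  u <- anchor / r
  ri <- pmax(r - (0:(n_beads - 1)) * step, floor_frac * r)
  outer(ri, u)
}

.assemble_frame <- function(coord_list, box, topology, time = 0, center = NULL) {
  nb <- topology$n_beads
  coords <- do.call(rbind, coord_list)
  if (!is.null(center)) coords <- sweep(coords, 2, center, `+`)
  n_mol <- length(coord_list)
  cg_frame(coords, box, rep(seq_len(n_mol), each = nb),
           rep(topology$name, n_mol), setNames(list(topology), topology$name),
           time = time)
}

.apply_noise <- function(coords, noise) {
  if (noise > 0) coords + matrix(stats::rnorm(length(coords), 0, noise), ncol = 3)
  else coords
}

# quasi-uniform surface placement: Fibonacci lattice on the unit sphere
# mapped onto the ellipsoid. A low-discrepancy lattice is essential here:
# with iid random placement the ordered-eigenvalue noise of the inertia
# tensor at N ~ a few hundred surfactants inflates the recovered
# eccentricities of a sphere to ~0.4, whereas the lattice keeps the moment
# anisotropy at the 1e-3 level.
.ellipsoid_surface_points <- function(n, a, b, c, phase = 0) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2 + phase
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(a * r * cos(phi), b * r * sin(phi), c * z)
}

# Thomsen approximation to the ellipsoid surface area (exact for spheres,
# relative error ~1e-3 in general)
ellipsoid_area <- function(a, b, c, p = 1.6075) {
  4 * pi * ((a^p * b^p + a^p * c^p + b^p * c^p) / 3)^(1 / p)
}

.coverage_check <- function(area, n, r_cut) {
  spacing <- sqrt(area / n)
  if (spacing > 1.4 * r_cut) {
    warning(sprintf(
      "coverage warning: %d surfactants give ~%.1f A head spacing on a %.0f A^2 surface; clusters may fragment",
      n, spacing, area))
  }
}

#' Synthetic ellipsoidal micelle
#'
#' Head beads are placed quasi-uniformly (Fibonacci lattice) on the ellipsoid
#' surface; tail beads
#' walk radially inward at fixed spacing (clamped at the core), emulating a
#' surfactant micelle with a hydrophobic interior.
#'
#' @param a,b,c Ellipsoid semiaxes, Angstrom, `a >= b >= c > 0`.
#' @param n Number of surfactants.
#' @param noise Isotropic Gaussian positional noise sigma, Angstrom.
#' @param box A [cg_box()]; default pads the structure generously.
#' @param seed RNG seed; output is bit-identical for identical (spec, seed).
#' @param bead_spacing Intra-chain bead spacing, Angstrom.
#' @param topology Surfactant topology
#'   (default [synthetic_surfactant_topology()]).
#' @param center Aggregate center; default box center.
#' @param time Frame time, ns.
#' @return List: `frame` (a [cg_frame()]) and `ground_truth` (semiaxes,
#'   analytic coordinate-pair eccentricities, Thomsen surface area, ellipsoid
#'   volume, member molecule ids).
#' @export
make_ellipsoid_micelle <- function(a, b, c, n = 300, noise = 0, box = NULL,
                                   seed = 1, bead_spacing = 3.5,
                                   topology = synthetic_surfactant_topology(),
                                   center = NULL, time = 0) {
  stopifnot(a >= b, b >= c, c > 0, n >= 1)
  if (is.null(box)) box <- cg_box(rep(2 * a + 80, 3))
  if (is.null(center)) center <- as.numeric(box) / 2
  nb <- topology$n_beads
  area <- ellipsoid_area(a, b, c)
  r_cut <- compute_rcut(min(topology$beads$sigma[topology$beads$role == "tail"]))
  .coverage_check(area, n, r_cut)
  frame <- withr::with_seed(seed, {
    heads <- .ellipsoid_surface_points(n, a, b, c)
    chains <- lapply(seq_len(n), function(i) {
      .apply_noise(.radial_chain(heads[i, ], bead_spacing, nb), noise)
    })
    .assemble_frame(chains, box, topology, time = time, center = center)
  })
  e <- coordinate_pair_eccentricities(a, b, c)
  list(frame = frame,
       ground_truth = list(kind = "ellipsoid_micelle", semiaxes = c(a, b, c),
                           e_ab = unname(e["e_ab"]), e_ac = unname(e["e_ac"]),
                           area = area, volume = 4 / 3 * pi * a * b * c,
                           n = n, members = seq_len(n), center = center))
}

#' Synthetic bilayer vesicle
#'
#' Two leaflets on concentric spheres: the outer leaflet's heads at
#' `r_outer` with tails pointing inward, the inner leaflet's heads at
#' `r_outer - shell_thickness` with tails pointing outward, chains meeting at
#' mid-shell. Leaflet populations are split in proportion to leaflet area.
#'
#' @param r_outer Outer radius, Angstrom.
#' @param shell_thickness Bilayer shell thickness, Angstrom
#'   (`< r_outer`).
#' @inheritParams make_ellipsoid_micelle
#' @return List: `frame`, `ground_truth` (outer/inner radii, shell volume
#'   `4/3 pi (R_out^3 - R_in^3)`, outer area `4 pi R_out^2`).
#' @export
make_vesicle <- function(r_outer, shell_thickness, n = 5600, noise = 0,
                         box = NULL, seed = 1,
                         topology = synthetic_surfactant_topology(),
                         center = NULL, time = 0) {
  stopifnot(r_outer > shell_thickness, shell_thickness > 0)
  r_inner <- r_outer - shell_thickness
  if (is.null(box)) box <- cg_box(rep(2 * r_outer + 80, 3))
  if (is.null(center)) center <- as.numeric(box) / 2
  nb <- topology$n_beads
  # chains span just short of mid-shell so opposing tail ends do not pile up
  # at one radius (which would spuriously inflate rho_max there); the
  # half-bead stagger leaves the radial bead density close to a uniform slab
  step <- (shell_thickness / 2) / (nb - 0.5)
  n_out <- round(n * r_outer^2 / (r_outer^2 + r_inner^2))
  n_in <- n - n_out
  r_cut <- compute_rcut(min(topology$beads$sigma[topology$beads$role == "tail"]))
  .coverage_check(4 * pi * r_outer^2, n_out, r_cut)
  frame <- withr::with_seed(seed, {
    h_out <- .ellipsoid_surface_points(n_out, r_outer, r_outer, r_outer)
    h_in <- .ellipsoid_surface_points(n_in, r_inner, r_inner, r_inner,
                                      phase = pi / 7)  # avoid radial alignment
    chains <- c(
      lapply(seq_len(n_out), function(i) {
        u <- h_out[i, ] / sqrt(sum(h_out[i, ]^2))
        .apply_noise(.chain_coords(h_out[i, ], -u, step, nb), noise)
      }),
      lapply(seq_len(n_in), function(i) {
        u <- h_in[i, ] / sqrt(sum(h_in[i, ]^2))
        .apply_noise(.chain_coords(h_in[i, ], u, step, nb), noise)
      })
    )
    .assemble_frame(chains, box, topology, time = time, center = center)
  })
  list(frame = frame,
       ground_truth = list(kind = "vesicle", r_outer = r_outer,
                           r_inner = r_inner,
                           shell_volume = 4 / 3 * pi * (r_outer^3 - r_inner^3),
                           outer_area = 4 * pi * r_outer^2,
                           n = n, members = seq_len(n), center = center))
}

#' Synthetic bicelle (disc-like bilayer patch)
#'
#' A flat circular bilayer of radius `disc_radius` and thickness `thickness`
#' with a semicircular rim, heads on the outside and tails meeting at the
#' midplane.
#'
#' @param disc_radius Radius of the flat bilayer region, Angstrom.
#' @param thickness Bilayer thickness, Angstrom.
#' @inheritParams make_ellipsoid_micelle
#' @return List: `frame`, `ground_truth` (radius, thickness, flat area).
#' @export
make_bicelle <- function(disc_radius, thickness, n = 500, noise = 0,
                         box = NULL, seed = 1,
                         topology = synthetic_surfactant_topology(),
                         center = NULL, time = 0) {
  stopifnot(disc_radius > 0, thickness > 0)
  if (is.null(box)) box <- cg_box(rep(2 * disc_radius + thickness + 80, 3))
  if (is.null(center)) center <- as.numeric(box) / 2
  nb <- topology$n_beads
  half_t <- thickness / 2
  step <- half_t / (nb - 1)
  area_flat <- 2 * pi * disc_radius^2
  area_rim <- pi^2 * disc_radius * thickness / 2 +
    4 * half_t^2  # half-torus around the edge (approximate)
  n_rim <- max(8L, round(n * area_rim / (area_flat + area_rim)))
  n_flat <- n - n_rim
  r_cut <- compute_rcut(min(topology$beads$sigma[topology$beads$role == "tail"]))
  .coverage_check(area_flat, n_flat, r_cut)
  golden <- (1 + sqrt(5)) / 2
  frame <- withr::with_seed(seed, {
    chains <- vector("list", n)
    # flat region: sunflower layout, alternating leaflets
    for (i in seq_len(n_flat)) {
      r <- disc_radius * sqrt((i - 0.5) / n_flat)
      phi <- 2 * pi * i / golden^2
      up <- i %% 2 == 0
      anchor <- c(r * cos(phi), r * sin(phi), if (up) half_t else -half_t)
      dir <- c(0, 0, if (up) -1 else 1)
      chains[[i]] <- .apply_noise(.chain_coords(anchor, dir, step, nb), noise)
    }
    # rim: quasi-uniform lattice on the semicircular cross-section
    for (i in seq_len(n_rim)) {
      phi <- 2 * pi * (i / golden^2 %% 1)
      theta <- pi * ((i - 0.5) / n_rim - 0.5)
      radial <- c(cos(phi), sin(phi), 0)
      anchor <- radial * (disc_radius + half_t * cos(theta)) +
        c(0, 0, half_t * sin(theta))
      dir <- -(radial * cos(theta) + c(0, 0, sin(theta)))
      chains[[n_flat + i]] <- .apply_noise(.chain_coords(anchor, dir, step, nb), noise)
    }
    .assemble_frame(chains, box, topology, time = time, center = center)
  })
  list(frame = frame,
       ground_truth = list(kind = "bicelle", disc_radius = disc_radius,
                           thickness = thickness, flat_area = area_flat,
                           n = n, members = seq_len(n), center = center))
}

#' Synthetic box-percolating lamella
#'
#' A bilayer spanning the full xy extent of the box: heads on two jittered
#' square lattices at `z0 +/- thickness/2` (lattices offset by half a cell so
#' opposing tails interdigitate), tails meeting at the midplane. Optional
#' sinusoidal corrugation displaces both leaflets in phase.
#'
#' @param box A [cg_box()]; the lamella spans x and y.
#' @param thickness Bilayer thickness, Angstrom (`< Lz`).
#' @param n Total surfactants (split equally between leaflets; rounded to the
#'   lattice).
#' @param corrugation Amplitude of `sin(2 pi x / Lx)` corrugation, Angstrom.
#' @inheritParams make_ellipsoid_micelle
#' @param z0 Midplane height; default `Lz / 2`.
#' @return List: `frame`, `ground_truth` (thickness, flat-case area per
#'   headgroup `2 Lx Ly / n`, corrugation).
#' @export
make_lamella <- function(box, thickness, n = 400, corrugation = 0, noise = 0,
                         seed = 1, topology = synthetic_surfactant_topology(),
                         z0 = NULL, time = 0) {
  box <- if (inherits(box, "cg_box")) box else cg_box(box)
  stopifnot(thickness > 0, thickness < box[3])
  if (is.null(z0)) z0 <- box[3] / 2
  nb <- topology$n_beads
  half_t <- thickness / 2
  step <- half_t / (nb - 1)
  n_leaf <- floor(n / 2)
  nx <- max(2L, round(sqrt(n_leaf * box[1] / box[2])))
  ny <- max(2L, round(n_leaf / nx))
  n_leaf <- nx * ny
  n_total <- 2L * n_leaf
  dx <- box[1] / nx
  dy <- box[2] / ny
  frame <- withr::with_seed(seed, {
    chains <- vector("list", n_total)
    m <- 0L
    for (leaf in c(1, -1)) {
      off <- if (leaf == 1) 0 else 0.5  # half-cell offset between leaflets
      for (ix in seq_len(nx) - 1) {
        for (iy in seq_len(ny) - 1) {
          m <- m + 1L
          x <- (ix + 0.5 + off) * dx
          y <- (iy + 0.5 + off) * dy
          anchor <- c(x, y, z0 + leaf * half_t)
          dir <- c(0, 0, -leaf)
          ch <- .chain_coords(anchor, dir, step, nb)
          ch[, 3] <- ch[, 3] + corrugation * sin(2 * pi * ch[, 1] / box[1])
          chains[[m]] <- .apply_noise(ch, noise)
        }
      }
    }
    .assemble_frame(chains, box, topology, time = time)
  })
  list(frame = frame,
       ground_truth = list(kind = "lamella", thickness = thickness,
                           area_per_headgroup = 2 * box[1] * box[2] / n_total,
                           corrugation = corrugation, n = n_total,
                           members = seq_len(n_total)))
}

#' Dispersed surfactant monomers
#'
#' @param n Number of monomers.
#' @param box A [cg_box()].
#' @param min_separation Minimum anchor separation, Angstrom.
#' @inheritParams make_ellipsoid_micelle
#' @return List: `frame`, `ground_truth`.
#' @export
make_monomers <- function(n, box, noise = 0, seed = 1,
                          topology = synthetic_surfactant_topology(),
                          min_separation = 30, time = 0) {
  box <- if (inherits(box, "cg_box")) box else cg_box(box)
  nb <- topology$n_beads
  frame <- withr::with_seed(seed, {
    anchors <- matrix(0, 0, 3)
    tries <- 0
    while (nrow(anchors) < n) {
      cand <- stats::runif(3) * as.numeric(box)
      ok <- !nrow(anchors) ||
        min(minimum_image_dist(matrix(cand, 1), anchors, box)) > min_separation
      if (ok) anchors <- rbind(anchors, cand)
      tries <- tries + 1
      if (tries > 1000 * n) stop("placement error: cannot place monomers", call. = FALSE)
    }
    chains <- lapply(seq_len(n), function(i) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      .apply_noise(.chain_coords(anchors[i, ], u, 3.5, nb), noise)
    })
    .assemble_frame(chains, box, topology, time = time)
  })
  list(frame = frame,
       ground_truth = list(kind = "monomers", n = n, members = seq_len(n)))
}

#' Dispersed multi-aggregate system with known partition
#'
#' Generates each component in its own frame, then places the components at
#' random centers with guaranteed clearance so the ground-truth partition is
#' preserved, and merges them into one frame.
#'
#' @param components List of component specs; each a list with `kind`
#'   (`"ellipsoid_micelle"`, `"vesicle"`, `"bicelle"`, `"monomers"`) plus
#'   the arguments of the corresponding generator (`box`, `seed`, `center`
#'   are managed here).
#' @param box A [cg_box()] for the combined frame.
#' @param seed RNG seed.
#' @param noise Positional noise passed to every component.
#' @param clearance Extra clearance between component envelopes, Angstrom.
#' @param topology Shared surfactant topology.
#' @param time Frame time, ns.
#' @return List: `frame`, `ground_truth` with `labels` (per-molecule
#'   component index; monomer components label each molecule separately as
#'   `"<comp>_<mol>"`), `components` (per-component ground truths).
#' @export
make_dispersed_system <- function(components, box, seed = 1, noise = 0,
                                  clearance = 15,
                                  topology = synthetic_surfactant_topology(),
                                  time = 0) {
  box <- if (inherits(box, "cg_box")) box else cg_box(box)
  gen <- list(ellipsoid_micelle = make_ellipsoid_micelle,
              vesicle = make_vesicle, bicelle = make_bicelle,
              monomers = make_monomers)
  built <- withr::with_seed(seed, {
    parts <- vector("list", length(components))
    for (i in seq_along(components)) {
      spec <- components[[i]]
      kind <- spec$kind
      if (is.null(gen[[kind]])) stop("unknown component kind: ", kind, call. = FALSE)
      args <- spec[setdiff(names(spec), "kind")]
      args$noise <- noise
      args$seed <- sample.int(.Machine$integer.max, 1)
      args$topology <- topology
      if (kind == "monomers") {
        # monomers are placed directly in the full box afterwards
        args$box <- box
      } else {
        args$box <- box
        args$center <- c(0, 0, 0)
      }
      parts[[i]] <- c(do.call(gen[[kind]], args), list(kind = kind))
    }
    # envelope radius of each non-monomer component
    radius <- vapply(parts, function(p) {
      if (p$kind == "monomers") return(NA_real_)
      max(sqrt(rowSums(p$frame$coords^2)))
    }, numeric(1))
    centers <- matrix(NA_real_, length(parts), 3)
    placed <- which(!is.na(radius))
    for (i in placed) {
      ok <- FALSE
      for (try in 1:2000) {
        cand <- stats::runif(3) * as.numeric(box)
        prev <- placed[placed < i]
        if (!length(prev) || all(
          minimum_image_dist(matrix(cand, 1), centers[prev, , drop = FALSE], box) >
            radius[i] + radius[prev] + clearance)) {
          ok <- TRUE
          centers[i, ] <- cand
          break
        }
      }
      if (!ok) stop("placement error: cannot place component ", i,
                    " without overlap", call. = FALSE)
    }
    # monomers must clear every placed component too
    mono <- which(is.na(radius))
    for (i in mono) {
      fr <- parts[[i]]$frame
      nb <- topology$n_beads
      n_mol <- length(fr$species)
      keepmask <- rep(TRUE, n_mol)
      anchors <- fr$coords[seq(1, nrow(fr$coords), by = nb), , drop = FALSE]
      for (m in seq_len(n_mol)) {
        for (try in 1:2000) {
          d <- minimum_image_dist(anchors[m, , drop = FALSE],
                                  centers[placed, , drop = FALSE], box)
          if (all(d > radius[placed] + clearance)) break
          anchors[m, ] <- stats::runif(3) * as.numeric(box)
          if (try == 2000) stop("placement error: cannot place monomer", call. = FALSE)
        }
        rows <- ((m - 1) * nb + 1):(m * nb)
        shift <- anchors[m, ] - fr$coords[rows[1], ]
        parts[[i]]$frame$coords[rows, ] <-
          sweep(fr$coords[rows, , drop = FALSE], 2, -shift)
      }
    }
    list(parts = parts, centers = centers)
  })

  parts <- built$parts
  centers <- built$centers
  coords <- list()
  labels <- character(0)
  gts <- list()
  mol_counter <- 0L
  for (i in seq_along(parts)) {
    fr <- parts[[i]]$frame
    cc <- fr$coords
    if (!is.na(centers[i, 1])) cc <- sweep(cc, 2, centers[i, ], `+`)
    coords[[i]] <- cc
    n_mol <- length(fr$species)
    if (parts[[i]]$kind == "monomers") {
      labels <- c(labels, paste0(i, "_", seq_len(n_mol)))
    } else {
      labels <- c(labels, rep(as.character(i), n_mol))
    }
    gts[[i]] <- parts[[i]]$ground_truth
    mol_counter <- mol_counter + n_mol
  }
  nb <- topology$n_beads
  all_coords <- wrap_coords(do.call(rbind, coords), box)
  frame <- cg_frame(all_coords, box, rep(seq_len(mol_counter), each = nb),
                    rep(topology$name, mol_counter),
                    setNames(list(topology), topology$name), time = time)
  list(frame = frame,
       ground_truth = list(kind = "mixture", labels = labels,
                           components = gts, centers = centers))
}
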