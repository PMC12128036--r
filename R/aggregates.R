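#' Clustering cutoff from the tail-bead Lennard-Jones sigma
#'
#' The single-linkage contact threshold is 5/4 of the Lennard-Jones sigma of
#' the smallest tail-group bead, which respects the different equilibrium
#' tail-tail distances of models coarse-grained at different resolutions
#' (5.875 Angstrom for regular 4.70-Angstrom tail beads, 4.250 Angstrom for
#' tiny 3.40-Angstrom tail beads).
#'
#' @param sigma Lennard-Jones sigma of the smallest tail bead, Angstrom.
#' @return The clustering cutoff `(5/4) * sigma`, Angstrom.
#' @export
#' @examples
#' compute_rcut(4.70)  # 5.875
#' compute_rcut(3.40)  # 4.250
compute_rcut <- function(sigma) {
  sigma <- as.numeric(sigma)
  if (length(sigma) != 1 || is.na(sigma) || sigma <= 0) {
    stop("sigma must be a single positive length (Angstrom)", call. = FALSE)
  }
  (5 / 4) * sigma
}

#' Clustering parameters
#'
#' @param r_cut Tail-bead contact distance in Angstrom. `NULL` (default)
#'   derives it per frame as [compute_rcut()] of the smallest tail-bead sigma
#'   declared in the frame's topology.
#' @param min_aggregation_number Aggregates below this size are excluded from
#'   *reporting* stages; the clustering partition itself always covers every
#'   surfactant (monomers are singleton clusters).
#' @return A list with class `"cluster_params"`.
#' @export
cluster_params <- function(r_cut = NULL, min_aggregation_number = 5) {
  if (!is.null(r_cut) && (length(r_cut) != 1 || r_cut <= 0)) {
    stop("r_cut must be a single positive length", call. = FALSE)
  }
  if (min_aggregation_number < 1) {
    stop("min_aggregation_number must be >= 1", call. = FALSE)
  }
  structure(list(r_cut = r_cut,
                 min_aggregation_number = as.integer(min_aggregation_number)),
            class = "cluster_params")
}

# smallest tail-bead sigma across the surfactant species present
smallest_tail_sigma <- function(frame) {
  sig <- Inf
  for (sp in unique(frame$species)) {
    tp <- frame$topology[[sp]]
    if (!tp$surfactant) next
    tails <- tp$beads$sigma[tp$beads$role == "tail"]
    if (!length(tails)) {
      stop("configuration error: surfactant species '", sp,
           "' declares no tail beads", call. = FALSE)
    }
    sig <- min(sig, tails)
  }
  if (!is.finite(sig)) stop("frame contains no surfactant species", call. = FALSE)
  sig
}

# All index pairs (i < j) of `coords` within r_cut under minimum-image metric.
# Cell list when the box admits >= 3 cells per axis, brute force otherwise;
# the two paths are equivalent and tested against each other.
contact_pairs <- function(coords, box, r_cut) {
  n <- nrow(coords)
  if (n < 2) return(cbind(integer(0), integer(0)))
  box <- as.numeric(box)
  ncell <- pmax(1L, as.integer(floor(box / r_cut)))
  if (n <= 400 || any(ncell < 3L)) {
    d <- minimum_image_dist(coords, coords, box)
    hit <- which(d <= r_cut & upper.tri(d), arr.ind = TRUE)
    return(unname(hit[order(hit[, 1], hit[, 2]), , drop = FALSE]))
  }
  w <- wrap_coords(coords, box)
  ci <- sapply(1:3, function(k) {
    pmin(ncell[k] - 1L, as.integer(floor(w[, k] / (box[k] / ncell[k]))))
  })
  key <- ci[, 1] + ncell[1] * (ci[, 2] + ncell[2] * ci[, 3])
  cells <- split(seq_len(n), key)
  cell_of <- as.integer(names(cells))
  # decode occupied cell triples
  kx <- cell_of %% ncell[1]
  ky <- (cell_of %/% ncell[1]) %% ncell[2]
  kz <- cell_of %/% (ncell[1] * ncell[2])
  occupied <- new.env(hash = TRUE, size = length(cells))
  for (i in seq_along(cells)) assign(as.character(cell_of[i]), i, envir = occupied)
  half <- rbind(
    c(1, 0, 0), c(-1, 1, 0), c(0, 1, 0), c(1, 1, 0),
    c(-1, -1, 1), c(0, -1, 1), c(1, -1, 1), c(-1, 0, 1), c(0, 0, 1),
    c(1, 0, 1), c(-1, 1, 1), c(0, 1, 1), c(1, 1, 1)
  )
  out <- vector("list", 2 * length(cells))
  m <- 0L
  pair_block <- function(ia, ib) {
    d <- minimum_image_dist(coords[ia, , drop = FALSE], coords[ib, , drop = FALSE], box)
    hit <- which(d <= r_cut, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    cbind(ia[hit[, 1]], ib[hit[, 2]])
  }
  for (i in seq_along(cells)) {
    ia <- cells[[i]]
    # within-cell pairs
    if (length(ia) > 1) {
      d <- minimum_image_dist(coords[ia, , drop = FALSE], coords[ia, , drop = FALSE], box)
      hit <- which(d <= r_cut & upper.tri(d), arr.ind = TRUE)
      if (nrow(hit)) {
        m <- m + 1L
        out[[m]] <- cbind(ia[hit[, 1]], ia[hit[, 2]])
      }
    }
    # half the neighbor cells, so each cell pair is visited once
    for (h in seq_len(nrow(half))) {
      nb <- c((kx[i] + half[h, 1]) %% ncell[1],
              (ky[i] + half[h, 2]) %% ncell[2],
              (kz[i] + half[h, 3]) %% ncell[3])
      nbkey <- as.character(nb[1] + ncell[1] * (nb[2] + ncell[2] * nb[3]))
      j <- occupied[[nbkey]]
      if (is.null(j)) next
      blk <- pair_block(ia, cells[[j]])
      if (!is.null(blk)) {
        m <- m + 1L
        out[[m]] <- blk
      }
    }
  }
  if (!m) return(cbind(integer(0), integer(0)))
  pairs <- do.call(rbind, out[seq_len(m)])
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  pairs <- unique(pairs)
  unname(pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE])
}

# connected components by union-find with path halving;
# returns the component root of each of n nodes
union_find_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (e in seq_len(nrow(pairs))) {
      ra <- find(pairs[e, 1])
      rb <- find(pairs[e, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Detect aggregates by single-linkage clustering of tail beads
#'
#' Two surfactant molecules belong to the same aggregate when any pair of
#' their tail-group beads lies within `r_cut` under the minimum image
#' convention; aggregates are the connected components of this contact
#' relation. The partition covers every surfactant molecule, so dispersed
#' monomers appear as singleton aggregates. Each aggregate is unwrapped across
#' the periodic boundary and flagged when it percolates (connects to its own
#' periodic image).
#'
#' @param frame A [cg_frame()].
#' @param params A [cluster_params()].
#' @param unwrap Unwrap member coordinates and set the percolation flag
#'   (default `TRUE`).
#' @return List of aggregates, largest first. Each has class
#'   `"cg_aggregate"` with fields `members` (molecule indices), `n`
#'   (aggregation number), `time`, `box`, `coords` (member bead coordinates,
#'   unwrapped unless percolating), `bead_mol` (member-local molecule index
#'   per bead row), `bead_role`, `bead_mass`, `percolating`.
#' @export
find_aggregates <- function(frame, params = cluster_params(), unwrap = TRUE) {
  stopifnot(inherits(frame, "cg_frame"))
  surf <- surfactant_molecules(frame)
  if (!length(surf)) stop("frame contains no surfactant molecules", call. = FALSE)
  r_cut <- params$r_cut
  if (is.null(r_cut)) r_cut <- compute_rcut(smallest_tail_sigma(frame))

  tail_idx <- which(frame$bead_role == "tail" & frame$mol_id %in% surf)
  pairs <- contact_pairs(frame$coords[tail_idx, , drop = FALSE], frame$box, r_cut)
  bead_a <- tail_idx[pairs[, 1]]
  bead_b <- tail_idx[pairs[, 2]]
  mol_a <- frame$mol_id[bead_a]
  mol_b <- frame$mol_id[bead_b]

  # connected components over surfactant molecules (deduped molecule pairs)
  midx <- match(seq_along(frame$species), surf)  # molecule -> local surf index
  ka <- midx[mol_a]; kb <- midx[mol_b]
  dedup <- !duplicated(paste(pmin(ka, kb), pmax(ka, kb), sep = "_"))
  root <- union_find_components(length(surf), cbind(ka, kb)[dedup, , drop = FALSE])
  comp <- split(surf, root)

  aggs <- lapply(comp, function(members) {
    sel <- mol_a %in% members
    .build_aggregate(frame, sort(members),
                     edges = cbind(bead_a[sel], bead_b[sel]),
                     unwrap = unwrap)
  })
  aggs[order(-vapply(aggs, `[[`, integer(1), "n"))]
}

# assemble one aggregate, optionally unwrapping via its contact edges
.build_aggregate <- function(frame, members, edges, unwrap) {
  bead_sel <- which(frame$mol_id %in% members)
  coords <- frame$coords[bead_sel, , drop = FALSE]
  mol_local <- match(frame$mol_id[bead_sel], members)
  box <- as.numeric(frame$box)
  percolating <- FALSE

  if (unwrap) {
    # make each molecule whole relative to its first bead (beads are grouped
    # and ordered by molecule, so the first row per molecule is a reference)
    first_row <- match(seq_along(members), mol_local)
    ref <- coords[first_row[mol_local], , drop = FALSE]
    coords <- ref + minimum_image_displacement(ref, coords, box)
    if (length(members) > 1 && nrow(edges)) {
      # molecule-level contact graph (one representative bead pair per
      # molecule pair), then BFS assigning integer lattice shifts; a
      # conflicting revisit means the cluster connects to its own periodic
      # image (percolation)
      row_of_bead <- integer(nrow(frame$coords))
      row_of_bead[bead_sel] <- seq_along(bead_sel)
      ea <- row_of_bead[edges[, 1]]
      eb <- row_of_bead[edges[, 2]]
      ma <- mol_local[ea]; mb <- mol_local[eb]
      keep <- ma != mb
      key <- paste(pmin(ma, mb)[keep], pmax(ma, mb)[keep], sep = "_")
      keep2 <- which(keep)[!duplicated(key)]
      ea <- ea[keep2]; eb <- eb[keep2]
      ma <- ma[keep2]; mb <- mb[keep2]
      ne <- length(ma)
      # per-molecule adjacency (edge indices, both directions)
      adj_edges <- split(c(seq_len(ne), seq_len(ne)), c(ma, mb))
      nm <- length(members)
      shift <- matrix(NA_real_, nm, 3)
      shift[1, ] <- 0
      queue <- integer(nm)
      queue[1] <- 1L
      head_i <- 1L; tail_i <- 1L
      while (head_i <= tail_i) {
        m <- queue[head_i]; head_i <- head_i + 1L
        for (e in adj_edges[[as.character(m)]]) {
          if (ma[e] == m) {
            other <- mb[e]; pa <- coords[ea[e], ]; pb <- coords[eb[e], ]
          } else {
            other <- ma[e]; pa <- coords[eb[e], ]; pb <- coords[ea[e], ]
          }
          dmin <- minimum_image_displacement(pa, pb, box)
          s_other <- shift[m, ] + round((pa + dmin - pb) / box)
          if (all(is.na(shift[other, ]))) {
            shift[other, ] <- s_other
            tail_i <- tail_i + 1L
            queue[tail_i] <- other
          } else if (any(abs(shift[other, ] - s_other) > 0.5)) {
            percolating <- TRUE
          }
        }
      }
      if (!percolating && !anyNA(shift)) {
        coords <- coords + shift[mol_local, , drop = FALSE] *
          matrix(box, nrow(coords), 3, byrow = TRUE)
      }
    }
  }

  structure(
    list(members = members, n = length(members), time = frame$time,
         box = frame$box, coords = coords, bead_mol = mol_local,
         bead_role = frame$bead_role[bead_sel],
         bead_mass = frame$bead_mass[bead_sel],
         percolating = percolating),
    class = "cg_aggregate"
  )
}

#' @export
print.cg_aggregate <- function(x, ...) {
  cat(sprintf("<aggregate N=%d t=%.3f ns%s>\n", x$n, x$time,
              if (x$percolating) " (percolating)" else ""))
  invisible(x)
}

#' Unwrap an aggregate across the periodic boundary
#'
#' Shifts member molecules by lattice vectors so that every tail-bead contact
#' edge uses its minimum image; sets `percolating = TRUE` (leaving coordinates
#' wrapped) when no consistent unwrapping exists because the cluster connects
#' to its own periodic image.
#'
#' @param aggregate A `"cg_aggregate"` (possibly built with `unwrap = FALSE`).
#' @param frame The frame it was detected in.
#' @param params The [cluster_params()] used for detection.
#' @return The aggregate with unwrapped `coords` and `percolating` set.
#' @export
unwrap_aggregate <- function(aggregate, frame, params = cluster_params()) {
  r_cut <- params$r_cut
  if (is.null(r_cut)) r_cut <- compute_rcut(smallest_tail_sigma(frame))
  bead_sel <- which(frame$mol_id %in% aggregate$members)
  tails <- bead_sel[frame$bead_role[bead_sel] == "tail"]
  pairs <- contact_pairs(frame$coords[tails, , drop = FALSE], frame$box, r_cut)
  .build_aggregate(frame, aggregate$members,
                   edges = cbind(tails[pairs[, 1]], tails[pairs[, 2]]),
                   unwrap = TRUE)
}

#' Normalized aggregation number
#'
#' Fraction of all surfactants in the frame that belong to the aggregate;
#' summed over the full partition (monomers included) it is 1.
#'
#' @param aggregate A `"cg_aggregate"`.
#' @param frame The frame it was detected in.
#' @return A fraction in (0, 1].
#' @export
normalized_aggregation_number <- function(aggregate, frame) {
  total <- length(surfactant_molecules(frame))
  if (total < 1) stop("frame has no surfactants", call. = FALSE)
  aggregate$n / total
}

#' Tabulate aggregates of one frame
#'
#' @param aggregates List of aggregates from [find_aggregates()].
#' @param frame The source frame.
#' @return data.frame: `time`, `aggregate_id`, `n`, `normalized_n`,
#'   `percolating`.
#' @export
aggregate_table <- function(aggregates, frame) {
  total <- length(surfactant_molecules(frame))
  data.frame(
    time = vapply(aggregates, `[[`, numeric(1), "time"),
    aggregate_id = seq_along(aggregates),
    n = vapply(aggregates, `[[`, integer(1), "n"),
    normalized_n = vapply(aggregates, `[[`, integer(1), "n") / total,
    percolating = vapply(aggregates, `[[`, logical(1), "percolating")
  )
}
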