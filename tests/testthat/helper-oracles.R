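# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's optimized code paths (cell lists, suffix sums,
# separable kernels) so they can act as references.

# exhaustive minimum-image displacement via the 27 lattice images
oracle_min_image <- function(p, q, box) {
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d <- q - p
  cand <- sweep(shifts %*% diag(box), 2, d, `+`)
  cand[which.min(rowSums(cand^2)), ]
}

# all-pairs single-linkage partition over tail beads (double loop + naive
# component growth), returning a per-molecule component label
oracle_partition <- function(tails, mol_of_tail, n_mol, box, r_cut) {
  lab <- seq_len(n_mol)
  nt <- nrow(tails)
  repeat {
    changed <- FALSE
    for (i in seq_len(nt - 1)) {
      for (j in (i + 1):nt) {
        d <- tails[j, ] - tails[i, ]
        d <- d - box * round(d / box)
        if (sqrt(sum(d^2)) <= r_cut) {
          a <- lab[mol_of_tail[i]]; b <- lab[mol_of_tail[j]]
          if (a != b) {
            lab[lab == max(a, b)] <- min(a, b)
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# canonical form of a partition (sorted list of sorted member sets)
canonical_partition <- function(labels) {
  unname(lapply(split(seq_along(labels), labels), sort))[order(
    vapply(split(seq_along(labels), labels), min, integer(1)))]
}

# direct two-pass evaluation of the marginal-standard-error curve
oracle_mse_curve <- function(y, k_max) {
  n <- length(y)
  vapply(0:k_max, function(k) {
    seg <- y[(k + 1):n]
    sum((seg - mean(seg))^2) / (n - k)^2
  }, numeric(1))
}

# untruncated double-loop Gaussian kernel sum at the grid nodes of a field,
# summed over the 27 periodic images of every point
oracle_density <- function(points, field, h) {
  nd <- dim(field$values)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% diag(field$box)
  out <- array(0, nd)
  for (i in 1:nd[1]) for (j in 1:nd[2]) for (k in 1:nd[3]) {
    node <- c((i - 1) * field$spacing[1], (j - 1) * field$spacing[2],
              (k - 1) * field$spacing[3])
    acc <- 0
    for (s in seq_len(nrow(shifts))) {
      d <- sweep(points, 2, node - shifts[s, ])
      acc <- acc + sum(exp(-rowSums(d^2) / (2 * h^2)))
    }
    out[i, j, k] <- acc
  }
  out
}

# small two-molecule frame with tail beads at a controlled separation
two_molecule_frame <- function(separation, box = cg_box(100, 100, 100)) {
  topo <- cg_topology("M2", list(bead_spec("H1", "S", "head"),
                                 bead_spec("T1", "R", "tail")))
  coords <- rbind(
    c(40, 50, 50), c(42, 50, 50),                  # mol 1: head, tail
    c(40, 60, 50), c(42 + separation, 50, 50))     # mol 2: head, tail
  cg_frame(coords, box, c(1, 1, 2, 2), c("M2", "M2"),
           list(M2 = topo), time = 0)
}

# random multi-molecule frame of 1-tail-bead surfactants for oracle checks
random_tail_frame <- function(n_mol, box_len, seed) {
  topo <- cg_topology("RND", list(bead_spec("H1", "S", "head"),
                                  bead_spec("T1", "R", "tail")))
  withr::with_seed(seed, {
    heads <- matrix(runif(3 * n_mol, 0, box_len), ncol = 3)
    tails <- heads + matrix(rnorm(3 * n_mol, 0, 2), ncol = 3)
    coords <- matrix(0, 2 * n_mol, 3)
    coords[seq(1, 2 * n_mol, 2), ] <- heads
    coords[seq(2, 2 * n_mol, 2), ] <- tails
    cg_frame(coords, cg_box(rep(box_len, 3)), rep(seq_len(n_mol), each = 2),
             rep("RND", n_mol), list(RND = topo))
  })
}

# axis-aligned unit cube as a closed outward-oriented triangle mesh
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))  # binary corner order
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = 1 (normal +z)
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6)    # x = 1
  )
  surface_mesh(v, f)
}
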