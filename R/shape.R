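#' Radius of gyration of an aggregate
#'
#' `R_g = sqrt( sum_i m_i |r_i|^2 / sum_i m_i )` where `r_i` is the
#' displacement of point `i` from the mass-weighted center and `m_i` its mass.
#' For aggregates each point is one surfactant (its center of mass), per
#' [surfactant_points()].
#'
#' @param positions Numeric n x 3 matrix of unwrapped coordinates (Angstrom).
#' @param masses Positive masses (amu); recycled if scalar.
#' @return Radius of gyration in Angstrom.
#' @export
#' @examples
#' radius_of_gyration(rbind(c(-2, 0, 0), c(2, 0, 0)), c(1, 1))  # 2
radius_of_gyration <- function(positions, masses = 1) {
  positions <- as.matrix(positions)
  masses <- rep_len(as.numeric(masses), nrow(positions))
  if (any(masses <= 0)) stop("masses must be positive", call. = FALSE)
  com <- colSums(positions * masses) / sum(masses)
  r2 <- rowSums(sweep(positions, 2, com)^2)
  sqrt(sum(masses * r2) / sum(masses))
}

#' Principal moments of inertia
#'
#' Eigenvalues of the inertia tensor `I = sum_i m_i (|r_i|^2 Id - r_i r_i^T)`
#' about the center of mass, in ascending order, plus the total mass. A
#' rank-deficient point configuration (collinear or coincident points) yields
#' a degeneracy warning but the moments are still returned.
#'
#' @inheritParams radius_of_gyration
#' @return List with `moments` (ascending, amu Angstrom^2), `total_mass`
#'   (amu) and `axes` (3 x 3 matrix of corresponding eigenvectors, columns).
#' @export
inertia_principal_moments <- function(positions, masses = 1) {
  positions <- as.matrix(positions)
  masses <- rep_len(as.numeric(masses), nrow(positions))
  com <- colSums(positions * masses) / sum(masses)
  r <- sweep(positions, 2, com)
  r2 <- rowSums(r^2)
  I <- diag(sum(masses * r2), 3) - crossprod(r * sqrt(masses))
  eig <- eigen((I + t(I)) / 2, symmetric = TRUE)
  moments <- rev(eig$values)
  if (moments[1] <= max(moments[3], 1) * 1e-12) {
    warning("degenerate point configuration: inertia tensor is rank-deficient")
  }
  list(moments = moments, total_mass = sum(masses), axes = eig$vectors[, 3:1])
}

#' Ellipsoid semiaxes from principal moments of inertia
#'
#' For a uniform solid ellipsoid with semiaxes `a >= b >= c` the ascending
#' moments are `A = M/5 (b^2 + c^2)`, `B = M/5 (a^2 + c^2)`,
#' `C = M/5 (a^2 + b^2)`; inverting gives
#' `a^2 = 5 (B + C - A) / (2 M)` and cyclic permutations.
#'
#' @param A,B,C Principal moments in ascending order (amu Angstrom^2).
#' @param M Total mass (amu).
#' @return Numeric vector `c(a, b, c)` with `a >= b >= c`, Angstrom.
#' @export
principal_semiaxes <- function(A, B, C, M) {
  if (M <= 0) stop("total mass must be positive", call. = FALSE)
  if (!(A <= B && B <= C)) stop("moments must be in ascending order A <= B <= C", call. = FALSE)
  a2 <- 5 * (B + C - A) / (2 * M)
  b2 <- 5 * (A + C - B) / (2 * M)
  c2 <- 5 * (A + B - C) / (2 * M)
  if (min(a2, b2, c2) <= 0) {
    stop("moments are not consistent with an ellipsoid (non-positive radicand)",
         call. = FALSE)
  }
  sort(sqrt(c(a2, b2, c2)), decreasing = TRUE)
}

#' Coordinate-pair eccentricities
#'
#' For ordered semiaxes `a >= b >= c`, the pair
#' `e_ab = sqrt(1 - b^2/a^2)` and `e_ac = sqrt(1 - c^2/a^2)` characterizes the
#' ellipsoid shape without losing axis-ratio information: spheres sit near
#' (0, 0), prolate ellipsoids on the diagonal, oblate ones on the e_ac axis,
#' and triaxial ones in between.
#'
#' @param a,b,c Semiaxes with `a >= b >= c > 0` (Angstrom). A length-3 vector
#'   may be given as `a`.
#' @return Named numeric vector `c(e_ab =, e_ac =)`, both in [0, 1).
#' @export
#' @examples
#' coordinate_pair_eccentricities(2, 1, 1)  # prolate: both ~0.866
coordinate_pair_eccentricities <- function(a, b = NULL, c = NULL) {
  if (is.null(b) && length(a) == 3) {
    c <- a[3]; b <- a[2]; a <- a[1]
  }
  if (!(a >= b && b >= c && c > 0)) {
    stop("semiaxes must satisfy a >= b >= c > 0", call. = FALSE)
  }
  c(e_ab = sqrt(1 - (b / a)^2), e_ac = sqrt(1 - (c / a)^2))
}

#' Classify an ellipsoid from its coordinate-pair eccentricities
#'
#' Thresholded version of the graphical shape map: spherical when both
#' eccentricities are small, prolate when they are similar, oblate when
#' `e_ab` is small but `e_ac` is not, triaxial otherwise.
#'
#' @param e_ab,e_ac Coordinate-pair eccentricities, `0 <= e_ab <= e_ac`.
#' @param sphere_tol Eccentricities below this count as "close to zero".
#' @param split_tol Maximum `e_ac - e_ab` gap still counted as prolate.
#' @return One of `"spherical"`, `"prolate"`, `"oblate"`, `"triaxial"`.
#' @export
classify_ellipsoid <- function(e_ab, e_ac, sphere_tol = 0.15, split_tol = 0.10) {
  if (e_ab > e_ac + 1e-12 || e_ab < 0) {
    stop("expected 0 <= e_ab <= e_ac", call. = FALSE)
  }
  if (e_ac < sphere_tol) return("spherical")
  if (e_ac - e_ab < split_tol) return("prolate")
  if (e_ab < sphere_tol) return("oblate")
  "triaxial"
}

#' Per-surfactant point representation of an aggregate
#'
#' Each surfactant is reduced to one point at the mass-weighted mean of its
#' beads, with mass equal to the sum of its bead masses. Shape metrics treat
#' the aggregate as this point set; set `resolution = "bead"` to use raw bead
#' coordinates and masses instead.
#'
#' @param aggregate A `"cg_aggregate"` (unwrapped).
#' @param resolution `"surfactant"` (default) or `"bead"`.
#' @return List with `positions` (n x 3) and `masses`.
#' @export
surfactant_points <- function(aggregate, resolution = c("surfactant", "bead")) {
  resolution <- match.arg(resolution)
  if (resolution == "bead") {
    return(list(positions = aggregate$coords, masses = aggregate$bead_mass))
  }
  mw <- aggregate$coords * aggregate$bead_mass
  msum <- rowsum(mw, aggregate$bead_mol)
  mtot <- rowsum(aggregate$bead_mass, aggregate$bead_mol)[, 1]
  list(positions = msum / mtot, masses = mtot)
}

#' Full shape descriptors for one aggregate
#'
#' Radius of gyration, ellipsoid semiaxes from the principal moments of
#' inertia, coordinate-pair eccentricities and the shape class. Percolating
#' aggregates are refused: their center of mass and inertia are undefined
#' under periodic wrapping.
#'
#' @param aggregate A `"cg_aggregate"` (unwrapped, non-percolating).
#' @param sphere_tol,split_tol Classification tolerances, see
#'   [classify_ellipsoid()].
#' @param resolution Point resolution, see [surfactant_points()].
#' @return List: `r_g`, `semiaxes` (a >= b >= c), `e_ab`, `e_ac`, `class`,
#'   `n`.
#' @export
shape_descriptors <- function(aggregate, sphere_tol = 0.15, split_tol = 0.10,
                              resolution = "surfactant") {
  if (isTRUE(aggregate$percolating)) {
    stop("percolation error: shape descriptors are undefined for a percolating aggregate",
         call. = FALSE)
  }
  pts <- surfactant_points(aggregate, resolution)
  rg <- radius_of_gyration(pts$positions, pts$masses)
  if (nrow(pts$positions) < 3) {
    return(list(r_g = rg, semiaxes = c(NA, NA, NA), e_ab = NA_real_,
                e_ac = NA_real_, class = NA_character_, n = aggregate$n))
  }
  mom <- suppressWarnings(inertia_principal_moments(pts$positions, pts$masses))
  ax <- tryCatch(
    principal_semiaxes(mom$moments[1], mom$moments[2], mom$moments[3], mom$total_mass),
    error = function(e) c(NA_real_, NA_real_, NA_real_))
  if (anyNA(ax)) {
    return(list(r_g = rg, semiaxes = ax, e_ab = NA_real_, e_ac = NA_real_,
                class = NA_character_, n = aggregate$n))
  }
  e <- coordinate_pair_eccentricities(ax)
  list(r_g = rg, semiaxes = ax, e_ab = unname(e["e_ab"]), e_ac = unname(e["e_ac"]),
       class = classify_ellipsoid(e["e_ab"], e["e_ac"], sphere_tol, split_tol),
       n = aggregate$n)
}

#' Radius of gyration inferred from small-angle scattering assumptions
#'
#' For an oblate ellipsoid with equal major semiaxes `a = b = eps * c` the
#' radius of gyration is `R_g = (c / sqrt(5)) * sqrt(1 + 2 eps^2)`; used to
#' convert an experimentally determined axis ratio and minor semiaxis into a
#' comparable `R_g`.
#'
#' @param c Minor semiaxis in Angstrom (e.g. the length of a fully stretched
#'   alkyl tail).
#' @param epsilon Ratio of major to minor semiaxes, `>= 1`.
#' @return Radius of gyration, Angstrom.
#' @export
#' @examples
#' experimental_rg(12.57, 1.22)  # ~11.21
experimental_rg <- function(c, epsilon) {
  if (c <= 0) stop("semiaxis c must be positive", call. = FALSE)
  if (epsilon < 1) stop("epsilon is the major:minor axis ratio and must be >= 1", call. = FALSE)
  (c / sqrt(5)) * sqrt(1 + 2 * epsilon^2)
}
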