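#' Willard-Chandler surface parameters
#'
#' @param bandwidth Gaussian kernel standard deviation h, Angstrom. Too large
#'   smooths away surface geometry; too small opens voids where the interior
#'   density fluctuates.
#' @param spacing Requested grid spacing, Angstrom; the effective spacing is
#'   the nearest value that divides each box edge exactly so the grid is
#'   periodic.
#' @param iso_fraction The isosurface is extracted at
#'   `iso_fraction * rho_max`, with `rho_max` the field maximum for the
#'   aggregate.
#' @param truncation Kernel truncation radius in multiples of the bandwidth.
#' @param max_cells Guard on the total grid size.
#' @return A list with class `"wc_params"`.
#' @export
wc_params <- function(bandwidth = 4.0, spacing = 2.0, iso_fraction = 1 / 3,
                      truncation = 4, max_cells = 2e7) {
  stopifnot(bandwidth > 0, spacing > 0, iso_fraction > 0, iso_fraction < 1,
            truncation > 0)
  structure(list(bandwidth = bandwidth, spacing = spacing,
                 iso_fraction = iso_fraction, truncation = truncation,
                 max_cells = max_cells),
            class = "wc_params")
}

#' Gaussian kernel density of bead positions on a periodic grid
#'
#' Evaluates the unnormalized sum of isotropic Gaussians
#' `exp(-|d|^2 / (2 h^2))` on a regular grid over the central box. In
#' `"supercell"` mode every point contributes through all 27 replicas of a
#' 3 x 3 x 3 supercell; in `"minimum_image"` mode through its nearest periodic
#' image only. The two modes coincide whenever the box is larger than twice
#' the kernel truncation radius. The density is left unnormalized because the
#' isosurface level is defined relative to the field maximum, so any common
#' factor cancels.
#'
#' @param points Numeric n x 3 matrix of bead coordinates, Angstrom (wrapped
#'   into the box internally).
#' @param box A [cg_box()] or numeric 3-vector.
#' @param params A [wc_params()].
#' @param mode `"supercell"` (default) or `"minimum_image"`.
#' @return A list with class `"density_field"`: `values` (3-d array),
#'   `box`, `spacing` (effective, per axis), `origin` (node 0 coordinate,
#'   always 0), `rho_max`.
#' @export
gaussian_density_grid <- function(points, box, params = wc_params(),
                                  mode = c("supercell", "minimum_image")) {
  mode <- match.arg(mode)
  points <- as.matrix(points)
  if (!nrow(points)) stop("need at least one point", call. = FALSE)
  box <- as.numeric(box)
  h <- params$bandwidth
  trunc_r <- params$truncation * h

  n_nodes <- pmax(4L, as.integer(round(box / params$spacing)))
  if (prod(n_nodes) > params$max_cells) {
    stop(sprintf(
      "resource error: grid of %d x %d x %d nodes exceeds max_cells; use a coarser spacing",
      n_nodes[1], n_nodes[2], n_nodes[3]), call. = FALSE)
  }
  eff <- box / n_nodes
  vals <- array(0, dim = n_nodes)
  w <- wrap_coords(points, box)
  half_w <- as.integer(ceiling(trunc_r / eff))  # window half-width in nodes

  add_point <- function(p, wrap_window) {
    # node window around p, per axis
    ctr <- as.integer(round(p / eff))
    contrib <- vector("list", 3)
    idx <- vector("list", 3)
    for (k in 1:3) {
      rng <- (ctr[k] - half_w[k]):(ctr[k] + half_w[k])
      xk <- rng * eff[k]
      dk <- xk - p[k]
      if (wrap_window) {
        keep <- rep(TRUE, length(rng))
        rng <- ((rng %% n_nodes[k]) + n_nodes[k]) %% n_nodes[k]
        # window wider than the box would double count nodes; collapse
        if (length(rng) >= n_nodes[k]) {
          rng <- 0:(n_nodes[k] - 1)
          xk <- rng * eff[k]
          dk <- xk - p[k]
          dk <- dk - box[k] * floor(dk / box[k] + 0.5)
        }
      } else {
        keep <- rng >= 0 & rng < n_nodes[k]
        rng <- rng[keep]
        dk <- dk[keep]
      }
      if (!length(rng)) return(invisible(NULL))
      idx[[k]] <- rng + 1L
      contrib[[k]] <- dk
    }
    # separable kernel: exp over the three axis profiles, then outer products
    gx <- exp(-contrib[[1]]^2 / (2 * h^2))
    gy <- exp(-contrib[[2]]^2 / (2 * h^2))
    gz <- exp(-contrib[[3]]^2 / (2 * h^2))
    g <- outer(outer(gx, gy), gz)
    d2 <- outer(outer(contrib[[1]]^2, contrib[[2]]^2, `+`), contrib[[3]]^2, `+`)
    g[d2 > trunc_r^2] <- 0
    vals[idx[[1]], idx[[2]], idx[[3]]] <<-
      vals[idx[[1]], idx[[2]], idx[[3]], drop = FALSE] + g
    invisible(NULL)
  }

  if (mode == "minimum_image") {
    # nearest image per node: wrapped window with minimum-image distances
    for (i in seq_len(nrow(w))) add_point(w[i, ], wrap_window = TRUE)
  } else {
    # all 27 replicas, each clipped to the central grid without wrapping
    shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
    for (i in seq_len(nrow(w))) {
      for (s in seq_len(nrow(shifts))) {
        p <- w[i, ] + shifts[s, ] * box
        # skip replicas that cannot reach the central box
        if (any(p < -trunc_r - eff) || any(p > box + trunc_r + eff)) next
        add_point(p, wrap_window = FALSE)
      }
    }
  }

  structure(
    list(values = vals, box = box, spacing = eff, origin = c(0, 0, 0),
         rho_max = max(vals)),
    class = "density_field"
  )
}

#' @export
print.density_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_field %d x %d x %d, rho_max = %.4g>\n",
              d[1], d[2], d[3], x$rho_max))
  invisible(x)
}
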