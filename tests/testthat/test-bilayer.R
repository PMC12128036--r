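# two flat periodic sheets as a stitched synthetic mesh fixture: each sheet is
# a triangulated grid over the periodic box at a fixed height
flat_sheet_mesh <- function(z_levels, box = c(100, 100, 60), nx = 10) {
  verts <- list()
  faces <- list()
  shifts <- list()
  v0 <- 0L
  dx <- box[1] / nx
  dy <- box[2] / nx
  for (z in z_levels) {
    g <- as.matrix(expand.grid(x = 0:(nx - 1), y = 0:(nx - 1)))
    verts[[length(verts) + 1]] <- cbind(g[, 1] * dx, g[, 2] * dy, z)
    vid <- function(i, j) v0 + (i %% nx) + nx * (j %% nx) + 1L
    fc <- list()
    sh <- list()
    for (i in 0:(nx - 1)) for (j in 0:(nx - 1)) {
      a <- vid(i, j); b <- vid(i + 1, j); cc <- vid(i + 1, j + 1); d <- vid(i, j + 1)
      fc[[length(fc) + 1]] <- rbind(c(a, b, cc), c(a, cc, d))
      # lattice shifts for the wrapped vertices of the two triangles
      sx_b <- if (i + 1 == nx) 1L else 0L
      sy_c <- if (j + 1 == nx) 1L else 0L
      sh[[length(sh) + 1]] <- rbind(
        c(0, 0, 0, sx_b, 0, 0, sx_b, sy_c, 0),
        c(0, 0, 0, sx_b, sy_c, 0, 0, sy_c, 0))
    }
    faces[[length(faces) + 1]] <- do.call(rbind, fc)
    shifts[[length(shifts) + 1]] <- do.call(rbind, sh)
    v0 <- v0 + nx * nx
  }
  surface_mesh(do.call(rbind, verts), do.call(rbind, faces), box = box,
               face_shift = matrix(as.integer(do.call(rbind, shifts)), ncol = 9))
}

test_that("leaflets split by connectivity and order by mean z", {
  m <- flat_sheet_mesh(c(10, 30))
  expect_equal(m$n_components, 2L)
  leaf <- split_bilayer_leaflets(m)
  expect_equal(mean(leaf$upper$vertices[, 3]), 30)
  expect_equal(mean(leaf$lower$vertices[, 3]), 10)
  expect_equal(leaf$n_extra_components, 0L)
})

test_that("a single closed surface is not a bilayer", {
  expect_error(split_bilayer_leaflets(icosphere(10, 2)), "not-a-bilayer")
})

test_that("extra components beyond two leaflets raise a warning", {
  sheets <- flat_sheet_mesh(c(10, 30))
  blob <- icosphere(4, 1, center = c(50, 50, 50))
  m <- surface_mesh(rbind(sheets$vertices, blob$vertices),
                    rbind(sheets$faces, blob$faces + nrow(sheets$vertices)),
                    box = sheets$box,
                    face_shift = rbind(sheets$face_shift,
                                       matrix(0L, nrow(blob$faces), 9)))
  expect_equal(m$n_components, 3L)
  expect_warning(leaf <- split_bilayer_leaflets(m), "extra component")
  expect_equal(leaf$n_extra_components, 1L)
  expect_equal(sort(c(mean(leaf$upper$vertices[, 3]), mean(leaf$lower$vertices[, 3]))),
               c(10, 30))
})

test_that("thickness of parallel flat sheets is their separation", {
  m <- flat_sheet_mesh(c(10, 30))
  leaf <- split_bilayer_leaflets(m)
  th <- bilayer_thickness(leaf$upper, leaf$lower)
  expect_true(all(abs(th$distances - 20) <= 1e-9))
  expect_equal(th$mean, 20)
  # pooling is symmetric under leaflet swap
  th2 <- bilayer_thickness(leaf$lower, leaf$upper)
  expect_equal(sort(th2$distances), sort(th$distances))
})

test_that("matched sinusoidal corrugation preserves mean thickness", {
  m <- flat_sheet_mesh(c(10, 30), nx = 20)
  corr <- m
  corr$vertices[, 3] <- corr$vertices[, 3] + 4 * sin(2 * pi * corr$vertices[, 1] / 100)
  corr <- surface_mesh(corr$vertices, corr$faces, box = corr$box,
                       face_shift = corr$face_shift)
  leaf <- split_bilayer_leaflets(corr)
  th <- bilayer_thickness(leaf$upper, leaf$lower)
  expect_equal(th$mean, 20, tolerance = 0.02)
})

test_that("area per headgroup is combined area over surfactants", {
  m <- flat_sheet_mesh(c(10, 30))
  leaf <- split_bilayer_leaflets(m)
  expect_equal(area_per_headgroup(leaf$upper, leaf$lower, 400), 50)
  expect_equal(area_per_headgroup(leaf$upper, leaf$lower, 800), 25)
  # corrugation increases area at equal N
  corr <- flat_sheet_mesh(c(10, 30), nx = 20)
  corr$vertices[, 3] <- corr$vertices[, 3] + 4 * sin(2 * pi * corr$vertices[, 1] / 100)
  corr <- surface_mesh(corr$vertices, corr$faces, box = corr$box,
                       face_shift = corr$face_shift)
  lc <- split_bilayer_leaflets(corr)
  expect_gt(area_per_headgroup(lc$upper, lc$lower, 400), 50)
})

test_that("slab isocontour offset matches a brute-force profile scan", {
  prm <- wc_params()
  delta <- wc_slab_offset(20, prm)
  # brute force: evaluate the erf slab profile on a fine grid
  z <- seq(10, 30, by = 1e-4)
  prof <- pnorm((10 - z) / prm$bandwidth) - pnorm((-10 - z) / prm$bandwidth)
  rho_max <- pnorm(10 / prm$bandwidth) - pnorm(-10 / prm$bandwidth)
  z_cross <- z[which.min(abs(prof - rho_max / 3))]
  expect_equal(10 + delta, z_cross, tolerance = 1e-3)
  expect_gt(delta, 0)
})
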