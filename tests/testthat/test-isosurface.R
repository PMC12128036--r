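test_that("single Gaussian isosurface is a sphere of radius h sqrt(2 ln 3)", {
  box <- cg_box(40, 40, 40)
  ctr <- c(20, 20, 20)
  f <- gaussian_density_grid(matrix(ctr, 1), box, wc_params())
  mesh <- willard_chandler_surface(f, wc_params())
  expect_equal(mesh$n_components, 1L)
  r <- sqrt(rowSums(sweep(mesh$vertices, 2, ctr)^2))
  r_want <- 4.0 * sqrt(2 * log(3))
  expect_true(all(abs(r - r_want) <= 2.0))  # within one grid spacing
  expect_true(all(mesh$edge_counts == 2))   # closed 2-manifold
})

test_that("wrapped and centered blobs give identical area and volume", {
  withr::with_seed(1, {
    pts <- matrix(rnorm(150, 0, 4), ncol = 3) + 20
  })
  box <- cg_box(40, 40, 40)
  a1 <- mesh_area_volume(willard_chandler_surface(
    gaussian_density_grid(pts, box, wc_params()), wc_params()))
  # grid-commensurate translation wrapping the blob across the corner
  pts2 <- wrap_coords(pts + 20, box)
  a2 <- mesh_area_volume(willard_chandler_surface(
    gaussian_density_grid(pts2, box, wc_params()), wc_params()))
  expect_equal(a2$area, a1$area, tolerance = 1e-9)
  expect_equal(a2$volume, a1$volume, tolerance = 1e-9)
  # arbitrary (grid-incommensurate) translation: equal within discretization
  pts3 <- wrap_coords(sweep(pts, 2, c(17.3, 21.9, 15.1), `+`), box)
  a3 <- mesh_area_volume(willard_chandler_surface(
    gaussian_density_grid(pts3, box, wc_params()), wc_params()))
  expect_equal(a3$volume, a1$volume, tolerance = 0.08)
  expect_equal(a3$area, a1$area, tolerance = 0.08)
})

test_that("unit cube mesh has area 6 and volume 1", {
  m <- unit_cube_mesh()
  av <- mesh_area_volume(m)
  expect_equal(av$area, 6, tolerance = 1e-12)
  expect_equal(av$volume, 1, tolerance = 1e-12)
})

test_that("icosphere area and volume converge to the closed form", {
  m <- icosphere(10, depth = 4)
  av <- mesh_area_volume(m)
  expect_equal(av$area, 4 * pi * 100, tolerance = 0.02)
  expect_equal(av$volume, 4 / 3 * pi * 1000, tolerance = 0.02)
})

test_that("nested reversed sphere subtracts its cavity", {
  outer <- icosphere(10, depth = 3)
  inner <- icosphere(5, depth = 3)
  # reverse the inner sphere so its normals point into the cavity
  inner_f <- inner$faces[, c(1, 3, 2)]
  m <- surface_mesh(rbind(outer$vertices, inner$vertices),
                    rbind(outer$faces, inner_f + nrow(outer$vertices)))
  av <- mesh_area_volume(m)
  expect_equal(m$n_components, 2L)
  expect_equal(av$volume, 4 / 3 * pi * (10^3 - 5^3), tolerance = 0.02)
  expect_equal(av$outer_volume, 4 / 3 * pi * 10^3, tolerance = 0.02)
})

test_that("open meshes are rejected with a hole count", {
  m <- unit_cube_mesh()
  open_mesh <- surface_mesh(m$vertices, m$faces[-1, ])
  expect_error(mesh_area_volume(open_mesh), "open-mesh")
})

test_that("per-surfactant metrics are simple ratios with guards", {
  pm <- per_surfactant_metrics(200, 50, 2)
  expect_equal(pm$area_per_surfactant, 100)
  expect_equal(pm$volume_per_surfactant, 25)
  expect_equal(pm$sa_to_volume, 4)
  pm2 <- per_surfactant_metrics(200, 50, 4)
  expect_equal(pm2$area_per_surfactant, 50)
  # sphere closed form: SA:V = 3/r
  m <- icosphere(10, depth = 3)
  av <- mesh_area_volume(m)
  expect_equal(per_surfactant_metrics(av$area, av$volume, 1)$sa_to_volume,
               0.3, tolerance = 0.02)
  expect_error(per_surfactant_metrics(10, 0, 1), "degenerate")
})

test_that("grid refinement changes sphere area and volume by < 5%", {
  box <- cg_box(40, 40, 40)
  pts <- matrix(c(20, 20, 20), 1)
  coarse <- mesh_area_volume(willard_chandler_surface(
    gaussian_density_grid(pts, box, wc_params(spacing = 2.0)),
    wc_params(spacing = 2.0)))
  fine <- mesh_area_volume(willard_chandler_surface(
    gaussian_density_grid(pts, box, wc_params(spacing = 1.0)),
    wc_params(spacing = 1.0)))
  expect_lt(abs(fine$area - coarse$area) / fine$area, 0.05)
  expect_lt(abs(fine$volume - coarse$volume) / fine$volume, 0.05)
})

test_that("mesh exports write valid PLY and OBJ", {
  m <- icosphere(5, depth = 1)
  ply <- withr::local_tempfile(fileext = ".ply")
  obj <- withr::local_tempfile(fileext = ".obj")
  write_ply(m, ply)
  write_obj(m, obj)
  pl <- readLines(ply)
  expect_equal(pl[1], "ply")
  expect_equal(sum(grepl("^3 ", pl)), nrow(m$faces))
  ol <- readLines(obj)
  expect_equal(sum(grepl("^v ", ol)), nrow(m$vertices))
  expect_equal(sum(grepl("^f ", ol)), nrow(m$faces))
})
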