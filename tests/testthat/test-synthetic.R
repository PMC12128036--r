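test_that("generators are bit-identical for identical spec and seed", {
  a <- suppressWarnings(make_ellipsoid_micelle(30, 25, 20, n = 100, noise = 1.5, seed = 42))
  b <- suppressWarnings(make_ellipsoid_micelle(30, 25, 20, n = 100, noise = 1.5, seed = 42))
  expect_identical(a$frame$coords, b$frame$coords)
  c1 <- suppressWarnings(make_dispersed_system(list(
    list(kind = "ellipsoid_micelle", a = 18, b = 16, c = 14, n = 40),
    list(kind = "monomers", n = 10)), box = cg_box(200, 200, 200),
    seed = 7, noise = 1))
  c2 <- suppressWarnings(make_dispersed_system(list(
    list(kind = "ellipsoid_micelle", a = 18, b = 16, c = 14, n = 40),
    list(kind = "monomers", n = 10)), box = cg_box(200, 200, 200),
    seed = 7, noise = 1))
  expect_identical(c1$frame$coords, c2$frame$coords)
  d <- suppressWarnings(make_ellipsoid_micelle(30, 25, 20, n = 100, noise = 1.5, seed = 43))
  expect_false(identical(a$frame$coords, d$frame$coords))
})

test_that("ellipsoid micelles classify into their ground-truth shape class", {
  cases <- list(
    list(abc = c(30, 30, 30), class = "spherical"),
    list(abc = c(60, 25, 25), class = "prolate"),
    list(abc = c(45, 45, 20), class = "oblate"),
    list(abc = c(50, 35, 18), class = "triaxial"))
  for (cs in cases) {
    g <- make_ellipsoid_micelle(cs$abc[1], cs$abc[2], cs$abc[3],
                                n = 350, noise = 0, seed = 7)
    aggs <- find_aggregates(g$frame)
    expect_equal(aggs[[1]]$n, 350L)
    sd_ <- shape_descriptors(aggs[[1]])
    expect_equal(sd_$class, cs$class)
    expect_lt(abs(sd_$e_ab - g$ground_truth$e_ab), 0.1)
    expect_lt(abs(sd_$e_ac - g$ground_truth$e_ac), 0.1)
  }
})

test_that("vesicle yields two nested surfaces and the expected shell volume", {
  v <- make_vesicle(80, 20, seed = 3)
  aggs <- find_aggregates(v$frame)
  expect_length(aggs, 1)
  expect_equal(normalized_aggregation_number(aggs[[1]], v$frame), 1.0)
  expect_equal(shape_descriptors(aggs[[1]])$class, "spherical")
  s <- aggregate_surface(aggs[[1]])
  expect_equal(s$n_components, 2L)
  # offset-corrected shell closed form (the isosurface of a sharp shell sits
  # delta outside the bead span on each side)
  delta <- wc_slab_offset(20)
  v_want <- 4 / 3 * pi * ((80 + delta)^3 - (60 - delta)^3)
  expect_lt(abs(s$volume - v_want) / v_want, 0.10)
  # lumen-inclusive outer volume is also reported and larger
  expect_gt(s$outer_volume, s$volume)
  expect_lt(abs(s$outer_volume - 4 / 3 * pi * (80 + delta)^3) /
              (4 / 3 * pi * (80 + delta)^3), 0.10)
})

test_that("bicelle is a cohesive non-percolating disc with high e_ac", {
  b <- make_bicelle(60, 20, n = 600, seed = 2, box = cg_box(400, 400, 400))
  aggs <- find_aggregates(b$frame)
  expect_equal(aggs[[1]]$n, 600L)
  expect_false(aggs[[1]]$percolating)
  sd_ <- shape_descriptors(aggs[[1]])
  expect_gt(sd_$e_ac, 0.8)
  expect_true(sd_$class %in% c("oblate", "triaxial"))
  s <- aggregate_surface(aggs[[1]])
  expect_gt(s$area, 2 * pi * 60^2)  # two faces plus rim exceed one disc side
})

test_that("lamella percolates and recovers thickness and area per headgroup", {
  l <- make_lamella(cg_box(100, 100, 80), thickness = 20, n = 400, seed = 5)
  gt <- l$ground_truth
  expect_equal(gt$area_per_headgroup, 2 * 100 * 100 / gt$n, tolerance = 1e-12)
  agg <- find_aggregates(l$frame)[[1]]
  expect_true(agg$percolating)
  field <- gaussian_density_grid(l$frame$coords, l$frame$box, wc_params())
  mesh <- willard_chandler_surface(field, wc_params())
  expect_equal(mesh$n_components, 2L)
  expect_true(all(mesh$component_percolating[, 1:2]))
  leaf <- split_bilayer_leaflets(mesh)
  th <- bilayer_thickness(leaf$upper, leaf$lower)
  expect_equal(th$mean, gt$thickness + 2 * wc_slab_offset(gt$thickness),
               tolerance = 2 / th$mean)  # within 2 Angstrom
  aph <- area_per_headgroup(leaf$upper, leaf$lower, gt$n)
  expect_lt(abs(aph - gt$area_per_headgroup), 5)
  # corrugation strictly increases area per headgroup at equal N
  lc <- make_lamella(cg_box(100, 100, 80), thickness = 20, n = 400,
                     corrugation = 5, seed = 5)
  fc <- gaussian_density_grid(lc$frame$coords, lc$frame$box, wc_params())
  mc <- willard_chandler_surface(fc, wc_params())
  lfc <- split_bilayer_leaflets(mc)
  expect_gt(area_per_headgroup(lfc$upper, lfc$lower, gt$n), aph)
})

test_that("dispersed systems recover the ground-truth partition exactly", {
  d <- suppressWarnings(make_dispersed_system(list(
    list(kind = "ellipsoid_micelle", a = 16, b = 14, c = 12, n = 10),
    list(kind = "ellipsoid_micelle", a = 18, b = 16, c = 14, n = 20),
    list(kind = "ellipsoid_micelle", a = 20, b = 18, c = 16, n = 30),
    list(kind = "ellipsoid_micelle", a = 22, b = 20, c = 18, n = 40),
    list(kind = "ellipsoid_micelle", a = 24, b = 22, c = 20, n = 50),
    list(kind = "monomers", n = 20)),
    box = cg_box(300, 300, 300), seed = 11))
  aggs <- suppressWarnings(find_aggregates(d$frame))
  sizes <- sort(unname(vapply(aggs, `[[`, integer(1), "n")), decreasing = TRUE)
  expect_equal(sizes[1:5], c(50L, 40L, 30L, 20L, 10L))
  expect_equal(sum(sizes == 1), 20)
  # the detected partition matches the ground-truth labels exactly
  part <- integer(length(d$ground_truth$labels))
  for (i in seq_along(aggs)) part[aggs[[i]]$members] <- i
  expect_identical(canonical_partition(part),
                   canonical_partition(d$ground_truth$labels))
  # min_aggregation_number filters reporting only: monomers stay in the table
  tab <- aggregate_table(aggs, d$frame)
  expect_equal(sum(tab$n >= 5), 5)
  expect_equal(nrow(tab), length(aggs))
})
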