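test_that("radius of gyration matches closed forms and the double-loop oracle", {
  expect_equal(radius_of_gyration(matrix(c(3, 4, 5), 1), 10), 0)
  expect_equal(radius_of_gyration(rbind(c(-2, 0, 0), c(2, 0, 0)), c(1, 1)), 2)
  withr::with_seed(31, {
    pos <- matrix(rnorm(120, sd = 8), ncol = 3)
    m <- runif(40, 30, 400)
    com <- colSums(pos * m) / sum(m)
    want <- sqrt(sum(m * rowSums(sweep(pos, 2, com)^2)) / sum(m))
    expect_equal(radius_of_gyration(pos, m), want, tolerance = 1e-10)
  })
})

test_that("principal moments match analytic cases and are rotation invariant", {
  sq <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  mom <- suppressWarnings(inertia_principal_moments(sq, 1))
  expect_equal(mom$moments, c(2, 2, 4), tolerance = 1e-12)
  withr::with_seed(7, {
    pos <- matrix(rnorm(90, sd = 5), ncol = 3)
    m <- runif(30, 1, 3)
    base <- inertia_principal_moments(pos, m)$moments
    q <- qr.Q(qr(matrix(rnorm(9), 3)))  # random orthogonal matrix
    rot <- inertia_principal_moments(pos %*% q, m)$moments
    expect_equal(rot, base, tolerance = 1e-8)
  })
  expect_warning(inertia_principal_moments(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 1),
                 "degenerate")
})

test_that("uniform ellipsoid sample recovers moments and semiaxes", {
  withr::with_seed(12, {
    # rejection-sample a filled ellipsoid (30, 20, 10)
    n <- 20000
    pts <- matrix(runif(3 * 3 * n, -1, 1), ncol = 3)
    pts <- pts[rowSums(pts^2) <= 1, ][1:n, ]
    pts <- sweep(pts, 2, c(30, 20, 10), `*`)
    mom <- inertia_principal_moments(pts, 1)
    M <- mom$total_mass
    expect_equal(mom$moments[1], M / 5 * (20^2 + 10^2), tolerance = 0.02)
    expect_equal(mom$moments[2], M / 5 * (30^2 + 10^2), tolerance = 0.02)
    expect_equal(mom$moments[3], M / 5 * (30^2 + 20^2), tolerance = 0.02)
    ax <- principal_semiaxes(mom$moments[1], mom$moments[2], mom$moments[3], M)
    expect_equal(ax, c(30, 20, 10), tolerance = 0.03)
  })
})

test_that("semiaxes invert the forward moment relations exactly", {
  expect_equal(principal_semiaxes(2 / 5 * 7 * 3^2, 2 / 5 * 7 * 3^2, 2 / 5 * 7 * 3^2, 7),
               c(3, 3, 3), tolerance = 1e-12)
  withr::with_seed(3, {
    for (i in 1:20) {
      abc <- sort(runif(3, 1, 50), decreasing = TRUE)
      M <- runif(1, 1, 100)
      A <- M / 5 * (abc[2]^2 + abc[3]^2)
      B <- M / 5 * (abc[1]^2 + abc[3]^2)
      C <- M / 5 * (abc[1]^2 + abc[2]^2)
      expect_equal(principal_semiaxes(A, B, C, M), abc, tolerance = 1e-10)
    }
  })
  expect_error(principal_semiaxes(10, 1, 1, 5), "ascending|ellipsoid")
  expect_error(principal_semiaxes(1, 1, 10, 5), "ellipsoid")
})

test_that("coordinate-pair eccentricities follow the closed form", {
  expect_equal(unname(coordinate_pair_eccentricities(3, 3, 3)), c(0, 0))
  e <- coordinate_pair_eccentricities(2, 1, 1)
  expect_equal(unname(e), c(sqrt(0.75), sqrt(0.75)), tolerance = 1e-12)
  e2 <- coordinate_pair_eccentricities(2, 2, 1)
  expect_equal(unname(e2), c(0, sqrt(0.75)), tolerance = 1e-12)
  expect_error(coordinate_pair_eccentricities(1, 2, 3), "a >= b >= c")
  # ordering invariant: e_ab <= e_ac < 1
  withr::with_seed(14, {
    for (i in 1:50) {
      abc <- sort(runif(3, 0.5, 40), decreasing = TRUE)
      e <- coordinate_pair_eccentricities(abc)
      expect_true(e["e_ab"] <= e["e_ac"] + 1e-12)
      expect_true(all(e >= 0) && all(e < 1))
    }
  })
})

test_that("ellipsoid classification covers the four shape regions", {
  expect_equal(classify_ellipsoid(0.01, 0.02), "spherical")
  expect_equal(classify_ellipsoid(0.80, 0.82), "prolate")
  expect_equal(classify_ellipsoid(0.05, 0.85), "oblate")
  expect_equal(classify_ellipsoid(0.40, 0.90), "triaxial")
  expect_error(classify_ellipsoid(0.5, 0.3), "e_ab <= e_ac")
})

test_that("scattering-derived radius of gyration matches the oblate formula", {
  expect_equal(experimental_rg(12.57, 1.22), 11.21, tolerance = 1e-3)
  expect_equal(experimental_rg(10, 1), 10 * sqrt(3 / 5), tolerance = 1e-12)
  expect_equal(experimental_rg(25.14, 1.22), 2 * experimental_rg(12.57, 1.22),
               tolerance = 1e-12)
  expect_error(experimental_rg(10, 0.8), "epsilon")
})

test_that("shape descriptors refuse percolating aggregates", {
  l <- make_lamella(cg_box(80, 80, 60), 18, n = 260, seed = 3)
  agg <- find_aggregates(l$frame)[[1]]
  expect_true(agg$percolating)
  expect_error(shape_descriptors(agg), "percolat")
})
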