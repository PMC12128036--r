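test_that("GRO coordinates convert nm to Angstrom on read", {
  topo <- cg_topology("AB", list(bead_spec("H1", "S", "head"),
                                 bead_spec("T1", "T", "tail")))
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "two beads",
    "    2",
    "    1AB    H1    1   1.000   1.000   1.000",
    "    1AB    T1    2   1.200   1.000   1.000",
    "   4.00000   4.00000   4.00000"
  ), path)
  fr <- read_gro(path, list(AB = topo))
  expect_equal(fr$coords[1, ], c(10, 10, 10))
  expect_equal(as.numeric(fr$box), c(40, 40, 40))
  expect_equal(fr$species, "AB")
})

test_that("write_gro then read_gro round-trips within format precision", {
  g <- suppressWarnings(make_ellipsoid_micelle(20, 18, 16, n = 30, seed = 4))
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(g$frame, path)
  fr2 <- read_gro(path, g$frame$topology)
  expect_lt(max(abs(fr2$coords - g$frame$coords)), 0.005 + 1e-12)  # 0.001 nm
  expect_equal(as.numeric(fr2$box), as.numeric(g$frame$box), tolerance = 1e-6)
  expect_equal(fr2$mol_id, g$frame$mol_id)
})

test_that("box line formats in nm with five decimals", {
  topo <- cg_topology("AB", list(bead_spec("H1", "S", "head"),
                                 bead_spec("T1", "T", "tail")))
  fr <- cg_frame(rbind(c(1, 1, 1), c(2, 2, 2)), cg_box(380, 380, 380),
                 c(1, 1), "AB", list(AB = topo))
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(fr, path)
  lines <- readLines(path)
  expect_match(lines[length(lines)], "38.00000\\s+38.00000\\s+38.00000")
})

test_that("malformed and truncated GRO files raise parse errors", {
  topo <- list(AB = cg_topology("AB", list(bead_spec("H1", "S", "head"),
                                           bead_spec("T1", "T", "tail"))))
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("truncated", "    4",
               "    1AB    H1    1   1.000   1.000   1.000",
               "    1AB    T1    2   1.200   1.000   1.000"), path)
  expect_error(read_gro(path, topo), "parse error|box")
  writeLines(c("bad line", "    2",
               "    1AB    H1    1   1.000   1.000   1.000",
               "    1AB    T1    2   xxxxx   1.000   1.000",
               "   4.0 4.0 4.0"), path)
  expect_error(read_gro(path, topo), "line 4")
  writeLines(c("triclinic", "    1",
               "    1AB    H1    1   1.000   1.000   1.000",
               "   4.0 4.0 4.0 0.0 0.0 1.2 0.0 0.0 0.0"), path)
  expect_error(read_gro(path, list(AB = cg_topology("AB", list(
    bead_spec("H1", "S", "head"), bead_spec("T1", "T", "tail")),
    surfactant = FALSE))), "triclinic|orthorhombic")
})

test_that("long names are truncated with a warning on GRO write", {
  topo <- cg_topology("LONGNAME", list(bead_spec("HEADBEAD1", "S", "head"),
                                       bead_spec("T1", "T", "tail")))
  fr <- cg_frame(rbind(c(1, 1, 1), c(2, 2, 2)), cg_box(50, 50, 50),
                 c(1, 1), "LONGNAME", list(LONGNAME = topo))
  path <- withr::local_tempfile(fileext = ".gro")
  expect_warning(write_gro(fr, path), "truncat")
})

test_that("trajectory JSON container round-trips frames and topology", {
  frames <- lapply(1:3, function(i) {
    suppressWarnings(make_ellipsoid_micelle(18, 16, 14, n = 20, seed = i, time = 2 * i))$frame
  })
  traj <- cg_trajectory(frames)
  path <- withr::local_tempfile(fileext = ".json")
  write_trajectory_json(traj, path)
  back <- read_trajectory_json(path)
  expect_equal(back$times, traj$times)
  expect_equal(back$frames[[2]]$coords, traj$frames[[2]]$coords)
  expect_equal(back$frames[[1]]$bead_role, traj$frames[[1]]$bead_role)
})

test_that("atomistic-to-CG mapping is the per-bead center of geometry", {
  atoms <- rbind(c(0, 0, 0), c(2, 0, 0), c(5, 5, 5))
  expect_equal(map_atomistic_to_cg(atoms, list(1, 2, 3)), atoms)
  expect_equal(map_atomistic_to_cg(atoms, list(1:2))[1, ], c(1, 0, 0))
  # brute-force mean oracle on a random molecule with overlapping sets
  withr::with_seed(11, {
    at <- matrix(rnorm(150), ncol = 3)
    mapping <- list(sample(50, 7), sample(50, 3), sample(50, 12), sample(50, 1))
    got <- map_atomistic_to_cg(at, mapping)
    want <- t(vapply(mapping, function(idx) {
      s <- c(0, 0, 0)
      for (i in idx) s <- s + at[i, ]
      s / length(idx)
    }, numeric(3)))
    expect_equal(got, want, tolerance = 1e-12)
    # permutation invariance over each bead's atom set
    got2 <- map_atomistic_to_cg(at, lapply(mapping, rev))
    expect_equal(got2, got, tolerance = 1e-12)
  })
  expect_error(map_atomistic_to_cg(atoms, list(integer(0))), "empty")
  expect_error(map_atomistic_to_cg(atoms, list(c(1, 9))), "index")
})

test_that("minimum-image displacement picks the nearest periodic image", {
  box <- cg_box(10, 10, 10)
  expect_equal(minimum_image_displacement(c(1, 1, 1), c(9, 9, 9), box),
               c(-2, -2, -2))
  expect_equal(minimum_image_displacement(c(3, 4, 5), c(3, 4, 5), box),
               c(0, 0, 0))
  withr::with_seed(21, {
    box2 <- c(8, 11, 15)
    for (rep in 1:200) {
      p <- runif(3) * box2   # in-box points: 27 images are exhaustive
      q <- runif(3) * box2
      got <- minimum_image_displacement(p, q, box2)
      want <- oracle_min_image(p, q, box2)
      expect_equal(got, unname(want), tolerance = 1e-9)
      expect_true(all(got >= -box2 / 2 - 1e-9) && all(got < box2 / 2 + 1e-9))
      expect_lte(sqrt(sum(got^2)), sqrt(3) / 2 * max(box2) + 1e-9)
    }
  })
})

test_that("bead defaults come from the size-class table and validate", {
  b <- bead_spec("T1", "R", "tail")
  expect_equal(b$mass, 72)
  expect_equal(b$sigma, 4.70)
  expect_equal(bead_spec("X", "T", "head")$sigma, 3.40)
  expect_error(bead_spec("X", "Q", "head"), "size class")
  expect_error(cg_topology("S", list(bead_spec("H", "S", "head"))), "tail")
  expect_error(cg_box(0, 1, 1), "positive")
})
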