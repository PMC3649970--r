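test_that("PDB parsing keeps one highest-occupancy altloc, drops water and H", {
  f <- tempfile(fileext = ".pdb")
  writeLines(minimal_pdb_text(), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 3)               # N, CA, CB (altloc A)
  cb <- m$atoms[m$atoms$elety == "CB", ]
  expect_equal(cb$x, 12.759)                   # occupancy 0.60 wins
  ca <- m$atoms[m$atoms$elety == "CA", ]
  expect_equal(c(ca$x, ca$y, ca$z), c(11.639, 6.071, -5.147))
  expect_false(any(m$atoms$element == "H"))
  expect_false(any(m$atoms$resid == "HOH"))
})

test_that("CSV atom tables round-trip through read_structure", {
  m <- synthetic_helix_dimer()
  f <- tempfile(fileext = ".csv")
  write.csv(m$atoms, f, row.names = FALSE)
  m2 <- read_structure(f)
  expect_equal(m2$atoms$x, m$atoms$x)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
})

test_that("SASA of an isolated atom matches the analytic sphere", {
  m <- structure_model(data.frame(chain = "A", resno = 1, resid = "GLY",
                                  elety = "C", x = 0, y = 0, z = 0))
  a <- sasa(m, probe_radius = 1.4, points_per_atom = 960)
  expect_equal(a, 4 * pi * (1.87 + 1.4)^2, tolerance = 1e-6)
})

test_that("SASA is additive for well-separated atoms", {
  m <- structure_model(data.frame(chain = "A", resno = 1:2, resid = "GLY",
                                  elety = "C", x = c(0, 50), y = 0, z = 0))
  a <- sasa(m, 1.4, 960)
  expect_equal(sum(a), 2 * 4 * pi * (1.87 + 1.4)^2, tolerance = 1e-6)
})

test_that("an atom enclosed in a dense shell has near-zero SASA", {
  m <- buried_atom_fixture()
  a <- sasa(m, 1.4, 480)
  expect_lt(a[1], 1)   # central atom; isolated value would be ~134 A^2
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  d <- 2.0
  R <- 1.87 + 1.4
  m <- structure_model(data.frame(chain = c("A", "B"), resno = 1,
                                  resid = "GLY", elety = "C",
                                  x = c(0, d), y = 0, z = 0))
  a <- sasa(m, 1.4, 4000)
  h <- R - d / 2
  expect_equal(unname(a[1]), 4 * pi * R^2 - 2 * pi * R * h,
               tolerance = 0.005)
  bia <- buried_interface_area(m, "A", "B", points_per_atom = 4000)
  expect_equal(bia$per_monomer, 2 * pi * R * h, tolerance = 0.005)
  expect_equal(bia$total_delta, 2 * bia$per_monomer, tolerance = 1e-12)
})

test_that("doubling the sphere sampling changes SASA by under 1%", {
  m <- synthetic_helix_dimer()
  s1 <- sum(sasa(m, 1.4, 240))
  s2 <- sum(sasa(m, 1.4, 480))
  expect_lt(abs(s2 / s1 - 1), 0.01)
})

test_that("a packed synthetic dimer buries a positive interface; separated chains none", {
  m <- synthetic_helix_dimer(spacing = 5)
  bia <- buried_interface_area(m, "A", "B")
  expect_gt(bia$per_monomer, 50)
  apart <- m
  apart$atoms$x[apart$atoms$chain == "B"] <-
    apart$atoms$x[apart$atoms$chain == "B"] + 100
  expect_message(bia0 <- buried_interface_area(apart, "A", "B"),
                 "do not contact")
  expect_equal(bia0$per_monomer, 0)
})

test_that("superposition RMSD is rigid-motion invariant and symmetric", {
  set.seed(3)
  n <- 40
  xyz <- matrix(rnorm(n * 3, sd = 6), ncol = 3)
  df <- data.frame(chain = "A", resno = 1:n, resid = "ALA", elety = "CA",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  mA <- structure_model(df)
  x2 <- rigid_transform(xyz)
  mB <- structure_model(transform(df, x = x2[, 1], y = x2[, 2], z = x2[, 3]))
  expect_equal(as.numeric(superpose_rmsd(mA, mB)), 0, tolerance = 1e-10)
  x3 <- xyz + matrix(rnorm(n * 3, sd = 0.3), ncol = 3)
  mC <- structure_model(transform(df, x = x3[, 1], y = x3[, 2], z = x3[, 3]))
  expect_equal(as.numeric(superpose_rmsd(mA, mC)),
               as.numeric(superpose_rmsd(mC, mA)), tolerance = 1e-10)
})

test_that("single-coordinate perturbation gives RMSD ~ delta/sqrt(N)", {
  set.seed(4)
  n <- 50
  xyz <- matrix(rnorm(n * 3, sd = 6), ncol = 3)
  df <- data.frame(chain = "A", resno = 1:n, resid = "ALA", elety = "CA",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  mA <- structure_model(df)
  delta <- 0.5
  xyz[7, 2] <- xyz[7, 2] + delta
  mB <- structure_model(transform(df, x = xyz[, 1], y = xyz[, 2],
                                  z = xyz[, 3]))
  r <- as.numeric(superpose_rmsd(mA, mB))
  expect_lt(abs(r - delta / sqrt(n)) / (delta / sqrt(n)), 0.15)
})

test_that("superposition agrees with the bio3d reference implementation", {
  set.seed(5)
  n <- 30
  xyz <- matrix(rnorm(n * 3, sd = 5), ncol = 3)
  noisy <- rigid_transform(xyz + matrix(rnorm(n * 3, sd = 0.4), ncol = 3))
  df <- data.frame(chain = "A", resno = 1:n, resid = "ALA", elety = "CA",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  mA <- structure_model(df)
  mB <- structure_model(transform(df, x = noisy[, 1], y = noisy[, 2],
                                  z = noisy[, 3]))
  ours <- as.numeric(superpose_rmsd(mA, mB))
  oracle <- bio3d::rmsd(as.vector(t(xyz)), as.vector(t(noisy)), fit = TRUE)
  expect_equal(ours, oracle, tolerance = 1e-3)
})

test_that("degenerate collinear selections are refused", {
  df <- data.frame(chain = "A", resno = 1:5, resid = "ALA", elety = "CA",
                   x = 1:5, y = 0, z = 0)
  mA <- structure_model(df)
  mB <- structure_model(transform(df, x = df$x + 1))
  expect_error(superpose_rmsd(mA, mB), "degenerate")
})

test_that("chain mapping pairs equivalent monomers across structures", {
  m <- synthetic_helix_dimer()
  a_only <- structure_model(m$atoms[m$atoms$chain == "A", ])
  b_relabelled <- m$atoms[m$atoms$chain == "A", ]
  b_relabelled$chain <- "X"
  xyz <- rigid_transform(as.matrix(b_relabelled[, c("x", "y", "z")]))
  b_relabelled$x <- xyz[, 1]; b_relabelled$y <- xyz[, 2]
  b_relabelled$z <- xyz[, 3]
  mB <- structure_model(b_relabelled)
  r <- superpose_rmsd(a_only, mB, chain_map = c(A = "X"))
  expect_equal(as.numeric(r), 0, tolerance = 1e-10)
  expect_equal(attr(r, "n_atoms"), sum(m$atoms$chain == "A"))
})
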