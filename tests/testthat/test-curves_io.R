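test_that("curve files parse, sort, and round-trip", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# a comment", "q I err", "0.01 100 1", "0.02 90 1",
               "0.03 80 1"), f)
  cv <- read_saxs_curve(f)
  expect_length(cv, 3)
  expect_equal(cv$I, c(100, 90, 80))

  # reversed rows give the same curve after sorting
  writeLines(c("0.03 80 1", "0.02 90 1", "0.01 100 1"), f)
  expect_equal(read_saxs_curve(f)$q, cv$q)
  expect_equal(read_saxs_curve(f)$I, cv$I)

  # extra columns ignored; non-positive sigma rows dropped with a warning
  writeLines(c("0.01 100 1 9 9", "0.02 90 1 9 9", "0.025 85 -1 0 0",
               "0.03 80 1 9 9"), f)
  expect_warning(cv2 <- read_saxs_curve(f), "non-positive sigma")
  expect_length(cv2, 3)

  # write/read round trip preserves values and metadata
  cv3 <- saxs_curve(c(0.0123456, 0.0234567, 0.11), c(1234.56, 98.7654, 3.2),
                    c(1.23456, 0.9, 0.1), label = "round trip",
                    window = c(0.01, 0.1))
  write_saxs_curve(cv3, f)
  back <- read_saxs_curve(f)
  expect_equal(back$q, cv3$q, tolerance = 1e-6)
  expect_equal(back$I, cv3$I, tolerance = 1e-6)
  expect_equal(back$sigma, cv3$sigma, tolerance = 1e-6)
  expect_equal(back$window, cv3$window)
  expect_equal(back$label, cv3$label)

  expect_error(read_saxs_curve(file.path(tempdir(), "nope.dat")), "cannot read")
  writeLines(c("0.01 1 1", "0.02 2 1"), f)
  expect_error(read_saxs_curve(f), "fewer than 3")
})

test_that("q from instrument geometry follows q = 4 pi sin(theta) / lambda", {
  expect_equal(q_from_angle(0, wavelength = 1), 0)
  expect_equal(q_from_angle(60, wavelength = 1), 2 * pi)
  # energy-only input: lambda = 12.3984 / E(keV)
  lam <- 12.3984 / 12.4
  expect_equal(q_from_angle(60, energy_kev = 12.4),
               4 * pi * sin(30 * pi / 180) / lam)
  expect_equal(lam, 0.99987, tolerance = 1e-5)
  expect_error(q_from_angle(60, wavelength = -1), "wavelength")
  expect_error(q_from_angle(190, wavelength = 1))
})

test_that("background subtraction propagates uncertainty in quadrature", {
  q <- c(0.01, 0.02, 0.03)
  s <- saxs_curve(q, c(10, 8, 6), c(1, 1, 1))
  b <- saxs_curve(q, c(4, 3, 2), c(1, 1, 1))
  d <- subtract_background(s, b)
  expect_equal(d$I, c(6, 5, 4))
  expect_equal(d$sigma, rep(sqrt(2), 3))

  # curve minus itself: zero intensity, sigma scaled by sqrt(2)
  z <- subtract_background(s, s)
  expect_equal(z$I, rep(0, 3))
  expect_equal(z$sigma, s$sigma * sqrt(2))

  # zero buffer is the identity; subtracting the buffer back restores sample
  zero <- saxs_curve(q, c(0, 0, 0), c(1e-9, 1e-9, 1e-9))
  expect_equal(subtract_background(s, zero)$I, s$I)
  restored <- saxs_curve(q, d$I + b$I, s$sigma)
  expect_equal(restored$I, s$I, tolerance = 1e-12)

  bad <- saxs_curve(q + 0.001, c(4, 3, 2), c(1, 1, 1))
  expect_error(subtract_background(s, bad), "grids differ")
})

test_that("PDB reading honours granularity, altLoc occupancy, and chains", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  O   ALA A   1      12.000   7.000  -5.000  1.00  0.00           O",
    "ATOM      4  CA AGLY A   2      12.000   7.000  -4.000  0.40  0.00           C",
    "ATOM      5  CA BGLY A   2      12.500   7.500  -4.500  0.60  0.00           C",
    "ATOM      6  CA  SER B   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      7  CB  SER B   1       1.500   2.500   3.500  1.00  0.00           C",
    "END"), f)
  m <- read_coordinates(f)
  # hand count: chain A has residues 1-2, chain B residue 1 -> 3 beads
  expect_equal(nrow(m$particles), 3)
  # highest-occupancy altLoc kept for A/2
  g2 <- m$particles[m$particles$chain == "A" & m$particles$resno == 2, ]
  expect_equal(g2$x, 12.5)
  # bead mass is the residue average mass
  expect_equal(m$particles$mass[m$particles$resid == "GLY"], 57.0519)

  ma <- read_coordinates(f, "atomic")
  expect_equal(nrow(ma$particles), 6)  # 5 unique A-sites + ... hand count: 3+1+2
  expect_error(read_coordinates(withr::local_tempfile(fileext = ".pdb")))
})

test_that("single-ATOM file yields a one-particle model", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), f)
  m <- read_coordinates(f)
  expect_equal(nrow(m$particles), 1)
  expect_equal(unname(unlist(m$particles[1, c("x", "y", "z")])), c(1, 2, 3))
})

test_that("bead models survive a PDB write/read cycle", {
  set.seed(1)
  bm <- bead_model(matrix(round(rnorm(30) * 8, 3), 10))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_coordinates(bm, f)
  back <- read_coordinates(f)
  expect_equal(coords(back), coords(bm), ignore_attr = TRUE)
})

test_that("sequence mass is the residue-mass sum plus one water, additive", {
  expect_equal(sequence_mass("")$mass, 18.0153)
  expect_equal(sequence_mass("G")$mass, 75.07, tolerance = 1e-4)
  expect_error(sequence_mass("GXZ"), "unknown")
  # additivity: mass(AB) = mass(A) + mass(B) - water
  set.seed(2)
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  for (i in 1:5) {
    s1 <- paste(sample(aa, 8, TRUE), collapse = "")
    s2 <- paste(sample(aa, 5, TRUE), collapse = "")
    expect_equal(sequence_mass(paste0(s1, s2))$mass,
                 sequence_mass(s1)$mass + sequence_mass(s2)$mass - 18.0153)
  }
})
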