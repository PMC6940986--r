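test_that("C2 axis detection is exact on constructed dimers and rejects non-dimers", {
  comp <- dimer_components()
  ax <- detect_c2_axis(comp$upper)
  expect_equal(ax$angle, 180, tolerance = 1e-6)
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-6)
  expect_lt(ax$rmsd, 1e-9)

  # jittered dimer: axis recovered within 2 degrees
  jit <- comp$upper
  jit$particles[, c("x", "y", "z")] <-
    jit$particles[, c("x", "y", "z")] +
    withr::with_seed(2, matrix(rnorm(3 * nrow(jit$particles), 0, 0.5),
                               ncol = 3))
  axj <- detect_c2_axis(jit)
  ang <- acos(abs(sum(axj$direction * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 2)
  expect_lt(abs(axj$angle - 180), 2)

  # duplicated monomer without rotation is not a C2 dimer
  half <- comp$upper$particles[comp$upper$particles$chain == "A", ]
  dup <- half; dup$chain <- "B"
  expect_error(detect_c2_axis(coord_model(rbind(half, dup))), "not a C2 dimer")
})

test_that("grid search recovers a ground-truth placement at 1% noise", {
  comp <- dimer_components()
  qg <- seq(0.01, 0.35, length.out = 80)
  truth <- place_components(comp$upper, comp$lower, 40, 34)
  ds <- simulate_curve(truth, qg, noise_spec(0.01, 1e-4, seed = 5))
  cands <- enumerate_assemblies(comp$upper, comp$lower, ds$noisy,
                                t_range = c(26, 46))
  best <- cands[1, ]
  expect_lte(circ_phi_dist(best$phi, 40), 5)
  expect_lte(abs(best$t - 34), 1)
  expect_lt(best$chi2, 2)
  # candidates passing the chi2 < 2 gate concentrate in the truth basin
  gated <- cands[cands$clash_count == 0 & cands$chi2 < 2, ]
  expect_true(all(circ_phi_dist(gated$phi, 40) <= 25))
  expect_true(all(abs(gated$t - 34) <= 2))
  expect_true(mean(circ_phi_dist(gated$phi, 40) <= 10) >= 0.5)

  # overlapping bodies are clash-flagged, leaving no survivors
  expect_warning(
    bad <- enumerate_assemblies(comp$upper, comp$lower, ds$noisy,
                                t_range = c(2, 6)),
    "clash")
  expect_true(all(bad$clash_count > 0))
})

test_that("chi2 ranking is invariant to global rotation of the input dimers", {
  comp <- dimer_components()
  qg <- seq(0.01, 0.3, length.out = 50)
  truth <- place_components(comp$upper, comp$lower, 60, 32)
  ds <- simulate_curve(truth, qg, noise_spec(0.01, 1e-4, seed = 8))
  c1 <- enumerate_assemblies(comp$upper, comp$lower, ds$noisy,
                             t_range = c(28, 40))
  # rotate the upper body arbitrarily; its canonical pose restores the frame
  R <- withr::with_seed(5, {
    M <- matrix(rnorm(9), 3); q <- qr.Q(qr(M)); if (det(q) < 0) q[, 1] <- -q[, 1]; q
  })
  up2 <- comp$upper
  up2$particles[, c("x", "y", "z")] <-
    as.matrix(up2$particles[, c("x", "y", "z")]) %*% t(R) +
    matrix(c(30, -12, 7), nrow(up2$particles), 3, byrow = TRUE)
  c2 <- enumerate_assemblies(up2, comp$lower, ds$noisy, t_range = c(28, 40))
  expect_equal(c1$chi2[1], c2$chi2[1], tolerance = 1e-3)
  expect_equal(c1$t[1], c2$t[1])
})

test_that("emitted assemblies keep exact C2 symmetry", {
  comp <- dimer_components()
  m <- place_components(comp$upper, comp$lower, 72.5, 33)
  pr <- m$particles
  for (pair in list(c("A", "B"), c("C", "D"))) {
    X1 <- as.matrix(pr[pr$chain == pair[1], c("x", "y", "z")])
    X2 <- as.matrix(pr[pr$chain == pair[2], c("x", "y", "z")])
    mirror <- cbind(-X1[, 1], -X1[, 2], X1[, 3])
    expect_lt(sqrt(mean(rowSums((mirror - X2)^2))), 1e-9)
  }
})

test_that("scenario 1 beats free-subunit scenarios on scenario-1 truth", {
  comp <- dimer_components()
  qg <- seq(0.01, 0.3, length.out = 50)
  truth <- place_components(comp$upper, comp$lower, 40, 34)
  free_lower <- coord_model(
    comp$lower$particles[comp$lower$particles$chain == "C", ])
  free_upper <- coord_model(
    comp$upper$particles[comp$upper$particles$chain == "A", ])
  for (seed in 11:13) {
    ds <- simulate_curve(truth, qg, noise_spec(0.01, 1e-4, seed = seed))
    s1 <- scenario_search(1, comp$upper, comp$lower, ds$noisy,
                          phi_step = 5, t_step = 1)
    s2 <- scenario_search(2, comp$upper, free_lower, ds$noisy,
                          phi_step = 30, t_step = 4, angle_step = 120,
                          radial_offsets = c(14, 18, 22))
    s3 <- scenario_search(3, free_upper, comp$lower, ds$noisy,
                          phi_step = 30, t_step = 4, angle_step = 120,
                          radial_offsets = c(19, 23, 27))
    expect_lte(s1$best$chi2, s2$best$chi2)
    expect_lte(s1$best$chi2, s3$best$chi2)
  }
})

test_that("conformer-resolved search separates flat from twisted truth", {
  qg <- seq(0.01, 0.35, length.out = 70)
  flat <- toy_dimer_components(toy_spec("two_domain_c2_dimer", twist = 0,
                                        n_beads = 160, seed = 3))
  twisted <- toy_dimer_components(toy_spec("two_domain_c2_dimer", twist = 30,
                                           n_beads = 160, seed = 3))
  truth <- place_components(flat$upper, flat$lower, 40, 32)
  ds <- simulate_curve(truth, qg, noise_spec(0.01, 1e-4, seed = 11))
  best_flat <- enumerate_assemblies(flat$upper, flat$lower, ds$noisy,
                                    t_range = c(26, 46))$chi2[1]
  best_twisted <- enumerate_assemblies(twisted$upper, flat$lower, ds$noisy,
                                       t_range = c(26, 46))$chi2[1]
  expect_gt(best_twisted - best_flat, 1.0)
})

test_that("a pseudo-symmetric partner produces two reported rotation minima", {
  comp <- dimer_components()
  lowx <- toy_cross_dimer(spacing = 4.5)
  qg <- seq(0.01, 0.3, length.out = 60)
  contact <- max(coords(lowx)[, 3]) - min(coords(comp$upper)[, 3])
  truth <- place_components(comp$upper, lowx, 30, ceiling(contact) + 2)
  ds <- simulate_curve(truth, qg, noise_spec(0.01, 1e-4, seed = 13))
  sr <- scenario_search(1, comp$upper, lowx, ds$noisy, chi2_gate = 5)
  expect_equal(nrow(sr$minima), 2)
  expect_lte(circ_phi_dist(sr$minima$phi[1], 30), 5)
  expect_equal(circ_phi_dist(sr$minima$phi[1], sr$minima$phi[2]), 90,
               tolerance = 0.12)
  # tie-break: the selected minimum has the larger complementarity
  rk <- rank_candidates(sr$minima, bodies = list(upper = attr(sr$all, "upper"),
                                                 lower = attr(sr$all, "lower")),
                        cfg = saxs_config(assembly = list(chi2_tie = 1)))
  expect_false(is.na(rk$complementarity[1]))
  expect_gte(rk$complementarity[1], max(rk$complementarity, na.rm = TRUE))
})

test_that("buried interface area follows the SASA convention", {
  # two bodies far apart bury nothing
  far <- bead_model(rbind(c(0, 0, 0), c(100, 0, 0)), chain = c("A", "B"))
  expect_equal(interface_area(far, "A", "B"), 0)
  expect_error(interface_area(far, "A", "A"), "overlap")

  # two touching single-bead spheres: buried area equals the analytic
  # spherical cap 2 pi R h cut by the neighbour sphere
  touch <- bead_model(rbind(c(0, 0, 0), c(7, 0, 0)), chain = c("A", "B"))
  Rs <- 3.5 + 1.4
  h <- Rs - 7 / 2
  expect_equal(interface_area(touch, "A", "B"), 2 * pi * Rs * h,
               tolerance = 0.02)

  # complementarity axioms
  cs <- complementarity_score(far, "A", "B")
  expect_equal(cs$score, 0)
  m <- place_components(dimer_components()$upper, dimer_components()$lower,
                        30, 24)
  cs2 <- complementarity_score(m, c("A", "B"), c("C", "D"))
  expect_gt(cs2$interface_area, 0)
  expect_equal(cs2$score,
               cs2$interface_area - 50 * cs2$near_clashes)
})
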