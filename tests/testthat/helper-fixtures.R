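# Shared fixtures, built once per test run. "Noiseless" curves carry a 1%
# proportional sigma plus a small floor so chi-square weighting is defined.

noiseless_curve <- function(model, q_grid, rel = 0.01) {
  I <- debye_intensity(model, q_grid, method = "exact")$I
  saxs_curve(q_grid, I, rel * abs(I) + 1e-4 * max(I))
}

sphere_model <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- generate_structure(toy_spec("sphere", radius = 20,
                                                            spacing = 2.5))
    memo
  }
})

sphere_curve <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- noiseless_curve(sphere_model(), seq(0.008, 1.0, length.out = 400))
    memo
  }
})

# centred dimer components for the assembly search (subsampled for speed)
dimer_components <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- toy_dimer_components(toy_spec("two_domain_c2_dimer",
                                             n_beads = 150, seed = 3))
    memo
  }
})

sphere_rg_true <- sqrt(3 / 5) * 20   # homogeneous sphere, R = 20 A

circ_phi_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
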