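#' Analysis configuration
#'
#' All tolerances, grid steps and penalty weights used across the pipeline,
#' as a nested list. Values can be overridden programmatically or from a YAML
#' file. Units: lengths in Angstrom, q in 1/Angstrom, volumes in nm^3.
#'
#' @param file optional path to a YAML file whose entries override defaults.
#' @param ... named overrides applied after the file, e.g.
#'   `saxs_config(debye = list(hist_bin = 0.05))`. Only supplied leaves are
#'   replaced.
#' @return nested list of settings.
#' @export
#' @examples
#' cfg <- saxs_config()
#' cfg$debye$hist_bin
saxs_config <- function(file = NULL, ...) {
  cfg <- list(
    debye = list(
      hist_bin = 0.1          # pair-distance histogram bin width (Angstrom)
    ),
    guinier = list(
      srg_min = 0.3,          # lower q*Rg bound of the fit window
      srg_max = 1.3,          # upper q*Rg bound (Guinier validity limit)
      max_iter = 20
    ),
    pr = list(
      n_r = 101,              # r-grid points from 0 to Dmax
      alpha_grid = 10^seq(-4, 2, length.out = 13),
      dmax_step = 2,          # Dmax scan step (Angstrom)
      w_neg = 10,             # negativity penalty weight in the Dmax score
      w_rough = 1             # roughness penalty weight in the Dmax score
    ),
    porod = list(
      exponent_srg = c(2.5, 6.5),  # q*Rg window for the power-law fit
      exponent_bins = 10,          # log-q bins of mean intensity for the fit
      mass_per_nm3 = 0.58        # kDa of protein per nm^3 of Porod volume
    ),
    beads = list(
      bond_target = 3.8,      # C-alpha virtual bond length (Angstrom)
      bond_range = c(3.0, 4.6),
      clash_dist = 3.0,
      w_bond = 10,
      w_clash = 10,
      step_sd = 1.0,          # Gaussian move size (Angstrom)
      chi2_ceiling = 5        # above this the result is flagged unconverged
    ),
    assembly = list(
      phi_step = 5,           # degrees
      t_step = 1,             # Angstrom
      t_below = 5,            # scan from contact - t_below ...
      t_above = 25,           # ... to contact + t_above
      angle_step = 30,        # free-subunit orientation scan (degrees)
      radial_step = 2,        # free-subunit radial offset scan (Angstrom)
      clash_dist = 3.0,
      chi2_gate = 2.0,
      chi2_tie = 0.2,         # chi2 difference treated as a tie
      near_clash = c(3.0, 3.5),
      near_clash_penalty = 50
    ),
    sasa = list(
      n_points = 960,         # sphere points per particle (Shrake-Rupley)
      probe = 1.4,            # probe radius (Angstrom)
      bead_radius = 3.5       # radius assigned to residue beads
    ),
    linker = list(
      bond = 3.8,
      clash_dist = 3.0,
      closure_tol = 0.5,
      cone_wide = 90,         # steering cone half-angle when slack (degrees)
      cone_narrow = 15        # ... when taut
    ),
    simulate = list(
      q_min = 0.004, q_max = 0.42, n_q = 512,
      rel_error = 0.02,       # epsilon: relative noise level
      floor_frac = 0.001      # delta: noise floor as a fraction of I(0)
    )
  )
  if (!is.null(file)) {
    over <- yaml::read_yaml(file)
    cfg <- modify_list_deep(cfg, over)
  }
  dots <- list(...)
  if (length(dots)) cfg <- modify_list_deep(cfg, dots)
  cfg
}

modify_list_deep <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}
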