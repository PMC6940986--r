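# Ground-truth toy structures and simulated SEC-SAXS-like curves. The
# flagship shape is a two-domain homodimer with exact C2 symmetry: an upper
# dimer of two ellipsoidal blocks (the nucleotide-sensing module pair) and a
# lower dimer (the cyclic-nucleotide-homology pair) stacked on the same
# 2-fold axis, with an optional twist of the upper blocks emulating the
# twisted vs flat disk conformations.

#' Toy structure specification
#'
#' @param shape `"sphere"`, `"ellipsoid"`, `"dumbbell"` or
#'   `"two_domain_c2_dimer"`.
#' @param radius sphere (or dumbbell lobe) radius, Angstrom.
#' @param semi_axes ellipsoid semi-axes (x, y, z), Angstrom; for the dimer,
#'   the upper-block semi-axes.
#' @param semi_axes2 lower-block semi-axes (dimer only).
#' @param lateral_offset,lateral_offset2 distance of each block centre from
#'   the 2-fold axis (upper / lower dimer).
#' @param separation axial distance between the upper and lower dimer
#'   centroid planes, Angstrom (dimer only; dumbbell: centre-to-centre
#'   distance).
#' @param twist rotation of each upper block about the vertical axis
#'   through its own centre, degrees in `[0, 90]`: the relative swing of
#'   the two disk halves about the 2-fold axis. 0 is the flat disk, larger
#'   values the twisted one.
#' @param n_beads optional target bead count; beads are subsampled (seeded)
#'   when the density fill exceeds it.
#' @param spacing bead lattice spacing, Angstrom (~1 bead per (4 A)^3 by
#'   default).
#' @param include_linkers add straight dummy-residue chains connecting upper
#'   and lower blocks within each protomer (C2-mirrored).
#' @param seed integer seed for any subsampling.
#' @return list of class `toy_spec`.
#' @export
toy_spec <- function(shape = c("sphere", "ellipsoid", "dumbbell",
                               "two_domain_c2_dimer"),
                     radius = 20, semi_axes = c(36, 12, 11),
                     semi_axes2 = c(30, 10, 10),
                     lateral_offset = 23, lateral_offset2 = 18,
                     separation = 62, twist = 0, n_beads = NULL,
                     spacing = 4, include_linkers = FALSE, seed = 1) {
  shape <- match.arg(shape)
  stopifnot(radius > 0, all(semi_axes > 0), all(semi_axes2 > 0),
            separation > 0, twist >= 0, twist <= 90, spacing > 0)
  structure(list(shape = shape, radius = radius, semi_axes = semi_axes,
                 semi_axes2 = semi_axes2, lateral_offset = lateral_offset,
                 lateral_offset2 = lateral_offset2, separation = separation,
                 twist = twist, n_beads = n_beads, spacing = spacing,
                 include_linkers = include_linkers, seed = seed),
            class = "toy_spec")
}

# Quasi-uniform lattice fill of an axis-aligned ellipsoid centred at origin.
ellipsoid_fill <- function(semi, spacing) {
  gr <- lapply(semi, function(s) seq(-s, s, by = spacing))
  X <- as.matrix(expand.grid(x = gr[[1]], y = gr[[2]], z = gr[[3]]))
  keep <- (X[, 1] / semi[1])^2 + (X[, 2] / semi[2])^2 + (X[, 3] / semi[3])^2 <= 1
  X[keep, , drop = FALSE]
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

c2_z <- function(X) cbind(-X[, 1], -X[, 2], X[, 2] * 0 + X[, 3])

straight_chain <- function(from, to, bond = 3.8) {
  d <- sqrt(sum((to - from)^2))
  n <- max(1, ceiling(d / bond) - 1)   # bond length d/(n+1) <= bond
  tfrac <- seq_len(n) / (n + 1)
  outer(tfrac, to - from) + matrix(from, n, 3, byrow = TRUE)
}

#' Generate a ground-truth toy structure
#'
#' Shapes are filled quasi-uniformly with beads on a cubic lattice (about
#' one bead per `spacing^3`). The two-domain dimer is C2-symmetric by
#' construction: block 2 of each dimer is the image of block 1 under the
#' 180-degree rotation about z, so the symmetry is exact to machine
#' precision. The truth parameters (Rg, Dmax, fill volume, twist) are
#' attached as `attr(model, "truth")`.
#'
#' @param spec a [toy_spec()].
#' @return a residue-bead [coord_model()]; chains A/B for the upper dimer,
#'   C/D for the lower, L/M for optional linkers.
#' @export
generate_structure <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  sp <- spec$spacing
  parts <- switch(spec$shape,
    sphere = {
      X <- ellipsoid_fill(rep(spec$radius, 3), sp)
      list(A = X)
    },
    ellipsoid = list(A = ellipsoid_fill(spec$semi_axes, sp)),
    dumbbell = {
      X <- ellipsoid_fill(rep(spec$radius, 3), sp)
      list(A = sweep(X, 2, c(0, 0, spec$separation / 2), "+"),
           B = sweep(X, 2, c(0, 0, -spec$separation / 2), "+"))
    },
    two_domain_c2_dimer = {
      up1 <- ellipsoid_fill(spec$semi_axes, sp) %*% t(rot_z(spec$twist))
      up1 <- sweep(up1, 2, c(spec$lateral_offset, 0, spec$separation / 2), "+")
      lo1 <- ellipsoid_fill(spec$semi_axes2, sp)
      lo1 <- sweep(lo1, 2, c(spec$lateral_offset2, 0, -spec$separation / 2), "+")
      out <- list(A = up1, B = c2_z(up1), C = lo1, D = c2_z(lo1))
      if (spec$include_linkers) {
        # straight chain from the bottom of upper block 1 to the top of
        # lower block 1, mirrored by the C2 operation
        from <- c(spec$lateral_offset, 0, spec$separation / 2 - spec$semi_axes[3])
        to <- c(spec$lateral_offset2, 0, -spec$separation / 2 + spec$semi_axes2[3])
        L <- straight_chain(from, to)
        out$L <- L
        out$M <- c2_z(L)
      }
      out
    })
  if (!is.null(spec$n_beads)) {
    n_tot <- sum(vapply(parts, nrow, 0L))
    if (spec$n_beads < 20) stop("n_beads too small for shape (< 20)")
    if (spec$n_beads < n_tot) {
      frac <- spec$n_beads / n_tot
      # mirror-related chain pairs (A/B, C/D, L/M) share subsample indices
      # so the C2 symmetry stays exact
      # linker chains (L/M) are kept whole: decimating them would break
      # their bonded-chain geometry
      pairs <- list(c("A", "B"), c("C", "D"))
      parts <- withr::with_seed(spec$seed, {
        for (pp in pairs) {
          if (!pp[1] %in% names(parts)) next
          idx <- sort(sample(nrow(parts[[pp[1]]]),
                             max(1, round(frac * nrow(parts[[pp[1]]])))))
          for (ch in intersect(pp, names(parts)))
            parts[[ch]] <- parts[[ch]][idx, , drop = FALSE]
        }
        parts
      })
    }
  }
  pr <- do.call(rbind, lapply(names(parts), function(ch) {
    X <- parts[[ch]]
    data.frame(chain = ch, resno = seq_len(nrow(X)), insert = "",
               resid = "GLY", x = X[, 1], y = X[, 2], z = X[, 3],
               mass = 110, f = 1, stringsAsFactors = FALSE)
  }))
  model <- coord_model(pr, granularity = "residue-bead")
  vol <- nrow(pr) * sp^3
  attr(model, "truth") <- list(
    Rg = model_rg(model), Dmax = max_pair_dist_cpp(coords(model)),
    volume = vol, twist = spec$twist, shape = spec$shape
  )
  model
}

#' Pseudo-four-fold lower dimer for rotation-degeneracy fixtures
#'
#' A C2 dimer whose footprint is nearly invariant under a 90-degree
#' rotation about the axis: each chain is one large block along x plus a
#' slightly smaller block along y. Fitting a candidate rotation against
#' data simulated from this body therefore admits two distinct minima
#' (phi and roughly phi + 90), emulating the rotamer-pair degeneracy that
#' symmetric rigid-body searches encounter.
#'
#' @param n_beads optional target bead count (seeded subsampling).
#' @param spacing bead lattice spacing, Angstrom.
#' @param seed integer seed.
#' @return a residue-bead [coord_model()] with chains C and D, centred,
#'   2-fold axis along +z.
#' @export
toy_cross_dimer <- function(n_beads = NULL, spacing = 4, seed = 1) {
  bx <- ellipsoid_fill(c(30, 10, 10), spacing)
  bx <- sweep(bx, 2, c(18, 0, 0), "+")
  by <- ellipsoid_fill(c(29, 10, 10), spacing) %*% t(rot_z(90))
  by <- sweep(by, 2, c(0, 17.5, 0), "+")
  c1 <- rbind(bx, by)
  if (!is.null(n_beads)) {
    stopifnot(n_beads >= 20)
    if (n_beads / 2 < nrow(c1))
      c1 <- withr::with_seed(seed,
        c1[sort(sample(nrow(c1), round(n_beads / 2))), , drop = FALSE])
  }
  c2 <- c2_z(c1)
  X <- rbind(c1, c2)
  X <- sweep(X, 2, colMeans(X))
  m <- bead_model(X, chain = rep(c("C", "D"), each = nrow(c1)))
  attr(m, "truth") <- list(Rg = model_rg(m), Dmax = max_pair_dist_cpp(X),
                           volume = NA_real_, shape = "pseudo4_dimer")
  m
}

#' Noise specification for simulated curves
#'
#' sigma(q) = rel_error * I(q) + floor_frac * I(0); noisy intensities are
#' the noiseless ones plus Gaussian noise of that width. The multiplicative
#' term mimics the signal-proportional error of column-mode SAXS frames and
#' the floor keeps sigma strictly positive at high q.
#'
#' @param rel_error relative error (default 0.02).
#' @param floor_frac noise floor as a fraction of I(0) (default 0.001).
#' @param seed integer seed.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(rel_error = 0.02, floor_frac = 0.001, seed = 1) {
  stopifnot(rel_error >= 0, floor_frac >= 0)
  structure(list(rel_error = rel_error, floor_frac = floor_frac, seed = seed),
            class = "noise_spec")
}

#' Simulate a SEC-SAXS-like dataset from a coordinate model
#'
#' The noiseless curve is the exact Debye intensity of the model; the noisy
#' curve adds Gaussian noise per [noise_spec()]. Deterministic for a given
#' seed.
#'
#' @param model a [coord_model()].
#' @param q_grid q values; default 512 points over 0.004..0.42 1/Angstrom.
#' @param noise a [noise_spec()].
#' @param cfg configuration list.
#' @return list of class `simulated_dataset`: `model`, `truth` (named list
#'   with Rg, Dmax, volume, and any generator annotations), `noiseless` and
#'   `noisy` ([saxs_curve()] objects).
#' @export
simulate_curve <- function(model, q_grid = NULL, noise = noise_spec(),
                           cfg = saxs_config()) {
  if (is.null(q_grid))
    q_grid <- seq(cfg$simulate$q_min, cfg$simulate$q_max,
                  length.out = cfg$simulate$n_q)
  mc <- debye_intensity(model, q_grid, method = "exact")
  I0 <- debye_exact_cpp(coords(model), rep(1, nrow(coords(model))), 0)[1]
  s <- noise$rel_error * mc$I + noise$floor_frac * I0
  s[s <= 0] <- 1e-10 * I0
  noisy_I <- withr::with_seed(noise$seed, mc$I + rnorm(length(s), 0, s))
  truth <- attr(model, "truth")
  if (is.null(truth))
    truth <- list(Rg = model_rg(model), Dmax = max_pair_dist_cpp(coords(model)),
                  volume = NA_real_)
  structure(list(
    model = model, truth = truth,
    noiseless = saxs_curve(q_grid, mc$I, s, label = "noiseless"),
    noisy = saxs_curve(q_grid, noisy_I, s, label = "noisy")
  ), class = "simulated_dataset")
}

#' Centred rigid-body components of the toy dimer
#'
#' Returns the upper (chains A/B) and lower (chains C/D) C2 dimers of a
#' [toy_spec()] as separate models, each centred at the origin with its
#' 2-fold axis along +z — the canonical pose the assembly search uses.
#'
#' @param spec a [toy_spec()] with shape `two_domain_c2_dimer`.
#' @return list with elements `upper` and `lower` ([coord_model()]s).
#' @export
toy_dimer_components <- function(spec) {
  stopifnot(spec$shape == "two_domain_c2_dimer")
  full <- generate_structure(spec)
  pr <- full$particles
  up <- pr[pr$chain %in% c("A", "B"), ]
  lo <- pr[pr$chain %in% c("C", "D"), ]
  center <- function(d) {
    d$x <- d$x - mean(d$x); d$y <- d$y - mean(d$y); d$z <- d$z - mean(d$z)
    rownames(d) <- NULL
    d
  }
  list(upper = coord_model(center(up)), lower = coord_model(center(lo)))
}

#' Place two centred components at a given rotation and axial separation
#'
#' The upper body stays in its canonical pose (centroid at origin, axis +z);
#' the lower body is rotated by `phi` degrees about z and translated down by
#' `t` Angstrom. This is exactly the candidate geometry scored by
#' [enumerate_assemblies()], so simulated truths and search candidates share
#' one convention.
#'
#' @param upper,lower centred [coord_model()]s (see [toy_dimer_components()]).
#' @param phi rotation about the shared axis, degrees.
#' @param t axial centroid separation, Angstrom.
#' @return combined [coord_model()].
#' @export
place_components <- function(upper, lower, phi, t) {
  lo <- lower$particles
  Xl <- as.matrix(lo[, c("x", "y", "z")]) %*% t(rot_z(phi))
  lo$x <- Xl[, 1]; lo$y <- Xl[, 2]; lo$z <- Xl[, 3] - t
  pr <- rbind(upper$particles, lo)
  rownames(pr) <- NULL
  m <- coord_model(pr)
  attr(m, "truth") <- list(Rg = model_rg(m), Dmax = max_pair_dist_cpp(coords(m)),
                           volume = NA_real_, phi = phi, t = t)
  m
}

#' Write the fixed benchmark fixture set
#'
#' Emits six ground-truth fixtures — sphere, dumbbell, flat dimer, twisted
#' dimer, dimer with linkers, and a degenerate two-rotation-minima case —
#' each as a truth PDB plus noiseless and noisy curves, with a TSV manifest
#' of the true parameters. Regeneration with the same seed is byte
#' identical.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed governing all noise draws.
#' @param n_q number of q points per curve.
#' @param cfg configuration list.
#' @return data.frame manifest (also written to `manifest.tsv`).
#' @export
make_benchmark_suite <- function(out_dir, seed = 1, n_q = 256,
                                 cfg = saxs_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("directory not writable: ", out_dir)
  qg <- seq(cfg$simulate$q_min, cfg$simulate$q_max, length.out = n_q)
  rows <- list()
  emit <- function(name, model, noiseless_I = NULL, extra = list(),
                   sub_seed) {
    ns <- noise_spec(seed = sub_seed)
    if (is.null(noiseless_I)) {
      dsets <- simulate_curve(model, qg, ns, cfg)
    } else {
      I0 <- max(noiseless_I)
      s <- ns$rel_error * noiseless_I + ns$floor_frac * I0
      noisy <- withr::with_seed(ns$seed,
                                noiseless_I + rnorm(length(s), 0, s))
      tr <- attr(model, "truth")
      dsets <- list(truth = tr,
                    noiseless = saxs_curve(qg, noiseless_I, s, "noiseless"),
                    noisy = saxs_curve(qg, noisy, s, "noisy"))
    }
    pdb <- file.path(out_dir, paste0(name, "_truth.pdb"))
    f0 <- file.path(out_dir, paste0(name, "_noiseless.dat"))
    f1 <- file.path(out_dir, paste0(name, "_noisy.dat"))
    write_coordinates(model, pdb)
    write_saxs_curve(dsets$noiseless, f0)
    write_saxs_curve(dsets$noisy, f1)
    tr <- if (!is.null(dsets$truth)) dsets$truth else attr(model, "truth")
    rows[[name]] <<- data.frame(
      name = name, pdb = basename(pdb), noiseless = basename(f0),
      noisy = basename(f1), Rg = tr$Rg, Dmax = tr$Dmax,
      volume = if (!is.null(tr$volume)) tr$volume else NA_real_,
      phi = if (!is.null(tr$phi)) tr$phi else NA_real_,
      t = if (!is.null(tr$t)) tr$t else NA_real_,
      label = if (!is.null(tr$shape)) tr$shape else name,
      seed = sub_seed, stringsAsFactors = FALSE)
  }
  emit("sphere", generate_structure(toy_spec("sphere", radius = 20, seed = seed)),
       sub_seed = seed + 1)
  emit("dumbbell",
       generate_structure(toy_spec("dumbbell", radius = 10, separation = 60,
                                   seed = seed)),
       sub_seed = seed + 2)
  emit("flat_dimer",
       generate_structure(toy_spec("two_domain_c2_dimer", twist = 0,
                                   seed = seed)),
       sub_seed = seed + 3)
  emit("twisted_dimer",
       generate_structure(toy_spec("two_domain_c2_dimer", twist = 30,
                                   seed = seed)),
       sub_seed = seed + 4)
  emit("dimer_linkers",
       generate_structure(toy_spec("two_domain_c2_dimer", twist = 0,
                                   include_linkers = TRUE, seed = seed)),
       sub_seed = seed + 5)
  # degenerate case: the lower body is pseudo-four-fold, so the rotation
  # search against this curve admits two minima ~90 degrees apart
  comp <- toy_dimer_components(toy_spec("two_domain_c2_dimer",
                                        n_beads = 150, seed = seed))
  lowx <- toy_cross_dimer(spacing = 4.5, seed = seed)
  contact <- max(coords(lowx)[, 3]) - min(coords(comp$upper)[, 3])
  m1 <- place_components(comp$upper, lowx, 30, ceiling(contact) + 2)
  tr <- attr(m1, "truth")
  tr$shape <- "degenerate_two_minima"
  attr(m1, "truth") <- tr
  emit("two_minima", m1, sub_seed = seed + 6)
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest
}
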