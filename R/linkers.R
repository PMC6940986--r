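# Dummy-residue completion of the disordered parts the rigid bodies lack:
# the interdomain linker between the two folded modules and the C-terminal
# tail. Chains are grown as biased self-avoiding walks at 3.8 A per step,
# steered toward the end anchor when one exists, and selected against the
# scattering curve.

#' Linker specification
#'
#' @param start numeric length-3 start-anchor position (Angstrom), the
#'   residue the chain grows from.
#' @param end optional end-anchor position; `NULL` for a free tail.
#' @param n_residues number of dummy residues to place (>= 1).
#' @param context optional [coord_model()] (or n x 3 matrix) the chain must
#'   not clash with.
#' @param chain chain id given to sampled beads.
#' @param resno_start first residue number of the sampled stretch.
#' @return list of class `linker_spec`.
#' @export
linker_spec <- function(start, end = NULL, n_residues, context = NULL,
                        chain = "L", resno_start = 1L) {
  stopifnot(length(start) == 3, n_residues >= 1)
  if (!is.null(end)) {
    stopifnot(length(end) == 3)
    gap <- sqrt(sum((end - start)^2))
    if (gap > 3.8 * (n_residues + 1))
      stop(sprintf(
        "infeasible linker: anchor gap %.1f A exceeds contour %.1f A (%d residues)",
        gap, 3.8 * (n_residues + 1), n_residues))
  }
  structure(list(start = start, end = end, n_residues = as.integer(n_residues),
                 context = context, chain = chain,
                 resno_start = as.integer(resno_start)),
            class = "linker_spec")
}

#' Residue ranges of the target construct's disordered parts
#'
#' The interdomain linker spans residues 512-544 (33 residues between the
#' end of the nucleotide-sensing module and the start of the
#' cyclic-nucleotide-homology domain) and the C-terminal tail residues
#' 731-775 (45 residues past the folded domain).
#'
#' @return list with `linker` and `tail`, each holding `range` and `n`.
#' @export
disordered_segments <- function() {
  list(linker = list(range = c(512L, 544L), n = 33L),
       tail = list(range = c(731L, 775L), n = 45L))
}

# unit vector uniform in a cone of half-angle `half` (deg) about axis u
cone_dir <- function(u, half) {
  u <- u / sqrt(sum(u^2))
  cmin <- cos(half * pi / 180)
  ct <- runif(1, cmin, 1)
  st <- sqrt(1 - ct^2)
  ph <- runif(1, 0, 2 * pi)
  # orthonormal frame around u
  p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- p - sum(p * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  ct * u + st * (cos(ph) * e1 + sin(ph) * e2)
}

#' Sample self-avoiding linker/tail conformations
#'
#' Beads are placed 3.8 Angstrom apart; for end-anchored chains the growth
#' direction is drawn from a cone steered toward the end anchor, narrowing
#' from a 90-degree half-angle when slack (remaining contour > 2 x
#' remaining gap) to 15 degrees when taut, and the final bead is solved
#' geometrically on the circle satisfying both its bond and the bond to the
#' anchor, so accepted chains close exactly. Free tails grow in uniform
#' random directions. Chains clashing with themselves or the context
#' (< 3 Angstrom) are rejected. Deterministic per seed.
#'
#' @param spec a [linker_spec()].
#' @param n_chains number of accepted chains wanted.
#' @param n_trials maximum growth attempts.
#' @param seed integer seed.
#' @param cfg configuration list.
#' @return list of n x 3 coordinate matrices (one per accepted chain), with
#'   attribute `acceptance_rate`.
#' @export
sample_linker <- function(spec, n_chains = 1, n_trials = 1000, seed = 1,
                          cfg = saxs_config()) {
  stopifnot(inherits(spec, "linker_spec"))
  bond <- cfg$linker$bond
  clash <- cfg$linker$clash_dist
  ctx <- if (is.null(spec$context)) NULL else as_points(spec$context)
  n <- spec$n_residues
  anchored <- !is.null(spec$end)
  chains <- list()
  trials <- 0L
  withr::with_seed(seed, {
    while (length(chains) < n_chains && trials < n_trials) {
      trials <- trials + 1L
      X <- matrix(NA_real_, n, 3)
      prev <- spec$start
      ok <- TRUE
      grow_to <- if (anchored) n - 1L else n
      for (i in seq_len(max(grow_to, 0L))) {
        placed <- FALSE
        # per-step retries: whole-chain rejection alone leaves long chains
        # with vanishing acceptance
        for (try in 1:30) {
          if (anchored) {
            gapv <- spec$end - prev
            gap <- sqrt(sum(gapv^2))
            remaining <- (n + 1 - i) * bond  # bonds left incl. bond to anchor
            slack <- remaining / max(gap, 1e-9)
            half <- if (slack > 2) cfg$linker$cone_wide else
              cfg$linker$cone_narrow + (cfg$linker$cone_wide - cfg$linker$cone_narrow) *
                max(0, (slack - 1)) / 1
            half <- min(cfg$linker$cone_wide, max(cfg$linker$cone_narrow, half))
            u <- cone_dir(gapv, half)
          } else {
            u <- rnorm(3); u <- u / sqrt(sum(u^2))
          }
          p <- prev + bond * u
          if (i > 2 && any(rowSums(sweep(X[1:(i - 2), , drop = FALSE], 2, p)^2) < clash^2)) next
          if (!is.null(ctx) && any(rowSums(sweep(ctx, 2, p)^2) < clash^2)) next
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
        X[i, ] <- p
        prev <- p
      }
      if (!ok) next
      if (anchored) {
        # close the chain: bead n must sit at `bond` from bead n-1 and from
        # the end anchor -> a point on the sphere-sphere intersection circle
        a <- if (n >= 2) X[n - 1, ] else spec$start
        bvec <- spec$end - a
        d <- sqrt(sum(bvec^2))
        if (d > 2 * bond || d < 1e-9) next
        mid <- a + bvec / 2
        rad <- sqrt(bond^2 - (d / 2)^2)
        u <- bvec / d
        p1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        e1 <- p1 - sum(p1 * u) * u; e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
                u[1] * e1[2] - u[2] * e1[1])
        ph <- runif(1, 0, 2 * pi)
        p <- mid + rad * (cos(ph) * e1 + sin(ph) * e2)
        if (n > 2 && any(rowSums(sweep(X[1:(n - 2), , drop = FALSE], 2, p)^2) < clash^2)) next
        if (!is.null(ctx) && any(rowSums(sweep(ctx, 2, p)^2) < clash^2)) next
        X[n, ] <- p
      }
      chains[[length(chains) + 1L]] <- X
    }
  })
  if (!length(chains))
    stop(sprintf("no accepted chains in %d trials (acceptance rate 0)", trials))
  attr(chains, "acceptance_rate") <- length(chains) / trials
  chains
}

#' Complete a symmetric assembly with linkers and tails
#'
#' Samples `ensemble_size` linker/tail conformer sets for protomer 1,
#' mirrors each by the assembly's C2 operation (so the hybrid stays exactly
#' symmetric), scores every completed model against the curve with
#' [fit_scale_chi2()], and returns the best single conformer.
#'
#' @param assembly combined [coord_model()] of the rigid assembly (C2 about
#'   z, as produced by [assembly_model()] / [place_components()]).
#' @param specs list of [linker_spec()]s for protomer 1 (e.g. one
#'   interdomain linker and one free tail).
#' @param data a [saxs_curve()].
#' @param ensemble_size conformer sets to try.
#' @param seed integer seed.
#' @param cfg configuration list.
#' @return list of class `hybrid_model`: `model` (assembly + linker beads,
#'   mirrored chains), `chi2_full`, `chi2_assembly`, `linkers` (list of
#'   protomer-1 chains used).
#' @export
build_hybrid <- function(assembly, specs, data, ensemble_size = 20, seed = 1,
                         cfg = saxs_config()) {
  Xa <- coords(assembly)
  fit0 <- fit_scale_chi2(debye_intensity(assembly, data$q, method = "exact"),
                         data)
  best <- NULL
  for (k in seq_len(ensemble_size)) {
    set_list <- lapply(seq_along(specs), function(j) {
      sp <- specs[[j]]
      sp$context <- Xa
      sample_linker(sp, n_chains = 1, n_trials = 2000,
                    seed = seed + 1000L * k + j, cfg = cfg)[[1]]
    })
    Xl <- do.call(rbind, set_list)
    Xfull <- rbind(Xa, Xl, c2_z(Xl))
    fit <- fit_scale_chi2(debye_intensity(Xfull, data$q, method = "exact"),
                          data)
    if (is.null(best) || fit$chi2 < best$chi2_full)
      best <- list(chains = set_list, chi2_full = fit$chi2)
  }
  pr <- assembly$particles
  add <- do.call(rbind, lapply(seq_along(best$chains), function(j) {
    X <- best$chains[[j]]
    sp <- specs[[j]]
    rn <- seq(sp$resno_start, length.out = nrow(X))
    rbind(
      data.frame(chain = sp$chain, resno = rn, insert = "", resid = "GLY",
                 x = X[, 1], y = X[, 2], z = X[, 3], mass = 110, f = 1,
                 stringsAsFactors = FALSE),
      {
        Xm <- c2_z(X)
        data.frame(chain = tolower(sp$chain), resno = rn, insert = "",
                   resid = "GLY", x = Xm[, 1], y = Xm[, 2], z = Xm[, 3],
                   mass = 110, f = 1, stringsAsFactors = FALSE)
      })
  }))
  model <- coord_model(rbind(pr, add))
  structure(list(model = model, chi2_full = best$chi2_full,
                 chi2_assembly = fit0$chi2, linkers = best$chains),
            class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf("<hybrid_model> chi2 full = %.3f (assembly alone %.3f), %d linker chains/protomer\n",
              x$chi2_full, x$chi2_assembly, length(x$linkers)))
  invisible(x)
}
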