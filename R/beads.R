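# Ab initio dummy-residue shape reconstruction: a chain-compatible bead
# model (one bead per residue, 3.8 A virtual bonds) is annealed against the
# experimental curve, and independent runs are aligned, filtered and
# averaged with the normalized spatial discrepancy as the metric.

#' Annealing schedule
#'
#' @param T0_factor initial temperature as a multiple of the starting
#'   energy.
#' @param cooling multiplicative temperature factor per stage, in (0, 1).
#' @param steps_per_stage Metropolis moves per stage; `NULL` means
#'   100 * n_residues.
#' @param max_stages maximum number of stages.
#' @param patience stop after this many stages without improving the best
#'   energy.
#' @param seed integer seed.
#' @return list of class `anneal_schedule`.
#' @export
anneal_schedule <- function(T0_factor = 10, cooling = 0.9,
                            steps_per_stage = NULL, max_stages = 60,
                            patience = 15, seed = 1) {
  stopifnot(cooling > 0, cooling < 1, max_stages >= 1)
  structure(list(T0_factor = T0_factor, cooling = cooling,
                 steps_per_stage = steps_per_stage, max_stages = max_stages,
                 patience = patience, seed = seed),
            class = "anneal_schedule")
}

# Random self-avoiding walk of n beads (bond length `bond`) inside a sphere
# of radius rmax, used as the annealing start.
random_saw <- function(n, bond, rmax, clash = 3.0, max_restart = 200) {
  for (attempt in seq_len(max_restart)) {
    X <- matrix(NA_real_, n, 3)
    X[1, ] <- runif(3, -rmax / 2, rmax / 2)
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (try in 1:30) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        p <- X[i - 1, ] + bond * u
        if (sum(p^2) > rmax^2) next
        if (i > 2) {
          d2 <- rowSums(sweep(X[1:(i - 2), , drop = FALSE], 2, p)^2)
          if (any(d2 < clash^2)) next
        }
        X[i, ] <- p; placed <- TRUE; break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(X)
  }
  stop("could not build an initial self-avoiding walk")
}

#' Ab initio dummy-residue reconstruction against a scattering curve
#'
#' Starting from a random self-avoiding walk of `n_residues` beads inside a
#' search sphere of radius Dmax/2, single-bead Gaussian moves (1 Angstrom)
#' are accepted by the Metropolis rule on
#' E = chi2(Debye curve vs data) + w_bond * sum (d_adj - 3.8)^2 +
#' w_clash * (# non-adjacent pairs closer than 3 Angstrom), with
#' stage-wise geometric cooling. Deterministic for a given schedule seed.
#'
#' @param curve a [saxs_curve()] from which a Guinier Rg (hence the Dmax/2
#'   search radius, via 2 Rg as the Dmax guess when none is given) is
#'   computable.
#' @param n_residues number of beads (>= 10).
#' @param schedule an [anneal_schedule()].
#' @param dmax search-sphere diameter; default the curve's Dmax via
#'   [find_dmax()] would be expensive, so 2 * Guinier Rg * 1.3 is used
#'   unless given.
#' @param cfg configuration list.
#' @return list of class `bead_model`: `model` (a [coord_model()]), `chi2`,
#'   `energy`, `converged`, `search_radius`, `schedule`.
#' @export
reconstruct_beads <- function(curve, n_residues, schedule = anneal_schedule(),
                              dmax = NULL, cfg = saxs_config()) {
  stopifnot(n_residues >= 10)
  g <- guinier_fit(curve, cfg = cfg)
  if (is.null(dmax)) dmax <- 2 * g$Rg * 1.3
  rsearch <- dmax / 2
  b <- cfg$beads
  sps <- if (is.null(schedule$steps_per_stage)) 100L * n_residues else
    schedule$steps_per_stage
  res <- withr::with_seed(schedule$seed, {
    X0 <- random_saw(n_residues, b$bond_target, rsearch, b$clash_dist)
    anneal_cpp(X0, curve$q, curve$I, curve$sigma, b$w_bond, b$w_clash,
               b$bond_target, b$clash_dist, 1.1 * rsearch, b$step_sd,
               schedule$T0_factor, schedule$cooling, as.integer(sps),
               as.integer(schedule$max_stages),
               as.integer(schedule$patience))
  })
  converged <- res$chi2 <= b$chi2_ceiling
  if (!converged)
    warning(sprintf("reconstruction did not converge: chi2 = %.2f > %.1f",
                    res$chi2, b$chi2_ceiling))
  out <- list(model = bead_model(res$X), chi2 = res$chi2,
              energy = res$energy, converged = converged,
              search_radius = rsearch, schedule = schedule)
  class(out) <- "bead_reconstruction"
  out
}

#' @export
print.bead_reconstruction <- function(x, ...) {
  cat(sprintf("<bead_reconstruction> %d beads, chi2 = %.3f%s\n",
              nrow(x$model$particles), x$chi2,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

as_points <- function(m) {
  if (inherits(m, "bead_reconstruction")) m <- m$model
  if (inherits(m, "coord_model")) coords(m) else as.matrix(m)
}

mean_nn_dist <- function(X) {
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  mean(apply(D, 1, min))
}

nsd_raw <- function(A, B) {
  DA <- mean_nn_dist(A); DB <- mean_nn_dist(B)
  D <- pracma::distmat(A, B)
  ab <- apply(D, 1, min); ba <- apply(D, 2, min)
  sqrt(0.5 * (sum(ab^2) / (nrow(A) * DB^2) + sum(ba^2) / (nrow(B) * DA^2)))
}

kabsch <- function(P, Q) {
  # rotation R minimizing ||R P - Q|| for centred point sets (rows)
  S <- svd(crossprod(Q, P))
  d <- sign(det(S$u %*% t(S$v)))
  S$u %*% diag(c(1, 1, d)) %*% t(S$v)
}

#' Optimal rigid superposition of two point-set models
#'
#' Centres both models, enumerates the four proper principal-axis sign
#' combinations (eight with inversion when allowed), refines each by
#' iterated nearest-neighbour correspondence and least-squares rotation
#' (10 iterations), and returns the transform minimizing the NSD.
#'
#' @param A,B models ([coord_model()], reconstruction results, or n x 3
#'   matrices); B is moved onto A.
#' @param allow_inversion also try the mirror image of B.
#' @return list with `R` (rotation applied to centred B), `center_A`,
#'   `center_B`, `inverted`, `nsd`, and `B_aligned` (transformed copy of
#'   B's coordinates).
#' @export
align_models <- function(A, B, allow_inversion = FALSE) {
  Ax <- as_points(A); Bx <- as_points(B)
  cA <- colMeans(Ax); cB <- colMeans(Bx)
  A0 <- sweep(Ax, 2, cA); B0 <- sweep(Bx, 2, cB)
  paxes <- function(X) {
    e <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
    V <- e$vectors
    if (det(V) < 0) V[, 3] <- -V[, 3]
    V
  }
  degenerate <- function(X) {
    ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)$values
    ev[2] < 1e-8 * max(ev, 1e-12)
  }
  if (degenerate(A0) || degenerate(B0)) {
    warning("degenerate (collinear) model: centroid-only alignment")
    return(list(R = diag(3), center_A = cA, center_B = cB, inverted = FALSE,
                nsd = nsd_raw(A0, B0), B_aligned = sweep(B0, 2, cA, "+")))
  }
  VA <- paxes(A0); VB <- paxes(B0)
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  best <- NULL
  for (inv in if (allow_inversion) c(FALSE, TRUE) else FALSE) {
    Bi <- if (inv) -B0 else B0
    VBi <- paxes(Bi)
    for (s in signs) {
      R0 <- VA %*% diag(s) %*% t(VBi)
      Bt <- Bi %*% t(R0)
      R <- R0
      for (it in 1:10) {
        # nearest-neighbour correspondence, then least-squares rotation
        D <- pracma::distmat(Bt, A0)
        j <- apply(D, 1, which.min)
        Rup <- kabsch(Bt, A0[j, , drop = FALSE])
        R <- Rup %*% R
        Bt <- Bi %*% t(R)
      }
      v <- nsd_raw(A0, Bt)
      if (is.null(best) || v < best$nsd)
        best <- list(R = R, inverted = inv, nsd = v, Bt = Bt)
    }
  }
  list(R = best$R, center_A = cA, center_B = cB, inverted = best$inverted,
       nsd = best$nsd, B_aligned = sweep(best$Bt, 2, cA, "+"))
}

#' Normalized spatial discrepancy between two models
#'
#' `NSD^2 = 1/2 ( (1/(N_A d_B^2)) sum_a min_b |a-b|^2 +
#' (1/(N_B d_A^2)) sum_b min_a |b-a|^2 )`, where d_X is the average
#' nearest-neighbour distance within model X. Zero for coincident point
#' sets; around 1 when the sets differ systematically at the scale of their
#' own sampling. Computed after optimal superposition unless `align =
#' FALSE`.
#'
#' @param A,B models or n x 3 matrices.
#' @param align superpose first with [align_models()].
#' @param allow_inversion passed to the alignment.
#' @return non-negative scalar.
#' @export
nsd <- function(A, B, align = TRUE, allow_inversion = FALSE) {
  Ax <- as_points(A); Bx <- as_points(B)
  if (!align) return(nsd_raw(Ax, Bx))
  align_models(Ax, Bx, allow_inversion = allow_inversion)$nsd
}

#' Align, filter and average an ensemble of reconstructions
#'
#' Computes all-pairs NSD, discards models whose mean NSD to the others
#' exceeds the ensemble mean by more than two standard deviations, aligns
#' the survivors onto the most typical model (lowest mean NSD), and builds
#' an occupancy-grid consensus (2 Angstrom voxels) thresholded to enclose
#' the median model volume.
#'
#' @param models list of >= 2 reconstructions (or [coord_model()]s /
#'   matrices) built against the same curve.
#' @param voxel consensus voxel edge, Angstrom.
#' @return list of class `ensemble_result`: `nsd_matrix`, `mean_nsd`
#'   (over surviving pairs), `kept`, `reference` (index into `models`),
#'   `averaged_model` (a [coord_model()] of occupied voxel centres).
#' @export
average_ensemble <- function(models, voxel = 2) {
  k <- length(models)
  if (k < 2) stop("need at least 2 models")
  pts <- lapply(models, as_points)
  M <- matrix(0, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    M[i, j] <- M[j, i] <- nsd(pts[[i]], pts[[j]])
  mean_i <- rowSums(M) / (k - 1)
  thr <- mean(mean_i) + 2 * sd(mean_i)
  kept <- which(mean_i <= thr)
  mean_kept <- rowSums(M[kept, kept, drop = FALSE]) / pmax(length(kept) - 1, 1)
  ref <- kept[which.min(mean_kept)]
  aligned <- lapply(kept, function(i) {
    if (i == ref) sweep(pts[[i]], 2, colMeans(pts[[ref]])) else
      sweep(align_models(pts[[ref]], pts[[i]])$B_aligned, 2,
            colMeans(pts[[ref]]))
  })
  # occupancy grid over all aligned survivors
  occ <- list()
  for (X in aligned) {
    key <- paste(floor(X[, 1] / voxel), floor(X[, 2] / voxel),
                 floor(X[, 3] / voxel))
    for (kk in unique(key)) occ[[kk]] <- (occ[[kk]] %||% 0L) + 1L
  }
  counts <- unlist(occ)
  target <- median(vapply(aligned, function(X) {
    length(unique(paste(floor(X[, 1] / voxel), floor(X[, 2] / voxel),
                        floor(X[, 3] / voxel))))
  }, 0))
  # keep the most-occupied voxels down to the median single-model volume
  ord <- order(-counts)
  sel <- names(counts)[ord[seq_len(min(target, length(counts)))]]
  cen <- do.call(rbind, lapply(strsplit(sel, " "), as.numeric))
  Xc <- (cen + 0.5) * voxel
  out <- list(nsd_matrix = M,
              mean_nsd = mean(M[kept, kept][upper.tri(M[kept, kept])]),
              kept = kept, reference = ref,
              averaged_model = bead_model(Xc, chain = "A"),
              n_voxels = nrow(Xc), voxel = voxel)
  class(out) <- "ensemble_result"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d/%d models kept, mean NSD = %.3f, reference = %d\n",
              length(x$kept), nrow(x$nsd_matrix), x$mean_nsd, x$reference))
  invisible(x)
}
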