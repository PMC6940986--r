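# C2-symmetric rigid-body assembly search: place two homodimers on a shared
# 2-fold axis, scan the rotation about the axis and the axial separation,
# rank clash-free candidates by reduced chi-square against the curve, gate
# by a threshold, and break near-ties by morphological complementarity
# (buried interface area minus a near-clash penalty).

rot_axis_angle <- function(R) {
  # angle (deg) and unit axis of a proper rotation matrix
  tr <- sum(diag(R))
  ang <- acos(pmin(pmax((tr - 1) / 2, -1), 1)) * 180 / pi
  if (ang > 179.9999) {
    # near-180: axis from the eigenvector of (R + I)
    M <- (R + diag(3)) / 2
    j <- which.max(diag(M))
    ax <- M[, j] / sqrt(M[j, j])
  } else {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    n <- sqrt(sum(ax^2))
    if (n < 1e-12) ax <- c(0, 0, 1) else ax <- ax / n
  }
  list(angle = ang, axis = ax)
}

#' Detect the 2-fold axis of a homodimer
#'
#' Finds the least-squares rotation mapping one chain onto the other over
#' their common residue numbers, and accepts it as a C2 operation when the
#' rotation angle is within 5 degrees of 180. The axis passes through the
#' midpoint of the two chain centroids with a deterministic sign (positive
#' z component, ties broken toward +x then +y).
#'
#' @param dimer a [coord_model()] with both chains.
#' @param chain_pair length-2 character vector of chain ids.
#' @return list of class `symmetry_axis`: `direction` (unit 3-vector),
#'   `center`, `angle` (degrees), `rmsd` of the superposition.
#' @export
detect_c2_axis <- function(dimer, chain_pair = NULL) {
  pr <- dimer$particles
  chains <- unique(pr$chain)
  if (is.null(chain_pair)) {
    if (length(chains) != 2) stop("give chain_pair for models with != 2 chains")
    chain_pair <- chains
  }
  A <- pr[pr$chain == chain_pair[1], ]
  B <- pr[pr$chain == chain_pair[2], ]
  common <- intersect(paste(A$resno, A$insert), paste(B$resno, B$insert))
  if (length(common) < 20) stop("fewer than 20 matched residues between chains")
  A <- A[match(common, paste(A$resno, A$insert)), ]
  B <- B[match(common, paste(B$resno, B$insert)), ]
  XA <- as.matrix(A[, c("x", "y", "z")]); XB <- as.matrix(B[, c("x", "y", "z")])
  cA <- colMeans(XA); cB <- colMeans(XB)
  R <- kabsch(sweep(XA, 2, cA), sweep(XB, 2, cB))
  aa <- rot_axis_angle(R)
  if (abs(aa$angle - 180) > 5)
    stop(sprintf("not a C2 dimer: rotation angle %.1f deg", aa$angle))
  dir <- aa$axis
  if (dir[3] < 0 || (dir[3] == 0 && (dir[1] < 0 || (dir[1] == 0 && dir[2] < 0))))
    dir <- -dir
  fit <- sweep(sweep(XA, 2, cA) %*% t(R), 2, cB, "+")
  structure(list(direction = dir, center = (cA + cB) / 2, angle = aa$angle,
                 rmsd = sqrt(mean(rowSums((fit - XB)^2)))),
            class = "symmetry_axis")
}

#' @export
print.symmetry_axis <- function(x, ...) {
  cat(sprintf("<symmetry_axis> angle %.2f deg, axis (%.3f, %.3f, %.3f), rmsd %.3g A\n",
              x$angle, x$direction[1], x$direction[2], x$direction[3], x$rmsd))
  invisible(x)
}

# Rotation taking unit vector u onto unit vector v.
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 deg about any axis perpendicular to u
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- p - sum(p * u) * u; w <- w / sqrt(sum(w^2))
    return(2 * outer(w, w) - diag(3))
  }
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

# Canonical pose: axis mapped to +z, centroid at origin.
canonicalize_dimer <- function(model, axis = NULL) {
  if (is.null(axis)) axis <- detect_c2_axis(model)
  X <- coords(model)
  R <- rotation_between(axis$direction, c(0, 0, 1))
  Xc <- sweep(X, 2, colMeans(X)) %*% t(R)
  pr <- model$particles
  pr$x <- Xc[, 1]; pr$y <- Xc[, 2]; pr$z <- Xc[, 3]
  m <- model; m$particles <- pr
  m
}

#' Enumerate C2-symmetric two-dimer assemblies on a shared axis
#'
#' Both input dimers must pass [detect_c2_axis()]; each is moved to its
#' canonical pose (2-fold axis along +z, centroid at the origin) so the two
#' axes are collinear, with the first body above the second. The rotation
#' phi of the lower body about the axis is scanned over `[0, 180)` degrees
#' (C2 symmetry makes phi and phi + 180 equivalent) and the axial centroid
#' separation t over contact - 5 to contact + 25 Angstrom, where contact is
#' the separation at which the axial extents just meet. Candidates with any
#' inter-body pair closer than 3 Angstrom are clash-flagged and excluded
#' from chi-square ranking; survivors are scored by [fit_scale_chi2()] of
#' the combined Debye curve against the data.
#'
#' @param upper,lower [coord_model()] dimers (e.g. the nucleotide-sensing
#'   module pair above, the cyclic-nucleotide-homology pair below).
#' @param data a [saxs_curve()].
#' @param phi_step,t_step grid steps (degrees, Angstrom).
#' @param t_range optional explicit axial-separation range overriding the
#'   contact-derived one.
#' @param cfg configuration list.
#' @return data.frame of class `assembly_candidates`, sorted by chi2
#'   (clash-free first): columns `phi`, `t`, `chi2`, `scale`, `clash_count`.
#'   The canonical bodies are attached as attributes `upper` and `lower`.
#' @export
enumerate_assemblies <- function(upper, lower, data,
                                 phi_step = NULL, t_step = NULL,
                                 t_range = NULL, cfg = saxs_config()) {
  phi_step <- phi_step %||% cfg$assembly$phi_step
  t_step <- t_step %||% cfg$assembly$t_step
  up <- canonicalize_dimer(upper)
  lo <- canonicalize_dimer(lower)
  Xu <- coords(up); Xl <- coords(lo)
  if (is.null(t_range)) {
    contact <- max(Xl[, 3]) - min(Xu[, 3])
    t_range <- c(contact - cfg$assembly$t_below, contact + cfg$assembly$t_above)
  }
  phis <- seq(0, 180 - phi_step, by = phi_step)
  ts <- seq(t_range[1], t_range[2], by = t_step)
  sc <- scan_phi_t_cpp(Xu, Xl, data$q, data$I, data$sigma, phis, ts,
                       cfg$assembly$clash_dist)
  out <- data.frame(
    phi = rep(phis, times = length(ts)),
    t = rep(ts, each = length(phis)),
    chi2 = as.vector(sc$chi2),
    scale = as.vector(sc$scale),
    clash_count = as.vector(sc$clash)
  )
  if (all(out$clash_count > 0))
    warning("all candidates clash: empty survivor set")
  out <- out[order(out$clash_count > 0, out$chi2), ]
  rownames(out) <- NULL
  attr(out, "upper") <- up
  attr(out, "lower") <- lo
  class(out) <- c("assembly_candidates", "data.frame")
  out
}

#' Build the coordinate model of one assembly candidate
#'
#' @param candidates an [enumerate_assemblies()] result (or any object with
#'   attributes `upper` and `lower` holding canonical bodies).
#' @param phi,t placement parameters (degrees, Angstrom).
#' @return combined [coord_model()].
#' @export
assembly_model <- function(candidates, phi, t) {
  place_components(attr(candidates, "upper"), attr(candidates, "lower"),
                   phi, t)
}

# Local minima of the chi2(phi) profile (min over t per phi), circular in
# phi with period 180.
phi_minima <- function(cands) {
  ok <- cands[cands$clash_count == 0 & is.finite(cands$chi2), ]
  if (nrow(ok) == 0) return(ok)
  prof <- do.call(rbind, lapply(split(ok, ok$phi), function(d)
    d[which.min(d$chi2), ]))
  prof <- prof[order(prof$phi), ]
  n <- nrow(prof)
  if (n < 3) return(prof)
  is_min <- vapply(seq_len(n), function(i) {
    l <- if (i == 1) n else i - 1
    r <- if (i == n) 1 else i + 1
    prof$chi2[i] <= prof$chi2[l] && prof$chi2[i] <= prof$chi2[r]
  }, logical(1))
  out <- prof[is_min, ]
  out <- out[order(out$chi2), ]
  # keep only minima at least 2 grid steps (circular) from a better one
  step <- min(diff(sort(unique(prof$phi))))
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    d <- abs(out$phi[i] - out$phi[seq_len(i - 1)][keep[seq_len(i - 1)]]) %% 180
    d <- pmin(d, 180 - d)
    if (length(d) && min(d) < 2 * step) keep[i] <- FALSE
  }
  out[keep, ]
}

#' Three-scenario symmetric assembly search
#'
#' Scenario 1 treats both dimers as rigid bodies and delegates to
#' [enumerate_assemblies()]. Scenarios 2 and 3 predefine one dimer (the
#' upper and the lower respectively) and treat a single subunit of the
#' other as free: its orientation (three Euler-like angles) and radial
#' offset from the axis are scanned on coarse grids, and its C2 mate is
#' generated by the predefined partner's 2-fold operation, so every
#' candidate remains exactly symmetric. Candidates are gated by
#' `chi2_gate`; the two best distinct rotation minima are reported when
#' both pass the gate (symmetric searches often admit a rotamer pair of
#' near-equivalent solutions).
#'
#' @param scenario 1, 2 or 3.
#' @param upper,lower for scenario 1, both dimers; for scenario 2 `lower`
#'   may be a free monomer, for scenario 3 `upper` may be.
#' @param data a [saxs_curve()].
#' @param chi2_gate acceptance threshold on reduced chi-square (default
#'   2.0; use 2.5 for complexes carrying a phosphatase partner).
#' @param phi_step,t_step,angle_step,radial_offsets grid controls; the
#'   angle grid and radial offsets apply to scenarios 2-3 only.
#' @param cfg configuration list.
#' @return list of class `scenario_result`: `candidates` (gated, sorted),
#'   `all` (ungated), `best`, `minima` (the distinct phi minima passing the
#'   gate, at most 2), `scenario`.
#' @export
scenario_search <- function(scenario, upper, lower, data, chi2_gate = NULL,
                            phi_step = NULL, t_step = NULL, angle_step = NULL,
                            radial_offsets = NULL, cfg = saxs_config()) {
  stopifnot(scenario %in% 1:3)
  chi2_gate <- chi2_gate %||% cfg$assembly$chi2_gate
  if (scenario == 1) {
    cands <- enumerate_assemblies(upper, lower, data, phi_step, t_step,
                                  cfg = cfg)
  } else {
    angle_step <- angle_step %||% cfg$assembly$angle_step
    fixed <- if (scenario == 2) upper else lower
    free <- if (scenario == 2) lower else upper
    fx <- canonicalize_dimer(fixed)
    # free subunit: single chain, centred
    Xf <- coords(free)
    Xf <- sweep(Xf, 2, colMeans(Xf))
    if (is.null(radial_offsets)) {
      r0 <- mean(sqrt(rowSums(sweep(coords(fx), 2, colMeans(coords(fx)))[, 1:2]^2)))
      radial_offsets <- seq(max(0, r0 - 2 * cfg$assembly$radial_step),
                            r0 + 2 * cfg$assembly$radial_step,
                            by = cfg$assembly$radial_step)
    }
    angs <- seq(0, 360 - angle_step, by = angle_step)
    angs_b <- seq(0, 180, by = angle_step)
    rows <- list()
    best_bodies <- NULL
    for (a1 in angs) for (b1 in angs_b) for (c1 in angs) {
      Rf <- rot_z(a1) %*% rot_x(b1) %*% rot_z(c1)
      Xr <- Xf %*% t(Rf)
      for (roff in radial_offsets) {
        Xp <- sweep(Xr, 2, c(roff, 0, 0), "+")
        pair <- rbind(Xp, c2_z(Xp))
        # pair plays the role of the mobile body on the shared axis
        prl <- bead_model(pair, chain = rep(c("Y", "Z"), each = nrow(Xp)))
        cn <- tryCatch(
          enumerate_assemblies_raw(fx, prl, data, phi_step, t_step, cfg),
          error = function(e) NULL)
        if (is.null(cn)) next
        cn$a1 <- a1; cn$b1 <- b1; cn$c1 <- c1; cn$radial <- roff
        k <- which(cn$clash_count == 0 & is.finite(cn$chi2))
        if (length(k)) {
          rows[[length(rows) + 1L]] <- cn[k, ]
          if (is.null(best_bodies) ||
              min(cn$chi2[k]) < best_bodies$chi2) {
            best_bodies <- list(upper = attr(cn, "upper"),
                                lower = attr(cn, "lower"),
                                chi2 = min(cn$chi2[k]))
          }
        }
      }
    }
    if (!length(rows)) {
      warning("no clash-free candidates in scenarios 2/3 scan")
      cands <- data.frame(phi = numeric(), t = numeric(), chi2 = numeric(),
                          scale = numeric(), clash_count = integer())
    } else {
      cands <- do.call(rbind, rows)
      cands <- cands[order(cands$chi2), ]
      rownames(cands) <- NULL
      attr(cands, "upper") <- best_bodies$upper
      attr(cands, "lower") <- best_bodies$lower
      class(cands) <- c("assembly_candidates", "data.frame")
    }
  }
  ok <- cands[cands$clash_count == 0 & is.finite(cands$chi2), ]
  gated <- ok[ok$chi2 < chi2_gate, ]
  mins <- phi_minima(cands)
  mins <- mins[mins$chi2 < chi2_gate, , drop = FALSE]
  if (nrow(mins) > 2) mins <- mins[1:2, ]
  structure(list(candidates = gated, all = cands,
                 best = if (nrow(ok)) ok[1, ] else NULL,
                 minima = mins, scenario = scenario,
                 chi2_gate = chi2_gate),
            class = "scenario_result")
}

# scenario 2/3 helper: like enumerate_assemblies but the mobile "dimer" is
# already canonical (constructed symmetric about z), skip axis detection
enumerate_assemblies_raw <- function(up_canon, lo_canon, data, phi_step,
                                     t_step, cfg) {
  phi_step <- phi_step %||% cfg$assembly$phi_step
  t_step <- t_step %||% cfg$assembly$t_step
  Xu <- coords(up_canon); Xl <- coords(lo_canon)
  Xl <- sweep(Xl, 2, c(0, 0, mean(Xl[, 3])))  # centre axially only
  contact <- max(Xl[, 3]) - min(Xu[, 3])
  ts <- seq(contact - cfg$assembly$t_below, contact + cfg$assembly$t_above,
            by = t_step)
  phis <- seq(0, 180 - phi_step, by = phi_step)
  sc <- scan_phi_t_cpp(Xu, Xl, data$q, data$I, data$sigma, phis, ts,
                       cfg$assembly$clash_dist)
  pr <- lo_canon$particles; pr$x <- Xl[, 1]; pr$y <- Xl[, 2]; pr$z <- Xl[, 3]
  lo2 <- lo_canon; lo2$particles <- pr
  out <- data.frame(
    phi = rep(phis, times = length(ts)),
    t = rep(ts, each = length(phis)),
    chi2 = as.vector(sc$chi2),
    scale = as.vector(sc$scale),
    clash_count = as.vector(sc$clash)
  )
  attr(out, "upper") <- up_canon
  attr(out, "lower") <- lo2
  class(out) <- c("assembly_candidates", "data.frame")
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> scenario %d: %d candidates pass chi2 < %.2f\n",
              x$scenario, nrow(x$candidates), x$chi2_gate))
  if (!is.null(x$best))
    cat(sprintf("  best: phi = %.1f deg, t = %.1f A, chi2 = %.3f\n",
                x$best$phi, x$best$t, x$best$chi2))
  if (nrow(x$minima) > 1)
    cat(sprintf("  second minimum: phi = %.1f deg, chi2 = %.3f\n",
                x$minima$phi[2], x$minima$chi2[2]))
  invisible(x)
}

# Shrake-Rupley solvent-accessible surface area per particle.
sasa_points <- function(n) {
  # Fibonacci sphere
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

sasa <- function(X, radii, probe, n_points) {
  S <- sasa_points(n_points)
  n <- nrow(X)
  rs <- radii + probe
  D2 <- as.matrix(dist(X))^2
  total <- 0
  for (i in seq_len(n)) {
    nb <- which(D2[i, ] < (rs[i] + rs)^2 & seq_len(n) != i)
    P <- sweep(S * rs[i], 2, X[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        d2 <- rowSums(sweep(P, 2, X[j, ])^2)
        free <- free & d2 > rs[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    total <- total + frac * 4 * pi * rs[i]^2
  }
  total
}

#' Buried interface area between two chain groups
#'
#' Buried area = (SASA(A) + SASA(B) - SASA(A union B)) / 2, the standard
#' convention for interface reporting. SASA is computed by sphere-point
#' sampling (960 points per particle, probe 1.4 Angstrom); residue beads
#' get a 3.5 Angstrom radius, atoms their element radii.
#'
#' @param model a [coord_model()].
#' @param groupA,groupB disjoint character vectors of chain ids.
#' @param probe probe radius, Angstrom.
#' @param cfg configuration list.
#' @return buried area in Angstrom^2.
#' @export
interface_area <- function(model, groupA, groupB, probe = NULL,
                           cfg = saxs_config()) {
  if (length(intersect(groupA, groupB)))
    stop("chain groups overlap")
  probe <- probe %||% cfg$sasa$probe
  pr <- model$particles
  radius_of <- function(d) {
    if (model$granularity == "residue-bead") return(rep(cfg$sasa$bead_radius, nrow(d)))
    # van der Waals radius keyed on the stored element mass
    vapply(d$mass, function(m) {
      if (m < 2) 1.2 else if (m < 13) 1.7 else if (m < 14.5) 1.55
      else if (m < 17) 1.52 else 1.8
    }, 0)
  }
  a <- pr[pr$chain %in% groupA, ]; b <- pr[pr$chain %in% groupB, ]
  if (!nrow(a) || !nrow(b)) stop("empty chain group")
  Xa <- as.matrix(a[, c("x", "y", "z")]); Xb <- as.matrix(b[, c("x", "y", "z")])
  ra <- radius_of(a); rb <- radius_of(b)
  np <- cfg$sasa$n_points
  sA <- sasa(Xa, ra, probe, np)
  sB <- sasa(Xb, rb, probe, np)
  sAB <- sasa(rbind(Xa, Xb), c(ra, rb), probe, np)
  (sA + sB - sAB) / 2
}

#' Morphological complementarity score of a candidate interface
#'
#' score = buried interface area - 50 * (number of inter-group pairs with
#' distance in the 3.0-3.5 Angstrom near-clash band). Used only to order
#' candidates whose chi-squares differ by less than 0.2: among
#' statistically equivalent fits, the assembly whose domains pack with the
#' larger clean interface is preferred.
#'
#' @param model combined [coord_model()] of the candidate (clash-free).
#' @param groupA,groupB chain groups of the two bodies.
#' @param cfg configuration list.
#' @return list with `score`, `interface_area`, `near_clashes`.
#' @export
complementarity_score <- function(model, groupA, groupB, cfg = saxs_config()) {
  area <- interface_area(model, groupA, groupB, cfg = cfg)
  pr <- model$particles
  Xa <- as.matrix(pr[pr$chain %in% groupA, c("x", "y", "z")])
  Xb <- as.matrix(pr[pr$chain %in% groupB, c("x", "y", "z")])
  lo <- cfg$assembly$near_clash[1]; hi <- cfg$assembly$near_clash[2]
  nc <- count_close_cross_cpp(Xa, Xb, hi) - count_close_cross_cpp(Xa, Xb, lo)
  list(score = area - cfg$assembly$near_clash_penalty * nc,
       interface_area = area, near_clashes = nc)
}

#' Order chi-square-tied candidates by complementarity
#'
#' Candidates within `chi2_tie` (default 0.2) of the best chi-square are
#' re-ranked by [complementarity_score()]; others keep their chi-square
#' order.
#'
#' @param candidates an [enumerate_assemblies()] result (with attached
#'   bodies) or the `minima` table of a [scenario_search()].
#' @param bodies list with `upper` and `lower` canonical [coord_model()]s;
#'   defaults to the attributes of `candidates`.
#' @param cfg configuration list.
#' @return `candidates` re-ordered, with `interface_area` and
#'   `complementarity` columns filled for the tied set.
#' @export
rank_candidates <- function(candidates, bodies = NULL, cfg = saxs_config()) {
  if (is.null(bodies))
    bodies <- list(upper = attr(candidates, "upper"),
                   lower = attr(candidates, "lower"))
  ok <- candidates[candidates$clash_count == 0 & is.finite(candidates$chi2), ]
  if (!nrow(ok)) return(candidates)
  best <- min(ok$chi2)
  tied <- which(ok$chi2 - best < cfg$assembly$chi2_tie)
  ok$interface_area <- NA_real_
  ok$complementarity <- NA_real_
  for (i in tied) {
    m <- place_components(bodies$upper, bodies$lower, ok$phi[i], ok$t[i])
    upc <- unique(bodies$upper$particles$chain)
    loc <- unique(bodies$lower$particles$chain)
    cs <- complementarity_score(m, upc, loc, cfg = cfg)
    ok$interface_area[i] <- cs$interface_area
    ok$complementarity[i] <- cs$score
  }
  o <- order(!(seq_len(nrow(ok)) %in% tied),
             -ifelse(is.na(ok$complementarity), -Inf, ok$complementarity),
             ok$chi2)
  out <- ok[o, ]
  rownames(out) <- NULL
  attr(out, "upper") <- bodies$upper
  attr(out, "lower") <- bodies$lower
  class(out) <- class(candidates)
  out
}
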