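#' Guinier analysis
#'
#' Weighted linear least squares of ln I vs q^2 over the largest contiguous
#' run of points with q*Rg in `[0.3, 1.3]`; Rg = sqrt(-3 slope),
#' I(0) = exp(intercept). The window is found by iterating from an initial
#' Rg guess (fit of the first 10 points) to self-consistency, at most 20
#' iterations; an explicit `window` (inclusive q-interval) overrides the
#' automatic choice.
#'
#' After convergence the upper end of the automatic window is trimmed while
#' a quadratic term in q^4 is both statistically significant and shifts Rg
#' by more than 0.5 percent: compact globular shapes deviate below the
#' Guinier line as q*Rg approaches 1.3, and fitting through that curvature
#' inflates Rg by 1-2 percent. On noisy data the curvature is rarely
#' significant and the full window is kept, matching how experimental sRg
#' limits reach 1.30.
#'
#' @param curve a [saxs_curve()]; its own analysis window, if set, bounds
#'   the search.
#' @param window optional explicit q-interval `c(q_lo, q_hi)`.
#' @param cfg configuration list, see [saxs_config()].
#' @return list of class `guinier_result`: `Rg`, `Rg_se`, `I0`, `window`,
#'   `sRg_low`, `sRg_high`, `r_squared`, `n_points`.
#' @export
guinier_fit <- function(curve, window = NULL, cfg = saxs_config()) {
  stopifnot(inherits(curve, "saxs_curve"))
  cv <- curve_window(curve)
  pos <- cv$I > 0
  q <- cv$q[pos]; I <- cv$I[pos]; s <- cv$sigma[pos]
  if (length(q) < 5) stop("too few positive-intensity points")
  wfit <- function(idx) {
    x <- q[idx]^2; y <- log(I[idx]); w <- (I[idx] / s[idx])^2
    fit <- lm(y ~ x, weights = w)
    fit
  }
  rg_from <- function(fit) {
    sl <- coef(fit)[[2]]
    if (sl >= 0) stop("no Guinier region: non-negative slope of ln I vs q^2")
    sqrt(-3 * sl)
  }
  if (!is.null(window)) {
    idx <- which(q >= window[1] & q <= window[2])
    if (length(idx) < 3) stop("explicit Guinier window holds fewer than 3 points")
  } else {
    n0 <- min(10, length(q))
    rg <- rg_from(wfit(seq_len(n0)))
    if (sum(q < cfg$guinier$srg_max / rg) < 10)
      stop("fewer than 10 points below q = 1.3/Rg")
    idx <- NULL
    for (it in seq_len(cfg$guinier$max_iter)) {
      lo <- cfg$guinier$srg_min / rg
      hi <- cfg$guinier$srg_max / rg
      idx_new <- which(q >= lo & q <= hi)
      if (length(idx_new) < 3) idx_new <- head(which(q <= hi), 10)
      if (length(idx_new) < 3) stop("no Guinier region: too few low-q points")
      rg_new <- rg_from(wfit(idx_new))
      conv <- !is.null(idx) && identical(idx, idx_new)
      idx <- idx_new
      rg <- rg_new
      if (conv) break
    }
    # trim the high-q end while systematic curvature biases the slope
    while (length(idx) > 10) {
      x <- q[idx]^2; y <- log(I[idx]); w <- (I[idx] / s[idx])^2
      fq <- tryCatch(lm(y ~ x + I(x^2), weights = w), error = function(e) NULL)
      if (is.null(fq) || anyNA(coef(fq))) break
      sm <- suppressWarnings(summary(fq))$coefficients
      if (nrow(sm) < 3 || !is.finite(sm[3, 3])) break
      sl2 <- coef(fq)[[2]]
      if (sl2 >= 0) break
      shift <- abs(sqrt(-3 * sl2) / rg - 1)
      if (abs(sm[3, 3]) > 3 && shift > 0.005) {
        idx <- idx[-((length(idx) - max(1, length(idx) %/% 10) + 1):length(idx))]
        rg <- rg_from(wfit(idx))
      } else break
    }
  }
  fit <- wfit(idx)
  sl <- coef(fit)[[2]]
  if (sl >= 0) stop("no Guinier region: non-negative slope of ln I vs q^2")
  rg <- sqrt(-3 * sl)
  se_sl <- suppressWarnings(summary(fit))$coefficients[2, 2]
  res <- list(
    Rg = rg,
    Rg_se = 3 * se_sl / (2 * rg),
    I0 = exp(coef(fit)[[1]]),
    window = c(min(q[idx]), max(q[idx])),
    sRg_low = min(q[idx]) * rg,
    sRg_high = max(q[idx]) * rg,
    r_squared = suppressWarnings(summary(fit))$r.squared,
    n_points = length(idx)
  )
  class(res) <- "guinier_result"
  res
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("<guinier_result> Rg = %.2f +/- %.2f A, I0 = %.4g\n",
              x$Rg, x$Rg_se, x$I0))
  cat(sprintf("  window q = %.4f..%.4f (q*Rg %.2f..%.2f), R^2 = %.4f, n = %d\n",
              x$window[1], x$window[2], x$sRg_low, x$sRg_high,
              x$r_squared, x$n_points))
  invisible(x)
}

# Design matrix of the indirect Fourier transform:
# I(q) = 4 pi sum_j w_j sinc(q r_j) P(r_j), trapezoid weights on the r grid.
ift_matrix <- function(q, r) {
  dr <- r[2] - r[1]
  w <- rep(dr, length(r)); w[1] <- w[length(r)] <- dr / 2
  qr <- outer(q, r)
  S <- ifelse(abs(qr) < 1e-12, 1, sin(qr) / qr)
  4 * pi * sweep(S, 2, w, "*")
}

# Second-difference (curvature) operator over the full r grid, acting on the
# interior values with implicit zero endpoints.
d2_matrix <- function(m) {
  # p has m interior values; full vector is c(0, p, 0) of length m + 2
  D <- matrix(0, m, m + 2)
  for (j in seq_len(m)) D[j, j:(j + 2)] <- c(1, -2, 1)
  D[, 2:(m + 1), drop = FALSE]
}

#' Pair-distance distribution by indirect Fourier transform
#'
#' Inverts I(q) = 4 pi int_0^Dmax P(r) sin(qr)/(qr) dr on a 101-point r grid
#' with the convention P(r) = gamma(r) r^2. The least-squares system is
#' weighted by 1/sigma, penalized by `alpha` times the sum of squared second
#' differences, constrained to P >= 0 with P(0) = P(Dmax) = 0. When `alpha`
#' is absent it is chosen at the corner of the (chi2, roughness) L-curve
#' over a log grid 1e-4..1e2.
#'
#' Derived quantities: Rg_pr^2 = int r^2 P dr / (2 int P dr),
#' I0_pr = 4 pi int P dr.
#'
#' @param curve a [saxs_curve()] (restricted to its analysis window).
#' @param Dmax maximum particle dimension (Angstrom), > 0.
#' @param alpha smoothness weight; `NULL` for automatic selection.
#' @param cfg configuration list.
#' @return list of class `pair_distribution`: `r`, `P`, `Dmax`, `Rg`, `I0`,
#'   `alpha`, `chi2` (fit of the back-transform to the data), `roughness`,
#'   `negativity` (fraction of unconstrained solution mass below zero).
#' @export
compute_pr <- function(curve, Dmax, alpha = NULL, cfg = saxs_config()) {
  stopifnot(Dmax > 0)
  cv <- curve_window(curve)
  if (Dmax < 2 * pi / max(cv$q) )
    warning("Dmax below the 2*pi/q_max resolution bound")
  r <- seq(0, Dmax, length.out = cfg$pr$n_r)
  m <- cfg$pr$n_r - 2
  A <- ift_matrix(cv$q, r)[, 2:(m + 1), drop = FALSE]
  Aw <- A / cv$sigma
  bw <- cv$I / cv$sigma
  D <- d2_matrix(m)
  lam0 <- sum(Aw^2) / sum(D^2)   # balances the two blocks at alpha = 1

  solve_at <- function(alpha) {
    M <- rbind(Aw, sqrt(alpha * lam0) * D)
    rhs <- c(bw, rep(0, m))
    p <- pracma::lsqnonneg(M, rhs)$x
    # unconstrained ridge solution for the negativity diagnostic
    pu <- tryCatch(qr.solve(M, rhs), error = function(e) p)
    Ifit <- as.vector(A %*% p)
    chi2 <- sum(((Ifit - cv$I) / cv$sigma)^2) / (length(cv$q) - 1)
    rough <- if (sum(p^2) > 0) sum((D %*% p)^2) / sum(p^2) else 0
    neg <- if (sum(abs(pu)) > 0) sum(abs(pmin(pu, 0))) / sum(abs(pu)) else 0
    list(p = p, chi2 = chi2, rough = rough, neg = neg)
  }

  if (is.null(alpha)) {
    grid <- cfg$pr$alpha_grid
    sols <- lapply(grid, solve_at)
    lx <- log10(vapply(sols, `[[`, 0, "chi2") + 1e-12)
    ly <- log10(vapply(sols, `[[`, 0, "rough") + 1e-12)
    # corner = farthest point from the chord joining the curve's endpoints
    vx <- (lx - lx[1]) / max(abs(lx[length(lx)] - lx[1]), 1e-12)
    vy <- (ly - ly[1]) / max(abs(ly[length(ly)] - ly[1]), 1e-12)
    dist <- abs(vx * (vy[length(vy)] - vy[1]) - vy * (vx[length(vx)] - vx[1]))
    k <- which.max(dist)
    alpha <- grid[k]
    sol <- sols[[k]]
  } else {
    sol <- solve_at(alpha)
  }
  P <- c(0, sol$p, 0)
  dr <- r[2] - r[1]
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2) * dr
  i0 <- 4 * pi * trapz(P)
  rg2 <- if (i0 > 0) trapz(r^2 * P) / (2 * trapz(P)) else NA_real_
  res <- list(r = r, P = P, Dmax = Dmax,
              Rg = if (is.na(rg2)) NA_real_ else sqrt(rg2),
              I0 = i0, alpha = alpha, chi2 = sol$chi2,
              roughness = sol$rough, negativity = sol$neg)
  class(res) <- "pair_distribution"
  res
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("<pair_distribution> Dmax = %.1f A, Rg = %.2f A, I0 = %.4g\n",
              x$Dmax, x$Rg, x$I0))
  cat(sprintf("  alpha = %.3g, back-transform chi2 = %.3g\n", x$alpha, x$chi2))
  invisible(x)
}

#' Back-transform of a pair distribution
#'
#' Forward-computes I(q) = 4 pi int P(r) sinc(qr) dr on a q grid; used to
#' check that the inversion reproduces the input curve.
#'
#' @param pr a [compute_pr()] result.
#' @param q_grid q values (1/Angstrom).
#' @return list with `q` and `I` (class `model_curve`).
#' @export
pr_to_curve <- function(pr, q_grid) {
  A <- ift_matrix(q_grid, pr$r)
  structure(list(q = q_grid, I = as.vector(A %*% pr$P)),
            class = "model_curve")
}

#' Select Dmax by scanning for the smoothest positive distribution
#'
#' Scans Dmax over `[2 Rg, 4 Rg]` (Guinier Rg) in 2-Angstrom steps. Each
#' candidate inversion is characterized by its fit chi2, the negativity of
#' the unconstrained solution, its roughness, and a truncation indicator
#' (the fraction of P mass crammed into the last 5 percent of the r range:
#' a too-small Dmax forces the genuine tail into a kink at the endpoint).
#' The selected Dmax is the smallest whose chi2 has reached the scan's
#' plateau (within 5 percent or +0.1) and whose truncation indicator is
#' below 5 percent, the threshold escalating if no candidate qualifies —
#' the automated version of the trial-and-error search for the smoothest
#' strictly positive distribution. A composite score (chi2 + w_neg *
#' negativity + w_rough * roughness) is reported per candidate for
#' inspection.
#'
#' The regularization weight is chosen automatically once, at the midpoint
#' of the scan, and held fixed across the scan unless given.
#'
#' @param curve a [saxs_curve()].
#' @param guinier optional precomputed [guinier_fit()] result.
#' @param range optional explicit Dmax scan range `c(lo, hi)` (Angstrom).
#' @param alpha optional fixed regularization weight for the whole scan.
#' @param cfg configuration list.
#' @return list with `Dmax`, `pr` (the winning [compute_pr()] result) and
#'   `scan` (data.frame of Dmax, chi2, negativity, roughness, tail_weight,
#'   score).
#' @export
find_dmax <- function(curve, guinier = NULL, range = NULL, alpha = NULL,
                      cfg = saxs_config()) {
  if (is.null(guinier)) guinier <- guinier_fit(curve, cfg = cfg)
  if (is.null(range)) range <- c(2, 4) * guinier$Rg
  dmaxs <- seq(range[1], range[2], by = cfg$pr$dmax_step)
  if (is.null(alpha)) {
    mid <- dmaxs[ceiling(length(dmaxs) / 2)]
    alpha <- compute_pr(curve, mid, cfg = cfg)$alpha
  }
  rows <- lapply(dmaxs, function(dm) {
    pr <- suppressWarnings(compute_pr(curve, dm, alpha = alpha, cfg = cfg))
    n <- length(pr$P)
    k <- max(2, round(0.05 * n))
    tailw <- if (max(pr$P) > 0) mean(pr$P[(n - k + 1):n]) / max(pr$P) else 0
    score <- pr$chi2 + cfg$pr$w_neg * pr$negativity +
      cfg$pr$w_rough * pr$roughness
    list(pr = pr, row = data.frame(Dmax = dm, chi2 = pr$chi2,
                                   negativity = pr$negativity,
                                   roughness = pr$roughness,
                                   tail_weight = tailw, score = score))
  })
  scan <- do.call(rbind, lapply(rows, `[[`, "row"))
  plateau <- max(min(scan$chi2) * 1.05, min(scan$chi2) + 0.1)
  k <- NULL
  for (tt in c(0.05, 0.1, 0.2, Inf)) {
    ok <- which(scan$chi2 <= plateau & scan$tail_weight <= tt)
    if (length(ok)) { k <- ok[1]; break }
  }
  list(Dmax = dmaxs[k], pr = rows[[k]]$pr, scan = scan)
}

#' Porod analysis: invariant, volume, exponent, molecular mass
#'
#' The Porod invariant Q = int q^2 I dq is assembled from three pieces: the
#' Guinier extrapolation below the first measured q, the trapezoid of the
#' data, and an analytic q^-4 tail beyond the last measured q. A flat
#' incoherent background B is first estimated from a least-squares fit of
#' I = K q^-4 + B over the high-q region (q*Rg >= 2.5) and subtracted, so
#' that discrete-scatterer self terms or detector offsets do not inflate Q.
#' The Porod volume is 2 pi^2 I(0) / Q (reported in nm^3) and the molecular
#' mass follows the 0.58 kDa per nm^3 rule; the coarser "half the Porod
#' volume in A^3 is the mass in Da" heuristic is reported alongside, never
#' mixed in. The Porod exponent is the power-law slope of ln I vs ln q over
#' q*Rg in `[2.5, 6.5]` (clipped to the data), fitted on the means of ten
#' log-q bins; binning the mean intensity keeps the near-zero oscillation
#' minima of compact particles from dragging the slope, and the window/bin
#' choice was validated against closed forms (sphere 4, pure power laws p,
#' ideal coil 2).
#'
#' @param curve a [saxs_curve()].
#' @param guinier a [guinier_fit()] result for the low-q extrapolation.
#' @param cfg configuration list.
#' @return list of class `porod_result`: `invariant`, `porod_volume` (nm^3),
#'   `porod_exponent`, `mw_porod` (kDa, 0.58 rule), `mw_half_volume` (kDa),
#'   `background`.
#' @export
porod_analysis <- function(curve, guinier, cfg = saxs_config()) {
  q <- curve$q; I <- curve$I
  Rg <- guinier$Rg; I0 <- guinier$I0
  hi <- q >= cfg$porod$exponent_srg[1] / Rg
  B <- 0; K <- NA_real_
  if (sum(hi) >= 5) {
    X <- cbind(q[hi]^-4, 1)
    cf <- tryCatch(qr.solve(X, I[hi]), error = function(e) c(NA, 0))
    K <- cf[1]
    B <- max(0, min(cf[2], min(I[hi])))
  }
  Isub <- I - B
  # exponent over q*Rg in [2.5, 6], log-binned to tame Debye oscillations
  win <- q >= cfg$porod$exponent_srg[1] / Rg & q <= cfg$porod$exponent_srg[2] / Rg
  exponent <- NA_real_
  if (sum(win) >= 5) {
    # bin the mean intensity (not the mean log) so that the near-zero minima
    # of oscillating compact-particle curves do not drag the slope
    lq <- log(q[win]); Iw <- Isub[win]
    nb <- min(cfg$porod$exponent_bins, max(3, floor(length(lq) / 4)))
    bins <- cut(lq, breaks = nb)
    bx <- tapply(lq, bins, mean)
    by <- log(tapply(Iw, bins, mean))
    ok <- is.finite(bx) & is.finite(by)
    if (sum(ok) >= 3) exponent <- -coef(lm(by[ok] ~ bx[ok]))[[2]]
  }
  # invariant
  gu <- function(x) x^2 * I0 * exp(-x^2 * Rg^2 / 3)
  Q_low <- stats::integrate(gu, 0, q[1])$value
  dq <- diff(q)
  y <- q^2 * Isub
  Q_data <- sum((y[-1] + y[-length(y)]) / 2 * dq)
  Kt <- if (is.finite(K) && K > 0) K else max(Isub[length(Isub)], 0) * q[length(q)]^4
  Q_tail <- Kt / q[length(q)]
  Q <- Q_low + Q_data + Q_tail
  if (Q <= 0) stop("non-positive Porod invariant")
  V_A3 <- 2 * pi^2 * I0 / Q
  V_nm3 <- V_A3 / 1000
  res <- list(invariant = Q, porod_volume = V_nm3,
              porod_exponent = unname(exponent),
              mw_porod = porod_mass(V_nm3, cfg),
              mw_half_volume = V_A3 / 2 / 1000,
              background = B)
  class(res) <- "porod_result"
  res
}

#' @export
print.porod_result <- function(x, ...) {
  cat(sprintf("<porod_result> V = %.1f nm^3, exponent = %.2f, MW = %.1f kDa (0.58/nm^3)\n",
              x$porod_volume, x$porod_exponent, x$mw_porod))
  invisible(x)
}

#' Molecular mass from a Porod volume
#'
#' The empirical rule for hydrated proteins: 0.58 kDa per nm^3 of Porod
#' volume.
#'
#' @param volume_nm3 Porod volume in nm^3.
#' @param cfg configuration list.
#' @return molecular mass in kDa.
#' @export
#' @examples
#' porod_mass(102)   # ~59 kDa
porod_mass <- function(volume_nm3, cfg = saxs_config()) {
  stopifnot(volume_nm3 > 0)
  cfg$porod$mass_per_nm3 * volume_nm3
}

#' Dimensionless Kratky transform
#'
#' x = q Rg, y = x^2 I(q)/I(0). A globular particle obeying the Guinier law
#' peaks at x = sqrt(3) with height 3/e (about 1.104); flexible chains
#' plateau at large x instead. The peak is located by parabolic
#' interpolation around the discrete maximum.
#'
#' @param curve a [saxs_curve()].
#' @param guinier a [guinier_fit()] result supplying Rg and I(0).
#' @return list of class `kratky_curve`: `x`, `y`, `x_peak`, `y_peak`.
#' @export
dimensionless_kratky <- function(curve, guinier) {
  x <- curve$q * guinier$Rg
  y <- x^2 * curve$I / guinier$I0
  i <- which.max(y)
  xp <- x[i]; yp <- y[i]
  if (i > 1 && i < length(y)) {
    # parabola through the three points around the discrete maximum; keep
    # the discrete peak when the three points are numerically collinear
    x3 <- x[(i - 1):(i + 1)]; y3 <- y[(i - 1):(i + 1)]
    cf <- suppressWarnings(coef(lm(y3 ~ x3 + I(x3^2))))
    if (!anyNA(cf) && is.finite(cf[[3]]) && cf[[3]] < 0) {
      xv <- -cf[[2]] / (2 * cf[[3]])
      if (xv >= x3[1] && xv <= x3[3]) {
        xp <- xv
        yp <- cf[[1]] + cf[[2]] * xv + cf[[3]] * xv^2
      }
    }
  }
  structure(list(x = x, y = y, x_peak = unname(xp), y_peak = unname(yp)),
            class = "kratky_curve")
}

#' Oligomeric-state estimate from mass ratio
#'
#' Ratio of the Porod-derived mass to the sequence mass of one protomer,
#' with the nearest-integer oligomeric state. A caution flag marks ratios
#' more than 0.35 away from the nearest integer, where the Porod estimate
#' does not cleanly identify a state.
#'
#' @param porod a [porod_analysis()] result (or a number, kDa).
#' @param monomer a [sequence_mass()] result (or a number, Da).
#' @return list with `ratio`, `state`, `caution`.
#' @export
oligomer_ratio <- function(porod, monomer) {
  mw_kda <- if (is.list(porod)) porod$mw_porod else porod
  mono_da <- if (is.list(monomer)) monomer$mass else monomer
  stopifnot(mono_da > 0)
  ratio <- mw_kda * 1000 / mono_da
  state <- round(ratio)
  list(ratio = ratio, state = as.integer(state),
       caution = abs(ratio - state) > 0.35)
}
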