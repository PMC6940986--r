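#' One-dimensional scattering curve
#'
#' Container for a measured or simulated SAXS profile: scattering-vector
#' magnitudes q (1/Angstrom), intensities I (arbitrary units) and their 1-sigma
#' uncertainties. Rows are sorted by q; q must end up strictly increasing and
#' all sigma strictly positive.
#'
#' @param q numeric vector of scattering-vector magnitudes (1/Angstrom).
#' @param I intensities, same length as `q`.
#' @param sigma 1-sigma uncertainties, same length, all > 0.
#' @param label free-text identifier.
#' @param window optional length-2 inclusive q-interval used for analysis.
#' @return object of class `saxs_curve`: a list with elements `q`, `I`,
#'   `sigma`, `label`, `window`.
#' @export
#' @examples
#' saxs_curve(c(0.01, 0.02, 0.03), c(100, 90, 80), c(1, 1, 1))
saxs_curve <- function(q, I, sigma, label = "", window = NULL) {
  stopifnot(length(q) == length(I), length(q) == length(sigma))
  if (length(q) < 3) stop("a scattering curve needs at least 3 points")
  ok <- is.finite(q) & is.finite(I) & is.finite(sigma)
  q <- q[ok]; I <- I[ok]; sigma <- sigma[ok]
  o <- order(q)
  q <- q[o]; I <- I[o]; sigma <- sigma[o]
  if (any(diff(q) <= 0)) {
    keep <- !duplicated(q)
    q <- q[keep]; I <- I[keep]; sigma <- sigma[keep]
  }
  if (any(sigma <= 0)) stop("all sigma must be > 0")
  if (length(q) < 3) stop("fewer than 3 valid points")
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] < window[2])
  }
  structure(list(q = q, I = I, sigma = sigma, label = as.character(label),
                 window = window),
            class = "saxs_curve")
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("<saxs_curve> %s: %d points, q = %.4g..%.4g 1/A\n",
              if (nzchar(x$label)) x$label else "(unlabeled)",
              length(x$q), min(x$q), max(x$q)))
  if (!is.null(x$window))
    cat(sprintf("  analysis window: %.4g..%.4g 1/A\n", x$window[1], x$window[2]))
  invisible(x)
}

#' @export
length.saxs_curve <- function(x) length(x$q)

#' Restrict a curve to its analysis window
#'
#' @param curve a [saxs_curve()].
#' @param window optional explicit window overriding the curve's own.
#' @return a `saxs_curve` containing only points inside the window.
#' @export
curve_window <- function(curve, window = NULL) {
  w <- if (!is.null(window)) window else curve$window
  if (is.null(w)) return(curve)
  keep <- curve$q >= w[1] & curve$q <= w[2]
  if (sum(keep) < 3) stop("window leaves fewer than 3 points")
  saxs_curve(curve$q[keep], curve$I[keep], curve$sigma[keep],
             label = curve$label, window = w)
}

#' Read a SAXS curve from whitespace-separated text
#'
#' Accepts the common 3+ column .dat dialect: q, I, sigma, with '#' comments
#' and non-numeric header lines skipped, extra columns ignored. Rows with
#' non-positive sigma are dropped with a warning.
#'
#' @param path file path.
#' @param label curve label; defaults to the file name.
#' @return a [saxs_curve()].
#' @export
read_saxs_curve <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  window <- NULL
  wl <- grep("^#\\s*window:", lines, value = TRUE)
  if (length(wl)) {
    v <- suppressWarnings(as.numeric(strsplit(sub("^#\\s*window:\\s*", "", wl[1]),
                                              "\\s+")[[1]]))
    if (length(v) >= 2 && all(is.finite(v[1:2]))) window <- v[1:2]
  }
  ll <- grep("^#\\s*label:", lines, value = TRUE)
  if (length(ll)) {
    lab <- sub("^#\\s*label:\\s*", "", ll[1])
    if (nzchar(lab)) label <- lab
  }
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(lines), "\\s+"), function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (length(v) >= 3 && all(is.finite(v[1:3]))) v[1:3] else NULL
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || nrow(rows) < 3) stop("fewer than 3 valid data rows in ", path)
  bad <- rows[, 3] <= 0
  if (any(bad)) {
    warning(sum(bad), " rows with non-positive sigma dropped")
    rows <- rows[!bad, , drop = FALSE]
  }
  if (nrow(rows) < 3) stop("fewer than 3 valid data rows in ", path)
  saxs_curve(rows[, 1], rows[, 2], rows[, 3], label = label, window = window)
}

#' Write a SAXS curve as 3-column text
#'
#' The header records the label and, when set, the analysis window, as '#'
#' comments; values are written with enough digits for a lossless round trip
#' at 6 significant figures.
#'
#' @param curve a [saxs_curve()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_saxs_curve <- function(curve, path) {
  stopifnot(inherits(curve, "saxs_curve"))
  hdr <- c(sprintf("# label: %s", curve$label),
           if (!is.null(curve$window))
             sprintf("# window: %.8g %.8g", curve$window[1], curve$window[2]),
           "# q(1/A) I sigma")
  body <- sprintf("%.8e %.8e %.8e", curve$q, curve$I, curve$sigma)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Scattering-vector magnitude from instrument geometry
#'
#' q = 4 pi sin(theta) / lambda, with 2*theta the full scattering angle.
#' When only the photon energy is given, lambda = 12.3984 / E(keV) Angstrom.
#'
#' @param two_theta scattering angle 2*theta in degrees, in `[0, 180)`.
#' @param wavelength X-ray wavelength in Angstrom.
#' @param energy_kev photon energy in keV; used when `wavelength` is missing.
#' @return q in 1/Angstrom.
#' @export
#' @examples
#' q_from_angle(60, wavelength = 1)   # 2*pi
q_from_angle <- function(two_theta, wavelength = NULL, energy_kev = NULL) {
  if (is.null(wavelength)) {
    if (is.null(energy_kev)) stop("give wavelength or energy_kev")
    wavelength <- 12.3984 / energy_kev
  }
  if (any(wavelength <= 0)) stop("wavelength must be > 0")
  if (any(two_theta < 0 | two_theta >= 180)) stop("2*theta must be in [0, 180)")
  4 * pi * sin(two_theta / 2 * pi / 180) / wavelength
}

#' Subtract a buffer curve from a sample curve
#'
#' Both curves must share the same q grid (tolerance 1e-6 1/Angstrom).
#' Uncertainties are propagated in quadrature.
#'
#' @param sample,buffer [saxs_curve()] objects on identical q grids.
#' @return a `saxs_curve` with I = I_sample - I_buffer.
#' @export
subtract_background <- function(sample, buffer) {
  stopifnot(inherits(sample, "saxs_curve"), inherits(buffer, "saxs_curve"))
  if (length(sample$q) != length(buffer$q) ||
      max(abs(sample$q - buffer$q)) > 1e-6)
    stop("q grids differ")
  saxs_curve(sample$q, sample$I - buffer$I,
             sqrt(sample$sigma^2 + buffer$sigma^2),
             label = paste0(sample$label, " - ", buffer$label),
             window = sample$window)
}
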