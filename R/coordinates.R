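# Average residue masses (Da) of the 20 standard amino acids, i.e. the
# monomer mass minus one water; summing them and adding 18.0153 gives the
# average molecular mass of the chain.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
  GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "C"
)

ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, MN = 54.938,
  CA = 40.078, `NA` = 22.990, CL = 35.45, K = 39.098
)

#' Coordinate model
#'
#' A coarse-grained (one bead per residue) or atomic 3D model. Particles
#' carry chain, residue number (with insertion code folded into the residue
#' key), residue name, Cartesian position in Angstrom, mass in Da and a
#' dimensionless scattering weight f (uniform 1 by default).
#'
#' @param particles data.frame with columns `chain`, `resno`, `insert`,
#'   `resid`, `x`, `y`, `z`, `mass`, `f`.
#' @param granularity `"atomic"` or `"residue-bead"`.
#' @return object of class `coord_model`.
#' @export
coord_model <- function(particles, granularity = c("residue-bead", "atomic")) {
  granularity <- match.arg(granularity)
  need <- c("chain", "resno", "insert", "resid", "x", "y", "z", "mass", "f")
  miss <- setdiff(need, names(particles))
  if (length(miss)) stop("particles lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(particles) < 1) stop("model needs at least one particle")
  if (!all(is.finite(as.matrix(particles[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (granularity == "residue-bead") {
    key <- paste(particles$chain, particles$resno, particles$insert)
    if (anyDuplicated(key)) stop("duplicate (chain, residue) in bead model")
  }
  structure(list(particles = particles, granularity = granularity),
            class = "coord_model")
}

#' @export
print.coord_model <- function(x, ...) {
  cat(sprintf("<coord_model> %s, %d particles, chains: %s\n", x$granularity,
              nrow(x$particles),
              paste(unique(x$particles$chain), collapse = " ")))
  invisible(x)
}

#' Coordinate matrix of a model
#' @param model a [coord_model()].
#' @return numeric matrix with one row per particle, columns x, y, z.
#' @export
coords <- function(model) {
  as.matrix(model$particles[, c("x", "y", "z")])
}

#' Build a bead model from a coordinate matrix
#'
#' Convenience constructor: one bead per row, sequential residue numbers on
#' one chain, unit scattering weight, glycine-like mass unless given.
#'
#' @param X n x 3 matrix of positions (Angstrom).
#' @param chain chain identifier(s), recycled.
#' @param resno residue numbers; default `1:n`.
#' @param mass per-bead mass in Da.
#' @return a residue-bead [coord_model()].
#' @export
bead_model <- function(X, chain = "A", resno = NULL, mass = 110) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(resno)) {
    resno <- stats::ave(seq_len(n), rep(chain, length.out = n),
                        FUN = seq_along)
  }
  coord_model(data.frame(
    chain = rep(chain, length.out = n), resno = resno, insert = "",
    resid = "GLY", x = X[, 1], y = X[, 2], z = X[, 3],
    mass = mass, f = 1, stringsAsFactors = FALSE
  ), granularity = "residue-bead")
}

#' Read a coordinate model from a PDB file
#'
#' Uses the first MODEL only; for alternate locations the highest-occupancy
#' conformer is kept. At residue-bead granularity one bead per residue is
#' placed at the C-alpha position (falling back to the geometric centroid of
#' the residue's atoms) and carries the standard average residue mass; at
#' atomic granularity each atom carries its element mass.
#'
#' @param path PDB file.
#' @param granularity `"residue-bead"` (default) or `"atomic"`.
#' @return a [coord_model()].
#' @export
read_coordinates <- function(path, granularity = c("residue-bead", "atomic")) {
  granularity <- match.arg(granularity)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("no parseable coordinates in ", path))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no parseable coordinates in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1
  # highest-occupancy alternate conformer per atom site
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  at <- at[order(key, -at$o), ]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ]

  if (granularity == "atomic") {
    elem <- toupper(trimws(at$elesy))
    elem[!nzchar(elem) | is.na(elem)] <-
      substr(gsub("[0-9]", "", trimws(at$elety[!nzchar(elem) | is.na(elem)])), 1, 1)
    mass <- unname(ELEMENT_MASS[elem])
    mass[is.na(mass)] <- ELEMENT_MASS[["C"]]
    pr <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                     resid = at$resid, x = at$x, y = at$y, z = at$z,
                     mass = mass, f = 1, stringsAsFactors = FALSE)
    # atoms within a residue share (chain, resno); disambiguate via rownames only
    m <- structure(list(particles = pr, granularity = "atomic"),
                   class = "coord_model")
    return(m)
  }

  sp <- split(at, paste(at$chain, at$resno, at$insert, sep = "\r"))
  rows <- lapply(sp, function(res) {
    ca <- res[res$elety == "CA", , drop = FALSE]
    pos <- if (nrow(ca) >= 1) {
      c(ca$x[1], ca$y[1], ca$z[1])
    } else {
      c(mean(res$x), mean(res$y), mean(res$z))
    }
    one <- AA_THREE_TO_ONE[res$resid[1]]
    mass <- if (!is.na(one)) unname(AA_RESIDUE_MASS[one]) else 110
    data.frame(chain = res$chain[1], resno = res$resno[1],
               insert = res$insert[1], resid = res$resid[1],
               x = pos[1], y = pos[2], z = pos[3], mass = mass, f = 1,
               stringsAsFactors = FALSE)
  })
  pr <- do.call(rbind, rows)
  pr <- pr[order(pr$chain, pr$resno, pr$insert), ]
  rownames(pr) <- NULL
  coord_model(pr, granularity = "residue-bead")
}

#' Write a coordinate model as PDB
#'
#' Bead models are written with one CA atom per bead; atomic models with
#' their stored residue/chain identities and generic C atoms.
#'
#' @param model a [coord_model()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_coordinates <- function(model, path) {
  pr <- model$particles
  elety <- if (model$granularity == "residue-bead") "CA" else "C"
  lines <- sprintf(
    "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(nrow(pr)) %% 100000, elety, substr(pr$resid, 1, 3),
    substr(paste0(pr$chain, " "), 1, 1), pr$resno %% 10000,
    pr$x, pr$y, pr$z, 1.0, 0.0)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Average molecular mass of a protein sequence
#'
#' Sum of standard average residue masses plus one water (18.0153 Da); the
#' empty sequence therefore returns the mass of water. Additive:
#' mass(AB) = mass(A) + mass(B) - 18.0153.
#'
#' @param sequence one-letter amino-acid string (case-insensitive).
#' @return list with `sequence` and `mass` (Da).
#' @export
#' @examples
#' sequence_mass("G")$mass   # 75.07
sequence_mass <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  aa <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  if (length(aa) == 0)
    return(list(sequence = "", mass = WATER_MASS))
  m <- AA_RESIDUE_MASS[aa]
  if (anyNA(m))
    stop("unknown amino-acid letter(s): ",
         paste(unique(aa[is.na(m)]), collapse = ", "))
  list(sequence = paste(aa, collapse = ""), mass = sum(m) + WATER_MASS)
}
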