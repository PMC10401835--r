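# Deterministic synthetic-peptide generator: ideal-geometry backbones with
# prescribed torsions, Gaussian perturbation, and rigid transforms.  Every
# test structure in the package is built here; nothing is downloaded.

# ideal backbone geometry (angstroms / degrees)
.BOND <- c(N_CA = 1.46, CA_C = 1.52, C_N = 1.33, C_O = 1.23)
.ANGLE <- c(N_CA_C = 111.0, CA_C_N = 116.6, C_N_CA = 121.9, CA_C_O = 120.5)

# place a new atom at distance `bond` from c, bond angle `ang` at c with b,
# torsion `tor` about the b-c axis relative to a (NeRF construction)
.place_atom <- function(a, b, c, bond, ang, tor) {
  angr <- ang * pi / 180; torr <- tor * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(angr), bond * sin(angr) * cos(torr),
         bond * sin(angr) * sin(torr))
  c + d[1] * bc + d[2] * m + d[3] * n
}

.expand_sequence <- function(sequence, length) {
  if (is.null(sequence)) sequence <- "A"
  ch <- rep_len(strsplit(toupper(sequence), "")[[1]], length)
  idx <- match(ch, .AA3TO1[.STANDARD_AA3])
  if (anyNA(idx)) {
    stop("sequence letters must be the 20 standard residues", call. = FALSE)
  }
  .STANDARD_AA3[idx]
}

#' Build a synthetic peptide backbone
#'
#' Constructs an N/CA/C/O backbone from ideal bond lengths and angles and
#' the requested torsions (omega fixed at 180).  `kind = "helix"` uses
#' phi = -57, psi = -47; `"strand"` uses phi = -120, psi = 130;
#' `"random_torsion"` draws phi/psi uniformly from (-180, 180] using `seed`.
#' Explicit `phi`/`psi` arguments override the kind presets.  The same seed
#' always reproduces identical coordinates.
#'
#' @param length residue count (>= 1).
#' @param kind `"helix"`, `"strand"` or `"random_torsion"`.
#' @param sequence one-letter sequence or repeat pattern (recycled to
#'   `length`); default poly-alanine.
#' @param phi,psi torsion overrides, degrees (scalar or per-residue).
#' @param noise_sigma per-coordinate Gaussian noise, angstroms.
#' @param seed integer seed for the random draws.
#' @param chain chain identifier.
#' @param id structure identifier.
#' @return a `prostat_structure` with `4 * length` atoms.
#' @export
build_peptide <- function(length, kind = c("helix", "strand", "random_torsion"),
                          sequence = NULL, phi = NULL, psi = NULL,
                          noise_sigma = 0, seed = 1, chain = "A",
                          id = NULL) {
  kind <- match.arg(kind)
  if (length < 1) stop("length must be at least 1", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be non-negative", call. = FALSE)
  preset <- switch(kind, helix = c(-57, -47), strand = c(-120, 130),
                   random_torsion = c(NA, NA))
  if (kind == "random_torsion" && (is.null(phi) || is.null(psi))) {
    old <- .Random.seed_save()
    set.seed(seed)
    if (is.null(phi)) phi <- stats::runif(length, -180, 180)
    if (is.null(psi)) psi <- stats::runif(length, -180, 180)
    .Random.seed_restore(old)
  }
  phi <- rep_len(if (is.null(phi)) preset[1] else phi, length)
  psi <- rep_len(if (is.null(psi)) preset[2] else psi, length)
  if (any(!is.finite(phi)) || any(!is.finite(psi))) {
    stop("invalid torsions", call. = FALSE)
  }
  name3 <- .expand_sequence(sequence, length)

  coords <- matrix(0, 4 * length, 3)
  # seed atoms of residue 1
  N1 <- c(0, 0, 0)
  CA1 <- c(.BOND["N_CA"], 0, 0)
  ang <- .ANGLE["N_CA_C"] * pi / 180
  C1 <- CA1 + .BOND["CA_C"] * c(-cos(ang), sin(ang), 0)
  pos <- list(N = N1, CA = CA1, C = C1)
  rows <- function(i) (4 * (i - 1) + 1):(4 * i)   # N, CA, C, O
  coords[1, ] <- N1; coords[2, ] <- CA1; coords[3, ] <- C1
  prev <- pos
  for (i in seq_len(length)) {
    if (i > 1) {
      N <- .place_atom(prev$N, prev$CA, prev$C, .BOND["C_N"],
                       .ANGLE["CA_C_N"], psi[i - 1])
      CA <- .place_atom(prev$CA, prev$C, N, .BOND["N_CA"],
                        .ANGLE["C_N_CA"], 180)          # omega
      C <- .place_atom(prev$C, N, CA, .BOND["CA_C"],
                       .ANGLE["N_CA_C"], phi[i])
      coords[4 * (i - 1) + 1, ] <- N
      coords[4 * (i - 1) + 2, ] <- CA
      coords[4 * (i - 1) + 3, ] <- C
      prev <- list(N = N, CA = CA, C = C)
    }
    # carbonyl O: in the peptide plane, opposite the next N (psi + 180)
    coords[4 * i, ] <- .place_atom(prev$N, prev$CA, prev$C, .BOND["C_O"],
                                   .ANGLE["CA_C_O"], psi[i] + 180)
  }

  atoms <- data.frame(
    record = "ATOM",
    serial = seq_len(4 * length),
    name = rep(c("N", "CA", "C", "O"), length),
    altloc = " ",
    resname = rep(name3, each = 4),
    chain = chain,
    resno = rep(seq_len(length), each = 4),
    icode = " ",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = 1, bfactor = 0,
    element = rep(c("N", "C", "C", "O"), length),
    stringsAsFactors = FALSE
  )
  atoms$chain_key <- paste0(chain, ".0")
  s <- structure(list(id = id %||% sprintf("%s%d", kind, length),
                      atoms = atoms, source = "synthetic"),
                 class = "prostat_structure")
  if (noise_sigma > 0) s <- perturb(s, noise_sigma, seed) else s
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Add Gaussian coordinate noise to a structure
#'
#' i.i.d. normal noise with standard deviation `sigma` on every coordinate;
#' `sigma = 0` returns the structure unchanged.  The caller's random state
#' is preserved; the same seed always yields the same noise.
#'
#' @param s a `prostat_structure`.
#' @param sigma noise standard deviation, angstroms (>= 0).
#' @param seed integer seed.
#' @return a perturbed deep copy.
#' @export
perturb <- function(s, sigma, seed = 1) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(s)
  xyz <- get_coords(s)
  old <- .Random.seed_save()
  set.seed(seed)
  noise <- matrix(stats::rnorm(length(xyz), 0, sigma), nrow(xyz), 3)
  .Random.seed_restore(old)
  set_coords(s, xyz + noise)
}

#' Apply a rigid transform to a fixture structure
#'
#' Thin alias of [transform_structure()] kept with the generator.
#'
#' @inheritParams transform_structure
#' @return transformed deep copy.
#' @export
rigid_transform <- function(s, rotation, translation = c(0, 0, 0)) {
  transform_structure(s, rotation, translation)
}

#' A uniformly random rotation matrix
#'
#' QR-based Haar-ish sampling with determinant fixed to +1; deterministic
#' for a given seed and independent of the caller's random state.
#'
#' @param seed integer seed.
#' @return 3x3 proper rotation matrix.
#' @export
random_rotation <- function(seed = 1) {
  old <- .Random.seed_save()
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  .Random.seed_restore(old)
  Q <- qr.Q(qr_)
  d <- diag(sign(diag(qr.R(qr_))))
  Q <- Q %*% d
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
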