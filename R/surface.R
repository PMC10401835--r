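# Solvent-accessible surface area (Shrake-Rupley) and relative accessibility
# against per-residue theoretical maxima.

# van der Waals radii (angstroms) for the heavy elements of proteins
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                SE = 1.90, H = 1.20)

#' Deterministic near-uniform points on the unit sphere
#'
#' Golden-spiral (Fibonacci) lattice: `n` points, no randomness.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = cos(theta) * sin(phi), y = sin(theta) * sin(phi), z = cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over every heavy atom: each atom's sphere of radius
#' r_vdw + probe is sampled on a deterministic golden-spiral lattice and a
#' test point counts as exposed when it lies outside the probe-expanded
#' sphere of every neighbouring atom.  ASA = (exposed / n_points) *
#' 4 pi (r_vdw + probe)^2.
#'
#' @param s a `prostat_structure`.
#' @param probe probe radius in angstroms (water: 1.4).
#' @param n_points test points per atom (>= 100).
#' @param include_het include HETATM records (default drops them).
#' @param include_hydrogens include hydrogen atoms (default drops them).
#' @param unknown_radius `NA` (default) to fail on elements without a known
#'   van der Waals radius, or a fallback radius in angstroms.
#' @return data.frame: one row per included atom with its identifiers,
#'   element, radius and `asa` (angstroms squared).
#' @export
shrake_rupley_asa <- function(s, probe = 1.4, n_points = 960,
                              include_het = FALSE, include_hydrogens = FALSE,
                              unknown_radius = NA) {
  stopifnot(probe > 0)
  if (n_points < 100) stop("n_points must be at least 100", call. = FALSE)
  a <- s$atoms
  if (!include_het) a <- a[a$record == "ATOM", , drop = FALSE]
  el <- toupper(a$element)
  if (!include_hydrogens) {
    keep <- !el %in% c("H", "D")
    a <- a[keep, , drop = FALSE]; el <- el[keep]
  }
  if (!nrow(a)) stop("no atoms left for ASA computation", call. = FALSE)
  r <- .VDW_RADII[el]
  if (anyNA(r)) {
    if (is.na(unknown_radius)) {
      bad <- which(is.na(r))[1]
      stop(sprintf(paste0("no van der Waals radius for element '%s' ",
                          "(atom %s %s%d); supply unknown_radius to use a ",
                          "fallback"),
                   el[bad], a$name[bad], a$resname[bad], a$resno[bad]),
           call. = FALSE)
    }
    r[is.na(r)] <- unknown_radius
  }
  r <- unname(r)
  xyz <- cbind(a$x, a$y, a$z)
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  rext <- r + probe

  # neighbour lists: atoms within r_i + r_j + 2*probe can occlude each other
  cut <- max(rext) + max(r) + probe
  asa <- numeric(n)
  # coarse grid binning to keep the neighbour search near-linear
  cell <- cut
  bin <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  binkey <- paste(bin[, 1], bin[, 2], bin[, 3])
  bybin <- split(seq_len(n), binkey)
  binidx <- unique(bin)
  rownames(binidx) <- unique(binkey)

  neighbours_of <- function(i) {
    b <- bin[i, ]
    keys <- as.vector(outer(
      as.vector(outer(paste(b[1] + (-1:1)), paste(b[2] + (-1:1)), paste)),
      paste(b[3] + (-1:1)), paste))
    cand <- unlist(bybin[keys], use.names = FALSE)
    cand[cand != i]
  }

  for (i in seq_len(n)) {
    cand <- neighbours_of(i)
    if (length(cand)) {
      d2 <- rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[i, ])^2)
      near <- cand[d2 < (rext[i] + r[cand] + probe)^2 & d2 > 1e-12]
    } else near <- integer(0)
    test <- sweep(pts * rext[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in near) {
      if (!any(exposed)) break
      dj2 <- rowSums(sweep(test[exposed, , drop = FALSE], 2, xyz[j, ])^2)
      exposed[exposed] <- dj2 > rext[j]^2
    }
    asa[i] <- sum(exposed) / n_points * 4 * pi * rext[i]^2
  }
  out <- a[, c("serial", "name", "resname", "chain", "resno", "icode",
               "chain_key", "element")]
  out$radius <- r
  out$asa <- asa
  out
}

#' Sum per-atom ASA into per-residue ASA
#'
#' @param atom_asa result of [shrake_rupley_asa()].
#' @param s the structure it was computed from (residue order).
#' @return data.frame: one row per ATOM-record residue (waters and other
#'   HETATM groups never enter the sums) with `resname`, `chain`, `resno`,
#'   `icode` and summed `asa`.
#' @export
residue_asa <- function(atom_asa, s) {
  rt <- residue_table(s)
  if (!nrow(rt)) return(cbind(rt, asa = numeric(0)))
  rkey <- paste(rt$chain_key, rt$resno, rt$icode, sep = "|")
  akey <- paste(atom_asa$chain_key, atom_asa$resno, atom_asa$icode, sep = "|")
  akey <- akey[atom_asa$resname != "HOH"]
  vals <- atom_asa$asa[atom_asa$resname != "HOH"]
  sums <- vapply(rkey, function(k) sum(vals[akey == k]), 0)
  out <- rt[, c("resname", "chain", "resno", "icode")]
  out$asa <- unname(sums)
  out
}

#' The packaged table of per-residue maximum accessible surface areas
#'
#' Theoretical maxima (extended-tripeptide context) for the 20 standard
#' residues, in angstroms squared; glycine holds the minimum and tryptophan
#' the maximum.
#'
#' @param path optional path to an override CSV with columns
#'   `residue,maxasa`.
#' @return named numeric vector over 3-letter residue codes.
#' @export
max_asa_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "maxasa.csv", package = "prostat")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  t <- stats::setNames(df$maxasa, toupper(df$residue))
  if (length(t) != 20 || any(t <= 0)) {
    stop("MaxASA table must hold 20 positive entries", call. = FALSE)
  }
  t
}

#' Relative solvent accessibility of a structure
#'
#' Computes per-residue ASA by Shrake-Rupley, then the relative accessibility
#' as 100 * sum(ASA) / sum(MaxASA), where the denominator sums the
#' theoretical per-residue maxima over the same residues.  Residues absent
#' from the MaxASA table are excluded from both sums and listed in
#' `skipped_residues`.  A sparse or single-residue input can legitimately
#' exceed 100 (the maxima assume a tripeptide context); a warning is issued.
#'
#' @param s a `prostat_structure`.
#' @param table MaxASA lookup from [max_asa_table()].
#' @param scale `"percent"` (0-100, default) or `"fraction"` (0-1).
#' @inheritParams shrake_rupley_asa
#' @return an object of class `accessibility_result`: list with
#'   `per_residue_asa` (data.frame), `total_asa`, `total_max_asa`,
#'   `rsa` (on the requested scale) and `skipped_residues`.
#' @export
relative_accessibility <- function(s, table = max_asa_table(), probe = 1.4,
                                   n_points = 960,
                                   scale = c("percent", "fraction"),
                                   unknown_radius = NA) {
  scale <- match.arg(scale)
  atom_asa <- shrake_rupley_asa(s, probe = probe, n_points = n_points,
                                unknown_radius = unknown_radius)
  res <- residue_asa(atom_asa, s)
  known <- res$resname %in% names(table)
  if (!any(known)) {
    stop("no residues with a MaxASA table entry; cannot compute relative ",
         "accessibility", call. = FALSE)
  }
  total_asa <- sum(res$asa[known])
  total_max <- sum(table[res$resname[known]])
  rsa <- total_asa / total_max * if (scale == "percent") 100 else 1
  if (rsa > (if (scale == "percent") 100 else 1)) {
    warning("relative accessibility exceeds the tripeptide maxima ",
            "(sparse or isolated-residue input)", call. = FALSE)
  }
  structure(list(per_residue_asa = res, total_asa = total_asa,
                 total_max_asa = total_max, rsa = rsa, scale = scale,
                 skipped_residues = res[!known, , drop = FALSE]),
            class = "accessibility_result")
}

#' @export
print.accessibility_result <- function(x, ...) {
  cat(sprintf("<accessibility: ASA %.1f A^2 / MaxASA %.1f A^2 = %.2f%s>\n",
              x$total_asa, x$total_max_asa, x$rsa,
              if (x$scale == "percent") "%" else ""))
  invisible(x)
}
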