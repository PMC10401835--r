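# Backbone dihedrals, Ramachandran-region classification, and the
# percent-favored model-quality score.

#' Signed torsion angle of four points
#'
#' The dihedral about the p2-p3 axis in degrees, IUPAC sign convention
#' (clockwise positive looking from p2 to p3), in (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-9 || sqrt(sum(b2^2)) < 1e-9 ||
      sqrt(sum(b3^2)) < 1e-9) {
    stop("degenerate dihedral: coincident consecutive points", call. = FALSE)
  }
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) {
    stop("degenerate dihedral: three collinear points", call. = FALSE)
  }
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / sqrt(sum(b2^2))
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.backbone_atom <- function(a, key, name) {
  i <- which(a$name == name)
  i[match(key, paste(a$chain_key[i], a$resno[i], a$icode[i], sep = "|"))]
}

#' Backbone phi/psi angles of every residue
#'
#' phi(i) = dihedral(C(i-1), N(i), CA(i), C(i)); psi(i) = dihedral(N(i),
#' CA(i), C(i), N(i+1)).  The first residue has no phi and the last no psi.
#' A peptide C-N distance above `break_cutoff` is treated as a chain break:
#' no angle is computed across it.  Residues missing a needed backbone atom
#' have the affected angle absent (NA) and are flagged.
#'
#' @param s a `prostat_structure` (typically one chain).
#' @param break_cutoff chain-break threshold on the C(i)-N(i+1) distance,
#'   angstroms.
#' @return data.frame: one row per residue with `resname`, `chain`, `resno`,
#'   `icode`, `phi`, `psi` (degrees, NA where undefined) and `incomplete`
#'   (TRUE when a backbone atom was missing).
#' @export
phi_psi <- function(s, break_cutoff = 2.5) {
  rt <- residue_table(s)
  a <- s$atoms[s$atoms$record == "ATOM", , drop = FALSE]
  n <- nrow(rt)
  out <- rt[, c("resname", "chain", "resno", "icode")]
  out$phi <- rep(NA_real_, n); out$psi <- rep(NA_real_, n)
  out$incomplete <- rep(FALSE, n)
  if (!n) return(out)
  key <- paste(rt$chain_key, rt$resno, rt$icode, sep = "|")
  iN <- .backbone_atom(a, key, "N")
  iCA <- .backbone_atom(a, key, "CA")
  iC <- .backbone_atom(a, key, "C")
  xyz <- cbind(a$x, a$y, a$z)
  at <- function(i) if (is.na(i)) NULL else xyz[i, ]
  out$incomplete <- is.na(iN) | is.na(iCA) | is.na(iC)
  same_chain <- c(FALSE, rt$chain_key[-1] == rt$chain_key[-n])
  linked <- function(i) {
    # peptide bond between residue i-1 and i, within one chain
    if (!same_chain[i]) return(FALSE)
    if (is.na(iC[i - 1]) || is.na(iN[i])) return(FALSE)
    sqrt(sum((xyz[iC[i - 1], ] - xyz[iN[i], ])^2)) <= break_cutoff
  }
  for (i in seq_len(n)) {
    if (i > 1 && !out$incomplete[i] && !is.na(iC[i - 1]) && linked(i)) {
      out$phi[i] <- dihedral(at(iC[i - 1]), at(iN[i]), at(iCA[i]), at(iC[i]))
    }
    if (i < n && !out$incomplete[i] && !is.na(iN[i + 1]) &&
        same_chain[i + 1] && !is.na(iC[i]) &&
        sqrt(sum((xyz[iC[i], ] - xyz[iN[i + 1], ])^2)) <= break_cutoff) {
      out$psi[i] <- dihedral(at(iN[i]), at(iCA[i]), at(iC[i]), at(iN[i + 1]))
    }
  }
  out
}

# Analytic Ramachandran region definitions.  These are a synthetic
# approximation of the classic favored/allowed regions (alpha, beta/PPII and
# left-handed-alpha basins, with dedicated glycine and proline classes)
# defined as ellipse/box unions -- NOT a curated empirical density; scores
# are comparable between structures analysed here but not with
# PROCHECK/SAVES numbers.
.in_ellipse <- function(phi, psi, c_phi, c_psi, r_phi, r_psi) {
  ((phi - c_phi) / r_phi)^2 + ((psi - c_psi) / r_psi)^2 <= 1
}

.rama_region_class <- function(phi, psi, restype) {
  if (restype == "GLY") {
    fav <- .in_ellipse(phi, psi, -63, -43, 55, 60) ||
      .in_ellipse(phi, psi, 63, 43, 55, 60) ||
      (phi >= -180 && phi <= -45 && (psi >= 90 || psi <= -150)) ||
      (phi >= 45 && phi <= 180 && (psi >= 150 || psi <= -90))
    if (fav) return("favored")
    if (.in_ellipse(phi, psi, -63, -43, 85, 90) ||
        .in_ellipse(phi, psi, 63, 43, 85, 90) ||
        abs(psi) >= 60) return("allowed")
    return("outlier")
  }
  if (restype == "PRO") {
    if (.in_ellipse(phi, psi, -61, -35, 25, 40) ||
        .in_ellipse(phi, psi, -61, 150, 25, 40)) return("favored")
    if (phi >= -110 && phi <= -35 &&
        (psi >= -60 && psi <= 190 || psi >= 100 || psi <= -170)) return("allowed")
    return("outlier")
  }
  # general (incl. pre-proline): alpha basin, beta/PPII basin, L-alpha basin
  fav <- .in_ellipse(phi, psi, -63, -43, 45, 50) ||
    (phi >= -170 && phi <= -50 && psi >= 90 && psi <= 180) ||
    (phi >= -170 && phi <= -50 && psi <= -160)
  if (fav) return("favored")
  allowed <- .in_ellipse(phi, psi, -63, -43, 75, 85) ||
    (phi >= -180 && phi <= -40 && (psi >= 70 || psi <= -140)) ||
    .in_ellipse(phi, psi, 60, 40, 40, 50)
  if (allowed) return("allowed")
  "outlier"
}

#' Classify a phi/psi pair into a Ramachandran region
#'
#' Looks the angles up in the packaged 2-degree grid thresholded into
#' favored / allowed / outlier, with separate grids for glycine and proline.
#' The grid is generated from analytic approximations of the classical
#' regions (see the package vignette); it is a synthetic reference, not a
#' curated empirical density.
#'
#' @param phi,psi angles in degrees, in (-180, 180].
#' @param restype 3-letter residue code; GLY and PRO get their own grids.
#' @return one of "favored", "allowed", "outlier".
#' @export
rama_classify <- function(phi, psi, restype = "ALA") {
  g <- rama_grid()
  cls <- if (restype %in% c("GLY", "PRO")) restype else "GEN"
  bi <- pmin(pmax(floor((phi + 180) / 2) + 1, 1), 180)
  bj <- pmin(pmax(floor((psi + 180) / 2) + 1, 1), 180)
  c("outlier", "allowed", "favored")[g[[cls]][cbind(bi, bj)] + 1L]
}

.rama_cache <- new.env(parent = emptyenv())

#' The packaged Ramachandran classification grid
#'
#' 2-degree by 2-degree grids (general, glycine, proline) with values
#' 0 = outlier, 1 = allowed, 2 = favored, generated deterministically from
#' the analytic region definitions.
#'
#' @return list of three 180x180 integer matrices (`GEN`, `GLY`, `PRO`).
#' @export
rama_grid <- function() {
  if (!is.null(.rama_cache$grid)) return(.rama_cache$grid)
  centers <- seq(-179, 179, by = 2)
  build <- function(restype) {
    m <- matrix(0L, 180, 180)
    for (i in seq_along(centers)) {
      for (j in seq_along(centers)) {
        r <- .rama_region_class(centers[i], centers[j], restype)
        m[i, j] <- c(outlier = 0L, allowed = 1L, favored = 2L)[r]
      }
    }
    m
  }
  .rama_cache$grid <- list(GEN = build("ALA"), GLY = build("GLY"),
                           PRO = build("PRO"))
  .rama_cache$grid
}

#' Ramachandran report and model-quality score for a structure
#'
#' Computes phi/psi for every residue, classifies each residue with both
#' angles, and scores the structure as 100 * favored / scored.
#'
#' @param s a `prostat_structure`.
#' @param break_cutoff chain-break threshold, angstroms.
#' @return an object of class `ramachandran_report`: list with
#'   `per_residue` (data.frame with phi, psi, region), `rc_score`
#'   (percentage) and `n_scored`.
#' @export
ramachandran_report <- function(s, break_cutoff = 2.5) {
  pp <- phi_psi(s, break_cutoff)
  pp$region <- NA_character_
  scorable <- !is.na(pp$phi) & !is.na(pp$psi)
  if (!any(scorable)) {
    stop("no residue has both phi and psi; cannot score", call. = FALSE)
  }
  for (i in which(scorable)) {
    pp$region[i] <- rama_classify(pp$phi[i], pp$psi[i], pp$resname[i])
  }
  n_scored <- sum(scorable)
  structure(list(per_residue = pp,
                 rc_score = 100 * sum(pp$region == "favored", na.rm = TRUE) /
                   n_scored,
                 n_scored = n_scored),
            class = "ramachandran_report")
}

#' Ramachandran model-quality score
#'
#' Percentage of residues (with both backbone angles defined) that fall in
#' the favored region; glycine and proline are scored against their own
#' grids.
#'
#' @inheritParams ramachandran_report
#' @return percentage in \[0, 100\].
#' @export
rc_score <- function(s, break_cutoff = 2.5) {
  ramachandran_report(s, break_cutoff)$rc_score
}

#' @export
print.ramachandran_report <- function(x, ...) {
  tab <- table(factor(x$per_residue$region,
                      levels = c("favored", "allowed", "outlier")))
  cat(sprintf("<ramachandran: %d scored, favored %d / allowed %d / outlier %d, score %.1f>\n",
              x$n_scored, tab["favored"], tab["allowed"], tab["outlier"],
              x$rc_score))
  invisible(x)
}
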