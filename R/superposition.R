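# Rigid-body superposition (Kabsch) and its scores: RMSD and the global
# distance test (GDT_P1/2/4/8, GDT_TS).

#' Optimal rigid superposition of paired point sets (Kabsch algorithm)
#'
#' Computes the rotation and translation mapping the mobile set `w` onto the
#' reference set `v` so that the RMSD over pairs is minimal.  The rotation is
#' obtained from the SVD of the coordinate cross-covariance with the usual
#' determinant sign correction, so a proper rotation (no reflection) is
#' always returned.
#'
#' @param p a `ca_pairs` object with at least 3 non-collinear pairs.
#' @return list with `rotation` (3x3, det +1), `translation` (length-3);
#'   the transform maps a mobile coordinate row-vector q to
#'   `q %*% t(rotation) + translation`.
#' @export
kabsch <- function(p) {
  stopifnot(inherits(p, "ca_pairs"))
  if (p$n < 3) {
    stop("superposition needs at least 3 paired residues (got ", p$n,
         "); with mode='identical' too few identical residues may remain - ",
         "try mode='all'", call. = FALSE)
  }
  v <- p$v; w <- p$w
  cv <- colMeans(v); cw <- colMeans(w)
  v0 <- sweep(v, 2, cv); w0 <- sweep(w, 2, cw)
  sv <- svd(crossprod(w0, v0))          # A = W0^T V0 (3x3)
  if (sv$d[2] < 1e-10) {
    stop("degenerate point set (collinear or coincident pairs); ",
         "superposition is not unique", call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = R, translation = as.numeric(cv - R %*% cw))
}

#' Root-mean-square deviation of paired coordinates
#'
#' `sqrt(mean(|v_i - w_i|^2))` over the pairs, in the same units as the
#' coordinates (angstroms).  No superposition is performed; apply
#' [kabsch()] / [transform_structure()] first if the sets are not already
#' superposed.
#'
#' @param p a `ca_pairs` object with at least one pair.
#' @return RMSD in angstroms.
#' @export
rmsd <- function(p) {
  stopifnot(inherits(p, "ca_pairs"))
  if (p$n == 0) stop("RMSD of an empty pair set is undefined", call. = FALSE)
  sqrt(mean(rowSums((p$v - p$w)^2)))
}

.pair_distances <- function(p) sqrt(rowSums((p$v - p$w)^2))

#' Percentage of pairs within a distance cutoff (GDT_PN)
#'
#' `100 * count(distance <= cutoff) / n` over the pairs; the comparison is
#' inclusive.  The denominator is the pair count by default; pass the
#' reference chain length as `denominator` for the stricter convention in
#' which alignment-dropped residues still count against the score.
#'
#' @param p a `ca_pairs` object with at least one pair.
#' @param cutoff positive distance cutoff in angstroms.
#' @param denominator denominator of the percentage; defaults to `p$n`.
#' @return percentage in \[0, 100\].
#' @export
gdt_pn <- function(p, cutoff, denominator = p$n) {
  stopifnot(inherits(p, "ca_pairs"))
  if (p$n == 0) stop("GDT of an empty pair set is undefined", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  100 * sum(.pair_distances(p) <= cutoff) / denominator
}

#' Global distance test total score (GDT_TS)
#'
#' Mean of GDT_P1, GDT_P2, GDT_P4 and GDT_P8 — the within-cutoff percentages
#' at 1, 2, 4 and 8 angstroms — computed from a single set of superposed
#' coordinates (not the per-cutoff maximal-subset search of the CASP
#' convention).
#'
#' @inheritParams gdt_pn
#' @return list with `gdt_p` (named vector over cutoffs 1, 2, 4, 8) and
#'   `gdt_ts`.
#' @export
gdt_ts <- function(p, denominator = p$n) {
  gp <- vapply(c(1, 2, 4, 8), function(k) gdt_pn(p, k, denominator), 0)
  names(gp) <- c("1", "2", "4", "8")
  list(gdt_p = gp, gdt_ts = mean(gp))
}

#' Apply a rigid transform to every atom of a structure
#'
#' @param s a `prostat_structure`.
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation length-3 vector, angstroms.
#' @return a transformed deep copy of `s`.
#' @export
transform_structure <- function(s, rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || det(rotation) < 0) {
    stop("not a proper rotation matrix (orthonormal with det +1)", call. = FALSE)
  }
  xyz <- get_coords(s)
  set_coords(s, sweep(xyz %*% t(rotation), 2, -as.numeric(translation)))
}

#' Superpose one structure onto another
#'
#' The full pipeline: extract the chain sequences, align them globally,
#' pair the aligned alpha-carbons (identical residues only by default),
#' compute the Kabsch transform, apply it to every atom of the mobile
#' structure, and score the transformed pairs with RMSD and GDT_TS.
#'
#' @param ref,mobile `prostat_structure` objects.
#' @param ref_chain,mobile_chain chain selections; `NULL` uses the first
#'   chain of each structure.
#' @param mode pairing mode, `"identical"` (default) or `"all"`; see
#'   [aligned_ca_pairs()].
#' @param m substitution matrix for the alignment step.
#' @param denominator `"pairs"` (default) or `"reference-length"` for the
#'   GDT percentage denominator.
#' @return an object of class `superposition_result`: list with `rotation`,
#'   `translation`, `rmsd`, `gdt_p`, `gdt_ts`, `n_pairs`, `mode`,
#'   `alignment`, `skipped` (residues without CA in either input) and
#'   `transformed_mobile` (deep copy; inputs untouched).
#' @export
superpose_structures <- function(ref, mobile, ref_chain = NULL,
                                 mobile_chain = NULL,
                                 mode = c("identical", "all"),
                                 m = blosum62(),
                                 denominator = c("pairs", "reference-length")) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  ra <- stage("select", get_chain(ref, ref_chain %||% chain_ids(ref)[1]))
  rb <- stage("select", get_chain(mobile, mobile_chain %||% chain_ids(mobile)[1]))
  sa <- stage("sequence", extract_sequence(ra))
  sb <- stage("sequence", extract_sequence(rb))
  al <- stage("align", global_align(sa, sb, m))
  ca_a <- stage("ca", ca_coordinates(ra))
  ca_b <- stage("ca", ca_coordinates(rb))
  pr <- stage("pair", aligned_ca_pairs(al, ca_a, ca_b, mode))
  tr <- stage("kabsch", kabsch(pr))
  moved <- stage("transform",
                 transform_structure(mobile, tr$rotation, tr$translation))
  w2 <- sweep(pr$w %*% t(tr$rotation), 2, -tr$translation)
  scored <- ca_pairs(pr$v, w2, mode = mode)
  den <- if (denominator == "pairs") scored$n else nchar(sa)
  g <- stage("score", gdt_ts(scored, den))
  structure(list(rotation = tr$rotation, translation = tr$translation,
                 rmsd = rmsd(scored), gdt_p = g$gdt_p, gdt_ts = g$gdt_ts,
                 n_pairs = scored$n, mode = mode, alignment = al,
                 skipped = list(ref = ca_a$skipped, mobile = ca_b$skipped),
                 transformed_mobile = moved),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf(paste0("<superposition: %d pairs (%s), RMSD %.4f A, ",
                     "GDT_TS %.1f [P1 %.1f P2 %.1f P4 %.1f P8 %.1f]>\n"),
              x$n_pairs, x$mode, x$rmsd, x$gdt_ts,
              x$gdt_p["1"], x$gdt_p["2"], x$gdt_p["4"], x$gdt_p["8"]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
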