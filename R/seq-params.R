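# Sequence-derived physicochemical parameters: molecular weight, GRAVY
# hydropathy, instability index, isoelectric point.

# average masses of the free amino acids (Da); a peptide bond removes one
# water per link
.AA_MASS <- c(A = 89.0932, R = 174.2010, N = 132.1179, D = 133.1027,
              C = 121.1582, E = 147.1293, Q = 146.1445, G = 75.0666,
              H = 155.1546, I = 131.1729, L = 131.1729, K = 146.1876,
              M = 149.2113, F = 165.1891, P = 115.1305, S = 105.0926,
              T = 119.1192, W = 204.2252, Y = 181.1885, V = 117.1463)
.WATER_MASS <- 18.0153

# Kyte-Doolittle hydropathy scale
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# ionizable-group pKa sets; N/C termini plus D, E, C, Y, H, K, R side chains
.PKA_SETS <- list(
  emboss = c(Nterm = 8.6, Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5,
             Y = 10.1, H = 6.5, K = 10.8, R = 12.5),
  bjellqvist = c(Nterm = 7.5, Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0,
                 Y = 10.0, H = 5.98, K = 10.0, R = 12.0)
)

.diwv_cache <- new.env(parent = emptyenv())

#' The dipeptide instability weight table (DIWV)
#'
#' The published 20x20 dipeptide weights behind the instability index.
#'
#' @return 20x20 numeric matrix, rows = first residue, cols = second.
#' @export
diwv_table <- function() {
  if (is.null(.diwv_cache$m)) {
    df <- utils::read.csv(system.file("extdata", "diwv.csv",
                                      package = "prostat"))
    aas <- sort(unique(df$first))
    m <- matrix(NA_real_, 20, 20, dimnames = list(aas, aas))
    m[cbind(df$first, df$second)] <- df$weight
    .diwv_cache$m <- m
  }
  .diwv_cache$m
}

.seq_chars <- function(seq, allow_x = TRUE) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq)) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  ch <- strsplit(toupper(seq), "")[[1]]
  ok <- names(.AA_MASS)
  if (allow_x) ok <- c(ok, "X")
  bad <- which(!ch %in% ok)
  if (length(bad)) {
    stop(sprintf("illegal residue '%s' at position %d", ch[bad[1]], bad[1]),
         call. = FALSE)
  }
  ch
}

#' Molecular weight of a peptide, in kilodaltons
#'
#' Sum of average residue masses minus one water per peptide bond.
#'
#' @param seq one-letter sequence.  "X" is an error unless
#'   `x_as_average = TRUE`, which substitutes the mean residue mass.
#' @param x_as_average treat "X" as an average-mass residue.
#' @return weight in kDa.
#' @export
molecular_weight <- function(seq, x_as_average = FALSE) {
  ch <- .seq_chars(seq, allow_x = x_as_average)
  if (!x_as_average && any(ch == "X")) {
    stop("sequence contains 'X'; set x_as_average = TRUE to use the mean ",
         "residue mass", call. = FALSE)
  }
  mass <- .AA_MASS[ch]
  mass[is.na(mass)] <- mean(.AA_MASS)
  (sum(mass) - (length(ch) - 1) * .WATER_MASS) / 1000
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy per residue; bounded by the scale extremes
#' -4.5 (arginine) and +4.5 (isoleucine).  "X" residues are excluded from
#' both the sum and the count.
#'
#' @param seq one-letter sequence.
#' @return GRAVY value in \[-4.5, 4.5\].
#' @export
gravy <- function(seq) {
  ch <- .seq_chars(seq)
  ch <- ch[ch != "X"]
  if (!length(ch)) stop("no scorable residues (all 'X')", call. = FALSE)
  mean(.KD[ch])
}

#' Instability index
#'
#' `(10 / L) * sum(DIWV[s_i, s_i+1])` over the L-1 dipeptides, using the
#' published dipeptide instability weights.  Dipeptides involving "X"
#' contribute weight 1.  The raw value is returned unclamped (it can exceed
#' 100); values above 40 conventionally predict an unstable protein.
#'
#' @param seq one-letter sequence of length >= 2.
#' @return instability index (dimensionless).
#' @export
instability_index <- function(seq) {
  ch <- .seq_chars(seq)
  L <- length(ch)
  if (L < 2) stop("instability index needs at least 2 residues", call. = FALSE)
  m <- diwv_table()
  a <- ch[-L]; b <- ch[-1]
  w <- rep(1, L - 1)
  ok <- a != "X" & b != "X"
  w[ok] <- m[cbind(a[ok], b[ok])]
  10 / L * sum(w)
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch over the N-terminus, C-terminus and the D/E/C/Y
#' (acidic) and H/K/R (basic) side chains.
#'
#' @param seq one-letter sequence.
#' @param ph pH value(s).
#' @param pka_set `"emboss"` (default) or `"bjellqvist"`.
#' @return net charge (same length as `ph`); strictly decreasing in pH.
#' @export
net_charge <- function(seq, ph, pka_set = c("emboss", "bjellqvist")) {
  pka <- .PKA_SETS[[match.arg(pka_set)]]
  ch <- .seq_chars(seq)
  counts <- table(factor(ch, levels = c("D", "E", "C", "Y", "H", "K", "R")))
  pos_pka <- c(pka["Nterm"], rep(pka["H"], counts["H"]),
               rep(pka["K"], counts["K"]), rep(pka["R"], counts["R"]))
  neg_pka <- c(pka["Cterm"], rep(pka["D"], counts["D"]),
               rep(pka["E"], counts["E"]), rep(pka["C"], counts["C"]),
               rep(pka["Y"], counts["Y"]))
  vapply(ph, function(p) {
    sum(1 / (1 + 10^(p - pos_pka))) - sum(1 / (1 + 10^(neg_pka - p)))
  }, 0)
}

#' Isoelectric point
#'
#' The pH at which the net charge crosses zero, found by bisection on
#' \[0, 14\] (the Henderson-Hasselbalch net charge is strictly decreasing in
#' pH, so the root is unique).
#'
#' @param seq one-letter sequence.
#' @param pka_set `"emboss"` (default) or `"bjellqvist"`.
#' @param tol bisection tolerance in pH units.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka_set = c("emboss", "bjellqvist"),
                              tol = 1e-3) {
  pka_set <- match.arg(pka_set)
  lo <- 0; hi <- 14
  if (net_charge(seq, lo, pka_set) < 0) return(lo)
  if (net_charge(seq, hi, pka_set) > 0) return(hi)
  iter <- 0
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid, pka_set)
    # stop once the interval is below tol AND the charge itself has vanished
    # (long sequences have steep charge curves, so interval width alone is
    # not enough for the |charge(pI)| root condition)
    if ((hi - lo <= tol / 2 && abs(q) < 1e-4) || iter > 200) break
    if (q > 0) lo <- mid else hi <- mid
    iter <- iter + 1
  }
  mid
}

#' All four sequence-derived parameters at once
#'
#' @param seq one-letter sequence.
#' @param pka_set pKa set for the isoelectric point.
#' @return an object of class `sequence_parameters`: list with
#'   `molecular_weight` (kDa), `instability_index`, `gravy` and
#'   `isoelectric_point`.
#' @export
compute_parameters <- function(seq, pka_set = "emboss") {
  structure(list(molecular_weight = molecular_weight(seq, x_as_average = TRUE),
                 instability_index = if (nchar(seq) >= 2)
                   instability_index(seq) else NA_real_,
                 gravy = gravy(seq),
                 isoelectric_point = isoelectric_point(seq, pka_set)),
            class = "sequence_parameters")
}

#' @export
print.sequence_parameters <- function(x, ...) {
  cat(sprintf("<params: MW %.3f kDa, instability %.1f, GRAVY %+.3f, pI %.2f>\n",
              x$molecular_weight, x$instability_index, x$gravy,
              x$isoelectric_point))
  invisible(x)
}
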