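# Global pairwise sequence alignment (Needleman-Wunsch, affine gaps) and the
# aligned-CA pairing that feeds superposition.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Build a substitution matrix object
#'
#' @param scores 20x20 (or larger) symmetric integer matrix with residue
#'   letters as dimnames.  An "X" row/column scoring 0 against everything is
#'   added if absent.
#' @param gap_open non-negative gap opening penalty.  A gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @param gap_extend non-negative per-position gap extension penalty; must
#'   not exceed `gap_open`.
#' @return an object of class `substitution_matrix`.
#' @export
substitution_matrix <- function(scores, gap_open = 10, gap_extend = 0.5) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)))
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be non-negative")
  if (gap_extend > gap_open) stop("gap_extend must not exceed gap_open")
  if (max(abs(scores - t(scores))) > 0) stop("substitution scores must be symmetric")
  if (!"X" %in% rownames(scores)) {
    scores <- rbind(cbind(scores, X = 0), X = 0)
  }
  structure(list(scores = scores, gap_open = gap_open, gap_extend = gap_extend),
            class = "substitution_matrix")
}

#' The default BLOSUM62 substitution matrix
#'
#' Published BLOSUM62 scores over the 20 standard residues, with "X" scoring
#' 0 against everything; gap opening 10 and extension 0.5 by default.
#'
#' @inheritParams substitution_matrix
#' @return a `substitution_matrix`.
#' @export
blosum62 <- function(gap_open = 10, gap_extend = 0.5) {
  path <- system.file("extdata", "blosum62.csv", package = "prostat")
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1]); rownames(m) <- df$aa
  substitution_matrix(m, gap_open, gap_extend)
}

#' Read a substitution matrix from an NCBI-format file
#'
#' Parses the whitespace-delimited matrix format distributed by NCBI
#' (comment lines starting with '#', a header row of letters, one labelled
#' row per letter).
#'
#' @param path file path.
#' @inheritParams substitution_matrix
#' @return a `substitution_matrix`.
#' @export
read_ncbi_matrix <- function(path, gap_open = 10, gap_extend = 0.5) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("not an NCBI-format matrix file: ", path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  m <- matrix(NA_real_, length(rows), length(hdr),
              dimnames = list(vapply(rows, `[`, "", 1), hdr))
  for (i in seq_along(rows)) m[i, ] <- as.numeric(rows[[i]][-1])
  keep <- intersect(rownames(m), .AA20)
  substitution_matrix(m[keep, keep, drop = FALSE], gap_open, gap_extend)
}

.check_seq <- function(seq, who, alphabet) {
  if (!nzchar(seq)) stop("sequence ", who, " is empty", call. = FALSE)
  ch <- strsplit(seq, "")[[1]]
  bad <- which(!ch %in% alphabet)
  if (length(bad)) {
    stop(sprintf("illegal character '%s' at position %d of sequence %s",
                 ch[bad[1]], bad[1], who), call. = FALSE)
  }
  ch
}

#' Global alignment of two protein sequences
#'
#' Needleman-Wunsch with affine gap penalties (a gap of length k costs
#' `gap_open + k * gap_extend`), maximizing the substitution-matrix score.
#' Traceback ties are broken deterministically: diagonal first, then a gap in
#' the second sequence, then a gap in the first.
#'
#' @param a,b protein sequences (20 standard letters plus "X").
#' @param m a `substitution_matrix`; default [blosum62()].
#' @return an object of class `alignment`: list with `aligned_a`, `aligned_b`
#'   (gapped strings of equal length), `score`, `identity` (fraction of
#'   non-gap columns with identical letters), and `pairs` (data.frame with
#'   0-based `index_a`, `index_b`, logical `identical`, one row per
#'   residue-vs-residue column).
#' @export
global_align <- function(a, b, m = blosum62()) {
  alphabet <- rownames(m$scores)
  ca <- .check_seq(a, "a", alphabet)
  cb <- .check_seq(b, "b", alphabet)
  n <- length(ca); p <- length(cb)
  S <- m$scores[ca, cb, drop = FALSE]
  go <- m$gap_open; ge <- m$gap_extend
  NEG <- -1e18

  # affine-gap DP (Gotoh): M match/mismatch, X gap in b (consume a), Y gap in a
  M <- matrix(NEG, n + 1, p + 1); X <- matrix(NEG, n + 1, p + 1)
  Y <- matrix(NEG, n + 1, p + 1)
  M[1, 1] <- 0
  if (n >= 1) X[2:(n + 1), 1] <- -(go + ge * seq_len(n))
  if (p >= 1) Y[1, 2:(p + 1)] <- -(go + ge * seq_len(p))
  for (i in 2:(n + 1)) {
    Mprev <- M[i - 1, ]; Xprev <- X[i - 1, ]; Yprev <- Y[i - 1, ]
    best_prev <- pmax(Mprev, Xprev, Yprev)
    X[i, ] <- pmax(best_prev - go - ge, Xprev - ge)
    Xi <- X[i, ]
    for (j in 2:(p + 1)) {
      M[i, j] <- max(Mprev[j - 1], Xprev[j - 1], Yprev[j - 1]) + S[i - 1, j - 1]
      Y[i, j] <- max(M[i, j - 1] - go - ge, X[i, j - 1] - go - ge,
                     Y[i, j - 1] - ge)
    }
  }
  score <- max(M[n + 1, p + 1], X[n + 1, p + 1], Y[n + 1, p + 1])

  # traceback; tie order: diagonal (M), gap in b (X), gap in a (Y)
  i <- n; j <- p
  state <- c("M", "X", "Y")[which.max(c(M[n + 1, p + 1], X[n + 1, p + 1],
                                        Y[n + 1, p + 1]))]
  ra <- character(0); rb <- character(0)
  tol <- 1e-9
  while (i > 0 || j > 0) {
    if (state == "M") {
      ra <- c(ca[i], ra); rb <- c(cb[j], rb)
      cur <- M[i + 1, j + 1] - S[i, j]
      state <- if (abs(cur - M[i, j]) < tol) "M"
               else if (abs(cur - X[i, j]) < tol) "X" else "Y"
      i <- i - 1; j <- j - 1
    } else if (state == "X") {          # gap in b: consume a
      ra <- c(ca[i], ra); rb <- c("-", rb)
      cur <- X[i + 1, j + 1]
      state <- if (abs(cur - (M[i, j + 1] - go - ge)) < tol) "M"
               else if (abs(cur - (X[i, j + 1] - ge)) < tol) "X" else "Y"
      i <- i - 1
    } else {                            # gap in a: consume b
      ra <- c("-", ra); rb <- c(cb[j], rb)
      cur <- Y[i + 1, j + 1]
      state <- if (abs(cur - (M[i + 1, j] - go - ge)) < tol) "M"
               else if (abs(cur - (Y[i + 1, j] - ge)) < tol) "Y" else "X"
      j <- j - 1
    }
    if (i == 0 && j > 0) state <- "Y"
    if (j == 0 && i > 0) state <- "X"
  }

  aligned_a <- paste(ra, collapse = ""); aligned_b <- paste(rb, collapse = "")
  both <- ra != "-" & rb != "-"
  ident <- both & ra == rb
  pairs <- data.frame(
    index_a = cumsum(ra != "-")[both] - 1L,
    index_b = cumsum(rb != "-")[both] - 1L,
    identical = ident[both]
  )
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = score,
                 identity = if (any(both)) mean(ident[both]) else 0,
                 pairs = pairs),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment score=%.1f identity=%.1f%% columns=%d>\n%s\n%s\n",
              x$score, 100 * x$identity, nchar(x$aligned_a),
              x$aligned_a, x$aligned_b))
  invisible(x)
}

#' Pair aligned alpha-carbon coordinates
#'
#' Builds the paired coordinate sets entering superposition: one (v, w) pair
#' per aligned column whose residues are identical (`mode = "identical"`, the
#' default) or merely both present (`mode = "all"`).  Columns whose residue
#' lacks a CA atom in either structure are dropped.
#'
#' @param al an [global_align()] result for the two chain sequences.
#' @param ca_a,ca_b [ca_coordinates()] results for the same chains.
#' @param mode `"identical"` or `"all"`.
#' @return an object of class `ca_pairs`: list with `v`, `w` (n x 3
#'   matrices), `n`, and `mode`.
#' @export
aligned_ca_pairs <- function(al, ca_a, ca_b, mode = c("identical", "all")) {
  mode <- match.arg(mode)
  pr <- al$pairs
  if (mode == "identical") pr <- pr[pr$identical, , drop = FALSE]
  na <- max(pr$index_a, -1L); nb <- max(pr$index_b, -1L)
  seq_len_a <- nchar(gsub("-", "", al$aligned_a))
  seq_len_b <- nchar(gsub("-", "", al$aligned_b))
  if (na >= seq_len_a || nb >= seq_len_b) {
    stop("alignment index out of range of the sequences", call. = FALSE)
  }
  ma <- match(pr$index_a, ca_a$residue_index)
  mb <- match(pr$index_b, ca_b$residue_index)
  keep <- !is.na(ma) & !is.na(mb)
  if (max(c(ca_a$residue_index, -1L)) >= seq_len_a ||
      max(c(ca_b$residue_index, -1L)) >= seq_len_b) {
    stop("CA coordinate index out of range of the aligned sequences", call. = FALSE)
  }
  v <- ca_a$coords[ma[keep], , drop = FALSE]
  w <- ca_b$coords[mb[keep], , drop = FALSE]
  ca_pairs(v, w, mode = mode)
}

#' Construct a paired-coordinate set
#'
#' @param v,w n x 3 coordinate matrices (reference and mobile).
#' @param mode provenance label.
#' @return a `ca_pairs` object.
#' @export
ca_pairs <- function(v, w, mode = "manual") {
  v <- as.matrix(v); w <- as.matrix(w)
  stopifnot(ncol(v) == 3, ncol(w) == 3, nrow(v) == nrow(w))
  if (nrow(v) && (!all(is.finite(v)) || !all(is.finite(w)))) {
    stop("non-finite coordinates in pair set", call. = FALSE)
  }
  structure(list(v = v, w = w, n = nrow(v), mode = mode), class = "ca_pairs")
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of upper-case sequences in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path, call. = FALSE)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE, forceDNAtolower = FALSE),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!length(recs)) stop("no sequences in FASTA file: ", path, call. = FALSE)
  out <- toupper(vapply(recs, function(r) as.character(r)[1], ""))
  names(out) <- vapply(recs, function(r) attr(r, "name"), "")
  out
}
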