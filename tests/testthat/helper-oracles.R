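# Independent oracles used across the suite.  Each one deliberately takes
# the naive route (explicit loops, exhaustive enumeration) so it shares no
# code path with the implementation it checks.

# exhaustive global-alignment score: enumerate every monotone path through
# the (n, p) grid, score substitutions column by column and charge each
# maximal gap run gap_open + k * gap_extend
enum_align_score <- function(a, b, m) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); p <- length(cb)
  paths <- list()
  walk <- function(i, j, moves) {
    if (i == n && j == p) {
      paths[[length(paths) + 1]] <<- moves
      return(invisible())
    }
    if (i < n && j < p) walk(i + 1, j + 1, c(moves, "D"))
    if (i < n) walk(i + 1, j, c(moves, "U"))
    if (j < p) walk(i, j + 1, c(moves, "L"))
  }
  walk(0, 0, character(0))
  score_path <- function(mv) {
    i <- 0; j <- 0; sc <- 0; run <- ""
    for (mvk in mv) {
      if (mvk == "D") {
        i <- i + 1; j <- j + 1
        sc <- sc + m$scores[ca[i], cb[j]]
        run <- ""
      } else {
        if (mvk != run) sc <- sc - m$gap_open
        sc <- sc - m$gap_extend
        if (mvk == "U") i <- i + 1 else j <- j + 1
        run <- mvk
      }
    }
    sc
  }
  max(vapply(paths, score_path, 0))
}

naive_rmsd <- function(v, w) {
  total <- 0
  for (i in seq_len(nrow(v))) {
    total <- total + (v[i, 1] - w[i, 1])^2 + (v[i, 2] - w[i, 2])^2 +
      (v[i, 3] - w[i, 3])^2
  }
  sqrt(total / nrow(v))
}

naive_gdt_pn <- function(v, w, cutoff) {
  cnt <- 0
  for (i in seq_len(nrow(v))) {
    d <- sqrt(sum((v[i, ] - w[i, ])^2))
    if (d <= cutoff) cnt <- cnt + 1
  }
  100 * cnt / nrow(v)
}

naive_instability <- function(seq) {
  m <- diwv_table()
  ch <- strsplit(seq, "")[[1]]
  s <- 0
  for (i in seq_len(length(ch) - 1)) {
    s <- s + m[ch[i], ch[i + 1]]
  }
  10 / length(ch) * s
}

random_pairs <- function(n, spread = 10) {
  v <- matrix(stats::runif(3 * n, -spread, spread), n, 3)
  w <- v + matrix(stats::rnorm(3 * n), n, 3)
  ca_pairs(v, w)
}

random_aa <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, TRUE),
        collapse = "")
}

# glue two structures into one (distinct chains assumed)
merge_structures <- function(s1, s2) {
  a <- rbind(s1$atoms, s2$atoms)
  a$serial <- seq_len(nrow(a))
  structure(list(id = paste0(s1$id, "+", s2$id), atoms = a,
                 source = "synthetic"),
            class = class(s1))
}
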