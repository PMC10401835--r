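test_that("RMSD matches the analytic cases", {
  v <- matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE)
  expect_equal(rmsd(ca_pairs(v, v)), 0)
  expect_equal(rmsd(ca_pairs(matrix(0, 1, 3), matrix(c(3, 4, 0), 1, 3))), 5)
  w <- v; w[2, ] <- w[2, ] + c(2, 0, 0)   # distances 0 and 2
  expect_equal(rmsd(ca_pairs(v, w)), sqrt(2))
  expect_error(rmsd(ca_pairs(matrix(0, 0, 3), matrix(0, 0, 3))), "empty")
})

test_that("vectorized RMSD and GDT equal the naive per-pair loop", {
  set.seed(101)
  for (k in 1:50) {
    p <- random_pairs(sample(1:200, 1))
    expect_equal(rmsd(p), naive_rmsd(p$v, p$w), tolerance = 1e-12)
    for (cutoff in c(1, 2, 4, 8)) {
      expect_equal(gdt_pn(p, cutoff), naive_gdt_pn(p$v, p$w, cutoff),
                   tolerance = 1e-12)
    }
  }
})

test_that("GDT percentages follow the cutoff definition", {
  base <- matrix(0, 3, 3)
  off <- rbind(c(0.5, 0, 0), c(3, 0, 0), c(9, 0, 0))
  p <- ca_pairs(base, off)
  expect_equal(gdt_pn(p, 2), 100 / 3)
  expect_equal(gdt_pn(p, 4), 200 / 3)
  ident <- ca_pairs(base, base)
  for (cutoff in c(0.1, 1, 8)) expect_equal(gdt_pn(ident, cutoff), 100)
  expect_error(gdt_pn(p, 0), "positive")
})

test_that("GDT_TS is the mean of the four cutoff percentages", {
  # every pair exactly 3 A apart: inside 4 and 8, outside 1 and 2
  v <- matrix(stats::rnorm(30), 10, 3)
  w <- v + matrix(rep(c(3, 0, 0), each = 10), 10, 3)
  g <- gdt_ts(ca_pairs(v, w))
  expect_equal(unname(g$gdt_p), c(0, 0, 100, 100))
  expect_equal(g$gdt_ts, 50)
  far <- gdt_ts(ca_pairs(v, v + 10 / sqrt(3)))
  expect_equal(far$gdt_ts, 0)
  expect_equal(gdt_ts(ca_pairs(v, v))$gdt_ts, 100)
})

test_that("GDT is monotone in the cutoff", {
  set.seed(5)
  for (k in 1:50) {
    p <- random_pairs(sample(2:100, 1))
    g <- gdt_ts(p)$gdt_p
    expect_true(all(diff(g) >= 0))
  }
})

test_that("Kabsch recovers a known rigid transform exactly", {
  set.seed(2)
  for (k in 1:20) {
    v <- matrix(stats::rnorm(60, sd = 5), 20, 3)
    R <- random_rotation(k); t <- stats::rnorm(3, sd = 10)
    w <- sweep(v %*% t(R), 2, -t)       # w = R v + t
    tr <- kabsch(ca_pairs(v, w))        # transform mapping w back onto v
    w2 <- sweep(w %*% t(tr$rotation), 2, -tr$translation)
    expect_lt(rmsd(ca_pairs(v, w2)), 1e-6)
    expect_equal(det(tr$rotation), 1, tolerance = 1e-8)
    expect_lt(max(abs(crossprod(tr$rotation) - diag(3))), 1e-8)
  }
})

test_that("Kabsch refuses reflections: mirror images keep det +1", {
  set.seed(9)
  v <- matrix(stats::rnorm(45), 15, 3)
  w <- v %*% diag(c(-1, 1, 1))          # mirror image
  tr <- kabsch(ca_pairs(v, w))
  expect_equal(det(tr$rotation), 1, tolerance = 1e-8)
})

test_that("Kabsch rejects too-few and degenerate pair sets", {
  v <- matrix(stats::rnorm(6), 2, 3)
  expect_error(kabsch(ca_pairs(v, v)), "at least 3")
  expect_error(kabsch(ca_pairs(v, v)), "mode='all'")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(ca_pairs(line, line)), "degenerate")
})

test_that("residual RMSD under coordinate noise stays near the noise level", {
  resid <- vapply(1:20, function(k) {
    set.seed(300 + k)
    v <- matrix(stats::rnorm(300, sd = 8), 100, 3)
    w <- v + matrix(stats::rnorm(300, sd = 0.1), 100, 3)
    R <- random_rotation(k)
    w <- sweep(w %*% t(R), 2, -c(1, 2, 3))
    tr <- kabsch(ca_pairs(v, w))
    rmsd(ca_pairs(v, sweep(w %*% t(tr$rotation), 2, -tr$translation)))
  }, 0)
  expect_true(all(resid <= 0.2))
  expect_true(all(resid > 0))
})

test_that("no rigid perturbation of the Kabsch transform lowers the RMSD", {
  set.seed(77)
  v <- matrix(stats::rnorm(90, sd = 4), 30, 3)
  w <- v + matrix(stats::rnorm(90, sd = 0.5), 30, 3)
  tr <- kabsch(ca_pairs(v, w))
  w0 <- sweep(w %*% t(tr$rotation), 2, -tr$translation)
  best <- rmsd(ca_pairs(v, w0))
  for (k in 1:100) {
    eps <- stats::rnorm(3, sd = 0.02)
    K <- matrix(c(0, -eps[3], eps[2], eps[3], 0, -eps[1],
                  -eps[2], eps[1], 0), 3, 3)
    Q <- diag(3) + K + K %*% K / 2      # small rotation
    Q <- qr.Q(qr(Q)); if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    dt <- stats::rnorm(3, sd = 0.02)
    wp <- sweep(w0 %*% t(Q), 2, -dt)
    expect_gte(rmsd(ca_pairs(v, wp)) + 1e-12, best)
  }
})

test_that("scores are invariant under a common rotation of both structures", {
  set.seed(13)
  ref <- build_peptide(20, "helix", sequence = "ACDEFGHIKLMNPQRSTVWY")
  mob <- perturb(ref, 0.4, seed = 21)
  base <- superpose_structures(ref, mob)
  Q <- random_rotation(99)
  res <- superpose_structures(rigid_transform(ref, Q, c(5, -3, 2)),
                              rigid_transform(mob, Q, c(5, -3, 2)))
  expect_equal(res$rmsd, base$rmsd, tolerance = 1e-8)
  expect_equal(res$gdt_ts, base$gdt_ts, tolerance = 1e-8)
})

test_that("superposing a rigid copy recovers it exactly", {
  s <- build_peptide(15, "helix", sequence = "ACDEFGHIKLMNPQR")
  moved <- rigid_transform(s, random_rotation(4), c(10, -5, 3))
  res <- superpose_structures(s, moved)
  expect_lt(res$rmsd, 1e-6)
  expect_equal(res$gdt_ts, 100)
  expect_equal(res$n_pairs, 15)
  # input untouched, transformed_mobile is a new object
  expect_equal(moved$atoms$x,
               rigid_transform(s, random_rotation(4), c(10, -5, 3))$atoms$x)
  back <- res$transformed_mobile
  expect_lt(max(abs(back$atoms$x - s$atoms$x)), 1e-6)
})

test_that("noisy copies score between the exact and unrelated extremes", {
  s <- build_peptide(30, "helix", sequence = "ACDEFGHIKL")
  noisy <- perturb(s, 0.5, seed = 8)
  res <- superpose_structures(s, noisy)
  expect_gt(res$rmsd, 0)
  expect_lt(res$rmsd, 1.0)
  expect_lt(res$gdt_p[["1"]], 100)
})

test_that("too few identical aligned residues advises mode='all'", {
  a <- build_peptide(8, "helix", sequence = "AAAAAAAA")
  b <- build_peptide(8, "helix", sequence = "GWGWGWGW")
  expect_error(superpose_structures(a, b, mode = "identical"), "mode='all'")
  expect_s3_class(superpose_structures(a, b, mode = "all"),
                  "superposition_result")
})

test_that("stage failures are labelled with the failing stage", {
  a <- build_peptide(8, "helix")
  err <- tryCatch(superpose_structures(a, a, ref_chain = "Z"),
                  error = conditionMessage)
  expect_match(err, "\\[select\\]")
})

test_that("superposition agrees with the reference least-squares fitter", {
  skip_if_not_installed("bio3d")
  s <- build_peptide(25, "helix", sequence = "ACDEFGHIKLMNPQRSTVWY")
  noisy <- perturb(s, 0.6, seed = 31)
  res <- superpose_structures(s, noisy)
  v <- ca_coordinates(s)$coords
  w <- ca_coordinates(noisy)$coords
  fitted <- bio3d::fit.xyz(as.vector(t(v)), as.vector(t(w)),
                           fixed.inds = 1:(3 * 25), mobile.inds = 1:(3 * 25))
  ref_rmsd <- sqrt(mean(rowSums((v - matrix(fitted, ncol = 3, byrow = TRUE))^2)))
  expect_equal(res$rmsd, ref_rmsd, tolerance = 1e-6)
})
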