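minimal_line <- "ATOM      1  CA  GLY A   1      11.104   6.134  -6.504  1.00  0.00           C"

test_that("a minimal ATOM record parses into one chain, residue and atom", {
  s <- parse_pdb(minimal_line)
  expect_s3_class(s, "prostat_structure")
  expect_equal(nrow(s$atoms), 1)
  expect_equal(chain_ids(s), "A")
  expect_equal(s$atoms$name, "CA")
  expect_equal(s$atoms$resname, "GLY")
  expect_equal(s$atoms$x, 11.104)
  expect_equal(s$atoms$occupancy, 1)
})

test_that("inputs without coordinates are rejected with a useful message", {
  expect_error(parse_pdb("", id = "empty-input"), "empty-input")
  expect_error(parse_pdb("HEADER    NOTHING HERE"), "no ATOM")
  bad <- "ATOM      1  CA  GLY A   1      xx.xxx   6.134  -6.504  1.00  0.00"
  expect_error(parse_pdb(bad), "line 1")
})

test_that("write/parse round trip preserves identity and coordinates", {
  h <- build_peptide(10, "helix", sequence = "ADKWS")
  s2 <- parse_pdb(write_pdb(h))
  expect_equal(nrow(s2$atoms), 40)
  expect_equal(s2$atoms$resname, h$atoms$resname)
  expect_equal(s2$atoms$resno, h$atoms$resno)
  expect_equal(s2$atoms$name, h$atoms$name)
  expect_equal(chain_ids(s2), chain_ids(h))
  xyz_in <- cbind(h$atoms$x, h$atoms$y, h$atoms$z)
  xyz_out <- cbind(s2$atoms$x, s2$atoms$y, s2$atoms$z)
  expect_lt(max(abs(xyz_in - xyz_out)), 0.001)
  # each residue carries the four backbone atoms
  for (i in 1:10) {
    expect_setequal(s2$atoms$name[s2$atoms$resno == i], c("N", "CA", "C", "O"))
  }
})

test_that("coordinates serialize into fixed 8-column fields", {
  s <- parse_pdb(minimal_line)
  s$atoms$x <- 1234.5678
  expect_match(write_pdb(s), "1234.568", fixed = TRUE)
})

test_that("altloc conformers resolve to highest occupancy, ties to first letter", {
  two <- paste(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       9.000   0.000   0.000  0.60  0.00           C",
    sep = "\n")
  s <- parse_pdb(two)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$x, 9)
  tie <- gsub("0.40", "0.60", two, fixed = TRUE)
  s2 <- parse_pdb(tie)
  expect_equal(s2$atoms$altloc, "A")
  expect_equal(s2$atoms$x, 0)
})

test_that("TER closes a chain and only the first MODEL is read", {
  txt <- paste(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "TER",
    "ATOM      2  CA  ALA A   9       5.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      3  CA  TRP B   1       9.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    sep = "\n")
  s <- parse_pdb(txt)
  expect_equal(nrow(s$atoms), 2)                      # model 2 dropped
  expect_equal(length(unique(s$atoms$chain_key)), 2)  # TER split
  expect_false("TRP" %in% s$atoms$resname)
})

test_that("sequence extraction maps residues to one-letter codes", {
  txt <- paste(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  TRP A   3       7.600   0.000   0.000  1.00  0.00           C",
    sep = "\n")
  expect_equal(extract_sequence(parse_pdb(txt)), "GAW")
  mse <- "HETATM    1  CA  MSE A   1       0.000   0.000   0.000  1.00  0.00           C"
  s <- parse_pdb(mse)
  expect_equal(extract_sequence(get_chain(s, het = TRUE), het = TRUE), "M")
  expect_equal(aa3_to_aa1(c("MSE", "GLY", "ZZZ")), c("M", "G", "X"))
  # HETATM excluded by default -> empty selection is an error at get_chain
  expect_error(get_chain(s), "empty")
})

test_that("CA coordinate extraction skips and reports residues without CA", {
  h <- build_peptide(10, "helix")
  cc <- ca_coordinates(h)
  expect_equal(nrow(cc$coords), 10)
  expect_equal(nrow(cc$skipped), 0)
  expect_equal(cc$residue_index, 0:9)
  # drop residue 3's CA
  h$atoms <- h$atoms[!(h$atoms$resno == 3 & h$atoms$name == "CA"), ]
  cc2 <- ca_coordinates(h)
  expect_equal(nrow(cc2$coords), 9)
  expect_equal(cc2$skipped$resno, 3)
})

test_that("sequence length equals residue count, CA count never exceeds it", {
  for (n in c(1, 5, 17)) {
    s <- build_peptide(n, "strand", sequence = "ARNDC")
    expect_equal(nchar(extract_sequence(s)), n)
    expect_lte(nrow(ca_coordinates(s)$coords), n)
    expect_equal(nrow(ca_coordinates(s)$coords), n)
  }
})

test_that("writing rejects empty structures and oversized atom names", {
  s <- parse_pdb(minimal_line)
  empty <- s; empty$atoms <- s$atoms[0, ]
  expect_error(write_pdb(empty), "empty")
  bad <- s; bad$atoms$name <- "CALCIUM"
  expect_error(write_pdb(bad), "4 characters")
})

test_that("written files agree with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  h <- build_peptide(8, "helix", sequence = "AGW")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(h, f)
  ref <- bio3d::read.pdb(f)
  expect_equal(nrow(ref$atom), 32)
  expect_equal(ref$atom$resid[seq(1, 32, 4)],
               rep(c("ALA", "GLY", "TRP"), length.out = 8))
  expect_equal(max(abs(cbind(ref$atom$x, ref$atom$y, ref$atom$z) -
                         cbind(h$atoms$x, h$atoms$y, h$atoms$z))), 0,
               tolerance = 1e-3)
})
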