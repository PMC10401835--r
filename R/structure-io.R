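# PDB coordinate I/O: fixed-column ATOM/HETATM/TER/MODEL/ENDMDL records in,
# a flat atom table + chain/residue accessors out.

# 3-letter -> 1-letter residue codes.  Non-standard residues with a common
# parent map to the parent (MSE -> M etc.); anything else becomes 'X'.
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
  GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  # documented non-standard mappings
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", SEP = "S", TPO = "T", PTR = "Y"
)

.STANDARD_AA3 <- names(.AA3TO1)[1:20]

#' Convert a 3-letter residue code to its 1-letter code
#'
#' Standard residues map to their usual letter; a small set of common
#' modified residues map to their parent (e.g. MSE to M, SEP to S).
#' Unknown codes map to "X".
#'
#' @param name3 character vector of 3-letter residue codes.
#' @return character vector of single letters.
#' @export
aa3_to_aa1 <- function(name3) {
  out <- .AA3TO1[toupper(name3)]
  out[is.na(out)] <- "X"
  unname(out)
}

.num_field <- function(txt, lineno, what) {
  v <- suppressWarnings(as.numeric(txt))
  bad <- is.na(v) & nzchar(trimws(txt))
  bad <- bad | (is.na(v) & what %in% c("x", "y", "z"))
  if (any(bad)) {
    stop(sprintf("malformed %s field in PDB record at line %d: '%s'",
                 what, lineno[which(bad)[1]], txt[which(bad)[1]]), call. = FALSE)
  }
  v
}

#' Parse PDB-format text into a structure object
#'
#' Reads fixed-column ATOM/HETATM records into a flat atom table wrapped in a
#' `prostat_structure` object.  Only the first MODEL of a multi-model file is
#' read; a TER record closes the current chain so a reused chain identifier
#' afterwards starts a new chain.  When a residue carries alternate-location
#' conformers, the highest-occupancy conformer of each atom is kept (ties
#' resolved alphabetically by altloc character).
#'
#' @param text a single string (or character vector of lines) of PDB text.
#' @param id structure identifier stored on the object.
#' @param source provenance string.
#' @return an object of class `prostat_structure`: a list with elements
#'   `id`, `atoms` (data.frame with columns record, serial, name, altloc,
#'   resname, chain, resno, icode, x, y, z, occupancy, bfactor, element,
#'   chain_key) and `source`.
#' @export
parse_pdb <- function(text, id = "structure", source = "text") {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  rec <- substr(lines, 1, 6)
  lineno <- seq_along(lines)

  # first model only
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl)) {
    keep <- lineno <= endmdl[1]
    lines <- lines[keep]; rec <- rec[keep]; lineno <- lineno[keep]
  }

  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_ter <- trimws(rec) == "TER"
  if (!any(is_atom)) {
    stop(sprintf("no ATOM or HETATM records found in input '%s'", id),
         call. = FALSE)
  }

  # chain segments delimited by TER: segment index increments after each TER
  seg <- cumsum(is_ter)

  al <- lines[is_atom]
  ln <- lineno[is_atom]
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  al <- pad(al, 80)

  atoms <- data.frame(
    record = trimws(substr(al, 1, 6)),
    serial = as.integer(.num_field(substr(al, 7, 11), ln, "serial")),
    name = trimws(substr(al, 13, 16)),
    altloc = substr(al, 17, 17),
    resname = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resno = as.integer(.num_field(substr(al, 23, 26), ln, "resno")),
    icode = substr(al, 27, 27),
    x = .num_field(substr(al, 31, 38), ln, "x"),
    y = .num_field(substr(al, 39, 46), ln, "y"),
    z = .num_field(substr(al, 47, 54), ln, "z"),
    occupancy = .num_field(substr(al, 55, 60), ln, "occupancy"),
    bfactor = .num_field(substr(al, 61, 66), ln, "bfactor"),
    element = trimws(substr(al, 77, 78)),
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$bfactor[is.na(atoms$bfactor)] <- 0
  # element fallback: first letter of the atom name
  noel <- !nzchar(atoms$element)
  atoms$element[noel] <- substr(gsub("[^A-Za-z].*$", "", atoms$name[noel]), 1, 1)
  atoms$segment <- seg[is_atom]
  atoms$chain_key <- paste0(atoms$chain, ".", atoms$segment)

  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in PDB input", call. = FALSE)
  }

  atoms <- .resolve_altloc(atoms)
  atoms$segment <- NULL

  structure(list(id = id, atoms = atoms, source = source),
            class = "prostat_structure")
}

# keep, per (chain_key, resno, icode, name), the highest-occupancy altloc;
# ties broken by alphabetically first altloc character
.resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain_key, atoms$resno, atoms$icode, atoms$name, sep = "|")
  if (!anyDuplicated(key)) {
    atoms$altloc[atoms$altloc != " "] <- atoms$altloc[atoms$altloc != " "]
    return(atoms)
  }
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  keep_first <- !duplicated(key[ord])
  sel <- sort(seq_len(nrow(atoms))[ord][keep_first])
  atoms[sel, , drop = FALSE]
}

#' Read a PDB file from disk
#'
#' @param path path to a PDB-format file.
#' @return a `prostat_structure`; see [parse_pdb()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path, call. = FALSE)
  parse_pdb(readLines(path, warn = FALSE),
            id = sub("\\.[^.]*$", "", basename(path)), source = path)
}

#' @export
print.prostat_structure <- function(x, ...) {
  ch <- chain_ids(x)
  cat(sprintf("<prostat_structure '%s': %d atoms, %d chain(s) [%s]>\n",
              x$id, nrow(x$atoms), length(ch), paste(ch, collapse = ",")))
  invisible(x)
}

#' Chain identifiers of a structure
#'
#' @param s a `prostat_structure`.
#' @return character vector of chain ids in file order.  Chains re-opened
#'   after a TER record are distinct chains and keep their letter.
#' @export
chain_ids <- function(s) {
  unique(s$atoms$chain[s$atoms$record == "ATOM"])
}

#' Extract one chain of a structure
#'
#' @param s a `prostat_structure`.
#' @param chain single chain identifier; `NULL` keeps every chain.
#' @param het if `FALSE` (default) HETATM records are dropped.
#' @return a `prostat_structure` restricted to the selection.
#' @export
get_chain <- function(s, chain = NULL, het = FALSE) {
  a <- s$atoms
  keep <- if (het) rep(TRUE, nrow(a)) else a$record == "ATOM"
  if (!is.null(chain)) keep <- keep & a$chain == chain
  if (!any(keep)) stop("chain selection '", chain, "' is empty", call. = FALSE)
  structure(list(id = s$id, atoms = a[keep, , drop = FALSE], source = s$source),
            class = "prostat_structure")
}

# residue-level view: one row per residue in file order
residue_table <- function(s, het = FALSE) {
  a <- s$atoms
  if (!het) a <- a[a$record == "ATOM", , drop = FALSE]
  if (!nrow(a)) {
    return(data.frame(chain_key = character(), chain = character(),
                      resno = integer(), icode = character(),
                      resname = character(), stringsAsFactors = FALSE))
  }
  key <- paste(a$chain_key, a$resno, a$icode, sep = "|")
  first <- !duplicated(key)
  data.frame(chain_key = a$chain_key[first], chain = a$chain[first],
             resno = a$resno[first], icode = a$icode[first],
             resname = a$resname[first], stringsAsFactors = FALSE)
}

#' Extract the one-letter sequence of a structure or chain
#'
#' One letter per residue in file order; HETATM-only residues (waters,
#' ligands) are excluded.  Residue codes outside the documented mapping
#' table become "X".
#'
#' @param s a `prostat_structure` (pre-select with [get_chain()] for one
#'   chain).
#' @param het include HETATM residues (e.g. MSE recorded as a heteroatom).
#' @return a single string; empty string for an empty selection.
#' @export
extract_sequence <- function(s, het = FALSE) {
  rt <- residue_table(s, het = het)
  if (!nrow(rt)) return("")
  paste(aa3_to_aa1(rt$resname), collapse = "")
}

#' Alpha-carbon coordinates of a structure or chain
#'
#' @param s a `prostat_structure`.
#' @return a list with `coords` (n x 3 matrix, one row per residue that has a
#'   CA atom, in residue order), `residue_index` (0-based index of each row
#'   into the residue list), `resno`, and `skipped` (data.frame of residues
#'   lacking a CA).
#' @export
ca_coordinates <- function(s) {
  rt <- residue_table(s)
  a <- s$atoms[s$atoms$record == "ATOM", , drop = FALSE]
  if (!nrow(rt)) {
    return(list(coords = matrix(numeric(), 0, 3), residue_index = integer(),
                resno = integer(), skipped = rt))
  }
  rkey <- paste(rt$chain_key, rt$resno, rt$icode, sep = "|")
  ca <- a[a$name == "CA", , drop = FALSE]
  ckey <- paste(ca$chain_key, ca$resno, ca$icode, sep = "|")
  m <- match(rkey, ckey)
  has <- !is.na(m)
  coords <- cbind(ca$x[m[has]], ca$y[m[has]], ca$z[m[has]])
  colnames(coords) <- c("x", "y", "z")
  list(coords = coords,
       residue_index = which(has) - 1L,
       resno = rt$resno[has],
       skipped = rt[!has, , drop = FALSE])
}

#' Serialize a structure to PDB-format text
#'
#' Writes fixed-column ATOM/HETATM records with coordinates to 3 decimals and
#' a TER record after each chain, so that re-parsing reproduces chain ids,
#' residue identities and coordinates.
#'
#' @param s a `prostat_structure` with at least one atom.
#' @return a single PDB-format string.
#' @export
write_pdb <- function(s) {
  a <- s$atoms
  if (is.null(a) || !nrow(a)) stop("cannot write an empty structure", call. = FALSE)
  if (any(nchar(a$name) > 4)) {
    stop("atom name longer than 4 characters: ",
         a$name[which(nchar(a$name) > 4)[1]], call. = FALSE)
  }
  # atom-name column convention: names of <= 3 chars start in column 14
  nm <- ifelse(nchar(a$name) >= 4, substr(paste0(a$name, "   "), 1, 4),
               substr(paste0(" ", a$name, "   "), 1, 4))
  rows <- sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  a$record, a$serial %% 100000L, nm, a$altloc, a$resname,
                  a$chain, a$resno, a$icode, a$x, a$y, a$z,
                  a$occupancy, a$bfactor, a$element)
  # TER after each chain segment
  out <- character(0)
  for (k in unique(a$chain_key)) {
    out <- c(out, rows[a$chain_key == k], "TER")
  }
  paste(c(out, "END", ""), collapse = "\n")
}

#' Write a structure to a PDB file
#'
#' @param s a `prostat_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  writeLines(write_pdb(s), path, sep = "")
  invisible(path)
}

# replace the coordinate block (n_atoms x 3 matrix), returning a deep copy
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms))
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

get_coords <- function(s) {
  cbind(x = s$atoms$x, y = s$atoms$y, z = s$atoms$z)
}
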