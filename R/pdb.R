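## Receptor structures: parsing, validation, writing.
##
## A receptor is a plain list with
##   $atoms            data.frame: chain, resno, insert, resid, elety, elesy,
##                     x, y, z, cofactor (logical)
##   $reference_points named list of length-3 numeric xyz (Angstrom)
## Heavy atoms only; waters removed; alternate locations already resolved.

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O", "TIP3", "TIP", "SOL")

#' Construct a receptor structure
#'
#' Low-level constructor used by [read_receptor()] and the synthetic-data
#' generator. Validates the core invariants: finite coordinates, every atom
#' assigned to a residue, and cofactor atoms disjoint from amino-acid atoms
#' (the `cofactor` column does the bookkeeping).
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety` (atom name), `elesy` (element symbol), `x`, `y`, `z` and logical
#'   `cofactor`.
#' @param reference_points named list of xyz points (Angstrom), e.g. the
#'   active-site spawning coordinates.
#' @return An object of class `"receptor"`.
#' @export
receptor <- function(atoms, reference_points = list()) {
  need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "cofactor")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atoms is missing columns: %s",
                          paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stopf("non-finite coordinates in atoms %s",
          paste(which(!is.finite(atoms$x + atoms$y + atoms$z)), collapse = ","))
  if (!nrow(atoms)) stopf("empty structure")
  atoms$chain <- as.character(atoms$chain)
  atoms$insert <- as.character(atoms$insert)
  atoms$insert[is.na(atoms$insert)] <- ""
  ## stable residue ordering within chains (author numbering + insertion code)
  ord <- order(atoms$chain, atoms$cofactor, atoms$resno, atoms$insert)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, reference_points = reference_points),
            class = "receptor")
}

#' @export
print.receptor <- function(x, ...) {
  a <- x$atoms
  prot <- a[!a$cofactor, ]
  nres <- nrow(unique(prot[, c("chain", "resno", "insert")]))
  cat("Receptor structure\n")
  cat(sprintf("  chains:   %s\n", paste(unique(a$chain), collapse = ", ")))
  cat(sprintf("  residues: %d   heavy atoms: %d   cofactor atoms: %d\n",
              nres, nrow(prot), sum(a$cofactor)))
  if (length(x$reference_points))
    cat(sprintf("  reference points: %s\n",
                paste(names(x$reference_points), collapse = ", ")))
  invisible(x)
}

## coordinate matrix of the protein (or cofactor) heavy atoms
receptor_xyz <- function(x, cofactor = FALSE) {
  a <- x$atoms[x$atoms$cofactor == cofactor, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

## residue key strings "chain|resno|insert" for a set of atom rows
residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
}

infer_element <- function(elety) {
  e <- gsub("[^A-Za-z]", "", elety)
  two <- toupper(substr(e, 1, 2))
  one <- toupper(substr(e, 1, 1))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "SE", "NA", "MN", "CU"),
         two, one)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records via [bio3d::read.pdb()] and reduces the model
#' to the convention used throughout the package: heavy atoms only
#' (hydrogens and deuteriums dropped), crystallographic waters removed,
#' alternate locations resolved to the highest occupancy (ties broken by
#' file order), and HETATM residues matching `cofactor` routed to a
#' dedicated cofactor atom set.
#'
#' @param file path to a PDB file.
#' @param chains optional character vector of chain identifiers to retain;
#'   all chains when `NULL`. Naming a chain absent from the file is an error.
#' @param cofactor residue name(s) flagged as the cofactor (default `"FAD"`).
#' @param reference_points named list of xyz reference points to attach
#'   (e.g. active-site spawning coordinates).
#' @return A `"receptor"` object.
#' @export
read_receptor <- function(file, chains = NULL, cofactor = "FAD",
                          reference_points = list()) {
  if (!file.exists(file)) stopf("no such file: %s", file)
  ## validate coordinate fields up front so errors can name the line
  lines <- readLines(file, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    fld <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
             substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(fld))))
      stopf("malformed coordinate field at line %d of %s", i, file)
  }
  pdb <- bio3d::read.pdb(file, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- " "
  if (!is.null(chains)) {
    if (!length(chains)) stopf("empty chain selection")
    missing_ch <- setdiff(chains, unique(a$chain))
    if (length(missing_ch))
      stopf("chain(s) not present in %s: %s", file,
            paste(missing_ch, collapse = ", "))
    a <- a[a$chain %in% chains, , drop = FALSE]
  }
  ## drop waters, then hydrogens
  a <- a[!(a$resid %in% WATER_RESIDUES), , drop = FALSE]
  elesy <- a$elesy
  blank <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[blank] <- infer_element(a$elety[blank])
  elesy <- toupper(trimws(elesy))
  keep <- !(elesy %in% c("H", "D"))
  a <- a[keep, , drop = FALSE]
  elesy <- elesy[keep]
  if (!nrow(a)) stopf("no heavy atoms left after filtering in %s", file)
  ## altloc resolution: highest occupancy, ties -> first encountered
  a$elesy <- elesy
  alt <- a$alt
  alt[is.na(alt)] <- ""
  if (any(nzchar(alt))) {
    occ <- a$o
    occ[is.na(occ)] <- 0
    key <- paste(a$chain, a$resno, a$insert, a$resid, a$elety, sep = "|")
    ord <- order(key, -occ, seq_len(nrow(a)))
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$resid, a$elety,
                             sep = "|")), , drop = FALSE]
    a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  }
  atoms <- data.frame(
    chain = a$chain, resno = a$resno, insert = a$insert, resid = a$resid,
    elety = a$elety, elesy = a$elesy, x = a$x, y = a$y, z = a$z,
    cofactor = a$resid %in% cofactor,
    stringsAsFactors = FALSE)
  receptor(atoms, reference_points)
}

#' Write a receptor structure to a PDB file
#'
#' Emits standard ATOM/HETATM records (cofactor atoms as HETATM) via
#' [bio3d::write.pdb()]. `read_receptor(write_receptor_pdb(x))` reproduces
#' `x` on all retained fields.
#'
#' @param x a `"receptor"` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_receptor_pdb <- function(x, file) {
  a <- x$atoms
  bio3d::write.pdb(
    pdb = NULL, file = file,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$cofactor, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resid, chain = a$chain,
    insert = ifelse(nzchar(a$insert), a$insert, NA),
    eleno = seq_len(nrow(a)), elety = a$elety, elesy = a$elesy)
  invisible(file)
}

## unique residues table of the protein part (cofactor excluded)
receptor_residues <- function(x) {
  a <- x$atoms[!x$atoms$cofactor, , drop = FALSE]
  unique(a[, c("chain", "resno", "insert", "resid")])
}
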