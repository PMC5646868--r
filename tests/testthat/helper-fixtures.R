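# fixtures built in code: tiny receptors, brute-force oracles, PDB text

atoms_df <- function(xyz, chain = "A", resno = 1, resid = "GLY",
                     elety = NULL, elesy = "C", cofactor = FALSE) {
  xyz <- rbind(xyz)
  n <- nrow(xyz)
  data.frame(chain = rep(chain, length.out = n),
             resno = rep(resno, length.out = n),
             insert = "",
             resid = rep(resid, length.out = n),
             elety = elety %||% paste0("C", seq_len(n)),
             elesy = rep(elesy, length.out = n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             cofactor = rep(cofactor, length.out = n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent O(n*m) contact count, no shared code with ligand_contacts()
brute_force_contacts <- function(ligand_xyz, atoms, cutoff) {
  ligand_xyz <- rbind(ligand_xyz)
  counts <- list()
  for (i in seq_len(nrow(atoms))) {
    for (k in seq_len(nrow(ligand_xyz))) {
      d <- sqrt(sum((as.numeric(atoms[i, c("x", "y", "z")]) -
                       ligand_xyz[k, ])^2))
      if (d < cutoff) {
        key <- paste(atoms$chain[i], atoms$resno[i], sep = "|")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  counts
}

# hand-rolled fixed-width PDB ATOM/HETATM line
pdb_line <- function(type = "ATOM", serial = 1, name = "CA", alt = " ",
                     resn = "GLY", chain = "A", resno = 1, x = 0, y = 0,
                     z = 0, occ = 1, b = 0, element = "C") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resn, chain, resno, x, y, z, occ, b,
          element)
}

# locations where the published reference inputs (PDB entry 1VAO, the
# supplementary subfamily alignments) may be dropped in for verification
real_data_path <- function(name) {
  file.path(system.file("extdata", "real", package = "ligapath"), name)
}

# one clean failure per criterion when a reference input has not been
# provided (the files are published but cannot be redistributed here)
real_data_missing <- function(...) {
  f <- vapply(c(...), real_data_path, character(1))
  absent <- !file.exists(f)
  if (any(absent))
    testthat::fail(paste("reference input(s) missing, see",
                         "inst/extdata/real/README.md:",
                         paste(names(f)[absent] %||% basename(f)[absent],
                               collapse = ", ")))
  any(absent)
}
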