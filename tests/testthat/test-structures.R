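test_that("PDB reading round-trips coordinates and drops what it should", {
  f <- withr::local_tempfile(fileext = ".pdb")

  # identity read-back of a single printed atom
  writeLines(pdb_line(x = 1.234, y = -5.678, z = 9.1), f)
  r <- read_receptor(f)
  expect_equal(nrow(r$atoms), 1)
  expect_equal(unname(unlist(r$atoms[1, c("x", "y", "z")])),
               c(1.234, -5.678, 9.100))

  # generated 2-chain fixture: 10 residues x 4 atoms per chain
  set.seed(42)
  atoms <- do.call(rbind, lapply(c("A", "B"), function(ch)
    do.call(rbind, lapply(1:10, function(i)
      atoms_df(matrix(rnorm(12, ifelse(ch == "A", 0, 30)), 4),
               chain = ch, resno = i,
               elety = c("CA", "CB", "CG", "CD"))))))
  write_receptor_pdb(receptor(atoms), f)
  r2 <- read_receptor(f)
  expect_equal(nrow(r2$atoms), 80)
  expect_setequal(unique(r2$atoms$chain), c("A", "B"))

  # waters discarded, hydrogens dropped, cofactor routed
  writeLines(c(pdb_line(serial = 1),
               pdb_line(type = "HETATM", serial = 2, name = "O", resn = "HOH",
                        resno = 90, x = 5, element = "O"),
               pdb_line(serial = 3, name = "H1", resno = 1, x = 1,
                        element = "H"),
               pdb_line(type = "HETATM", serial = 4, name = "C1",
                        resn = "FAD", resno = 99, x = 3)), f)
  r3 <- read_receptor(f)
  expect_equal(nrow(r3$atoms), 2)
  expect_false(any(r3$atoms$resid %in% c("HOH", "WAT")))
  expect_false(any(r3$atoms$elesy == "H"))
  expect_equal(sum(r3$atoms$cofactor), 1)
})

test_that("alternate locations resolve to highest occupancy then file order", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(serial = 1, alt = "A", x = 1, occ = 0.4),
               pdb_line(serial = 2, alt = "B", x = 2, occ = 0.6),
               pdb_line(serial = 3, name = "CB", alt = "A", x = 3, occ = 0.5),
               pdb_line(serial = 4, name = "CB", alt = "B", x = 4, occ = 0.5)),
             f)
  r <- read_receptor(f)
  expect_equal(nrow(r$atoms), 2)
  expect_equal(r$atoms$x[r$atoms$elety == "CA"], 2)  # higher occupancy
  expect_equal(r$atoms$x[r$atoms$elety == "CB"], 3)  # tie -> first in file
})

test_that("malformed coordinate fields and bad selections are errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  bad <- pdb_line()
  substr(bad, 31, 38) <- "  xx.yyy"
  writeLines(bad, f)
  expect_error(read_receptor(f), "line 1")
  writeLines(pdb_line(), f)
  expect_error(read_receptor(f, chains = "Z"), "chain")
  expect_error(read_receptor(f, chains = character(0)), "empty")
})

test_that("SASA matches the analytic sphere and is additive when separated", {
  iso <- receptor(atoms_df(c(0, 0, 0), elesy = "X"))
  s <- shrake_rupley_sasa(iso, radii = c(X = 1.9))
  expect_equal(s$atom, 4 * pi * 3.3^2, tolerance = 0.01)

  two <- receptor(atoms_df(rbind(c(0, 0, 0), c(10, 0, 0)), elesy = "X"))
  s2 <- shrake_rupley_sasa(two, radii = c(X = 1.9))
  expect_equal(sum(s2$atom), 2 * s$atom, tolerance = 1e-9)

  expect_error(shrake_rupley_sasa(iso, radii = c(C = 1.7)), "X")
})

test_that("a caged atom has zero SASA and SASA never grows with neighbours", {
  cage_dirs <- ligapath:::sphere_lattice(60)
  at <- rbind(atoms_df(c(0, 0, 0)),
              atoms_df(cage_dirs * 2.0, resno = 2))
  s <- shrake_rupley_sasa(receptor(at))
  expect_equal(s$atom[1], 0)

  # per-atom monotonicity: adding one more occluder cannot raise SASA
  base <- atoms_df(rbind(c(0, 0, 0), c(2.5, 0, 0)), resno = c(1, 2))
  more <- rbind(base, atoms_df(c(0, 2.5, 0), resno = 3))
  s_base <- shrake_rupley_sasa(receptor(base))$atom
  s_more <- shrake_rupley_sasa(receptor(more))$atom
  expect_true(all(s_more[1:2] <= s_base + 1e-9))
})

test_that("surface classification uses inclusive relative accessibility", {
  res <- receptor(atoms_df(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0)),
                           resid = "GLY"))
  sasa <- shrake_rupley_sasa(res)$residue$sasa

  # fully exposed residue scored against its own reference -> rel_acc 1
  cls <- classify_surface_residues(res, max_sasa = c(GLY = sasa))
  expect_equal(cls$rel_acc, 1)
  expect_true(cls$is_surface)

  # exactly at the 30% threshold -> surface (inclusive convention)
  cls30 <- classify_surface_residues(res, max_sasa = c(GLY = sasa / 0.30))
  expect_equal(cls30$rel_acc, 0.30)
  expect_true(cls30$is_surface)

  # buried residue (zero SASA) is not surface
  cage <- atoms_df(ligapath:::sphere_lattice(60) * 2.0, resno = 2,
                   resid = "ALA")
  r <- receptor(rbind(atoms_df(c(0, 0, 0), resid = "GLY"), cage))
  cls0 <- classify_surface_residues(r)
  expect_false(cls0$is_surface[cls0$resid == "GLY"])

  expect_error(classify_surface_residues(res, max_sasa = c(ALA = 100)),
               "GLY")
})

test_that("interface residues obey the inclusive 4 A criterion", {
  near <- receptor(rbind(atoms_df(c(0, 0, 0), chain = "A"),
                         atoms_df(c(3.9, 0, 0), chain = "B")))
  got <- interface_residues(near)
  expect_equal(nrow(got), 2)

  far <- receptor(rbind(atoms_df(c(0, 0, 0), chain = "A"),
                        atoms_df(c(4.1, 0, 0), chain = "B")))
  expect_equal(nrow(interface_residues(far)), 0)

  # boundary: exactly 4.0 is included
  at4 <- receptor(rbind(atoms_df(c(0, 0, 0), chain = "A"),
                        atoms_df(c(4.0, 0, 0), chain = "B")))
  expect_equal(nrow(interface_residues(at4)), 2)

  # symmetric under chain relabeling
  swapped <- near
  swapped$atoms$chain <- ifelse(swapped$atoms$chain == "A", "B", "A")
  got_sw <- interface_residues(receptor(swapped$atoms))
  expect_setequal(paste(got$resno, got$resid),
                  paste(got_sw$resno, got_sw$resid))

  single <- receptor(atoms_df(c(0, 0, 0), chain = "A"))
  expect_error(interface_residues(single), "single chain")

  # cofactor atoms must not create interfaces
  fad <- receptor(rbind(atoms_df(c(0, 0, 0), chain = "A"),
                        atoms_df(c(3, 0, 0), chain = "A", resno = 99,
                                 resid = "FAD", cofactor = TRUE),
                        atoms_df(c(6, 0, 0), chain = "B")))
  expect_equal(nrow(interface_residues(fad)), 0)
})

test_that("ligand contacts use a strict 2.7 A cutoff and match brute force", {
  r <- receptor(atoms_df(c(0, 0, 0)))
  expect_equal(ligand_contacts(c(2.69, 0, 0), r)$count, 1L)
  expect_equal(nrow(ligand_contacts(c(2.70, 0, 0), r)), 0)

  set.seed(7)
  for (rep in 1:20) {
    atoms <- atoms_df(matrix(runif(150, 0, 10), 50),
                      resno = rep(1:10, each = 5))
    lig <- matrix(runif(15, 0, 10), 5)
    got <- ligand_contacts(lig, receptor(atoms))
    want <- brute_force_contacts(lig, atoms, 2.7)
    got_map <- setNames(as.list(got$count),
                        paste(got$chain, got$resno, sep = "|"))
    expect_equal(got_map[order(names(got_map))],
                 want[order(names(want))])
  }

  # monotone in the cutoff
  atoms <- atoms_df(matrix(runif(60, 0, 6), 20), resno = rep(1:5, each = 4))
  lig <- matrix(runif(9, 0, 6), 3)
  for (cut in c(2, 3, 4)) {
    a <- ligand_contacts(lig, receptor(atoms), cutoff = cut)
    b <- ligand_contacts(lig, receptor(atoms), cutoff = cut + 1)
    for (i in seq_len(nrow(a))) {
      j <- which(b$resno == a$resno[i])
      expect_true(length(j) == 1 && b$count[j] >= a$count[i])
    }
  }
})

test_that("centroid distance to a reference point is Euclidean", {
  expect_equal(distance_to_point(rbind(c(3, 4, 0)), c(0, 0, 0)), 5)
  expect_equal(distance_to_point(rbind(c(1, 1, 1), c(-1, -1, -1)),
                                 c(0, 0, 0)), 0)
  xyz <- matrix(rnorm(30), 10)
  expect_equal(distance_to_point(xyz, c(1, 2, 3)),
               sqrt(sum((colMeans(xyz) - c(1, 2, 3))^2)))
  # mass weighting moves the centroid
  expect_equal(centroid(rbind(c(0, 0, 0), c(4, 0, 0)), weights = c(3, 1)),
               c(1, 0, 0))
})
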