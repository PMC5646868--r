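## Solvent-accessible surface area (Shrake-Rupley) and the surface-residue
## classification built on it.

#' Bondi van der Waals radii (Angstrom) by element symbol
#' @return Named numeric vector.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
    FE = 1.80, ZN = 1.39, MG = 1.73, MN = 1.73, CU = 1.40, "NA" = 2.27,
    K = 2.75, CA = 2.31)
}

#' Theoretical maximum solvent accessibility per residue type
#'
#' Tien et al. (2013) theoretical maximum SASA values (Angstrom^2) used as
#' the denominator of relative accessibility. Note these are a published
#' convention; other tools (e.g. SwissPDBviewer) use different reference
#' values, which shifts surface-residue counts near the threshold.
#'
#' @return Named numeric vector keyed by 3-letter residue name.
#' @export
max_sasa_reference <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLU = 223, GLN = 225, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
}

## Deterministic quasi-uniform unit-sphere lattice (Fibonacci / golden
## section spiral). No randomness: SASA is reproducible bit for bit.
sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by the Shrake-Rupley point-counting method on a
#' deterministic golden-section sphere lattice: each atom is inflated by the
#' probe radius, test points are placed on the inflated sphere, and a point
#' is accessible when it lies outside every neighbouring inflated sphere.
#' Per-residue SASA is the sum over the residue's atoms. Heavy atoms only;
#' cofactor atoms occlude but are not reported as residues.
#'
#' @param x a `"receptor"` object or an atom data.frame as in [receptor()].
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points quadrature points per atom (default 960).
#' @param radii named vector of van der Waals radii by element symbol.
#' @param include_cofactor logical; include cofactor atoms as occluders
#'   (default `TRUE`).
#' @return list with `atom` (numeric vector, Angstrom^2 per atom row) and
#'   `residue` (data.frame chain, resno, insert, resid, sasa).
#' @export
shrake_rupley_sasa <- function(x, probe = 1.4, n_points = 960,
                               radii = vdw_radii(), include_cofactor = TRUE) {
  atoms <- if (inherits(x, "receptor")) x$atoms else x
  if (!include_cofactor) atoms <- atoms[!atoms$cofactor, , drop = FALSE]
  stopifnot(probe > 0, n_points >= 1)
  unknown <- setdiff(unique(atoms$elesy), names(radii))
  if (length(unknown))
    stopf("no van der Waals radius for element(s): %s",
          paste(unknown, collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- unname(radii[atoms$elesy]) + probe
  n <- nrow(xyz)
  pts <- sphere_lattice(n_points)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d <- dist_to_rows(xyz[i, ], xyz)
    nb <- which(d < r[i] + r & seq_len(n) != i)
    p <- pts * r[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > r[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  prot <- !atoms$cofactor
  key <- residue_key(atoms)
  res_area <- tapply(area[prot], factor(key[prot], levels = unique(key[prot])),
                     sum)
  res <- unique(atoms[prot, c("chain", "resno", "insert", "resid")])
  res$sasa <- as.numeric(res_area)
  rownames(res) <- NULL
  list(atom = area, residue = res)
}

#' Classify surface residues by relative solvent accessibility
#'
#' A residue is on the surface when its SASA in the full assembly, divided
#' by the reference maximal SASA for its residue type, meets the threshold
#' (inclusive). The study convention is 30% accessibility in the dimer.
#'
#' @param x a `"receptor"` object.
#' @param threshold relative-accessibility cutoff (default 0.30, inclusive).
#' @param max_sasa named reference vector (see [max_sasa_reference()]).
#' @inheritParams shrake_rupley_sasa
#' @return data.frame chain, resno, insert, resid, sasa, rel_acc,
#'   is_surface.
#' @export
classify_surface_residues <- function(x, threshold = 0.30,
                                      max_sasa = max_sasa_reference(),
                                      probe = 1.4, n_points = 960,
                                      radii = vdw_radii()) {
  res <- shrake_rupley_sasa(x, probe = probe, n_points = n_points,
                            radii = radii)$residue
  unknown <- setdiff(unique(res$resid), names(max_sasa))
  if (length(unknown))
    stopf("no reference maximal SASA for residue type(s): %s",
          paste(unknown, collapse = ", "))
  res$rel_acc <- res$sasa / unname(max_sasa[res$resid])
  res$is_surface <- res$rel_acc >= threshold
  res
}
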