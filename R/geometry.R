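## Geometric primitives: interface residues, ligand contacts, centroid
## distances, quaternions, Kabsch superposition.

#' Subunit-interface residues
#'
#' A residue belongs to the subunit interface when any of its heavy atoms
#' lies within `cutoff` (inclusive) of a heavy atom of a different chain.
#' Cofactor atoms are excluded from both sides of the comparison.
#'
#' @param x a `"receptor"` object with at least two chains.
#' @param cutoff distance criterion in Angstrom (default 4.0, inclusive).
#' @return data.frame chain, resno, insert, resid of interface residues.
#' @export
interface_residues <- function(x, cutoff = 4.0) {
  a <- x$atoms[!x$atoms$cofactor, , drop = FALSE]
  chains <- unique(a$chain)
  if (length(chains) < 2)
    stopf("interface undefined: structure has a single chain")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  hit <- rep(FALSE, nrow(a))
  for (ch in chains) {
    own <- a$chain == ch
    other <- xyz[!own, , drop = FALSE]
    idx <- which(own)
    for (i in idx) {
      if (!hit[i] && any(dist_to_rows(xyz[i, ], other) <= cutoff))
        hit[i] <- TRUE
    }
  }
  res <- unique(a[hit, c("chain", "resno", "insert", "resid")])
  res <- res[order(res$chain, res$resno, res$insert), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Protein-ligand atom contacts per residue
#'
#' Counts atom pairs (one protein heavy atom, one ligand atom) at distance
#' strictly below `cutoff`; the study's contact criterion is 2.7 Angstrom.
#' Residues with zero contacts are omitted.
#'
#' @param ligand_xyz numeric matrix (n x 3) of ligand atom coordinates.
#' @param x a `"receptor"` object.
#' @param cutoff contact distance in Angstrom, strict inequality
#'   (default 2.7).
#' @return data.frame chain, resno, insert, resid, count.
#' @export
ligand_contacts <- function(ligand_xyz, x, cutoff = 2.7) {
  ligand_xyz <- rbind(ligand_xyz)
  if (!nrow(ligand_xyz)) stopf("empty ligand atom set")
  a <- x$atoms[!x$atoms$cofactor, , drop = FALSE]
  if (!nrow(a)) stopf("empty receptor atom set")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  cnt <- integer(nrow(a))
  for (k in seq_len(nrow(ligand_xyz)))
    cnt <- cnt + (dist_to_rows(ligand_xyz[k, ], xyz) < cutoff)
  key <- residue_key(a)
  per <- tapply(cnt, factor(key, levels = unique(key)), sum)
  res <- unique(a[, c("chain", "resno", "insert", "resid")])
  res$count <- as.integer(per)
  res <- res[res$count > 0, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Ligand centroid and its distance to a reference point
#'
#' The reaction coordinate of the migration explorer: Euclidean distance
#' from the ligand centroid (unweighted by default; masses of C/N/O are
#' nearly uniform) to a named reference point such as the active-site
#' spawning coordinate.
#'
#' @param ligand_xyz numeric matrix (n x 3).
#' @param point numeric xyz of length 3.
#' @param weights optional per-atom masses for a mass-weighted centroid.
#' @return distance in Angstrom.
#' @export
distance_to_point <- function(ligand_xyz, point, weights = NULL) {
  vnorm(centroid(ligand_xyz, weights) - point)
}

#' @rdname distance_to_point
#' @export
centroid <- function(ligand_xyz, weights = NULL) {
  ligand_xyz <- rbind(ligand_xyz)
  if (!nrow(ligand_xyz)) stopf("empty ligand atom set")
  if (is.null(weights)) return(colMeans(ligand_xyz))
  colSums(ligand_xyz * weights) / sum(weights)
}

## quaternions ---------------------------------------------------------------
## convention: q = c(w, x, y, z), unit norm, acting as a rotation

quat_normalize <- function(q) q / vnorm(q)

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / vnorm(axis)
  c(cos(angle / 2), sin(angle / 2) * axis)
}

quat_rotation_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    n <- vnorm(v)
    if (n > 1e-12) return(v / n)
  }
}

## Kabsch least-squares superposition: returns list(R, t) with
## transformed = x %*% R + t (rows are points); R is a proper rotation.
kabsch <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  A <- sweep(from, 2, cf); B <- sweep(to, 2, ct)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, t = as.numeric(ct - cf %*% R))
}

apply_transform <- function(xyz, tr) {
  sweep(rbind(xyz) %*% tr$R, 2, tr$t, "+")
}
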