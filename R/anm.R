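## Anisotropic network model: low-frequency normal modes of a C-alpha
## elastic network, used for collective backbone perturbations.

#' Low-frequency anisotropic network model modes
#'
#' Builds the standard ANM Hessian over C-alpha positions — pairwise
#' Hookean springs with uniform force constant between atoms closer than
#' `cutoff` — and eigendecomposes it. A connected network has exactly six
#' zero-frequency modes (rigid-body translations and rotations); these are
#' discarded and the next `n_modes` eigenvectors (lowest nonzero
#' eigenvalues) are returned.
#'
#' @param calpha numeric matrix (N x 3) of C-alpha coordinates, N >= 3.
#' @param cutoff spring cutoff in Angstrom (default 15).
#' @param n_modes number of internal modes to return (default 6, the
#'   number used for backbone perturbation).
#' @param tol relative eigenvalue tolerance separating rigid-body modes.
#' @return list with `modes` (3N x n_modes orthonormal columns, atom-major
#'   xyz layout), `eigenvalues` (the corresponding nonzero eigenvalues,
#'   ascending) and `n_rigid` (number of near-zero modes found, 6).
#' @export
anm_modes <- function(calpha, cutoff = 15, n_modes = 6, tol = 1e-8) {
  calpha <- as.matrix(calpha)
  n <- nrow(calpha)
  if (n < 3) stopf("need at least 3 C-alpha atoms")
  if (cutoff <= 0) stopf("cutoff must be positive")
  d <- as.matrix(stats::dist(calpha))
  adj <- d < cutoff & upper.tri(d)
  ## connectivity check before any linear algebra
  g <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1)
    stopf("disconnected elastic network: %d components", comp$no)
  H <- matrix(0, 3 * n, 3 * n)
  pairs <- which(adj, arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    dv <- calpha[j, ] - calpha[i, ]
    blk <- -tcrossprod(dv) / sum(dv * dv)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  e <- eigen(H, symmetric = TRUE)
  ev <- rev(e$values)                      # ascending
  vec <- e$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  zero_tol <- tol * max(abs(ev))
  n_rigid <- sum(ev < zero_tol)
  if (n_rigid > 6)
    stopf("degenerate elastic network: %d near-zero modes (expected 6)",
          n_rigid)
  if (n_rigid < 6)
    stopf("rigid-body modes not resolved: %d near-zero modes", n_rigid)
  idx <- seq(n_rigid + 1, length.out = min(n_modes, 3 * n - n_rigid))
  list(modes = vec[, idx, drop = FALSE],
       eigenvalues = ev[idx],
       n_rigid = n_rigid)
}

## Displace C-alpha coordinates along one mode, scaled so the largest
## per-atom displacement equals `step` (Angstrom).
anm_displace <- function(calpha, mode, step) {
  m <- matrix(mode, ncol = 3, byrow = TRUE)
  amp <- sqrt(rowSums(m^2))
  calpha + m * (step / max(amp))
}
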