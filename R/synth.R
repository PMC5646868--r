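## Synthetic study system: a C2-symmetric two-chain receptor with a buried
## site per chain connected to bulk solvent by designed channels, an
## analytic energy oracle, trajectories with known ground truth, and
## subfamily alignments with planted per-column categories. Everything the
## pipeline consumes can be generated here with truth labels, so every
## downstream stage is testable without external structure or alignment
## downloads. Geometry and energetics are desk-scale stand-ins: they mimic
## the topology of a dimeric flavoenzyme (buried site, channels, two-fold
## symmetry), not its real shape or force field.

STANDARD_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLU", "GLN",
                       "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                       "PRO", "SER", "THR", "TRP", "TYR", "VAL")

toy_spec_defaults <- function() {
  list(site_offset = 7, cage_radius = 5, channel_radius = 3.0,
       inner_radius = 2.4, well_depth = 2.0, well_width = 1.5,
       k_perp = 0.3, core_radius = 1.8, k_rep = 10, bulk_z = 24)
}

## one ring of pseudo-residues around the z axis at height z
ring_residues <- function(z, n, spec, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  lapply(th, function(t) {
    u <- c(cos(t), sin(t))
    rbind(CA = c(u * spec$channel_radius, z),
          CB = c(u * spec$inner_radius, z),
          CG = c(u * spec$channel_radius, z + 0.5),
          CD = c(u * spec$channel_radius, z - 0.5))
  })
}

#' Generate the synthetic channel receptor and its energy oracle
#'
#' Builds a two-chain, C2-symmetric pseudo-protein: each chain carries a
#' buried site on the z axis enclosed by a cage of pseudo-residues (4
#' heavy atoms each), one channel leading from the site to bulk solvent
#' (ground-truth "cap" path) and one channel leading to the partner
#' chain's site through the subunit interface (ground-truth
#' "subunit_interface" path). A small two-atom cofactor (FAD) sits beside
#' each site. The analytic energy oracle combines a Gaussian well at each
#' site, a harmonic restraint perpendicular to the channel centerline and
#' a soft-core repulsion from receptor atoms; the bulk plateau is zero.
#'
#' @param n_res_per_chain requested pseudo-residues per chain (>= 20);
#'   rounded to the design lattice (a cage of 12 plus rings of 6).
#' @param seed RNG seed (residue-name assignment); generation is
#'   deterministic per seed.
#' @param spec named list overriding geometry/energy defaults
#'   (site_offset, cage_radius, channel_radius, inner_radius, well_depth,
#'   well_width, k_perp, core_radius, k_rep, bulk_z).
#' @return list with `receptor` (a `"receptor"` with reference points
#'   siteA/siteB/bulkA/bulkB), `oracle` (energy oracle contract), `paths`
#'   (ground-truth path residue numbers, shared by both chains), `spec`.
#' @export
make_toy_receptor <- function(n_res_per_chain = 42, seed = 1, spec = list()) {
  if (n_res_per_chain < 20) stopf("need n_res_per_chain >= 20")
  spec <- utils::modifyList(toy_spec_defaults(), spec)
  if (spec$inner_radius <= spec$core_radius)
    stopf("channel centerline passes through steric cores (inner_radius %.2f <= core_radius %.2f)",
          spec$inner_radius, spec$core_radius)
  set.seed(seed)
  sA <- c(0, 0, spec$site_offset)
  sB <- c(0, 0, -spec$site_offset)

  ## cage: 12 residues on a sphere around the site, poles left open
  lat <- sphere_lattice(40)
  lat <- lat[abs(lat[, 3]) < 0.75, , drop = FALSE][1:12, , drop = FALSE]
  cage <- lapply(seq_len(12), function(i) {
    u <- lat[i, ]
    tang <- c(-u[2], u[1], 0); tang <- tang / max(vnorm(tang), 1e-9)
    rbind(CA = sA + u * spec$cage_radius,
          CB = sA + u * (spec$cage_radius - 0.6),
          CG = sA + u * spec$cage_radius + 0.7 * tang,
          CD = sA + u * spec$cage_radius - 0.7 * tang)
  })

  ## rings of 6 lining the two channels
  n_rings <- max(4, round((n_res_per_chain - 12) / 6))
  n_int <- max(2, round(n_rings * 2 / 5))
  n_bulk <- n_rings - n_int
  z_int <- seq(1.5, spec$site_offset - 3, length.out = n_int)
  z_bulk <- seq(spec$site_offset + 4, spec$bulk_z - 8, length.out = n_bulk)
  interface <- unlist(lapply(seq_along(z_int), function(k)
    ring_residues(z_int[k], 6, spec, phase = 0.3 * k)), recursive = FALSE)
  bulk <- unlist(lapply(seq_along(z_bulk), function(k)
    ring_residues(z_bulk[k], 6, spec, phase = 0.3 * k)), recursive = FALSE)

  res_list <- c(cage, interface, bulk)
  n_res <- length(res_list)
  res_names <- sample(STANDARD_RESIDUES, n_res, replace = TRUE)
  paths <- list(subunit_interface = 12 + seq_along(interface),
                cap = 12 + length(interface) + seq_along(bulk))

  build_chain <- function(ch, mirror) {
    rows <- lapply(seq_len(n_res), function(i) {
      xyz <- res_list[[i]]
      if (mirror) xyz <- cbind(xyz[, 1], -xyz[, 2], -xyz[, 3])
      data.frame(chain = ch, resno = i, insert = "", resid = res_names[i],
                 elety = rownames(res_list[[i]]), elesy = "C",
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], cofactor = FALSE)
    })
    do.call(rbind, rows)
  }
  fad <- function(ch, s, mirror) {
    xyz <- rbind(s + c(2.5, 0, -1), s + c(2.5, 0.8, 0))
    data.frame(chain = ch, resno = n_res + 1, insert = "", resid = "FAD",
               elety = c("C1", "C2"), elesy = "C",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], cofactor = TRUE)
  }
  atoms <- rbind(build_chain("A", FALSE), fad("A", sA, FALSE),
                 build_chain("B", TRUE), fad("B", sB, TRUE))
  ## design check: no protein atom may sit inside the channel steric core
  radial <- sqrt(atoms$x^2 + atoms$y^2)
  if (any(!atoms$cofactor & radial < spec$core_radius))
    stopf("channel centerline passes through steric cores")
  rec <- receptor(atoms, reference_points = list(
    siteA = sA, siteB = sB,
    bulkA = c(0, 0, spec$bulk_z), bulkB = c(0, 0, -spec$bulk_z)))

  rec_xyz <- as.matrix(rec$atoms[, c("x", "y", "z")])
  energy_parts <- function(lig_xyz, receptor_xyz = NULL) {
    lig_xyz <- rbind(lig_xyz)
    rx <- receptor_xyz %||% rec_xyz
    p <- colMeans(lig_xyz)
    well <- -spec$well_depth *
      (exp(-sum((p - sA)^2) / (2 * spec$well_width^2)) +
       exp(-sum((p - sB)^2) / (2 * spec$well_width^2)))
    rep_e <- 0
    for (k in seq_len(nrow(lig_xyz))) {
      d <- dist_to_rows(lig_xyz[k, ], rx)
      close <- d < spec$core_radius
      if (any(close))
        rep_e <- rep_e + spec$k_rep * sum((spec$core_radius - d[close])^2)
    }
    restraint <- spec$k_perp * (p[1]^2 + p[2]^2)
    c(well = well, repulsion = rep_e, restraint = restraint)
  }
  oracle <- list(
    total_energy = function(lig_xyz, receptor_xyz = NULL)
      sum(energy_parts(lig_xyz, receptor_xyz)),
    binding_energy = function(lig_xyz, receptor_xyz = NULL) {
      e <- energy_parts(lig_xyz, receptor_xyz)
      unname(e["well"] + e["repulsion"])
    })
  list(receptor = rec, oracle = oracle, paths = paths, spec = spec)
}

#' Generate a synthetic trajectory with known ground truth
#'
#' Moves a one-atom ligand along one of the toy receptor's ground-truth
#' channels (or keeps it in the site) with Gaussian positional jitter,
#' and jitters every pseudo-residue's backbone with a planned per-residue
#' standard deviation, so downstream RMSF, contact, path-assignment and
#' exit detection can be scored against the truth: the isotropic jitter
#' gives an expected RMSF of `sigma * sqrt(3)` per residue.
#'
#' @param toy result of [make_toy_receptor()].
#' @param route `"cap"` (site to bulk, exits), `"subunit_interface"`
#'   (site to partner site, stays inside), `"mixed"` (interface first,
#'   then out through the cap channel) or `"none"` (parked in the site).
#' @param n_frames number of frames.
#' @param jitter ligand positional jitter sd, Angstrom.
#' @param sigma per-residue backbone jitter sd, scalar or vector
#'   (Angstrom per axis).
#' @param exit_step for exiting routes: frame index at which the ligand
#'   is placed beyond the exit criterion (and stays out); `NULL` for a
#'   smooth ramp.
#' @param chain chain whose site the ligand starts in (`"A"` default).
#' @param seed RNG seed.
#' @return list with `frames` (trajectory data.frame), `receptor_series`
#'   (array frames x residues x 3 of chain C-alpha positions) and
#'   `truth` (route, exit_step, sigma).
#' @export
make_synthetic_trajectory <- function(toy, route = c("cap",
                                                     "subunit_interface",
                                                     "mixed", "none"),
                                      n_frames = 200, jitter = 0.05,
                                      sigma = 0.1, exit_step = NULL,
                                      chain = "A", seed = 1) {
  route <- match.arg(route)
  set.seed(seed)
  sp <- toy$spec
  s0 <- sp$site_offset
  z_out <- sp$bulk_z + 4                     # safely beyond the exit radius
  flip <- if (chain == "A") 1 else -1
  zpath <- switch(route,
    none = rep(s0, n_frames),
    cap = if (is.null(exit_step)) seq(s0, z_out, length.out = n_frames)
      else c(seq(s0, sp$bulk_z - 9, length.out = max(1, exit_step - 1)),
             rep(z_out, n_frames - exit_step + 1)),
    subunit_interface = seq(s0, -s0, length.out = n_frames),
    mixed = {
      a <- floor(n_frames / 3)
      c(seq(s0, 1.5, length.out = a),
        seq(1.5, sp$site_offset + 4, length.out = a),
        seq(sp$site_offset + 4, sp$bulk_z - 9,
            length.out = n_frames - 2 * a))
    })
  zpath <- flip * zpath
  xy <- matrix(rnorm(2 * n_frames, 0, jitter), ncol = 2)
  z <- zpath + rnorm(n_frames, 0, jitter)
  refs <- toy$receptor$reference_points
  own <- refs[[if (chain == "A") "siteA" else "siteB"]]
  other <- refs[[if (chain == "A") "siteB" else "siteA"]]
  frames <- data.frame(
    traj_id = 1L, step = seq_len(n_frames), accepted = TRUE,
    x = xy[, 1], y = xy[, 2], z = z,
    qw = 1, qx = 0, qy = 0, qz = 0,
    e_total = NA_real_, e_binding = NA_real_,
    dist_refA_A = NA_real_, dist_refB_A = NA_real_)
  for (k in seq_len(n_frames)) {
    p <- c(frames$x[k], frames$y[k], frames$z[k])
    frames$e_total[k] <- toy$oracle$total_energy(rbind(p))
    frames$e_binding[k] <- toy$oracle$binding_energy(rbind(p))
    frames$dist_refA_A[k] <- vnorm(p - own)
    frames$dist_refB_A[k] <- vnorm(p - other)
  }
  ## per-residue backbone series (C-alpha of the ligand-bearing chain)
  a <- toy$receptor$atoms
  ca <- a[a$chain == chain & a$elety == "CA" & !a$cofactor, ]
  n_res <- nrow(ca)
  sigma <- rep(sigma, length.out = n_res)
  base <- as.matrix(ca[, c("x", "y", "z")])
  series <- array(NA_real_, c(n_frames, n_res, 3))
  for (j in seq_len(n_res))
    series[, j, ] <- matrix(rep(base[j, ], each = n_frames), ncol = 3) +
      matrix(rnorm(3 * n_frames, 0, sigma[j]), ncol = 3)
  list(frames = frames, receptor_series = series,
       truth = list(route = route,
                    exit_step = if (route %in% c("cap", "mixed"))
                      exit_step %||% NA_integer_ else NA_integer_,
                    sigma = sigma, chain = chain))
}

#' Generate a labelled synthetic alignment with planted column categories
#'
#' Emulates the statistical structure of a merged three-subfamily
#' alignment: each query position is planted as conserved (one similarity
#' group shared by all subfamilies at full occupancy), similar (shared
#' group at 60-85% occupancy per subfamily), dissimilar (three mutually
#' distinct groups, no VAO/EUGO agreement) or PCMH-unlike (VAO and EUGO
#' share a group, PCMH gets a different one). Gaps are injected at
#' `gap_rate` everywhere except the anchor column and the query record;
#' the anchor column is planted as all-histidine for covalent-anchor
#' filter tests. The query record is gap-free, so query positions equal
#' alignment positions.
#'
#' @param n_positions alignment length in query positions (default 560).
#' @param counts named record counts per subfamily (default
#'   `c(VAO = 121, EUGO = 117, PCMH = 30)`, the study's subfamily sizes).
#' @param fractions named category fractions (default conserved 0.29,
#'   pcmh_unlike 0.25, similar 0.26, dissimilar 0.20, echoing the
#'   full-protein headline figures); ignored when `categories` is given.
#' @param categories optional data.frame (`position`, `category`) fixing
#'   the plan explicitly.
#' @param gap_rate per-cell gap probability in `[0, 1)` (default 0.02).
#' @param anchor_position query position planted as the all-His covalent
#'   anchor (default `min(422, n_positions)`); forced to `conserved`.
#' @param seed RNG seed.
#' @return list with `msa` (labelled `"msa"`, query id `"query_VAO"`),
#'   `truth` (data.frame position, category, planted groups) and the
#'   resolved `plan`.
#' @export
make_synthetic_msa <- function(n_positions = 560,
                               counts = c(VAO = 121, EUGO = 117, PCMH = 30),
                               fractions = c(conserved = 0.29,
                                             similar = 0.26,
                                             dissimilar = 0.20,
                                             pcmh_unlike = 0.25),
                               categories = NULL, gap_rate = 0.02,
                               anchor_position = min(422, n_positions),
                               seed = 1) {
  stopifnot(all(counts >= 1), gap_rate >= 0, gap_rate < 1)
  set.seed(seed)
  groups <- similarity_groups()
  gnames <- names(groups)
  if (is.null(categories)) {
    stopifnot(abs(sum(fractions) - 1) < 1e-9)
    n_cat <- round(fractions * n_positions)
    n_cat[1] <- n_positions - sum(n_cat[-1])     # fix rounding drift
    cats <- rep(names(n_cat), n_cat)
    categories <- data.frame(position = seq_len(n_positions),
                             category = sample(cats))
  }
  stopifnot(nrow(categories) == n_positions)
  ## the anchor column must be conserved; swap categories with a planned
  ## conserved position so the planted totals stay exactly as requested
  at_anchor <- which(categories$position == anchor_position)
  if (categories$category[at_anchor] != "conserved") {
    donor <- which(categories$category == "conserved")[1]
    if (!is.na(donor)) {
      categories$category[donor] <- categories$category[at_anchor]
    }
    categories$category[at_anchor] <- "conserved"
  }
  if (any(categories$category %in% c("similar")) && any(counts < 2))
    stopf("infeasible plan: 'similar' columns need >= 2 records per subfamily")

  subfam <- rep(names(counts), counts)
  n_rec <- length(subfam)
  ids <- unlist(lapply(names(counts), function(s)
    sprintf("%s_%03d", s, seq_len(counts[[s]]))))
  ids[1] <- "query_VAO"
  seqs <- matrix("-", n_rec, n_positions)
  draw <- function(g, n) sample(groups[[g]], n, replace = TRUE)
  truth_group <- matrix(NA_character_, n_positions, 3,
                        dimnames = list(NULL, c("VAO", "EUGO", "PCMH")))
  for (p in seq_len(n_positions)) {
    cat_p <- categories$category[categories$position == p]
    if (p == anchor_position) {
      seqs[, p] <- "H"
      truth_group[p, ] <- "basic"
      next
    }
    if (cat_p == "conserved") {
      g <- sample(gnames, 1)
      seqs[, p] <- draw(g, n_rec)
      truth_group[p, ] <- g
    } else if (cat_p == "similar") {
      g <- sample(gnames, 1)
      others <- setdiff(gnames, g)
      for (s in names(counts)) {
        idx <- which(subfam == s)
        occ <- runif(1, 0.60, 0.85)
        k <- max(2, round(occ * length(idx)))
        k <- min(k, length(idx) - 1)
        seqs[idx[seq_len(k)], p] <- draw(g, k)
        rest <- idx[-seq_len(k)]
        og <- rep(others, length.out = length(rest))
        for (r in seq_along(rest))
          seqs[rest[r], p] <- draw(og[r], 1)
      }
      truth_group[p, ] <- g
    } else if (cat_p == "dissimilar") {
      gs <- sample(gnames, 3)
      for (i in 1:3) {
        idx <- which(subfam == c("VAO", "EUGO", "PCMH")[i])
        seqs[idx, p] <- draw(gs[i], length(idx))
      }
      truth_group[p, ] <- gs
    } else if (cat_p == "pcmh_unlike") {
      g <- sample(gnames, 1)
      gp <- sample(setdiff(gnames, g), 1)
      for (s in c("VAO", "EUGO")) {
        idx <- which(subfam == s)
        seqs[idx, p] <- draw(g, length(idx))
      }
      idx <- which(subfam == "PCMH")
      seqs[idx, p] <- draw(gp, length(idx))
      truth_group[p, ] <- c(g, g, gp)
    } else stopf("unknown planted category '%s'", cat_p)
  }
  ## gap injection: never in the query record or the anchor column; kept
  ## sparse enough that planted categories survive the gap-inclusive
  ## denominator
  if (gap_rate > 0) {
    mask <- matrix(runif(n_rec * n_positions) < gap_rate, n_rec)
    mask[1, ] <- FALSE
    mask[, anchor_position] <- FALSE
    seqs[mask] <- "-"
  }
  out <- msa(seqs, ids, labels = subfam, query = "query_VAO")
  truth <- data.frame(position = seq_len(n_positions),
                      category = categories$category[
                        order(categories$position)],
                      vao_group = truth_group[, 1],
                      eugo_group = truth_group[, 2],
                      pcmh_group = truth_group[, 3])
  list(msa = out, truth = truth,
       plan = list(n_positions = n_positions, counts = counts,
                   gap_rate = gap_rate, anchor_position = anchor_position,
                   seed = seed))
}

#' @rdname write_receptor_pdb
#' @export
write_fixture_pdb <- function(x, file) write_receptor_pdb(x, file)
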