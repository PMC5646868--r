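## Trajectory analysis: RMSF, contact tables, binding-energy/distance
## profiles, path assignment, exit detection, dimer symmetry mapping.

#' Root mean square fluctuation per residue
#'
#' `RMSF_i = sqrt(mean_t ||r_i(t) - <r_i>||^2)` over each residue's
#' representative atom series. The representative atom is chosen upstream
#' (C-alpha by convention); pass an all-atom series for all-atom RMSF.
#'
#' @param series numeric array `frames x residues x 3` (or a matrix
#'   `frames x 3` for a single residue).
#' @return numeric vector of RMSF values (Angstrom), one per residue.
#' @export
rmsf <- function(series) {
  if (is.matrix(series)) dim(series) <- c(nrow(series), 1, 3)
  stopifnot(length(dim(series)) == 3, dim(series)[3] == 3)
  if (dim(series)[1] < 2)
    stopf("RMSF needs at least 2 frames, got %d", dim(series)[1])
  mu <- apply(series, c(2, 3), mean)
  dev2 <- (sweep(series[, , 1, drop = FALSE], 2, mu[, 1]))^2 +
          (sweep(series[, , 2, drop = FALSE], 2, mu[, 2]))^2 +
          (sweep(series[, , 3, drop = FALSE], 2, mu[, 3]))^2
  sqrt(apply(dev2, 2, mean))
}

## distribution summaries for boxplot-style reporting
rmsf_summary <- function(values) {
  q <- quantile(values, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  data.frame(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}

## reconstruct ligand world coordinates for one frame row
frame_ligand_xyz <- function(row, template) {
  pose <- ligand_pose(template, trans = c(row$x, row$y, row$z),
                      quat = quat_normalize(c(row$qw, row$qx, row$qy,
                                              row$qz)))
  pose_coords(pose)
}

#' Per-frame and total ligand contact table for a trajectory
#'
#' Reconstructs the ligand world coordinates of every accepted frame and
#' counts protein-ligand atom contacts (strict 2.7 Angstrom criterion by
#' default) per residue, per frame, plus totals over the trajectory.
#'
#' @param frames trajectory data.frame (one trajectory or several; columns
#'   as written by [write_trajectories()]).
#' @param receptor a `"receptor"` object.
#' @param ligand_template ligand local-frame coordinates (n x 3).
#' @param cutoff contact distance, strict inequality (default 2.7).
#' @return list with `per_frame` (data.frame step, chain, resno, insert,
#'   resid, count) and `totals` (aggregated over frames).
#' @export
contact_table <- function(frames, receptor, ligand_template, cutoff = 2.7) {
  per <- vector("list", nrow(frames))
  for (k in seq_len(nrow(frames))) {
    xyz <- frame_ligand_xyz(frames[k, ], ligand_template)
    ct <- ligand_contacts(xyz, receptor, cutoff)
    if (nrow(ct)) {
      ct$step <- frames$step[k]
      per[[k]] <- ct
    }
  }
  per <- do.call(rbind, per)
  if (is.null(per))
    per <- data.frame(chain = character(), resno = integer(),
                      insert = character(), resid = character(),
                      count = integer(), step = integer())
  totals <- if (nrow(per)) {
    agg <- aggregate(count ~ chain + resno + insert + resid, per, sum)
    agg[order(agg$chain, agg$resno), , drop = FALSE]
  } else per[, c("chain", "resno", "insert", "resid", "count")]
  rownames(totals) <- NULL
  list(per_frame = per, totals = totals)
}

## signed reaction coordinate: + distance to the own-chain reference,
## - distance to the other-chain reference when the ligand is nearer the
## other chain; exact tie -> positive sign (documented convention)
signed_reaction_coord <- function(frames) {
  a <- frames$dist_refA_A
  b <- frames$dist_refB_A
  ifelse(is.na(b) | a <= b, a, -b)
}

#' Binding-energy versus distance profile
#'
#' Bins the signed ligand-reference distance (positive toward the own
#' subunit's reference point, negative when the ligand is nearer the
#' partner subunit's; ties positive) and reports per-bin minimum and
#' spread of the binding energy, the scatter the study uses to judge
#' favourable positions along a path.
#'
#' @param frames trajectory data.frame with `e_binding`, `dist_refA_A`,
#'   `dist_refB_A`.
#' @param bin_width bin width in Angstrom (default 1).
#' @return data.frame: bin mid-point, per-bin minimum / median / maximum
#'   binding energy and frame count.
#' @export
energy_distance_profile <- function(frames, bin_width = 1) {
  s <- signed_reaction_coord(frames)
  bin <- floor(s / bin_width)
  idx <- split(seq_along(s), bin)
  out <- data.frame(
    mid = (as.numeric(names(idx)) + 0.5) * bin_width,
    e_min = vapply(idx, function(i) min(frames$e_binding[i]), numeric(1)),
    e_median = vapply(idx, function(i)
      stats::median(frames$e_binding[i]), numeric(1)),
    e_max = vapply(idx, function(i) max(frames$e_binding[i]), numeric(1)),
    n = lengths(idx))
  out <- out[order(out$mid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign migration-path labels to a trajectory
#'
#' Each accepted frame is labelled with the path whose residue set
#' receives the largest contact count in a window of `window` frames on
#' either side; frames with no path contacts stay unlabelled, ties stay
#' unlabelled. The trajectory label is the ordered set of visited paths:
#' a single path name, or `"mixed: a->b"` when the ligand moved between
#' paths.
#'
#' @param contacts result of [contact_table()] (its `per_frame` part is
#'   used) or the per-frame data.frame itself.
#' @param frames the trajectory data.frame the contacts were computed
#'   from (supplies the frame order).
#' @param path_definitions named list of residue-number vectors (protein
#'   numbering), e.g. [vao_path_residues()] or a custom set.
#' @param receptor optional `"receptor"`; when given, path residues
#'   absent from the receptor raise an error.
#' @param window half-width of the smoothing window in frames (default
#'   5).
#' @return list with `frame_labels` (character per frame, `NA` when
#'   unlabelled) and `trajectory_label`.
#' @export
assign_path <- function(contacts, frames, path_definitions,
                        receptor = NULL, window = 5) {
  per <- if (is.list(contacts) && !is.data.frame(contacts))
    contacts$per_frame else contacts
  stopifnot(is.list(path_definitions), length(path_definitions) >= 1)
  if (!is.null(receptor)) {
    known <- unique(receptor$atoms$resno[!receptor$atoms$cofactor])
    bad <- setdiff(unlist(path_definitions), known)
    if (length(bad))
      stopf("path definitions name residues absent from the receptor: %s",
            paste(sort(bad), collapse = ", "))
  }
  steps <- frames$step
  nf <- length(steps)
  paths <- names(path_definitions)
  ## per-frame raw counts per path
  raw <- matrix(0, nf, length(paths), dimnames = list(NULL, paths))
  if (nrow(per)) {
    fidx <- match(per$step, steps)
    for (p in paths) {
      inp <- per$resno %in% path_definitions[[p]]
      if (any(inp)) {
        tab <- tapply(per$count[inp], fidx[inp], sum)
        raw[as.integer(names(tab)), p] <- tab
      }
    }
  }
  ## windowed sums
  win <- matrix(0, nf, length(paths), dimnames = list(NULL, paths))
  for (f in seq_len(nf)) {
    lo <- max(1, f - window); hi <- min(nf, f + window)
    win[f, ] <- colSums(raw[lo:hi, , drop = FALSE])
  }
  labels <- rep(NA_character_, nf)
  for (f in seq_len(nf)) {
    m <- max(win[f, ])
    if (m > 0) {
      at <- which(win[f, ] == m)
      if (length(at) == 1) labels[f] <- paths[at]
    }
  }
  visited <- unique(labels[!is.na(labels)])
  traj_label <- if (!length(visited)) NA_character_
    else if (length(visited) == 1) visited
    else paste0("mixed: ", paste(visited, collapse = "->"))
  list(frame_labels = labels, trajectory_label = traj_label)
}

#' Detect ligand exit from the receptor
#'
#' The ligand has exited when the minimum heavy-atom distance between the
#' ligand and the receptor exceeds `threshold` for `persistence`
#' consecutive accepted frames; the reported exit step is the first frame
#' of that run. Single-frame excursions do not count.
#'
#' @param frames trajectory data.frame.
#' @param receptor a `"receptor"` object.
#' @param ligand_template ligand local-frame coordinates.
#' @param threshold exit distance in Angstrom (default 8).
#' @param persistence consecutive frames required (default 3).
#' @return list with `exited` (logical) and `step` (first exit step or
#'   `NA`).
#' @export
detect_exit <- function(frames, receptor, ligand_template,
                        threshold = 8, persistence = 3) {
  rec <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  out <- vapply(seq_len(nrow(frames)), function(k) {
    xyz <- frame_ligand_xyz(frames[k, ], ligand_template)
    min(vapply(seq_len(nrow(xyz)), function(i)
      min(dist_to_rows(xyz[i, ], rec)), numeric(1)))
  }, numeric(1)) > threshold
  streak <- 0L
  for (k in seq_along(out)) {
    streak <- if (out[k]) streak + 1L else 0L
    if (streak >= persistence)
      return(list(exited = TRUE, step = frames$step[k - persistence + 1L]))
  }
  list(exited = FALSE, step = NA_integer_)
}

#' Dimer symmetry map between the two subunits
#'
#' Least-squares (Kabsch) superposition of chain A C-alpha atoms onto
#' chain B, returned as a rigid transform that can be applied to ligand
#' poses or coordinates to mirror data between the subunits. On an exactly
#' two-fold symmetric dimer the map is an involution: applying it twice
#' returns the input.
#'
#' @param receptor a `"receptor"` with two chains of equal mappable
#'   C-alpha counts.
#' @param chains length-2 character: source and target chain (default the
#'   first two chains).
#' @return object of class `"symmetry_map"`: `R` (proper rotation), `t`
#'   (translation), usable via [apply_symmetry()].
#' @export
symmetry_map <- function(receptor, chains = NULL) {
  a <- receptor$atoms[!receptor$atoms$cofactor & receptor$atoms$elety == "CA", ]
  chs <- chains %||% unique(a$chain)[1:2]
  ca1 <- as.matrix(a[a$chain == chs[1], c("x", "y", "z")])
  ca2 <- as.matrix(a[a$chain == chs[2], c("x", "y", "z")])
  if (nrow(ca1) != nrow(ca2) || nrow(ca1) < 3)
    stopf("chains %s and %s have unequal mappable C-alpha counts (%d vs %d)",
          chs[1], chs[2], nrow(ca1), nrow(ca2))
  tr <- kabsch(ca1, ca2)
  structure(c(tr, list(chains = chs)), class = "symmetry_map")
}

#' @rdname symmetry_map
#' @param map a `"symmetry_map"`.
#' @param xyz coordinate matrix (n x 3) or length-3 point.
#' @return `apply_symmetry()`: transformed coordinates.
#' @export
apply_symmetry <- function(map, xyz) {
  one <- is.null(dim(xyz))
  out <- apply_transform(rbind(xyz), map)
  if (one) as.numeric(out) else out
}

#' Default migration-path residue sets
#'
#' Residue sets (protein numbering of the 560-residue flavoenzyme subunit)
#' lining the four migration paths: cap (25 residues), FAD (36), subunit
#' interface (53) and re-side (22). The published record names only the
#' most flexible or most contacted members of each path plus the set
#' sizes, so these defaults are reconstructions: every residue named in
#' the path descriptions, padded with immediate sequence neighbours of
#' named members up to the documented set size. Override with your own
#' sets via [read_path_definitions()] wherever exact membership matters.
#'
#' @return named list of integer vectors: `cap`, `fad`,
#'   `subunit_interface`, `re`.
#' @export
vao_path_residues <- function() {
  list(
    cap = c(171, 311, 312, 313, 315, 316, 353, 354, 355, 389, 390, 391,
            392, 393, 394, 395, 396, 397, 398, 399, 400, 401, 410, 412,
            413),
    fad = c(97, 98, 99, 100, 101, 102, 104, 105, 106, 113, 114, 115, 116,
            117, 118, 423, 424, 425, 501, 502, 503, 504, 505, 506, 507,
            508, 509, 510, 511, 542, 543, 544, 545, 546, 547, 548),
    subunit_interface = c(182, 183, 184, 185, 186, 187, 188, 191, 192,
                          193, 194, 195, 196, 197, 243, 244, 245, 248,
                          249, 250, 254, 255, 256, 273, 274, 275, 299,
                          300, 301, 302, 303, 304, 306, 307, 308, 309,
                          310, 311, 355, 356, 357, 401, 402, 427, 428,
                          429, 461, 462, 463, 464, 465, 466, 468),
    re = c(50, 51, 52, 53, 54, 55, 56, 59, 60, 61, 62, 103, 104, 105,
           106, 148, 171, 174, 407, 408, 411, 475))
}

#' Read / write path or residue-group definitions as TSV
#'
#' Two- or three-column TSV: `name`, `resnum` and optionally `chain`.
#'
#' @param file TSV path.
#' @return named list of integer residue-number vectors.
#' @export
read_path_definitions <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("name", "resnum") %in% names(d)))
    stopf("path definition TSV needs columns 'name' and 'resnum'")
  split(as.integer(d$resnum), d$name)
}

#' @rdname read_path_definitions
#' @param paths named list of residue-number vectors.
#' @export
write_path_definitions <- function(paths, file) {
  d <- data.frame(name = rep(names(paths), lengths(paths)),
                  resnum = unlist(paths, use.names = FALSE))
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
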