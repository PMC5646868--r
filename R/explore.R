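## Monte Carlo ligand-migration engine: rigid-body move set, Metropolis
## filter, spawning trajectory management, adaptive entry epochs, optional
## ANM backbone moves, all over a pluggable energy oracle.

#' Rigid-body ligand pose
#'
#' A pose is the rigid-body state of the ligand: centroid translation,
#' unit-quaternion orientation, and the ligand template atoms in a local
#' frame centred at the origin. World coordinates are
#' `rotation(template) + translation`.
#'
#' @param template numeric matrix (n x 3) of ligand atom coordinates; the
#'   centroid is moved to the origin.
#' @param trans centroid position, xyz Angstrom.
#' @param quat unit quaternion `c(w, x, y, z)`.
#' @return list of class `"ligand_pose"`.
#' @export
ligand_pose <- function(template, trans = c(0, 0, 0), quat = c(1, 0, 0, 0)) {
  template <- rbind(template)
  template <- sweep(template, 2, colMeans(template))
  if (abs(vnorm(quat) - 1) > 1e-9) stopf("quaternion is not unit norm")
  structure(list(trans = as.numeric(trans), quat = as.numeric(quat),
                 template = template),
            class = "ligand_pose")
}

#' @rdname ligand_pose
#' @param pose a `"ligand_pose"`.
#' @return `pose_coords()`: world-frame coordinate matrix.
#' @export
pose_coords <- function(pose) {
  R <- quat_rotation_matrix(pose$quat)
  sweep(pose$template %*% t(R), 2, pose$trans, "+")
}

#' Perturb a ligand pose
#'
#' One Monte Carlo move: a translation of magnitude uniform in
#' `trans_range` along a random unit direction, plus a rotation about a
#' random axis by an angle uniform in `rot_range`. The translation
#' direction persists for `persistence` consecutive calls (directional
#' persistence used by entry simulations), tracked through `dir_state`.
#'
#' @param pose a `"ligand_pose"`.
#' @param trans_range length-2 numeric, Angstrom.
#' @param rot_range length-2 numeric, radians.
#' @param persistence steps a translation direction is kept (default 1).
#' @param dir_state opaque state from the previous call, or `NULL` to draw
#'   a fresh direction.
#' @return list with `pose` (perturbed, quaternion renormalised) and
#'   `dir_state` to pass to the next call.
#' @export
perturb_pose <- function(pose, trans_range, rot_range, persistence = 1,
                         dir_state = NULL) {
  stopifnot(trans_range[1] <= trans_range[2], rot_range[1] <= rot_range[2])
  if (is.null(dir_state) || dir_state$remaining <= 0)
    dir_state <- list(dir = random_unit_vector(), remaining = persistence)
  mag <- runif(1, trans_range[1], trans_range[2])
  trans <- pose$trans + mag * dir_state$dir
  dir_state$remaining <- dir_state$remaining - 1
  quat <- pose$quat
  angle <- runif(1, rot_range[1], rot_range[2])
  if (angle > 0) {
    dq <- quat_from_axis_angle(random_unit_vector(), angle)
    quat <- quat_normalize(quat_multiply(dq, quat))
  }
  pose$trans <- trans
  pose$quat <- quat
  list(pose = pose, dir_state = dir_state)
}

#' Metropolis acceptance test
#'
#' Accepts a proposed energy with probability
#' `min(1, exp(-(e_new - e_old) / temperature))`. Non-finite proposals are
#' rejected.
#'
#' @param e_old,e_new energies in oracle units.
#' @param temperature Boltzmann factor scale kT (> 0, oracle units).
#' @return logical.
#' @export
metropolis_accept <- function(e_old, e_new, temperature = 1) {
  stopifnot(temperature > 0)
  if (!is.finite(e_new)) return(FALSE)
  d <- e_new - e_old
  if (d <= 0) return(TRUE)
  runif(1) < exp(-d / temperature)
}

#' Spawning filter over a trajectory population
#'
#' Implements restart-at-best trajectory management: the best reaction
#' coordinate over all live trajectories is found (updated at every call),
#' and any trajectory lagging the best by more than `spawning_range` is
#' flagged for reset to a copy of the best trajectory's state.
#'
#' @param coords numeric vector of per-trajectory reaction coordinates.
#' @param spawning_range allowed lag behind the best value, Angstrom
#'   (default 4).
#' @param direction `"max"` when larger coordinates are better (exit
#'   simulations: distance from the active-site spawning point), `"min"`
#'   otherwise.
#' @return list with `best` (index of the best trajectory) and `reset`
#'   (logical vector, `TRUE` for trajectories to restart at the best).
#' @export
spawn_filter <- function(coords, spawning_range = 4,
                         direction = c("max", "min")) {
  direction <- match.arg(direction)
  stopifnot(length(coords) >= 1, spawning_range > 0)
  if (direction == "min") coords <- -coords
  best <- which.max(coords)
  list(best = best, reset = (coords[best] - coords) > spawning_range)
}

#' Leader clustering of ligand positions
#'
#' Single-pass leader algorithm: each point joins the first existing
#' cluster whose leader lies within `radius`, otherwise it founds a new
#' cluster.
#'
#' @param points numeric matrix (n x 3).
#' @param radius cluster radius, Angstrom.
#' @return list with `assignment` (cluster id per point), `leaders`
#'   (row indices of cluster leaders) and `sizes` (cluster populations).
#' @export
leader_cluster <- function(points, radius) {
  points <- rbind(points)
  n <- nrow(points)
  leaders <- 1L
  assignment <- integer(n)
  assignment[1] <- 1L
  if (n > 1) for (i in 2:n) {
    d <- dist_to_rows(points[i, ], points[leaders, , drop = FALSE])
    k <- which(d <= radius)[1]
    if (is.na(k)) {
      leaders <- c(leaders, i)
      assignment[i] <- length(leaders)
    } else assignment[i] <- k
  }
  list(assignment = assignment, leaders = leaders,
       sizes = tabulate(assignment, nbins = length(leaders)))
}

#' Adaptive-epoch restart selection
#'
#' After an epoch of Monte Carlo steps the accepted ligand positions are
#' clustered (leader clustering) and new initial conditions are drawn from
#' the cluster leaders with probability proportional to the inverse of the
#' cluster population, prioritising sparsely visited regions.
#'
#' @param centroids accepted ligand centroids, matrix (n x 3).
#' @param cluster_radius leader-clustering radius, Angstrom.
#' @param n_starts number of restart states to draw.
#' @return list with the clustering (`assignment`, `leaders`, `sizes`),
#'   `weights` (normalised inverse-population weights per cluster) and
#'   `starts` (row indices into `centroids` of the selected restart
#'   states).
#' @export
adaptive_epoch <- function(centroids, cluster_radius, n_starts) {
  cl <- leader_cluster(centroids, cluster_radius)
  w <- (1 / cl$sizes) / sum(1 / cl$sizes)
  pick <- sample.int(length(cl$leaders), n_starts, replace = TRUE, prob = w)
  c(cl, list(weights = w, starts = cl$leaders[pick]))
}

#' Exploration configuration
#'
#' Collects the tunable parameters of the migration explorer with defaults
#' matching the study protocol: exit moves draw translations from
#' 0.75-1.75 Angstrom and rotations from 0.05-0.25 rad; entry moves use
#' larger translations (1.25-2.5 Angstrom) with the direction kept for
#' three consecutive steps; the small-ligand preset uses 0.5-1.5 Angstrom
#' and 0.1-0.3 rad; the spawning lag range is 4 Angstrom; adaptive epochs
#' last 12 steps.
#'
#' @param mode `"exit"` or `"entry"`.
#' @param preset `"phenolic"` (default) or `"small"` (dioxygen/peroxide
#'   scale moves).
#' @param trans_range,rot_range move ranges; mode/preset defaults when
#'   `NULL`.
#' @param persistence translation-direction persistence (entry default 3,
#'   exit 1).
#' @param temperature Metropolis kT in oracle units (default 1).
#' @param spawning_point name of the receptor reference point used as the
#'   reaction-coordinate origin (default `"siteA"`).
#' @param other_point reference point of the partner subunit for signed
#'   distance profiles (default `"siteB"`).
#' @param spawning_range spawning lag range, Angstrom (default 4).
#' @param spawn_cadence apply the spawning filter every this many steps
#'   (default 5).
#' @param n_trajectories number of parallel trajectories.
#' @param max_steps maximum Monte Carlo steps per trajectory.
#' @param adaptive list: `epoch_length` (default 12), `cluster_radius`
#'   (default 2 Angstrom).
#' @param anm list: `enabled`, `cutoff`, `n_modes`, `step` for backbone
#'   perturbation.
#' @param exit_threshold minimum ligand-receptor heavy-atom distance that
#'   counts as having left the protein (default 8 Angstrom).
#' @param seed integer RNG seed; trajectory `i` uses stream `seed + i`.
#' @return list of class `"migration_config"`.
#' @export
migration_config <- function(mode = c("exit", "entry"),
                             preset = c("phenolic", "small"),
                             trans_range = NULL, rot_range = NULL,
                             persistence = NULL, temperature = 1,
                             spawning_point = "siteA", other_point = "siteB",
                             spawning_range = 4, spawn_cadence = 5,
                             n_trajectories = 20, max_steps = 500,
                             adaptive = list(), anm = list(),
                             exit_threshold = 8, seed = 1) {
  mode <- match.arg(mode)
  preset <- match.arg(preset)
  if (is.null(trans_range))
    trans_range <- if (preset == "small") c(0.5, 1.5)
      else if (mode == "entry") c(1.25, 2.5) else c(0.75, 1.75)
  if (is.null(rot_range))
    rot_range <- if (preset == "small") c(0.1, 0.3) else c(0.05, 0.25)
  if (is.null(persistence)) persistence <- if (mode == "entry") 3 else 1
  adaptive <- utils::modifyList(list(epoch_length = 12, cluster_radius = 2),
                                adaptive)
  anm <- utils::modifyList(
    list(enabled = FALSE, cutoff = 15, n_modes = 6, step = 0.5), anm)
  stopifnot(trans_range[1] <= trans_range[2],
            rot_range[1] <= rot_range[2],
            spawning_range > 0, adaptive$epoch_length >= 1,
            temperature > 0, n_trajectories >= 1, max_steps >= 1)
  structure(list(mode = mode, preset = preset, trans_range = trans_range,
                 rot_range = rot_range, persistence = persistence,
                 temperature = temperature, spawning_point = spawning_point,
                 other_point = other_point, spawning_range = spawning_range,
                 spawn_cadence = spawn_cadence,
                 n_trajectories = n_trajectories, max_steps = max_steps,
                 adaptive = adaptive, anm = anm,
                 exit_threshold = exit_threshold, seed = as.integer(seed)),
            class = "migration_config")
}

## energy oracle contract: list(total_energy, binding_energy), each a
## function(lig_xyz, receptor_xyz = NULL) returning a scalar.
check_oracle <- function(oracle) {
  if (!is.list(oracle) || !is.function(oracle$total_energy) ||
      !is.function(oracle$binding_energy))
    stopf("oracle must be a list with functions total_energy, binding_energy")
  oracle
}

## per-trajectory RNG streams, kept deterministic regardless of the
## interleaved execution order
rng_restore <- function(state) {
  if (is.null(state)) return(invisible())
  assign(".Random.seed", state, envir = globalenv())
}
rng_save <- function() get(".Random.seed", envir = globalenv())
rng_init <- function(seed) { set.seed(seed); rng_save() }

## evenly spread positions on a sphere enclosing the receptor: bulk start
## states for entry simulations
bulk_start_positions <- function(rec_xyz, n = 6, margin = 8) {
  ctr <- colMeans(rec_xyz)
  radius <- max(dist_to_rows(ctr, rec_xyz)) + margin
  pts <- sphere_lattice(n) * radius
  sweep(pts, 2, ctr, "+")
}

#' Explore ligand migration paths by Monte Carlo
#'
#' Runs an ensemble of rigid-body Monte Carlo trajectories of a ligand in
#' a receptor over a pluggable energy oracle. Each step perturbs the pose
#' ([perturb_pose()]), optionally displaces the receptor backbone along a
#' random low-frequency elastic-network mode, and filters the move with a
#' Metropolis test. Exit simulations drive the ligand outward with the
#' spawning procedure ([spawn_filter()]) on the distance from the
#' active-site spawning point; entry simulations start from bulk-solvent
#' positions and restart every adaptive epoch from sparsely populated
#' position clusters ([adaptive_epoch()]). A trajectory ends when the
#' ligand has left the receptor (minimum heavy-atom distance above the
#' exit threshold for three consecutive accepted frames) or after
#' `max_steps`.
#'
#' @param receptor a `"receptor"` object whose `reference_points` include
#'   the configured spawning point.
#' @param ligand_template ligand atom coordinates (n x 3) in any frame;
#'   re-centred internally.
#' @param oracle energy oracle: `list(total_energy, binding_energy)`, each
#'   `function(lig_xyz, receptor_xyz = NULL)` returning a scalar in the
#'   oracle's own units (qualitative scale).
#' @param config a [migration_config()].
#' @param start_poses optional list of `"ligand_pose"` start states, one
#'   per trajectory; defaults are mode-dependent (exit: docked at the
#'   spawning point; entry: six bulk positions assigned round-robin).
#' @return object of class `"migration"`: per-trajectory accepted frames,
#'   exit flags/steps, acceptance rates and the configuration.
#' @export
explore_migration <- function(receptor, ligand_template, oracle,
                              config = migration_config(),
                              start_poses = NULL) {
  oracle <- check_oracle(oracle)
  stopifnot(inherits(config, "migration_config"))
  rec_all <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  refs <- receptor$reference_points
  own_pt <- refs[[config$spawning_point]]
  if (is.null(own_pt))
    stopf("receptor has no reference point named '%s'", config$spawning_point)
  other_pt <- refs[[config$other_point]]
  ntraj <- config$n_trajectories

  ## ANM setup (modes computed once on the reference backbone)
  anm <- NULL
  if (isTRUE(config$anm$enabled)) {
    ca_idx <- which(receptor$atoms$elety == "CA" & !receptor$atoms$cofactor)
    anm <- anm_modes(rec_all[ca_idx, , drop = FALSE],
                     cutoff = config$anm$cutoff,
                     n_modes = config$anm$n_modes)
    anm$ca_idx <- ca_idx
  }

  ## start states
  shared_rng <- rng_init(config$seed)
  if (is.null(start_poses)) {
    start_poses <- if (config$mode == "exit") {
      lapply(seq_len(ntraj), function(i) ligand_pose(ligand_template, own_pt))
    } else {
      rng_restore(shared_rng)
      bulk <- bulk_start_positions(rec_all, n = 6)
      shared_rng <- rng_save()
      lapply(seq_len(ntraj), function(i)
        ligand_pose(ligand_template, bulk[((i - 1) %% nrow(bulk)) + 1, ]))
    }
  }

  traj <- lapply(seq_len(ntraj), function(i) {
    rng <- rng_init(config$seed + i)
    pose <- start_poses[[i]]
    list(pose = pose,
         e = oracle$total_energy(pose_coords(pose)),
         dir_state = NULL, rng = rng,
         frames = list(), exited = FALSE, exit_step = NA_integer_,
         streak = 0L, first_out = NA_integer_,
         proposed = 0L, accepted = 0L, failed = FALSE)
  })

  record_frame <- function(tr, i, step) {
    xyz <- pose_coords(tr$pose)
    ctr <- colMeans(xyz)
    tr$frames[[length(tr$frames) + 1]] <- data.frame(
      traj_id = i, step = step, accepted = TRUE,
      x = ctr[1], y = ctr[2], z = ctr[3],
      qw = tr$pose$quat[1], qx = tr$pose$quat[2],
      qy = tr$pose$quat[3], qz = tr$pose$quat[4],
      e_total = tr$e,
      e_binding = oracle$binding_energy(xyz),
      dist_refA_A = vnorm(ctr - own_pt),
      dist_refB_A = if (is.null(other_pt)) NA_real_
                    else vnorm(ctr - other_pt))
    tr
  }

  for (step in seq_len(config$max_steps)) {
    live <- which(!vapply(traj, function(t) t$exited || t$failed, logical(1)))
    if (!length(live)) break
    for (i in live) {
      tr <- traj[[i]]
      rng_restore(tr$rng)
      prop <- perturb_pose(tr$pose, config$trans_range, config$rot_range,
                           config$persistence, tr$dir_state)
      tr$dir_state <- prop$dir_state
      lig_xyz <- pose_coords(prop$pose)
      rxyz <- NULL
      if (!is.null(anm)) {
        k <- sample.int(ncol(anm$modes), 1)
        sgn <- sample(c(-1, 1), 1)
        rxyz <- rec_all
        ca <- rxyz[anm$ca_idx, , drop = FALSE]
        rxyz[anm$ca_idx, ] <- anm_displace(ca, sgn * anm$modes[, k],
                                           config$anm$step)
      }
      tr$proposed <- tr$proposed + 1L
      e_new <- tryCatch(oracle$total_energy(lig_xyz, rxyz), error = function(e) NA_real_)
      if (is.na(e_new) && tr$proposed == 1L && !length(tr$frames)) {
        ## oracle broken at the very start: mark failed, keep others going
        tr$failed <- TRUE
        traj[[i]] <- tr
        next
      }
      if (metropolis_accept(tr$e, e_new, config$temperature)) {
        tr$pose <- prop$pose
        tr$e <- e_new
        tr$accepted <- tr$accepted + 1L
        tr <- record_frame(tr, i, step)
        ## exit bookkeeping on accepted frames (exit simulations only; an
        ## entry ligand legitimately starts far from the receptor)
        if (config$mode == "exit") {
        cur <- pose_coords(tr$pose)
        mind <- min(vapply(seq_len(nrow(cur)), function(a)
          min(dist_to_rows(cur[a, ], rec_all)), numeric(1)))
        if (mind > config$exit_threshold) {
          if (tr$streak == 0L) tr$first_out <- step
          tr$streak <- tr$streak + 1L
          if (tr$streak >= 3L) {
            tr$exited <- TRUE
            tr$exit_step <- tr$first_out
          }
        } else {
          tr$streak <- 0L
          tr$first_out <- NA_integer_
        }
        }
      }
      tr$rng <- rng_save()
      traj[[i]] <- tr
    }

    if (config$mode == "exit" && step %% config$spawn_cadence == 0) {
      ok <- which(!vapply(traj, `[[`, logical(1), "failed"))
      coords <- vapply(traj[ok], function(t)
        vnorm(t$pose$trans - own_pt), numeric(1))
      sf <- spawn_filter(coords, config$spawning_range, "max")
      donor <- traj[[ok[sf$best]]]
      for (j in which(sf$reset)) {
        i <- ok[j]
        if (traj[[i]]$exited) next
        traj[[i]]$pose <- donor$pose
        traj[[i]]$e <- donor$e
        traj[[i]]$dir_state <- NULL
        traj[[i]]$streak <- 0L
      }
    }

    if (config$mode == "entry" && step %% config$adaptive$epoch_length == 0) {
      ok <- which(!vapply(traj, `[[`, logical(1), "failed"))
      acc <- do.call(rbind, unlist(lapply(traj[ok], `[[`, "frames"),
                                   recursive = FALSE))
      if (!is.null(acc) && nrow(acc) >= 1) {
        rng_restore(shared_rng)
        ep <- adaptive_epoch(as.matrix(acc[, c("x", "y", "z")]),
                             config$adaptive$cluster_radius, length(ok))
        shared_rng <- rng_save()
        for (j in seq_along(ok)) {
          i <- ok[j]
          row <- acc[ep$starts[j], ]
          traj[[i]]$pose <- ligand_pose(
            traj[[i]]$pose$template,
            trans = c(row$x, row$y, row$z),
            quat = quat_normalize(c(row$qw, row$qx, row$qy, row$qz)))
          traj[[i]]$e <- oracle$total_energy(pose_coords(traj[[i]]$pose))
          traj[[i]]$dir_state <- NULL
          traj[[i]]$streak <- 0L
        }
      }
    }
  }

  frames <- lapply(traj, function(t)
    if (length(t$frames)) do.call(rbind, t$frames) else NULL)
  structure(list(
    trajectories = frames,
    exited = vapply(traj, `[[`, logical(1), "exited"),
    exit_step = vapply(traj, `[[`, integer(1), "exit_step"),
    failed = vapply(traj, `[[`, logical(1), "failed"),
    acceptance = vapply(traj, function(t)
      if (t$proposed) t$accepted / t$proposed else NA_real_, numeric(1)),
    config = config,
    reference_points = refs,
    inputs = list(receptor = receptor, ligand_template = ligand_template,
                  oracle = oracle)),
    class = "migration")
}

#' @export
print.migration <- function(x, ...) {
  cat(sprintf("Ligand migration ensemble (%s mode)\n", x$config$mode))
  cat(sprintf("  trajectories: %d   max steps: %d   seed: %d\n",
              x$config$n_trajectories, x$config$max_steps, x$config$seed))
  cat(sprintf("  exited: %d/%d (%.0f%%)\n", sum(x$exited), length(x$exited),
              100 * mean(x$exited)))
  cat(sprintf("  mean acceptance rate: %.2f\n",
              mean(x$acceptance, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.migration <- function(object, ...) {
  d <- as.data.frame(object)
  out <- list(
    mode = object$config$mode,
    n_trajectories = object$config$n_trajectories,
    exited_fraction = mean(object$exited),
    exit_steps = object$exit_step[object$exited],
    acceptance = object$acceptance,
    energy_range = if (nrow(d)) range(d$e_binding) else c(NA, NA),
    reaction_coord_range = if (nrow(d)) range(d$dist_refA_A) else c(NA, NA))
  class(out) <- "summary.migration"
  out
}

#' @export
print.summary.migration <- function(x, ...) {
  cat(sprintf("Migration summary (%s mode, %d trajectories)\n",
              x$mode, x$n_trajectories))
  cat(sprintf("  exited: %.0f%%", 100 * x$exited_fraction))
  if (length(x$exit_steps))
    cat(sprintf("  (exit steps: median %d, range %d-%d)",
                as.integer(stats::median(x$exit_steps)),
                min(x$exit_steps), max(x$exit_steps)))
  cat("\n")
  cat(sprintf("  acceptance: %.2f (mean)\n", mean(x$acceptance, na.rm = TRUE)))
  cat(sprintf("  binding energy range: [%.2f, %.2f]\n",
              x$energy_range[1], x$energy_range[2]))
  cat(sprintf("  reaction coordinate range: [%.2f, %.2f] A\n",
              x$reaction_coord_range[1], x$reaction_coord_range[2]))
  invisible(x)
}

#' @export
as.data.frame.migration <- function(x, ...) {
  keep <- !vapply(x$trajectories, is.null, logical(1))
  if (!any(keep)) return(data.frame())
  out <- do.call(rbind, x$trajectories[keep])
  rownames(out) <- NULL
  out
}

#' @export
plot.migration <- function(x, bin_width = 1, ...) {
  d <- as.data.frame(x)
  if (!nrow(d)) stopf("no accepted frames to plot")
  s <- signed_reaction_coord(d)
  plot(s, d$e_binding, pch = 16, cex = 0.4, col = rgb(0.2, 0.2, 0.6, 0.4),
       xlab = "signed distance to reference point (A)",
       ylab = "binding energy (oracle units)", ...)
  prof <- energy_distance_profile(d, bin_width = bin_width)
  points(prof$mid, prof$e_min, type = "b", pch = 4, col = "red")
  invisible(x)
}

#' Re-run a migration ensemble with fresh random seeds
#'
#' @param object a `"migration"` result.
#' @param nsim number of replicate ensembles.
#' @param seed base seed; replicate `k` uses `seed + 1000 * k`.
#' @param ... unused.
#' @return list of `"migration"` objects.
#' @export
simulate.migration <- function(object, nsim = 1, seed = NULL, ...) {
  seed <- seed %||% object$config$seed
  lapply(seq_len(nsim), function(k) {
    cfg <- object$config
    cfg$seed <- as.integer(seed + 1000 * k)
    explore_migration(object$inputs$receptor, object$inputs$ligand_template,
                      object$inputs$oracle, cfg)
  })
}

#' Write / read a trajectory table as TSV
#'
#' Columns: traj_id, step, accepted, x, y, z, qw, qx, qy, qz, e_total,
#' e_binding, dist_refA_A, dist_refB_A.
#'
#' @param x a `"migration"` object or a frame data.frame.
#' @param file path to a TSV file.
#' @return `write_trajectories()`: `file` invisibly;
#'   `read_trajectories()`: a data.frame.
#' @export
write_trajectories <- function(x, file) {
  d <- if (inherits(x, "migration")) as.data.frame(x) else x
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(file) {
  read.delim(file, stringsAsFactors = FALSE)
}
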