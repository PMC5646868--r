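test_that("pose perturbation respects ranges and directional persistence", {
  tmpl <- rbind(c(0, 0, 0), c(1, 0, 0))
  p0 <- ligand_pose(tmpl, trans = c(0, 0, 0))

  # zero rotation range leaves the orientation untouched
  set.seed(1)
  out <- perturb_pose(p0, c(0.75, 1.75), c(0, 0))
  expect_equal(out$pose$quat, c(1, 0, 0, 0))

  # magnitudes uniform in [0.75, 1.75]: bounds and mean within 3 SE
  set.seed(2)
  mags <- replicate(1e4, {
    o <- perturb_pose(p0, c(0.75, 1.75), c(0, 0))
    sqrt(sum(o$pose$trans^2))
  })
  expect_true(all(mags >= 0.75 & mags <= 1.75))
  se <- (1 / sqrt(12)) / sqrt(1e4)
  expect_lt(abs(mean(mags) - 1.25), 3 * se)

  # quaternion stays unit norm under composed rotations
  set.seed(3)
  p <- p0
  for (i in 1:50) p <- perturb_pose(p, c(0.1, 0.2), c(0.05, 0.25))$pose
  expect_equal(sqrt(sum(p$quat^2)), 1, tolerance = 1e-9)

  # persistence 3: one translation direction for three steps, then a new one
  set.seed(4)
  pose <- p0; st <- NULL; dirs <- list()
  for (i in 1:4) {
    prev <- pose$trans
    o <- perturb_pose(pose, c(1, 1), c(0, 0), persistence = 3,
                      dir_state = st)
    pose <- o$pose; st <- o$dir_state
    dirs[[i]] <- pose$trans - prev
  }
  expect_equal(dirs[[1]], dirs[[2]])
  expect_equal(dirs[[2]], dirs[[3]])
  expect_gt(max(abs(dirs[[4]] - dirs[[3]])), 1e-6)
})

test_that("Metropolis acceptance reproduces the Boltzmann law", {
  # downhill always accepted
  set.seed(1)
  expect_true(all(replicate(100, metropolis_accept(5, 5 - runif(1)))))
  # non-finite proposals rejected
  expect_false(metropolis_accept(0, Inf))
  expect_false(metropolis_accept(0, NaN))
  # zero-temperature limit rejects uphill moves
  expect_false(metropolis_accept(0, 0.1, temperature = 1e-12))

  # acceptance rate at de/kT = 1 equals exp(-1) within 3 binomial sigma
  set.seed(11)
  n <- 1e5
  acc <- sum(replicate(n, metropolis_accept(0, 1, temperature = 1)))
  p <- exp(-1)
  expect_lt(abs(acc / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("two-state chain occupancy matches the Boltzmann ratio", {
  # states with energies 0 and de; proposal = switch state
  de <- 0.7
  set.seed(21)
  state <- 0L; visits <- c(0L, 0L); n <- 4e4
  for (i in 1:n) {
    e_old <- if (state == 0L) 0 else de
    e_new <- if (state == 0L) de else 0
    if (metropolis_accept(e_old, e_new)) state <- 1L - state
    visits[state + 1L] <- visits[state + 1L] + 1L
  }
  p1 <- exp(-de) / (1 + exp(-de))       # expected occupancy of the high state
  se <- sqrt(p1 * (1 - p1) / n)          # iid bound; chain mixes fast here
  expect_lt(abs(visits[2] / n - p1), 5 * se)
})

test_that("ANM yields six rigid-body modes and orthonormal internal modes", {
  set.seed(5)
  ca <- matrix(rnorm(60, sd = 3), 20)    # dense cloud, connected at 15 A
  m <- anm_modes(ca, cutoff = 15, n_modes = 6)
  expect_equal(m$n_rigid, 6)
  expect_true(all(m$eigenvalues > 1e-8))
  gram <- t(m$modes) %*% m$modes
  expect_lt(max(abs(gram - diag(6))), 1e-8)

  # two far-separated clusters are reported as disconnected
  far <- rbind(ca, ca + 100)
  expect_error(anm_modes(far, cutoff = 15), "2 components")

  expect_error(anm_modes(ca[1:2, ]), "at least 3")
})

test_that("spawning keeps the population within range of the best", {
  expect_equal(spawn_filter(c(10, 6.1))$reset, c(FALSE, FALSE))
  got <- spawn_filter(c(10, 5.9))
  expect_equal(got$best, 1)
  expect_equal(got$reset, c(FALSE, TRUE))
  expect_equal(spawn_filter(c(3, 3, 3))$reset, rep(FALSE, 3))
  # direction "min": smaller is better
  expect_equal(spawn_filter(c(1, 6), direction = "min")$reset,
               c(FALSE, TRUE))
})

test_that("adaptive restarts prioritise sparsely populated clusters", {
  # two poses 0.1 A apart at radius 2 form a single cluster
  pts <- rbind(c(0, 0, 0), c(0.1, 0, 0))
  cl <- leader_cluster(pts, 2)
  expect_equal(length(cl$leaders), 1)

  set.seed(6)
  ep1 <- adaptive_epoch(pts, 2, 10)
  expect_true(all(ep1$starts == 1))

  # populations {10, 1}: inverse weights 1/10 and 1 -> p = {1/11, 10/11}
  pts2 <- rbind(matrix(rnorm(30, sd = 0.1), 10), c(50, 0, 0))
  set.seed(7)
  ep2 <- adaptive_epoch(pts2, 2, 1e4)
  expect_equal(ep2$sizes, c(10, 1))
  expect_equal(ep2$weights, c(1 / 11, 10 / 11))
  frac_small <- mean(ep2$starts == ep2$leaders[2])
  p <- 10 / 11
  expect_lt(abs(frac_small - p), 3 * sqrt(p * (1 - p) / 1e4))
})

test_that("a flat energy landscape accepts every move", {
  toy <- make_toy_receptor(seed = 1)
  flat <- list(total_energy = function(x, r = NULL) 0,
               binding_energy = function(x, r = NULL) 0)
  m <- explore_migration(toy$receptor, rbind(c(0, 0, 0)), flat,
                         migration_config(n_trajectories = 3,
                                          max_steps = 40, seed = 2))
  expect_true(all(m$acceptance[!m$exited] == 1 | m$exited))
  d <- as.data.frame(m)
  expect_true(all(d$accepted))
})

test_that("low temperature concentrates trajectories at a harmonic minimum", {
  toy <- make_toy_receptor(seed = 1)
  mu <- c(0, 0, 7)
  well <- list(total_energy = function(x, r = NULL)
                 2 * sum((colMeans(rbind(x)) - mu)^2),
               binding_energy = function(x, r = NULL) 0)
  cfg <- migration_config(mode = "exit", trans_range = c(0.2, 0.8),
                          rot_range = c(0, 0), temperature = 0.1,
                          n_trajectories = 20, max_steps = 200,
                          spawn_cadence = 1e9, seed = 9)
  # start 5 A away from the minimum; low kT must funnel poses into it
  starts <- lapply(1:20, function(i)
    ligand_pose(rbind(c(0, 0, 0)), trans = mu + c(5, 0, 0)))
  m <- explore_migration(toy$receptor, rbind(c(0, 0, 0)), well, cfg,
                         start_poses = starts)
  finals <- t(vapply(m$trajectories, function(d)
    unlist(d[nrow(d), c("x", "y", "z")]), numeric(3)))
  dist_to_min <- sqrt(rowSums(sweep(finals, 2, mu)^2))
  expect_gte(mean(dist_to_min < 1), 0.95)
})

test_that("identical seed and config give byte-identical trajectory files", {
  toy <- make_toy_receptor(seed = 1)
  lig <- rbind(c(0, 0, 0), c(1.2, 0, 0))
  cfg <- migration_config(n_trajectories = 5, max_steps = 60, seed = 13)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_trajectories(explore_migration(toy$receptor, lig, toy$oracle, cfg),
                     f1)
  write_trajectories(explore_migration(toy$receptor, lig, toy$oracle, cfg),
                     f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # and a different seed explores differently
  cfg2 <- cfg; cfg2$seed <- 14L
  f3 <- withr::local_tempfile()
  write_trajectories(explore_migration(toy$receptor, lig, toy$oracle, cfg2),
                     f3)
  expect_false(unname(tools::md5sum(f1)) == unname(tools::md5sum(f3)))
})

test_that("ANM backbone moves keep the run finite and bounded", {
  toy <- make_toy_receptor(seed = 1)
  cfg <- migration_config(n_trajectories = 2, max_steps = 25,
                          anm = list(enabled = TRUE, step = 0.3), seed = 4)
  m <- explore_migration(toy$receptor, rbind(c(0, 0, 0)), toy$oracle, cfg)
  d <- as.data.frame(m)
  expect_true(all(is.finite(d$e_total)))
})
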