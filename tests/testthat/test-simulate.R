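test_that("native-state energy equals minus epsilon times contact count", {
  topo <- u_chain_topology()
  v <- potential_energy(topo, make_u_chain()$coords)
  expect_lt(abs(v + 2), 1e-3)

  hp <- make_helix_hairpin(30)
  thp <- build_topology(hp)
  expect_lt(abs(potential_energy(thp, hp$coords) + nrow(thp$contacts)), 1e-3)
})

test_that("bonded terms vanish at the native geometry and respond harmonically", {
  topo <- u_chain_topology()
  x <- make_u_chain()$coords
  t0 <- topo
  t0$contacts <- t0$contacts[0, ]
  t0$nonnative <- t0$nonnative[0, ]
  expect_equal(potential_energy(t0, x), 0, tolerance = 1e-12)

  # stretch the last bond by 0.1 A along its own axis: V += K_r * 0.01
  dir <- (x[6, ] - x[5, ]) / sqrt(sum((x[6, ] - x[5, ])^2))
  x2 <- x
  x2[6, ] <- x2[6, ] + 0.1 * dir
  expect_equal(potential_energy(t0, x2), 100 * 0.01, tolerance = 1e-9)
})

test_that("analytic forces agree with finite differences", {
  topo <- u_chain_topology()
  x <- make_u_chain()$coords

  # at the native minimum forces are ~0
  expect_lt(max(abs(forces(topo, x))), 1e-3)

  set.seed(7)
  for (rep in 1:3) {
    xp <- x + matrix(stats::rnorm(18, 0, 0.15), 6, 3)
    f <- forces(topo, xp)
    fd <- fd_forces(topo, xp)
    expect_lt(max(abs(f - fd)) / max(abs(fd)), 1e-5)
    expect_lt(max(abs(colSums(f))), 1e-9)  # translation invariance
  }

  thp <- hairpin30_topology()
  xp <- thp$coords + matrix(stats::rnorm(90, 0, 0.1), 30, 3)
  expect_lt(max(abs(forces(thp, xp) - fd_forces(thp, xp))) /
              max(abs(fd_forces(thp, xp))), 1e-5)
})

test_that("overlapping beads are rejected", {
  topo <- u_chain_topology()
  x <- make_u_chain()$coords
  x[5, ] <- x[1, ]
  expect_error(potential_energy(topo, x), "overlap")
})

test_that("Q follows the gamma threshold rule", {
  topo <- u_chain_topology()
  native <- make_u_chain()$coords
  expect_equal(compute_q(topo, native)$q, 1.0)

  straight <- cbind(3.8 * (0:5), 0, 0)
  res <- compute_q(topo, straight)
  expect_equal(res$q, 0.0)
  expect_equal(res$formed, c(FALSE, FALSE))

  expect_equal(compute_q(topo, straight, gamma = 1e6)$q, 1.0)
  expect_error(compute_q(topo, native, gamma = 0.9), "gamma")

  # monotone in gamma: growing gamma never unforms a contact
  set.seed(3)
  x <- native + matrix(stats::rnorm(18, 0, 0.6), 6, 3)
  gammas <- c(1.05, 1.2, 1.5, 2, 3)
  qs <- vapply(gammas, function(g) compute_q(topo, x, g)$q, numeric(1))
  expect_true(all(diff(qs) >= 0))
})

test_that("trajectories are bit-reproducible for a fixed seed", {
  topo <- hairpin30_topology()
  cfg <- sim_config(0.8, n_steps = 2000, save_every = 100, seed = 42)
  t1 <- run_langevin(topo, cfg)
  t2 <- run_langevin(topo, cfg)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$energies, t2$energies)
  t3 <- run_langevin(topo, sim_config(0.8, n_steps = 2000, save_every = 100,
                                      seed = 43))
  expect_false(identical(t1$energies, t3$energies))
})

test_that("a cold run stays in the folded basin", {
  topo <- hairpin30_topology()
  tr <- cached("hp30_cold",
               run_langevin(topo, sim_config(0.1, n_steps = 1e5,
                                             save_every = 100, seed = 5)))
  expect_gt(mean(tr$q_values), 0.9)
})

test_that("zero-contact topologies report Q = 1 with a warning", {
  st <- calpha_structure(1:8, cbind(3.8 * (0:7), 0, 0))
  topo <- suppressWarnings(build_topology(st))
  expect_warning(res <- compute_q(topo, st$coords), "no native contacts")
  expect_equal(res$q, 1.0)
  expect_warning(
    tr <- run_langevin(topo, sim_config(0.5, n_steps = 500,
                                        save_every = 100, seed = 1)),
    "no native contacts")
  expect_true(all(tr$q_values == 1.0))
})

test_that("microcanonical integration conserves total energy", {
  topo <- u_chain_topology()
  tr <- run_langevin(topo, sim_config(0.2, n_steps = 1e4, timestep = 1e-4,
                                      friction = 0, save_every = 10,
                                      seed = 9))
  etot <- tr$energies + tr$kinetic
  expect_lt(max(etot) - min(etot), 1e-3)
})

test_that("kinetic energy satisfies equipartition at low temperature", {
  topo <- hairpin30_topology()
  tr <- cached("hp30_cold",
               run_langevin(topo, sim_config(0.1, n_steps = 1e5,
                                             save_every = 100, seed = 5)))
  ndof <- 3 * topo$n_residues
  mean_ke_per_dof <- mean(tr$kinetic[-(1:200)]) / ndof
  expect_lt(abs(mean_ke_per_dof - 0.1 / 2) / (0.1 / 2), 0.05)
})

test_that("mean potential energy increases with temperature", {
  topo <- hairpin30_topology()
  temps <- c(0.3, 0.6, 0.9, 1.2)
  means <- vapply(seq_along(temps), function(k) {
    tr <- run_langevin(topo, sim_config(temps[k], n_steps = 1e5,
                                        save_every = 100, seed = 20 + k))
    mean(tr$energies[-(1:300)])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("rmsd handles superposition, translation and symmetric stretch", {
  set.seed(11)
  a <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(rmsd(a, a), 0)
  shifted <- sweep(a, 2, c(5, -3, 2), `+`)
  expect_equal(rmsd(shifted, a, superpose = TRUE), 0, tolerance = 1e-10)
  expect_gt(rmsd(shifted, a, superpose = FALSE), 1)

  # 2-bead pair stretched symmetrically by 2*delta about its center
  delta <- 0.7
  pair <- rbind(c(-1, 0, 0), c(1, 0, 0))
  stretched <- rbind(c(-1 - delta, 0, 0), c(1 + delta, 0, 0))
  expect_equal(rmsd(stretched, pair, superpose = TRUE), delta,
               tolerance = 1e-10)
  expect_error(rmsd(a, a[1:5, ]), "identical dimensions")
})

test_that("rmsd with superposition matches an independent implementation", {
  set.seed(13)
  ref <- matrix(stats::rnorm(45), 15, 3)
  mov <- ref + matrix(stats::rnorm(45, 0, 0.4), 15, 3)
  theta <- 0.8
  rot <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0), c(0, 0, 1))
  mov_rot <- sweep(mov %*% rot, 2, c(3, 1, -2), `+`)
  ours <- rmsd(mov_rot, ref, superpose = TRUE)
  theirs <- bio3d::rmsd(as.numeric(t(ref)), as.numeric(t(mov_rot)),
                        fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("radius of gyration matches the direct formula", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1.0)
  expect_equal(radius_of_gyration(matrix(5, 4, 3)), 0.0)
  x <- make_u_chain()$coords
  centered <- sweep(x, 2, colMeans(x))
  expect_equal(radius_of_gyration(x), sqrt(sum(centered^2) / nrow(x)))
})

test_that("rmsf captures per-residue fluctuation and the discard contract", {
  base <- make_u_chain()$coords
  frames <- array(rep(base, 10), dim = c(6, 3, 10))
  expect_equal(rmsf(frames, discard_first = 0), rep(0, 6))

  # one bead alternating between two positions 2d apart, superposition off
  d <- 0.5
  for (k in seq_len(10))
    frames[3, 1, k] <- base[3, 1] + if (k %% 2 == 0) d else -d
  vals <- rmsf(frames, discard_first = 0, superpose = FALSE)
  expect_equal(vals[3], d)
  expect_equal(vals[-3], rep(0, 5))

  # discard_first = 0.5 on 10 frames keeps the last 5
  frames2 <- frames
  frames2[, , 1:5] <- 99  # garbage that must be ignored
  v2 <- rmsf(frames2, discard_first = 0.5, superpose = FALSE)
  d5 <- mean(c(rep(-d, 2), rep(d, 3)))  # frames 6..10 pattern
  expect_equal(v2[3], sqrt(mean((c(d, -d, d, -d, d) - d5)^2)))
  expect_error(rmsf(frames, discard_first = 0.95), "fewer than 2")
})

test_that("trajectory sidecar round-trips", {
  topo <- u_chain_topology()
  tr <- run_langevin(topo, sim_config(0.3, n_steps = 1000, save_every = 100,
                                      seed = 2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(tr, xyz_file = xyz, tsv_file = tsv)
  side <- read_trajectory_tsv(tsv)
  expect_equal(side$q, tr$q_values, tolerance = 1e-12)
  expect_equal(side$energy, tr$energies, tolerance = 1e-12)
  first <- readLines(xyz, n = 2)
  expect_equal(as.integer(first[1]), 6L)
})
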