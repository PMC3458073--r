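# Short helper trajectory on the u-chain fixture (2 contacts) shared by
# several tests.
u_chain_traj <- function() {
  cached("u_traj",
         run_langevin(u_chain_topology(),
                      sim_config(0.5, n_steps = 2e4, save_every = 100,
                                 seed = 17)))
}

test_that("contact partition splits the fixture as enumerated", {
  topo <- u_chain_topology()
  part <- partition_contacts(topo, 6, 6)
  # region = bead 6 only: contact (2,6) is CTR, (1,5) is core
  expect_equal(nrow(part$ctr_contacts), 1L)
  expect_equal(c(part$ctr_contacts$i, part$ctr_contacts$j), c(2L, 6L))
  expect_equal(c(part$core_contacts$i, part$core_contacts$j), c(1L, 5L))
  # disjoint and exhaustive
  expect_equal(sort(c(part$ctr_idx, part$core_idx)),
               seq_len(nrow(topo$contacts)))

  all_region <- partition_contacts(topo, 1, 6)
  expect_equal(nrow(all_region$core_contacts), 0L)

  expect_warning(no_touch <- partition_contacts(topo, 3, 3), "empty")
  expect_equal(nrow(no_touch$ctr_contacts), 0L)
  expect_error(partition_contacts(topo, 100, 120), "no residues")
})

test_that("Q decomposition satisfies the counting identity on every frame", {
  tr <- u_chain_traj()
  part <- partition_contacts(tr$topology, 6, 6)
  dec <- q_decompose(tr, part)
  n_core <- length(part$core_idx); n_ctr <- length(part$ctr_idx)
  n_tot <- n_core + n_ctr
  expect_equal(n_core * dec$q_core + n_ctr * dec$q_ctr,
               n_tot * dec$q_total, tolerance = 1e-15)
  # decomposition agrees with the trajectory's recorded Q series
  expect_equal(dec$q_total, tr$q_values, tolerance = 1e-12)
})

test_that("decomposition anchors: native frame and core-only frame", {
  topo <- hairpin30_topology()
  tail_first <- 26L
  part <- partition_contacts(topo, tail_first, 30)
  expect_gt(length(part$ctr_idx), 0L)
  expect_gt(length(part$core_idx), 0L)

  native <- topo$coords
  # displace the tail far away: only core contacts stay formed
  broken <- native
  broken[tail_first:30, ] <- broken[tail_first:30, ] +
    matrix(rep(c(0, 0, 50), each = 31L - tail_first), ncol = 3)
  fake <- structure(list(
    frames = array(c(native, broken), dim = c(30, 3, 2)),
    energies = c(0, 0), kinetic = c(0, 0), q_values = c(1, NA),
    steps = 1:2, topology = topo,
    config = sim_config(0.5, n_steps = 2, save_every = 1)),
    class = "go_trajectory")
  dec <- q_decompose(fake, part)
  expect_equal(unlist(dec[1, c("q_core", "q_ctr")]),
               c(q_core = 1, q_ctr = 1))
  expect_equal(dec$q_core[2], 1)
  expect_equal(dec$q_ctr[2], 0)
})

test_that("substate classification follows the declared thresholds", {
  dec <- data.frame(q_core = c(1.0, 0.9, 0.1, 0.5, 0.7),
                    q_ctr = c(1.0, 0.1, 0.9, 0.4, 0.5))
  lab <- classify_substates(dec)
  expect_equal(as.character(lab), c("N1", "N2", "U", "other", "N1"))
  expect_equal(attr(lab, "thresholds")[["core_folded"]], 0.7)
  expect_error(classify_substates(dec, core_folded = 1.2), "0, 1")
  # invariant to frame order
  ord <- c(3, 1, 5, 2, 4)
  expect_equal(as.character(classify_substates(dec[ord, ])),
               as.character(lab)[ord])
})

test_that("joint log-probability maps normalize and marginalize correctly", {
  set.seed(23)
  dec <- data.frame(q_core = stats::runif(4000), q_ctr = stats::runif(4000))
  lp <- joint_logprob_map(dec, bins = 10)
  expect_equal(sum(exp(lp[is.finite(lp)])), 1, tolerance = 1e-12)
  # marginal over Q_ctr equals the directly histogrammed Q_core counts
  marg <- rowSums(exp(lp))
  direct <- tabulate(pmin(floor(dec$q_core * 10) + 1L, 10L), 10L) / 4000
  expect_equal(marg, direct, tolerance = 1e-12)
  # independent uniforms: each bin within 3 binomial standard errors
  p0 <- 1 / 100
  se <- sqrt(p0 * (1 - p0) / 4000)
  expect_true(all(abs(exp(lp) - p0) < 3.5 * se))

  # constant series occupies one bin with log p = 0
  const <- data.frame(q_core = rep(0.62, 200), q_ctr = rep(0.31, 200))
  lpc <- joint_logprob_map(const)
  expect_equal(max(lpc), 0)
  expect_equal(sum(is.finite(lpc)), 1L)
  expect_warning(joint_logprob_map(const[1:10, ]), "fewer than 100")
})

test_that("contact probabilities average formation over selected frames", {
  topo <- u_chain_topology()
  native <- make_u_chain()$coords
  extended <- cbind(3.8 * (0:5), 0, 0)
  fake <- structure(list(
    frames = array(c(native, extended, native, extended),
                   dim = c(6, 3, 4)),
    energies = numeric(4), kinetic = numeric(4),
    q_values = c(1, 0, 1, 0), steps = 1:4, topology = topo,
    config = sim_config(0.5, n_steps = 4, save_every = 1)),
    class = "go_trajectory")
  all_probs <- contact_probability_matrix(fake)
  expect_equal(all_probs$probability, c(0.5, 0.5))
  native_only <- contact_probability_matrix(fake, select = fake$q_values > 0.5)
  expect_equal(native_only$probability, c(1, 1))
  expect_equal(attr(native_only, "n_frames"), 2L)
  expect_error(contact_probability_matrix(fake, select = rep(FALSE, 4)),
               "no frames selected")
})

test_that("native-ensemble contacts are better formed than TSE contacts", {
  tr <- cached("hp30_tm",
               run_langevin(hairpin30_topology(),
                            sim_config(1.05, n_steps = 6e5, save_every = 200,
                                       seed = 71)))
  native_sel <- function(q) q >= 0.8
  if (sum(native_sel(tr$q_values)) > 0 &&
      sum(tse_select()(tr$q_values)) > 0) {
    p_native <- contact_probability_matrix(tr, select = native_sel)
    p_tse <- contact_probability_matrix(tr, select = tse_select())
    expect_gt(mean(p_native$probability), mean(p_tse$probability))
    expect_true(all(p_tse$probability >= 0 & p_tse$probability <= 1))
  } else {
    fail("trajectory did not visit both native and transition regions")
  }
})
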