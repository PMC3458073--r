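test_that("u-chain contact map matches brute-force enumeration", {
  topo <- u_chain_topology()
  bf <- brute_force_contacts(make_u_chain())
  expect_equal(topo$contacts$i, bf$i)
  expect_equal(topo$contacts$j, bf$j)
  expect_equal(topo$contacts$r0, bf$r0)
  # exactly (1,5) and (2,6) at 3.8 * sqrt(2)
  expect_equal(nrow(topo$contacts), 2L)
  expect_equal(unname(as.matrix(topo$contacts[, c("i", "j")])),
               rbind(c(1L, 5L), c(2L, 6L)))
  expect_equal(topo$contacts$r0, rep(3.8 * sqrt(2), 2), tolerance = 1e-12)
  # (1,6) has separation 5 but distance 3.8 < 4.0: excluded
  expect_false(any(topo$contacts$i == 1 & topo$contacts$j == 6))
})

test_that("straight chains have no native contacts", {
  n <- 12
  st <- calpha_structure(1:n, cbind(3.8 * (0:(n - 1)), 0, 0))
  topo <- suppressWarnings(build_topology(st))
  expect_equal(nrow(topo$contacts), 0L)
})

test_that("bonded term counts and default constants follow the model", {
  topo <- hairpin30_topology()
  n <- topo$n_residues
  expect_equal(nrow(topo$bonds), n - 1L)
  expect_equal(nrow(topo$angles), n - 2L)
  expect_equal(nrow(topo$dihedrals), n - 3L)
  expect_equal(topo$K_r, 100)
  expect_equal(topo$K_theta, 20)
  expect_equal(topo$K_phi1, 1)
  expect_equal(topo$K_phi3, 0.5)
  expect_equal(topo$epsilon, 1)
})

test_that("topology construction is deterministic", {
  st <- make_helix_hairpin(24)
  expect_identical(build_topology(st), build_topology(st))
})

test_that("truncation keeps the requested range and preserves numbering", {
  st <- make_helix_hairpin(30)
  full <- truncate_structure(st, 1, 30)
  expect_equal(full$coords, st$coords)
  expect_equal(full$residue_ids, st$residue_ids)

  st6 <- make_u_chain()
  tr <- truncate_structure(st6, 1, 4)
  expect_equal(length(tr$residue_ids), 4L)
  topo <- suppressWarnings(build_topology(tr))
  expect_equal(nrow(topo$contacts), 0L)  # all pairs have j <= i+3

  expect_error(truncate_structure(st6, 1, 99), "not present")
  expect_error(truncate_structure(st6, 5, 2), "keep_first")
})

test_that("a 121-residue construct truncated at the CTR keeps 106 residues", {
  st <- calpha_structure(90:210, cbind(3.8 * (0:120), 0, 0))
  tr <- truncate_structure(st, 90, 195)
  expect_equal(length(tr$residue_ids), 106L)
  expect_equal(range(tr$residue_ids), c(90L, 195L))
})

test_that("truncate-then-build equals build-then-subset for contacts", {
  st <- make_helix_hairpin(34)
  full <- build_topology(st)
  keep_last <- 20L
  sub <- build_topology(truncate_structure(st, 1, keep_last))
  expected <- full$contacts[full$contacts$j <= keep_last, , drop = FALSE]
  rownames(expected) <- NULL
  expect_equal(sub$contacts, expected)
  # bonded reference values agree on the kept range
  expect_equal(sub$bonds$r0, full$bonds$r0[seq_len(keep_last - 1L)])
  expect_equal(sub$angles$theta0, full$angles$theta0[seq_len(keep_last - 2L)])
})

test_that("PDB writer and reader are inverse to coordinate precision", {
  st <- make_u_chain()
  txt <- write_pdb(st)
  back <- read_pdb_calpha(txt)
  expect_equal(back$residue_ids, st$residue_ids)
  expect_equal(back$coords, st$coords, tolerance = 1e-3)

  hp <- make_helix_hairpin(25)
  hp$residue_ids <- hp$residue_ids + 89L  # author numbering offset
  back2 <- read_pdb_calpha(write_pdb(hp))
  expect_equal(back2$residue_ids, 90:114)
  expect_equal(back2$coords, hp$coords, tolerance = 1e-3)
})

test_that("PDB reader filters chains and reports failures clearly", {
  a <- make_u_chain()
  b <- make_helix_hairpin(20)
  b$chain_id <- "B"
  b_lines <- grep("^ATOM", write_pdb(b), value = TRUE)
  b_lines <- vapply(seq_along(b_lines), function(k)  # renumber atom serials
    paste0(substr(b_lines[k], 1, 6), formatC(6 + k, width = 5),
           substr(b_lines[k], 12, nchar(b_lines[k]))), character(1))
  two_chains <- c(grep("^ATOM", write_pdb(a), value = TRUE), b_lines, "END")
  got_b <- read_pdb_calpha(two_chains, chain = "B")
  expect_equal(length(got_b$residue_ids), 20L)
  expect_equal(got_b$chain_id, "B")
  expect_error(read_pdb_calpha(two_chains), "specify 'chain'")
  expect_error(read_pdb_calpha(two_chains, chain = "Z"), "A, B")
  expect_error(read_pdb_calpha("REMARK nothing here\nEND"), "ATOM|CA")
})

test_that("topology survives a text round trip", {
  topo <- hairpin30_topology()
  f <- withr::local_tempfile(fileext = ".top")
  write_topology(topo, f)
  back <- read_topology(f)
  expect_equal(back$contacts, topo$contacts, tolerance = 1e-12)
  expect_equal(back$bonds, topo$bonds, tolerance = 1e-12)
  expect_equal(back$angles, topo$angles, tolerance = 1e-12)
  expect_equal(back$dihedrals$phi0, topo$dihedrals$phi0, tolerance = 1e-12)
  expect_equal(back$K_r, topo$K_r)
})

test_that("native coordinates give Q = 1 whenever contacts exist", {
  for (n in c(20L, 30L, 47L)) {
    st <- make_helix_hairpin(n)
    topo <- build_topology(st)
    expect_gt(nrow(topo$contacts), 0L)
    expect_equal(compute_q(topo, st$coords)$q, 1.0)
  }
})

test_that("structure invariants are enforced", {
  expect_error(calpha_structure(c(1, 1, 2), diag(3)), "strictly increasing")
  expect_error(calpha_structure(1:2, rbind(c(0, 0, 0), c(Inf, 0, 0))),
               "finite")
  expect_error(build_topology(calpha_structure(1:3, cbind(3.8 * (0:2), 0, 0))),
               "at least 4")
  # chain-break gate
  broken <- calpha_structure(1:5, cbind(c(0, 3.8, 7.6, 20, 23.8), 0, 0))
  expect_error(build_topology(broken), "consecutive C-alpha distance")
})
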