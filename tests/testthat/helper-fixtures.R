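# Shared fixtures and independent oracles used across test files.

u_chain_topology <- function(...) {
  suppressWarnings(build_topology(make_u_chain(), ...))
}

# Independent brute-force contact enumeration: scans all residue pairs with
# plain R arithmetic, no use of build_topology internals.
brute_force_contacts <- function(structure, lo = 4.0, hi = 6.0,
                                 min_sep = 4L) {
  x <- structure$coords
  n <- nrow(x)
  out <- list()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (j - i < min_sep) next
    d <- sqrt(sum((x[i, ] - x[j, ])^2))
    if (d >= lo && d <= hi) out[[length(out) + 1L]] <- c(i, j, d)
  }
  if (length(out) == 0L) return(data.frame(i = integer(), j = integer(),
                                           r0 = numeric()))
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1L]), j = as.integer(m[, 2L]), r0 = m[, 3L])
}

# Central finite-difference gradient of the potential.
fd_forces <- function(topology, coords, h = 1e-5) {
  fd <- coords * 0
  for (i in seq_len(nrow(coords))) for (k in 1:3) {
    xp <- coords; xp[i, k] <- xp[i, k] + h
    xm <- coords; xm[i, k] <- xm[i, k] - h
    fd[i, k] <- -(potential_energy(topology, xp) -
                  potential_energy(topology, xm)) / (2 * h)
  }
  fd
}

# Reference parameter sets for the two frataxin constructs (chemical
# denaturation at 20 C, thermal melts).
chem_params_gdmcl_210 <- list(dG0 = 6.7, m = 2.9, S0_N = 304, S0_U = 147)
chem_params_urea_210 <- list(dG0 = 7.1, m = 1.45, S0_N = 693, S0_U = 461)
thermal_params_210 <- list(dH = 92, Tm_C = 70.5, dCp = 1.9,
                           S0_N = -14.3, S0_U = -0.8,
                           l_N = 0.01, l_U = 0.005)
thermal_params_195 <- list(dH = 28, Tm_C = 40.4, dCp = 1.0,
                           S0_N = -14.3, S0_U = -0.8,
                           l_N = 0.01, l_U = 0.005)

# Small trajectory cache so several test files can reuse the same runs.
.test_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

hairpin30_topology <- function() {
  cached("hp30", build_topology(make_helix_hairpin(30)))
}
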