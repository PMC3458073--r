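#' Six-bead U-shaped test chain
#'
#' A planar chain whose native contact map is provable by hand: beads at
#' (0,0,0), (3.8,0,0), (7.6,0,0), (7.6,3.8,0), (3.8,3.8,0), (0,3.8,0)
#' Angstrom. Exactly two pairs satisfy the native-contact rule (sequence
#' separation >= 4, distance 4--6 Angstrom): (1,5) and (2,6), both at
#' 3.8*sqrt(2) ~ 5.374 Angstrom. Pair (1,6) has separation 5 but distance
#' 3.8 Angstrom and is excluded by the lower distance bound.
#'
#' @return A [calpha_structure()] with residues numbered 1--6.
#' @export
make_u_chain <- function() {
  coords <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0),
                  c(7.6, 3.8, 0), c(3.8, 3.8, 0), c(0, 3.8, 0))
  calpha_structure(1:6, coords, label = "u-chain")
}

#' Compact two-strand toy chain with a packing tail
#'
#' Analytic stand-in for a small single-domain fold: two antiparallel
#' strands (3.8 Angstrom spacing along the chain, 5.0 Angstrom between
#' strands) joined by a turn bead, followed by a short tail -- the last
#' `ceiling(0.15 * n)` residues -- that lies along the groove above the
#' two-strand sheet, 3.6 Angstrom over the sheet plane and midway between
#' the strands, so that every packed tail bead contacts *both* strands.
#' The tail mimics a C-terminal region acting as a conformational lock:
#' because its contacts bridge the two strands, they exist only when the
#' core is folded, and deleting the tail genuinely destabilizes the fold.
#' (A tail packed against a single strand fails as a lock: its contacts
#' survive core unfolding, so truncation would remove more unfolded-state
#' chain entropy than folded-state enthalpy and *raise* the melting
#' temperature.) A +/-0.15 Angstrom alternation perpendicular to each
#' strand keeps every dihedral well-defined while leaving all designed
#' contact distances inside the 4--6 Angstrom window. The geometry is
#' closed-form; `seed` is accepted for interface symmetry with the
#' stochastic generators but unused.
#'
#' @param n chain length, 20--60 residues.
#' @param seed ignored (deterministic geometry).
#' @return A [calpha_structure()] with residues numbered 1--n; the tail
#'   region is `attr(x, "tail_first")` to n.
#' @export
make_helix_hairpin <- function(n, seed = NULL) {
  n <- as.integer(n)
  if (n < 20L || n > 60L) stop("'n' must be between 20 and 60")
  n_tail <- ceiling(0.15 * n)
  body <- n - n_tail
  s1 <- ceiling((body - 1L) / 2)
  s2 <- body - 1L - s1
  zig <- function(k) 0.15 * (-1)^k
  p1 <- t(vapply(seq_len(s1), function(k)
    c(3.8 * (k - 1L), 0, zig(k)), numeric(3L)))
  turn <- c(3.8 * (s1 - 1L) + 2.69, 2.5, 0)
  p2 <- t(vapply(seq_len(s2), function(k)
    c(3.8 * (s1 - 1L) - 3.8 * (k - 1L), 5.0, zig(k)), numeric(3L)))
  x_e <- 3.8 * (s1 - s2)
  connector <- c(x_e - 1.0, 3.75, 1.9)
  tail <- t(vapply(seq_len(n_tail - 1L), function(k)
    c(x_e + 3.8 * (k - 1L), 2.5 + zig(k), 3.6), numeric(3L)))
  coords <- rbind(p1, turn, p2, connector, tail)
  st <- calpha_structure(seq_len(n), coords,
                         label = sprintf("helix-hairpin-%d", n))
  attr(st, "tail_first") <- n - n_tail + 1L
  st
}

#' Write a C-alpha structure as PDB text
#'
#' Emits standard ATOM records (atom name CA, occupancy 1.00, element C)
#' parseable by [read_pdb_calpha()]; author residue numbering and the chain
#' id are preserved.
#'
#' @param structure a [calpha_structure()].
#' @param file optional output path; if `NULL` the PDB text is returned as a
#'   character vector of lines.
#' @return `file` (invisibly) or the PDB lines.
#' @export
write_pdb <- function(structure, file = NULL) {
  stopifnot(inherits(structure, "calpha_structure"))
  n <- length(structure$residue_ids)
  if (n > 99999L) stop("more than 99999 atoms cannot be written to PDB")
  path <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(structure$coords)),
                   resno = structure$residue_ids,
                   resid = structure$residue_names,
                   eleno = seq_len(n), elety = rep("CA", n),
                   chain = rep(structure$chain_id, n),
                   o = rep(1, n), b = rep(0, n),
                   elesy = rep("C", n))
  if (is.null(file)) {
    txt <- readLines(path)
    unlink(path)
    return(txt)
  }
  invisible(file)
}

#' Synthetic chemical denaturation curve
#'
#' Evaluates the two-state linear-extrapolation (Santoro-Bolen) signal model
#' on a denaturant grid and optionally adds Gaussian noise; `noise_sd = 0`
#' returns exact model values.
#'
#' @param params named list with `dG0` (kcal/mol), `m` (kcal/mol/M), `S0_N`,
#'   `S0_U` (signal), optional `slope_N`, `slope_U` (signal/M, default 0) and
#'   `temperature_K` (default 293.15).
#' @param x numeric vector of denaturant concentrations (M).
#' @param noise_sd standard deviation of additive Gaussian noise (signal
#'   units).
#' @param seed optional integer seed for the noise.
#' @return `data.frame(x, signal)`.
#' @export
make_chem_curve <- function(params, x, noise_sd = 0, seed = NULL) {
  if (length(x) == 0L) stop("'x' grid is empty")
  s <- chem_signal(x, params)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    s <- s + stats::rnorm(length(s), 0, noise_sd)
  }
  data.frame(x = x, signal = s)
}

#' Synthetic thermal denaturation curve
#'
#' Evaluates the two-state thermal signal model (Gibbs-Helmholtz free energy
#' with linear folded/unfolded baselines) on a temperature grid, optionally
#' with additive Gaussian noise.
#'
#' @param params named list with `dH` (kcal/mol at Tm), `Tm_C` (deg C),
#'   `dCp` (kcal/mol/K), `S0_N`, `S0_U` (signal intercepts), optional `l_N`,
#'   `l_U` (baseline slopes per K, default 0).
#' @param T_C numeric vector of temperatures in deg C.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed optional integer seed.
#' @return `data.frame(T_C, signal)`.
#' @export
make_thermal_curve <- function(params, T_C, noise_sd = 0, seed = NULL) {
  if (length(T_C) == 0L) stop("temperature grid is empty")
  s <- thermal_signal(T_C + 273.15, params)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    s <- s + stats::rnorm(length(s), 0, noise_sd)
  }
  data.frame(T_C = T_C, signal = s)
}

#' Boltzmann samples of an analytic two-level system
#'
#' Draws exact Boltzmann-distributed energies of a system with a ground
#' state of energy 0 and degeneracy 1 and an excited level at `dE` with
#' degeneracy `g`: at temperature T (k_B = 1) the excited-state probability
#' is `p = g exp(-dE/T) / (1 + g exp(-dE/T))`. The closed-form partition
#' function makes this the independent benchmark for the histogram
#' reweighting machinery.
#'
#' @param dE level spacing (reduced energy), > 0.
#' @param g excited-level degeneracy, >= 1.
#' @param temperatures vector of reduced temperatures.
#' @param n_per_T samples per temperature.
#' @param seed integer seed.
#' @return A list with one element per temperature:
#'   `list(temperature, energies)`, directly usable as WHAM runs.
#' @export
make_two_level_samples <- function(dE, g, temperatures, n_per_T,
                                   seed = 1L) {
  if (dE <= 0) stop("'dE' must be positive")
  if (g < 1) stop("'g' must be >= 1")
  set.seed(seed)
  lapply(temperatures, function(tt) {
    p <- g * exp(-dE / tt) / (1 + g * exp(-dE / tt))
    list(temperature = tt,
         energies = dE * stats::rbinom(n_per_T, 1L, p))
  })
}
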