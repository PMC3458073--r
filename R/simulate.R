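#' Simulation configuration
#'
#' Reduced units throughout: temperature in epsilon/k_B, time in the
#' intrinsic unit tau, all bead masses 1. The default timestep (0.0005 tau)
#' is conservative for the stiff harmonic bonds (K_r = 100 epsilon).
#'
#' @param temperature reduced temperature, > 0.
#' @param n_steps number of integration steps.
#' @param timestep integration timestep in tau.
#' @param friction Langevin friction in 1/tau; 0 gives microcanonical
#'   velocity-Verlet dynamics.
#' @param save_every record a frame every this many steps.
#' @param seed integer seed; expanded via `set.seed()` before the run.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(temperature, n_steps, timestep = 5e-4,
                       friction = 1.0, save_every = 100L, seed = 1L) {
  if (temperature <= 0) stop("'temperature' must be > 0")
  if (timestep <= 0) stop("'timestep' must be > 0")
  n_steps <- as.integer(n_steps); save_every <- as.integer(save_every)
  if (save_every < 1L || n_steps < save_every)
    stop("need n_steps >= save_every >= 1")
  if (friction < 0) stop("'friction' must be >= 0")
  structure(list(temperature = temperature, timestep = timestep,
                 friction = friction, n_steps = n_steps,
                 save_every = save_every, seed = as.integer(seed)),
            class = "sim_config")
}

#' Potential energy of a conformation
#'
#' Evaluates the structure-based potential: harmonic bonds and angles,
#' 1- and 3-fold cosine dihedrals about the native reference, a 10--12
#' attractive well of depth epsilon for each native contact, and the
#' smooth truncated repulsive wall for non-native pairs. At the native coordinates
#' the bonded and repulsive terms vanish and each contact contributes
#' exactly -epsilon.
#'
#' @param topology a `go_topology` from [build_topology()].
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @return Potential energy in units of epsilon.
#' @export
potential_energy <- function(topology, coords) {
  coords <- check_coords(topology, coords)
  go_energy_cpp(topology, coords)
}

#' Analytic forces on each bead
#'
#' @inheritParams potential_energy
#' @return n x 3 matrix of forces (epsilon / Angstrom), equal to the
#'   negative analytic gradient of [potential_energy()].
#' @export
forces <- function(topology, coords) {
  coords <- check_coords(topology, coords)
  go_forces_cpp(topology, coords)
}

check_coords <- function(topology, coords) {
  stopifnot(inherits(topology, "go_topology"))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != topology$n_residues || ncol(coords) != 3L)
    stop("'coords' must be ", topology$n_residues, " x 3")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  coords
}

#' Fraction of native contacts Q
#'
#' A native contact is counted as formed when the instantaneous pair
#' distance is below `gamma` times its native distance (default gamma =
#' 1.2). For a topology with an empty contact list Q is defined as 1 with a
#' warning.
#'
#' @inheritParams potential_energy
#' @param gamma formation threshold multiplier, > 1.
#' @return `list(q, formed)` where `formed` is the per-contact logical
#'   vector.
#' @export
compute_q <- function(topology, coords, gamma = 1.2) {
  if (gamma <= 1) stop("'gamma' must be > 1")
  coords <- check_coords(topology, coords)
  if (nrow(topology$contacts) == 0L) {
    warning("topology has no native contacts; Q defined as 1.0")
    return(list(q = 1.0, formed = logical(0L)))
  }
  go_q_cpp(topology, coords, gamma)
}

#' Constant-temperature Langevin run
#'
#' Integrates the structure-based model with the BAOAB Langevin scheme,
#' recording coordinates, potential and kinetic energy and Q every
#' `save_every` steps. Runs are bit-reproducible for a fixed seed.
#'
#' @param topology a `go_topology`.
#' @param config a [sim_config()].
#' @param start starting conformation; defaults to the native coordinates
#'   stored in the topology.
#' @param gamma contact-formation multiplier used for the recorded Q series.
#' @return An object of class `go_trajectory`: list with `frames`
#'   (n x 3 x n_frames array, Angstrom), `energies`, `kinetic`, `q_values`,
#'   `steps`, `config`, `topology`.
#' @export
run_langevin <- function(topology, config, start = topology$coords,
                         gamma = 1.2) {
  stopifnot(inherits(config, "sim_config"))
  start <- check_coords(topology, start)
  if (nrow(topology$contacts) == 0L)
    warning("topology has no native contacts; Q reported as 1.0 throughout")
  set.seed(config$seed)
  res <- go_langevin_cpp(topology, start, config$temperature,
                         config$timestep, config$friction, gamma,
                         config$n_steps, config$save_every)
  structure(list(frames = res$frames, energies = res$energies,
                 kinetic = res$kinetic, q_values = res$q_values,
                 steps = res$steps, final = res$final,
                 config = config, topology = topology, gamma = gamma),
            class = "go_trajectory")
}

#' @export
print.go_trajectory <- function(x, ...) {
  cat(sprintf(paste0("go_trajectory: %d frames of %d beads at T = %.3g ",
                     "(mean Q = %.3f)\n"),
              length(x$energies), x$topology$n_residues,
              x$config$temperature, mean(x$q_values)))
  invisible(x)
}

#' Root-mean-square deviation between two conformations
#'
#' With `superpose = TRUE` (default) an optimal rigid-body least-squares
#' superposition (Kabsch algorithm, uniform weights) is applied before
#' computing the RMSD.
#'
#' @param coords,ref n x 3 coordinate matrices.
#' @param superpose remove the rigid-body difference first?
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coords, ref, superpose = TRUE) {
  coords <- as.matrix(coords); ref <- as.matrix(ref)
  if (!all(dim(coords) == dim(ref)))
    stop("'coords' and 'ref' must have identical dimensions")
  if (superpose) coords <- kabsch_superpose(coords, ref)
  sqrt(mean(rowSums((coords - ref)^2)))
}

kabsch_superpose <- function(coords, ref) {
  cm <- colMeans(coords); rm_ <- colMeans(ref)
  a <- sweep(coords, 2L, cm); b <- sweep(ref, 2L, rm_)
  s <- svd(crossprod(a, b))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(a %*% t(rot), 2L, rm_, `+`)
}

#' Radius of gyration
#'
#' @param coords n x 3 coordinate matrix.
#' @return Mass-uniform radius of gyration about the centroid, Angstrom.
#' @export
radius_of_gyration <- function(coords) {
  coords <- as.matrix(coords)
  sqrt(mean(rowSums(sweep(coords, 2L, colMeans(coords))^2)))
}

#' Per-residue root-mean-square fluctuation
#'
#' Discards the first `discard_first` fraction of frames as equilibration,
#' superposes the remaining frames onto their mean structure (mean updated
#' once after the first superposition pass), and reports each residue's
#' fluctuation about the final mean.
#'
#' @param trajectory a `go_trajectory`, or an n x 3 x F coordinate array.
#' @param discard_first fraction of initial frames to discard, in [0, 1).
#' @param superpose superpose frames onto the mean structure first?
#' @return Numeric vector of per-residue RMSF values, Angstrom.
#' @export
rmsf <- function(trajectory, discard_first = 0.5, superpose = TRUE) {
  frames <- if (inherits(trajectory, "go_trajectory")) trajectory$frames
            else trajectory
  stopifnot(length(dim(frames)) == 3L)
  nf <- dim(frames)[3L]
  keep <- seq.int(floor(discard_first * nf) + 1L, nf)
  if (length(keep) < 2L) stop("fewer than 2 frames retained after discard")
  fr <- lapply(keep, function(k) frames[, , k])
  if (superpose) {
    mean_xyz <- Reduce(`+`, fr) / length(fr)
    fr <- lapply(fr, kabsch_superpose, ref = mean_xyz)
    mean_xyz <- Reduce(`+`, fr) / length(fr)
    fr <- lapply(fr, kabsch_superpose, ref = mean_xyz)
  }
  mean_xyz <- Reduce(`+`, fr) / length(fr)
  dev2 <- Reduce(`+`, lapply(fr, function(m) rowSums((m - mean_xyz)^2)))
  sqrt(dev2 / length(fr))
}

#' Write a trajectory as multi-frame XYZ plus a TSV sidecar
#'
#' The XYZ file uses element field "CA"; the sidecar holds step, potential
#' energy, kinetic energy and Q per frame and is what the WHAM layer
#' consumes.
#'
#' @param trajectory a `go_trajectory`.
#' @param xyz_file,tsv_file output paths; either may be `NULL` to skip.
#' @return Invisibly, a list of the written paths.
#' @export
write_trajectory <- function(trajectory, xyz_file = NULL, tsv_file = NULL) {
  stopifnot(inherits(trajectory, "go_trajectory"))
  if (!is.null(xyz_file)) {
    n <- dim(trajectory$frames)[1L]
    con <- file(xyz_file, "w")
    for (k in seq_along(trajectory$energies)) {
      cat(n, "\nstep ", trajectory$steps[k], "\n", sep = "", file = con)
      xyz <- trajectory$frames[, , k]
      cat(sprintf("CA %.4f %.4f %.4f", xyz[, 1L], xyz[, 2L], xyz[, 3L]),
          sep = "\n", file = con)
    }
    close(con)
  }
  if (!is.null(tsv_file)) {
    utils::write.table(
      data.frame(step = trajectory$steps, energy = trajectory$energies,
                 kinetic = trajectory$kinetic, q = trajectory$q_values),
      tsv_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(xyz = xyz_file, tsv = tsv_file))
}

#' Read a trajectory TSV sidecar
#'
#' @param file path written by [write_trajectory()].
#' @return `data.frame(step, energy, kinetic, q)`.
#' @export
read_trajectory_tsv <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t")
}
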