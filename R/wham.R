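#' Multi-temperature WHAM on (E, Q) histograms
#'
#' Combines constant-temperature runs into a consensus estimate of the
#' density of states over joint (energy, Q) bins by direct iteration of the
#' self-consistent WHAM equations in log space (log-sum-exp stabilized).
#' Each bin's Boltzmann factor uses the sample-mean energy of the bin
#' rather than its geometric center, which removes the leading
#' discretization bias in reweighted moments.
#'
#' @param runs list of runs, each a list with elements `temperature`
#'   (reduced), `energies` (numeric vector) and optionally `q` (numeric
#'   vector in [0, 1], same length). [wham_runs()] builds this from
#'   `go_trajectory` objects.
#' @param n_energy_bins number of energy bins spanning the pooled range.
#' @param n_q_bins number of Q bins over [0, 1]; `NULL` chooses
#'   `min(n_contacts, 50)` when Q is supplied (Q is intrinsically discrete
#'   with spacing 1/n_contacts) and 1 otherwise.
#' @param n_contacts contact count used for the default Q binning.
#' @param tol convergence tolerance: maximum absolute change of the per-run
#'   free-energy shifts between iterations.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   residual history in `attr(condition, "residuals")`.
#' @return An object of class `wham_result`: log density of states
#'   `log_omega` (energy bins x Q bins, -Inf where unsampled), per-bin mean
#'   energy `E_mean` and `E2_mean`, bin edges and centers, per-run shifts
#'   `f`, run temperatures, iteration count and final residual.
#' @export
wham_solve <- function(runs, n_energy_bins = 60L, n_q_bins = NULL,
                       n_contacts = NULL, tol = 1e-7, max_iter = 1e5L) {
  if (length(runs) < 1L) stop("need at least one run")
  temps <- vapply(runs, function(r) as.numeric(r$temperature), numeric(1L))
  if (any(!is.finite(temps)) || any(temps <= 0))
    stop("run temperatures must be positive")
  e_all <- lapply(runs, function(r) as.numeric(r$energies))
  q_all <- lapply(runs, function(r) if (is.null(r$q)) NULL else as.numeric(r$q))
  has_q <- !vapply(q_all, is.null, logical(1L))
  if (any(has_q) && !all(has_q))
    stop("either all runs or no runs must carry a Q series")
  use_q <- all(has_q)

  erange <- range(unlist(e_all))
  if (diff(erange) == 0) erange <- erange + c(-0.5, 0.5)
  e_edges <- seq(erange[1L] - 1e-9 * max(1, abs(erange[1L])),
                 erange[2L] + 1e-9 * max(1, abs(erange[2L])),
                 length.out = n_energy_bins + 1L)
  if (is.null(n_q_bins))
    n_q_bins <- if (use_q) min(max(1L, as.integer(n_contacts %||% 50L)), 50L)
                else 1L
  q_edges <- seq(0, 1 + 1e-9, length.out = n_q_bins + 1L)

  nb_e <- n_energy_bins; nb_q <- n_q_bins
  counts <- matrix(0, nb_e, nb_q)
  e_sum <- matrix(0, nb_e, nb_q)
  e2_sum <- matrix(0, nb_e, nb_q)
  n_k <- integer(length(runs))
  e_hist_k <- matrix(0, length(runs), nb_e)  # per-run energy histogram
  for (k in seq_along(runs)) {
    e <- e_all[[k]]
    be <- pmin(pmax(findInterval(e, e_edges, rightmost.closed = TRUE), 1L),
               nb_e)
    bq <- if (use_q)
      pmin(pmax(findInterval(q_all[[k]], q_edges, rightmost.closed = TRUE),
                1L), nb_q)
    else rep(1L, length(e))
    idx <- cbind(be, bq)
    for (r in seq_along(e)) {
      counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] + 1
      e_sum[idx[r, 1L], idx[r, 2L]] <- e_sum[idx[r, 1L], idx[r, 2L]] + e[r]
      e2_sum[idx[r, 1L], idx[r, 2L]] <- e2_sum[idx[r, 1L], idx[r, 2L]] + e[r]^2
    }
    n_k[k] <- length(e)
    e_hist_k[k, ] <- tabulate(be, nb_e)
  }

  ord <- order(temps)
  if (length(runs) > 1L) {
    for (a in seq_len(length(runs) - 1L)) {
      h1 <- e_hist_k[ord[a], ] / n_k[ord[a]]
      h2 <- e_hist_k[ord[a + 1L], ] / n_k[ord[a + 1L]]
      if (sum(pmin(h1, h2)) < 0.01)
        warning(sprintf(paste0("energy histograms of adjacent temperatures ",
                               "%.4g and %.4g overlap by < 1%%; WHAM bridging",
                               " will be poor"),
                        temps[ord[a]], temps[ord[a + 1L]]))
    }
  }

  occ <- which(counts > 0)
  E_b <- e_sum[occ] / counts[occ]
  log_cnt <- log(counts[occ])
  log_nk <- log(n_k)
  beta_k <- 1 / temps
  f <- rep(0, length(runs))
  residuals <- numeric(0L)
  # log denominator_b = logsumexp_k( log n_k + f_k - beta_k E_b )
  for (it in seq_len(as.integer(max_iter))) {
    a_kb <- outer(log_nk + f, rep(1, length(occ))) -
      outer(beta_k, E_b)                       # K x B
    mx <- apply(a_kb, 2L, max)
    log_den <- mx + log(colSums(exp(sweep(a_kb, 2L, mx))))
    log_omega_occ <- log_cnt - log_den
    b_kb <- sweep(-outer(beta_k, E_b), 2L, log_omega_occ, `+`)  # K x B
    mxk <- apply(b_kb, 1L, max)
    f_new <- -(mxk + log(rowSums(exp(b_kb - mxk))))
    f_new <- f_new - f_new[1L]
    res <- max(abs(f_new - f))
    residuals <- c(residuals, res)
    f <- f_new
    if (res < tol) break
  }
  if (residuals[length(residuals)] >= tol && length(runs) > 1L) {
    cond <- simpleError(sprintf(
      "WHAM did not converge in %d iterations (final residual %.3g)",
      as.integer(max_iter), residuals[length(residuals)]))
    attr(cond, "residuals") <- residuals
    stop(cond)
  }

  # normalize so sum(exp(log_omega)) = 1: removes the arbitrary anchor and
  # makes the result invariant to run order
  mxo <- max(log_omega_occ)
  log_omega_occ <- log_omega_occ -
    (mxo + log(sum(exp(log_omega_occ - mxo))))
  log_omega <- matrix(-Inf, nb_e, nb_q)
  log_omega[occ] <- log_omega_occ
  E_mean <- matrix(NA_real_, nb_e, nb_q); E_mean[occ] <- E_b
  E2_mean <- matrix(NA_real_, nb_e, nb_q)
  E2_mean[occ] <- e2_sum[occ] / counts[occ]

  structure(
    list(log_omega = log_omega, E_mean = E_mean, E2_mean = E2_mean,
         counts = counts, e_edges = e_edges, q_edges = q_edges,
         e_centers = (e_edges[-1L] + e_edges[-length(e_edges)]) / 2,
         q_centers = (q_edges[-1L] + q_edges[-length(q_edges)]) / 2,
         f = f, temperatures = temps, n_iter = length(residuals),
         residual = residuals[length(residuals)],
         residual_history = residuals),
    class = "wham_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wham_result <- function(x, ...) {
  cat(sprintf(paste0("wham_result: %d runs (T in [%.3g, %.3g]), %d x %d ",
                     "(E, Q) bins, %d iterations, residual %.2e\n"),
              length(x$temperatures), min(x$temperatures),
              max(x$temperatures), length(x$e_centers),
              length(x$q_centers), x$n_iter, x$residual))
  invisible(x)
}

#' Build WHAM runs from trajectories
#'
#' Extracts the (energy, Q) series of each trajectory, discarding an
#' initial equilibration fraction.
#'
#' @param trajectories list of `go_trajectory` objects.
#' @param discard_first fraction of initial frames to discard.
#' @return A list of runs for [wham_solve()].
#' @export
wham_runs <- function(trajectories, discard_first = 0.5) {
  lapply(trajectories, function(tr) {
    stopifnot(inherits(tr, "go_trajectory"))
    nf <- length(tr$energies)
    keep <- seq.int(floor(discard_first * nf) + 1L, nf)
    list(temperature = tr$config$temperature,
         energies = tr$energies[keep], q = tr$q_values[keep])
  })
}

reweight_logp <- function(result, temperature) {
  lw <- result$log_omega - result$E_mean / temperature
  lw[!is.finite(lw)] <- -Inf
  mx <- max(lw)
  lw - (mx + log(sum(exp(lw - mx))))
}

#' Heat capacity curve and melting temperature from WHAM weights
#'
#' Reweights the consensus density of states to each grid temperature and
#' computes Cv(T) = (<E^2> - <E>^2) / T^2 per molecule (k_B = 1). The
#' melting temperature is the Cv argmax on the grid, ties broken toward
#' lower T; the argmax search excludes the outermost half-gaps of the
#' simulated temperature ladder, where reweighting rests on a single
#' histogram's tails and Cv estimates spike spuriously.
#'
#' @param result a `wham_result`.
#' @param T_grid temperature grid; defaults to 2001 points spanning the
#'   simulated bracket. Temperatures more than `guard` fractionally outside
#'   the bracket are an error.
#' @param guard allowed fractional extrapolation beyond the simulated
#'   temperature bracket (default 0.2).
#' @return An object of class `thermo_curves`: `data.frame(T, E_mean, Cv)`
#'   plus `Tm`.
#' @export
heat_capacity <- function(result, T_grid = NULL, guard = 0.2) {
  stopifnot(inherits(result, "wham_result"))
  bracket <- range(result$temperatures)
  if (is.null(T_grid))
    T_grid <- seq(bracket[1L], bracket[2L], length.out = 2001L)
  lo <- bracket[1L] * (1 - guard); hi <- bracket[2L] * (1 + guard)
  if (any(T_grid < lo | T_grid > hi))
    stop(sprintf(
      "temperature grid extends beyond the simulated bracket [%.4g, %.4g] by more than %.0f%%",
      bracket[1L], bracket[2L], 100 * guard))
  em <- e2 <- numeric(length(T_grid))
  for (i in seq_along(T_grid)) {
    p <- exp(reweight_logp(result, T_grid[i]))
    em[i] <- sum(p * result$E_mean, na.rm = TRUE)
    e2[i] <- sum(p * result$E2_mean, na.rm = TRUE)
  }
  cv <- pmax((e2 - em^2), 0) / T_grid^2
  # Tm = Cv argmax, searched only where the transition is actually
  # bracketed: reweighting right at the outermost run temperatures
  # amplifies the tails of the single hottest/coldest histogram, so the
  # search window shrinks by half the outermost ladder gaps.
  tsim <- sort(unique(x = c(result$temperatures)))
  if (length(tsim) > 1L) {
    lo <- tsim[1L] + diff(tsim[1:2]) / 2
    hi <- tsim[length(tsim)] - diff(tsim[(length(tsim) - 1L):length(tsim)]) / 2
  } else {
    lo <- -Inf; hi <- Inf
  }
  inside <- which(T_grid >= lo & T_grid <= hi)
  if (length(inside) == 0L) inside <- seq_along(T_grid)
  tm <- T_grid[inside][which.max(cv[inside])]  # first max = lowest-T tie
  structure(list(curve = data.frame(T = T_grid, E_mean = em, Cv = cv),
                 Tm = tm),
            class = "thermo_curves")
}

#' @export
print.thermo_curves <- function(x, ...) {
  cat(sprintf("thermo_curves: Tm = %.4g, peak Cv = %.4g (%d grid points)\n",
              x$Tm, max(x$curve$Cv), nrow(x$curve)))
  invisible(x)
}

#' Free-energy profile along Q at a temperature
#'
#' F(Q) = -T log P(Q | T) from the reweighted joint distribution, with the
#' minimum shifted to zero. Q bins that are empty but lie inside the
#' occupied envelope are reported as NA with a warning.
#'
#' @param result a `wham_result` whose runs carried a Q series.
#' @param temperature reduced temperature at which to evaluate the profile.
#' @return `data.frame(q, F)` at the Q bin centers, with attribute
#'   `temperature`.
#' @export
free_energy_profile <- function(result, temperature) {
  stopifnot(inherits(result, "wham_result"))
  if (length(result$q_centers) < 2L)
    stop("the WHAM result has no Q resolution (runs without a Q series)")
  lp <- reweight_logp(result, temperature)
  mx <- apply(lp, 2L, max)
  pq_log <- ifelse(is.finite(mx),
                   mx + log(colSums(exp(sweep(lp, 2L, mx)), na.rm = TRUE)),
                   -Inf)
  occ <- which(is.finite(pq_log))
  f_q <- rep(NA_real_, length(pq_log))
  f_q[occ] <- -temperature * pq_log[occ]
  if (length(occ) > 0L) {
    inside <- seq.int(min(occ), max(occ))
    holes <- setdiff(inside, occ)
    if (length(holes) > 0L)
      warning(length(holes),
              " empty Q bin(s) inside the occupied envelope masked as NA")
    f_q <- f_q - min(f_q, na.rm = TRUE)
  }
  out <- data.frame(q = result$q_centers, F = f_q)
  attr(out, "temperature") <- temperature
  out
}

#' Barrier height of a two-basin free-energy profile
#'
#' Locates discrete local minima of F(Q); with at least two, the saddle is
#' the maximum of F between the two deepest minima and the barrier is
#' F(saddle) - F(unfolded minimum) (the lower-Q one of the pair), reported
#' in units of k_B T at the profile's temperature. With fewer than two
#' minima the barrier is undefined and `NULL` is returned with a warning.
#'
#' @param profile output of [free_energy_profile()].
#' @return `list(barrier_kt, barrier_eps, q_unfolded, q_folded, q_saddle)`
#'   or `NULL`.
#' @export
barrier_height <- function(profile) {
  temperature <- attr(profile, "temperature")
  ok <- which(!is.na(profile$F))
  q <- profile$q[ok]; f <- profile$F[ok]
  n <- length(f)
  if (n < 3L) {
    warning("profile too short to locate minima; barrier undefined")
    return(NULL)
  }
  is_min <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) f[i] <= f[i - 1L] else f[i] < f[i + 1L]
    right <- if (i < n) f[i] <= f[i + 1L] else f[i] < f[i - 1L]
    left && right
  }, logical(1L))
  # collapse plateaus of equal F to a single representative
  mins <- which(is_min)
  if (length(mins) > 1L)
    mins <- mins[c(TRUE, diff(mins) > 1L | diff(f[mins]) != 0)]
  if (length(mins) < 2L) {
    warning("only one free-energy minimum found; barrier undefined")
    return(NULL)
  }
  two <- mins[order(f[mins])][1:2]
  two <- sort(two)
  between <- seq.int(two[1L], two[2L])
  saddle <- between[which.max(f[between])]
  unfolded <- if (q[two[1L]] < q[two[2L]]) two[1L] else two[2L]
  folded <- setdiff(two, unfolded)
  list(barrier_kt = (f[saddle] - f[unfolded]) / temperature,
       barrier_eps = f[saddle] - f[unfolded],
       q_unfolded = q[unfolded], q_folded = q[folded],
       q_saddle = q[saddle])
}

#' Temperature scan of a topology: simulate, WHAM, thermodynamics
#'
#' Convenience driver used throughout the package: runs seeded Langevin
#' trajectories at each ladder temperature, pools them with [wham_solve()],
#' and extracts the heat-capacity curve, melting temperature and the
#' free-energy profile with its barrier at Tm. The ladder is annealed: the
#' lowest-temperature run starts from the native structure and each
#' subsequent run starts from the final frame of the previous one, so every
#' run begins near its own equilibrium ensemble. Per-run seeds are derived
#' from `seed` as `seed + run index`.
#'
#' @param topology a `go_topology`.
#' @param temperatures ladder of reduced temperatures bracketing the
#'   expected transition.
#' @param n_steps,save_every,timestep,friction per-run integration settings
#'   (see [sim_config()]).
#' @param seed base integer seed.
#' @param discard_first equilibration fraction discarded per run.
#' @param gamma contact-formation multiplier for Q.
#' @return list with `trajectories`, `wham`, `thermo` (a `thermo_curves`),
#'   `Tm`, `profile_at_tm` and `barrier` (possibly `NULL`).
#' @export
thermo_scan <- function(topology, temperatures, n_steps = 1e6,
                        save_every = 250L, timestep = 2e-3, friction = 1.0,
                        seed = 1L, discard_first = 0.25, gamma = 1.2) {
  ord <- order(temperatures)
  trajs <- vector("list", length(temperatures))
  start <- topology$coords
  for (k in ord) {
    trajs[[k]] <- run_langevin(
      topology,
      sim_config(temperature = temperatures[k], n_steps = n_steps,
                 timestep = timestep, friction = friction,
                 save_every = save_every, seed = seed + k),
      start = start, gamma = gamma)
    start <- trajs[[k]]$final
  }
  wh <- wham_solve(wham_runs(trajs, discard_first),
                   n_contacts = nrow(topology$contacts))
  th <- heat_capacity(wh)
  prof <- free_energy_profile(wh, th$Tm)
  bar <- withCallingHandlers(barrier_height(prof),
                             warning = function(w) invokeRestart("muffleWarning"))
  list(trajectories = trajs, wham = wh, thermo = th, Tm = th$Tm,
       profile_at_tm = prof, barrier = bar)
}
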