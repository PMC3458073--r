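#' Gas constant in kcal mol-1 K-1
#' @keywords internal
R_KCAL <- 1.9872e-3

#' Two-state chemical-denaturation signal (Santoro-Bolen model)
#'
#' Linear-extrapolation model for an equilibrium unfolding transition
#' followed by a spectroscopic probe: the free energy of unfolding is
#' `dG(x) = dG0 - m * x`, native and unfolded baselines are linear in
#' denaturant, and the observed signal is their population-weighted
#' average,
#' `S(x) = [(S0_N + slope_N x) + (S0_U + slope_U x) K] / (1 + K)` with
#' `K = exp(-dG(x) / (R T))`.
#'
#' @param x denaturant concentration(s), M.
#' @param params named list (or `chemical_fit`): `dG0` (kcal/mol), `m`
#'   (kcal/mol/M), `S0_N`, `S0_U`, optional `slope_N`, `slope_U` (default
#'   0) and `temperature_K` (default 293.15, i.e. 20 deg C).
#' @return Signal value(s).
#' @export
chem_signal <- function(x, params) {
  p <- as.list(params)
  slope_N <- p$slope_N %||% 0; slope_U <- p$slope_U %||% 0
  tK <- p$temperature_K %||% 293.15
  K <- exp(-(p$dG0 - p$m * x) / (R_KCAL * tK))
  ((p$S0_N + slope_N * x) + (p$S0_U + slope_U * x) * K) / (1 + K)
}

#' Fit a two-state chemical denaturation curve
#'
#' Nonlinear least squares on the Santoro-Bolen signal model. The m-value
#' may be fixed (the usual practice when using a predicted m for a protein
#' of the given size) or fitted. Initialization is deterministic: baseline
#' intercepts from the curve ends, baseline slopes 0, the midpoint Cm from
#' the mid-signal crossing, and `dG0 = m * Cm`.
#'
#' @param data data frame whose first two columns are denaturant
#'   concentration (M) and signal, e.g. from [read_unfolding_table()].
#' @param m fixed m-value (kcal/mol/M) or `NULL` to fit it.
#' @param temperature_K isothermal temperature, K (default 293.15).
#' @param fit_baseline_slopes fit linear baseline slopes (default TRUE;
#'   they are initialized at 0 either way).
#' @return An object of class `chemical_fit` with elements `dG0`, `m`,
#'   `Cm` (= dG0/m exactly), `S0_N`, `S0_U`, `slope_N`, `slope_U`,
#'   `temperature_K`, `fixed` (named logicals), `sigma` (residual standard
#'   deviation), `residuals`, `vcov` (free parameters) and `fit` (the
#'   underlying nls object).
#' @export
fit_chemical <- function(data, m = NULL, temperature_K = 293.15,
                         fit_baseline_slopes = TRUE) {
  d <- data.frame(x = data[[1L]], s = data[[2L]])
  d <- d[order(d$x), ]
  if (nrow(d) < 6L) stop("need at least 6 points spanning the transition")
  init <- transition_init(d$x, d$s)
  if (is.null(init))
    stop("no transition detectable: the signal has no interior mid-crossing")
  m_fixed <- !is.null(m)
  m0 <- if (m_fixed) m else 2
  start <- list(dG0 = max(m0 * init$mid, 0.5), S0_N = init$s_lo,
                S0_U = init$s_hi)
  fixed <- list(temperature_K = temperature_K)
  if (m_fixed) fixed$m <- m else start$m <- m0
  if (fit_baseline_slopes) {
    start$slope_N <- 0; start$slope_U <- 0
  } else {
    fixed$slope_N <- 0; fixed$slope_U <- 0
  }
  model <- function(x, dG0, m, S0_N, S0_U, slope_N, slope_U)
    chem_signal(x, list(dG0 = dG0, m = m, S0_N = S0_N, S0_U = S0_U,
                        slope_N = slope_N, slope_U = slope_U,
                        temperature_K = temperature_K))
  form <- s ~ model(x, dG0, m, S0_N, S0_U, slope_N, slope_U)
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM,
            list(form, data = cbind(d, fixed), start = start,
                 control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e)
      stop("chemical fit failed (", conditionMessage(e),
           "); check that the data span the transition", call. = FALSE))
  cf <- as.list(stats::coef(fit))
  for (nm in names(fixed)) cf[[nm]] <- fixed[[nm]]
  res <- stats::residuals(fit)
  amp <- abs(cf$S0_U + cf$slope_U * cf$dG0 / cf$m -
             (cf$S0_N + cf$slope_N * cf$dG0 / cf$m))
  if (stats::sd(res) > 0 && amp < 3 * stats::sd(res))
    stop("no transition detectable: fitted amplitude below the noise level")
  structure(
    list(dG0 = cf$dG0, m = cf$m, Cm = cf$dG0 / cf$m, S0_N = cf$S0_N,
         S0_U = cf$S0_U, slope_N = cf$slope_N %||% 0,
         slope_U = cf$slope_U %||% 0, temperature_K = temperature_K,
         fixed = c(m = m_fixed, baselines = !fit_baseline_slopes),
         sigma = stats::sigma(fit), residuals = res,
         vcov = stats::vcov(fit), fit = fit, data = d),
    class = "chemical_fit")
}

#' @export
print.chemical_fit <- function(x, ...) {
  cat(sprintf(paste0("chemical_fit: dG0 = %.3f kcal/mol, m = %.3f%s ",
                     "kcal/mol/M, Cm = %.3f M (sigma = %.3g)\n"),
              x$dG0, x$m, if (x$fixed[["m"]]) " (fixed)" else "", x$Cm,
              x$sigma))
  invisible(x)
}

# Deterministic two-state initialization: end-point baselines and the
# mid-signal crossing. Returns NULL when no interior crossing exists.
transition_init <- function(x, s) {
  k <- max(2L, round(length(x) * 0.15))
  s_lo <- mean(s[seq_len(k)])
  s_hi <- mean(s[seq.int(length(s) - k + 1L, length(s))])
  if (abs(s_hi - s_lo) < 1e-12 * (abs(s_lo) + 1)) return(NULL)
  fmid <- (s - s_lo) / (s_hi - s_lo)
  cross <- which(diff(sign(fmid - 0.5)) != 0)
  if (length(cross) == 0L) return(NULL)
  i <- cross[1L]
  w <- (0.5 - fmid[i]) / (fmid[i + 1L] - fmid[i])
  list(mid = x[i] + w * (x[i + 1L] - x[i]), s_lo = s_lo, s_hi = s_hi)
}

#' Gibbs-Helmholtz free energy of unfolding
#'
#' `dG(T) = dH (1 - T/Tm) - dCp [(Tm - T) + T log(T/Tm)]` with `dH` the
#' unfolding enthalpy at Tm and `dCp` the unfolding heat-capacity change;
#' `dG(Tm) = 0` by construction.
#'
#' @param dH unfolding enthalpy at Tm, kcal/mol.
#' @param Tm melting temperature, K.
#' @param dCp heat-capacity change of unfolding, kcal/mol/K.
#' @param T temperature(s), K.
#' @return Free energy of unfolding in kcal/mol.
#' @export
gibbs_helmholtz <- function(dH, Tm, dCp, T) {
  if (any(T <= 0) || Tm <= 0) stop("temperatures must be positive (K)")
  dH * (1 - T / Tm) - dCp * ((Tm - T) + T * log(T / Tm))
}

#' Two-state thermal-denaturation signal
#'
#' Observed signal as the population-weighted average of linear native and
#' unfolded baselines, with the unfolded fraction
#' `f_U = K / (1 + K)`, `K = exp(-dG(T) / (R T))` and dG from
#' [gibbs_helmholtz()]. At Tm the two states are equally populated.
#'
#' @param T_K temperature(s), K.
#' @param params named list (or `thermal_fit`): `dH` (kcal/mol), `Tm_C`
#'   (deg C) or `Tm_K` (K), `dCp` (kcal/mol/K), `S0_N`, `S0_U` (baseline
#'   intercepts at 0 K), optional `l_N`, `l_U` (slopes per K, default 0).
#' @return Signal value(s).
#' @export
thermal_signal <- function(T_K, params) {
  p <- as.list(params)
  tm <- p$Tm_K %||% (p$Tm_C + 273.15)
  l_N <- p$l_N %||% 0; l_U <- p$l_U %||% 0
  dg <- gibbs_helmholtz(p$dH, tm, p$dCp, T_K)
  K <- exp(-dg / (R_KCAL * T_K))
  fU <- K / (1 + K)
  (p$S0_N + l_N * T_K) * (1 - fU) + (p$S0_U + l_U * T_K) * fU
}

#' Fit a two-state thermal denaturation curve
#'
#' Nonlinear least squares on the thermal two-state model with linear
#' baselines. dCp may be fixed (as done for well-characterized proteins
#' from predicted values) or fitted. Initialization is deterministic:
#' baselines from linear fits to the first and last quarter of the data,
#' Tm from the mid-crossing of the baseline-normalized unfolded fraction,
#' and dH from the van 't Hoff slope at that crossing.
#'
#' @param data data frame whose first two columns are temperature and
#'   signal.
#' @param dCp fixed heat-capacity change (kcal/mol/K) or `NULL` to fit it.
#' @param unit `"C"` (default) if the temperature column is in deg C,
#'   `"K"` for Kelvin.
#' @return An object of class `thermal_fit` with `dH`, `Tm_K`, `Tm_C`,
#'   `dCp`, baselines `S0_N`, `l_N`, `S0_U`, `l_U`, `fixed`, `sigma`,
#'   `residuals`, `vcov` and `fit`.
#' @export
fit_thermal <- function(data, dCp = NULL, unit = c("C", "K")) {
  unit <- match.arg(unit)
  tK <- if (unit == "C") data[[1L]] + 273.15 else data[[1L]]
  d <- data.frame(tK = tK, s = data[[2L]])
  d <- d[order(d$tK), ]
  if (nrow(d) < 8L)
    stop("need at least 8 points with pre- and post-transition coverage")
  n <- nrow(d)
  q <- max(3L, floor(n / 4))
  pre <- stats::lm(s ~ tK, d[seq_len(q), ])
  post <- stats::lm(s ~ tK, d[seq.int(n - q + 1L, n), ])
  sN <- stats::predict(pre, d); sU <- stats::predict(post, d)
  fu <- (d$s - sN) / (sU - sN)
  cross <- which(diff(sign(fu - 0.5)) != 0)
  if (length(cross) == 0L)
    stop("no transition detectable: unfolded fraction never crosses 0.5")
  i <- cross[1L]
  w <- (0.5 - fu[i]) / (fu[i + 1L] - fu[i])
  tm0 <- d$tK[i] + w * (d$tK[i + 1L] - d$tK[i])
  # van 't Hoff: dfU/dT at Tm = dH / (4 R Tm^2)
  slope <- (fu[i + 1L] - fu[i]) / (d$tK[i + 1L] - d$tK[i])
  dh0 <- min(max(4 * R_KCAL * tm0^2 * slope, 10), 300)
  dcp_fixed <- !is.null(dCp)
  start <- list(dH = dh0, Tm_K = tm0,
                S0_N = stats::coef(pre)[[1L]], l_N = stats::coef(pre)[[2L]],
                S0_U = stats::coef(post)[[1L]], l_U = stats::coef(post)[[2L]])
  fixed <- list()
  if (dcp_fixed) fixed$dCp <- dCp else start$dCp <- 1
  model <- function(tK, dH, Tm_K, dCp, S0_N, l_N, S0_U, l_U)
    thermal_signal(tK, list(dH = dH, Tm_K = Tm_K, dCp = dCp, S0_N = S0_N,
                            l_N = l_N, S0_U = S0_U, l_U = l_U))
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM,
            list(s ~ model(tK, dH, Tm_K, dCp, S0_N, l_N, S0_U, l_U),
                 data = if (length(fixed)) cbind(d, fixed) else d,
                 start = start,
                 control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e)
      stop("thermal fit failed (", conditionMessage(e),
           "); check pre-/post-transition coverage", call. = FALSE))
  cf <- as.list(stats::coef(fit))
  for (nm in names(fixed)) cf[[nm]] <- fixed[[nm]]
  structure(
    list(dH = cf$dH, Tm_K = cf$Tm_K, Tm_C = cf$Tm_K - 273.15,
         dCp = cf$dCp, S0_N = cf$S0_N, l_N = cf$l_N, S0_U = cf$S0_U,
         l_U = cf$l_U, fixed = c(dCp = dcp_fixed),
         sigma = stats::sigma(fit), residuals = stats::residuals(fit),
         vcov = stats::vcov(fit), fit = fit, data = d),
    class = "thermal_fit")
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat(sprintf(paste0("thermal_fit: dH = %.1f kcal/mol, Tm = %.2f C, ",
                     "dCp = %.2f%s kcal/mol/K (sigma = %.3g)\n"),
              x$dH, x$Tm_C, x$dCp,
              if (x$fixed[["dCp"]]) " (fixed)" else "", x$sigma))
  invisible(x)
}

#' Protein stability curve dG(T)
#'
#' Evaluates the Gibbs-Helmholtz free energy on a dense temperature grid
#' (0.1 K spacing) and reports the maximum and its position. With dCp > 0
#' the curve has a unique interior maximum at the temperature satisfying
#' `log(Tm / T*) = dH / (Tm dCp)`; with dCp <= 0 no interior maximum
#' exists and the maximum fields are `NA` with a warning.
#'
#' @param params a `thermal_fit` or a named list with `dH`, `dCp` and
#'   `Tm_K` or `Tm_C`.
#' @param T_range_C length-2 temperature range in deg C (default -20 to
#'   Tm + 10).
#' @return An object of class `stability_curve`: `data.frame(T_C, dG)`
#'   plus `dG_max`, `T_at_max_C` (grid resolution 0.1 K).
#' @export
stability_curve <- function(params, T_range_C = NULL) {
  p <- as.list(params)
  tm <- p$Tm_K %||% (p$Tm_C + 273.15)
  if (is.null(T_range_C)) T_range_C <- c(-20, tm - 273.15 + 10)
  tC <- seq(T_range_C[1L], T_range_C[2L], by = 0.1)
  dg <- gibbs_helmholtz(p$dH, tm, p$dCp, tC + 273.15)
  if (p$dCp <= 0) {
    warning("dCp <= 0: the stability curve has no interior maximum")
    dg_max <- NA_real_; t_max <- NA_real_
  } else {
    k <- which.max(dg)
    dg_max <- dg[k]; t_max <- tC[k]
  }
  structure(list(curve = data.frame(T_C = tC, dG = dg),
                 dG_max = dg_max, T_at_max_C = t_max,
                 dH = p$dH, Tm_K = tm, dCp = p$dCp),
            class = "stability_curve")
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("stability_curve: dG_max = %.2f kcal/mol at %.1f C (Tm = %.2f C)\n",
              x$dG_max, x$T_at_max_C, x$Tm_K - 273.15))
  invisible(x)
}

#' Read a two-column unfolding data table
#'
#' Delimited text with denaturant concentration (or temperature) in the
#' first column and signal in the second; lines starting with `#` are
#' comments.
#'
#' @param file path.
#' @param sep field separator (default whitespace).
#' @return A two-column data frame.
#' @export
read_unfolding_table <- function(file, sep = "") {
  utils::read.table(file, header = FALSE, sep = sep, comment.char = "#",
                    col.names = c("x", "signal"))
}
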