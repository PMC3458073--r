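#' Partition native contacts into region and core classes
#'
#' Splits a topology's native contacts into those touching a residue-id
#' region (e.g. the frataxin C-terminal region, residues 196--210) and the
#' remainder. A contact belongs to the region class when at least one
#' partner's author residue id lies in `[region_first, region_last]`; the
#' two classes are disjoint and exhaustive.
#'
#' @param topology a `go_topology`.
#' @param region_first,region_last author residue ids bounding the region
#'   (inclusive); at least one topology residue must fall inside.
#' @return An object of class `contact_partition` with `ctr_idx` /
#'   `core_idx` (row indices into `topology$contacts`), the contact tables
#'   themselves and the region definition.
#' @export
partition_contacts <- function(topology, region_first, region_last) {
  stopifnot(inherits(topology, "go_topology"))
  ids <- topology$residue_ids
  in_region <- ids >= region_first & ids <= region_last
  if (!any(in_region))
    stop("no residues in region [", region_first, ", ", region_last, "]")
  con <- topology$contacts
  touches <- in_region[con$i] | in_region[con$j]
  if (!any(touches))
    warning("no native contacts touch the region; CTR class is empty")
  structure(list(region = c(region_first, region_last),
                 ctr_idx = which(touches), core_idx = which(!touches),
                 ctr_contacts = con[touches, , drop = FALSE],
                 core_contacts = con[!touches, , drop = FALSE],
                 n_total = nrow(con)),
            class = "contact_partition")
}

#' @export
print.contact_partition <- function(x, ...) {
  cat(sprintf("contact_partition: region %d-%d, %d CTR / %d core contacts\n",
              x$region[1L], x$region[2L], length(x$ctr_idx),
              length(x$core_idx)))
  invisible(x)
}

#' Decompose the Q series of a trajectory into core and region components
#'
#' For every frame, each component is the fraction of its own contact class
#' formed (distance below gamma times native). The counting identity
#' `n_core * Q_core + n_ctr * Q_CTR = n_total * Q_total` holds exactly for
#' every frame. An empty region class yields Q_CTR = 1 with a warning (same
#' empty-set convention as [compute_q()]).
#'
#' @param trajectory a `go_trajectory`.
#' @param partition a [partition_contacts()] result built from the same
#'   topology.
#' @param gamma contact-formation multiplier.
#' @return `data.frame(frame, q_core, q_ctr, q_total)`.
#' @export
q_decompose <- function(trajectory, partition, gamma = 1.2) {
  stopifnot(inherits(trajectory, "go_trajectory"),
            inherits(partition, "contact_partition"))
  topo <- trajectory$topology
  if (nrow(topo$contacts) != partition$n_total)
    stop("partition does not match the trajectory's topology")
  if (length(partition$ctr_idx) == 0L)
    warning("empty CTR contact class; Q_CTR reported as 1.0")
  nf <- length(trajectory$energies)
  out <- matrix(0, nf, 3L)
  for (k in seq_len(nf)) {
    formed <- go_q_cpp(topo, trajectory$frames[, , k], gamma)$formed
    out[k, 1L] <- if (length(partition$core_idx))
      mean(formed[partition$core_idx]) else 1.0
    out[k, 2L] <- if (length(partition$ctr_idx))
      mean(formed[partition$ctr_idx]) else 1.0
    out[k, 3L] <- mean(formed)
  }
  data.frame(frame = seq_len(nf), q_core = out[, 1L], q_ctr = out[, 2L],
             q_total = out[, 3L])
}

#' Joint log-probability map over (Q_core, Q_CTR)
#'
#' Bins the decomposed series on a regular grid over [0, 1]^2 and returns
#' the log of the joint relative frequency (so `sum(exp(map))` over
#' occupied bins is 1). Empty bins carry `-Inf`.
#'
#' @param decomposed output of [q_decompose()].
#' @param bins number of bins per axis (default 25).
#' @return Matrix (Q_core bins x Q_CTR bins) of log probabilities with bin
#'   edge attributes `core_edges`, `ctr_edges` and center attributes.
#' @export
joint_logprob_map <- function(decomposed, bins = 25L) {
  if (nrow(decomposed) < 100L)
    warning("fewer than 100 frames; the joint map will be noisy")
  edges <- seq(0, 1 + 1e-9, length.out = bins + 1L)
  bi <- pmin(pmax(findInterval(decomposed$q_core, edges,
                               rightmost.closed = TRUE), 1L), bins)
  bj <- pmin(pmax(findInterval(decomposed$q_ctr, edges,
                               rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0, bins, bins)
  for (r in seq_along(bi))
    counts[bi[r], bj[r]] <- counts[bi[r], bj[r]] + 1
  lp <- log(counts) - log(nrow(decomposed))
  attr(lp, "core_edges") <- edges
  attr(lp, "ctr_edges") <- edges
  attr(lp, "centers") <- (edges[-1L] + edges[-length(edges)]) / 2
  lp
}

#' Classify frames into native substates
#'
#' Operational substate definitions on the (Q_core, Q_CTR) plane: `N1` has
#' the core folded and the region consolidated (`q_core >= core_folded` and
#' `q_ctr >= ctr_bound`), `N2` has the core folded but the region unbound,
#' `U` has the core unfolded (`q_core <= core_unfolded`), everything else
#' is `other`. The thresholds used are recorded as an attribute.
#'
#' @param decomposed output of [q_decompose()].
#' @param core_folded,ctr_bound,core_unfolded thresholds in [0, 1].
#' @return Factor of labels (levels N1, N2, U, other), one per frame, with
#'   attribute `thresholds`.
#' @export
classify_substates <- function(decomposed, core_folded = 0.7,
                               ctr_bound = 0.5, core_unfolded = 0.3) {
  th <- c(core_folded = core_folded, ctr_bound = ctr_bound,
          core_unfolded = core_unfolded)
  if (any(th < 0 | th > 1)) stop("thresholds must lie in [0, 1]")
  lab <- ifelse(decomposed$q_core >= core_folded,
                ifelse(decomposed$q_ctr >= ctr_bound, "N1", "N2"),
                ifelse(decomposed$q_core <= core_unfolded, "U", "other"))
  lab <- factor(lab, levels = c("N1", "N2", "U", "other"))
  attr(lab, "thresholds") <- th
  lab
}

#' Per-contact formation probability over selected frames
#'
#' Computes, for each native contact, the fraction of selected frames in
#' which it is formed. The default selector takes every frame; pass a
#' logical vector or a predicate on the frame Q values to restrict e.g. to
#' a transition-state ensemble ([tse_select()]).
#'
#' @param trajectory a `go_trajectory`.
#' @param select `NULL` (all frames), a logical vector over frames, or a
#'   function mapping the frame Q vector to such a logical vector.
#' @param gamma contact-formation multiplier.
#' @return `data.frame(i, j, resid_i, resid_j, probability)` with attribute
#'   `n_frames` (number of contributing frames).
#' @export
contact_probability_matrix <- function(trajectory, select = NULL,
                                       gamma = 1.2) {
  stopifnot(inherits(trajectory, "go_trajectory"))
  topo <- trajectory$topology
  nf <- length(trajectory$energies)
  keep <- if (is.null(select)) rep(TRUE, nf)
          else if (is.function(select)) select(trajectory$q_values)
          else as.logical(select)
  if (length(keep) != nf) stop("'select' must produce one flag per frame")
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("no frames selected; widen the Q window or the selection predicate")
  acc <- numeric(nrow(topo$contacts))
  for (k in idx)
    acc <- acc + go_q_cpp(topo, trajectory$frames[, , k], gamma)$formed
  out <- data.frame(i = topo$contacts$i, j = topo$contacts$j,
                    resid_i = topo$residue_ids[topo$contacts$i],
                    resid_j = topo$residue_ids[topo$contacts$j],
                    probability = acc / length(idx))
  attr(out, "n_frames") <- length(idx)
  out
}

#' Transition-state ensemble frame selector
#'
#' Frames whose Q lies within `window` of the barrier-top value 0.5,
#' intended for trajectories run at the melting temperature.
#'
#' @param q_center center of the window (default 0.5).
#' @param window half-width in Q (default 0.05).
#' @return A predicate suitable for [contact_probability_matrix()].
#' @export
tse_select <- function(q_center = 0.5, window = 0.05) {
  function(q) abs(q - q_center) <= window
}
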