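# Linearization: per-trial, per-position-bin spike counts, occupancy and
# speed — the substrate of all spatial statistics.
#
# The analysis span of a trial runs from its start to the first lick at the
# waterspout; the return run to the start box is excluded.  The track is
# divided into n_bins equal bins; bin x covers ((x-1)/n, x/n] of the track
# (half-open, upper-inclusive; bin 1 closed at 0).  Each inter-sample
# interval's duration is split across the bins its position range covers,
# proportionally to the path length in each bin (position is linear within
# an interval) — the same piecewise-linear model used to place spikes, so
# numerator and denominator of the rate estimator stay consistent.  Each
# spike goes to the bin of its linearly interpolated position at spike
# time.  Speed per bin is bin width / occupancy.

pos_to_bin <- function(pos, track_length, n_bins) {
  b <- ceiling(pos / track_length * n_bins)
  pmin(pmax(b, 1L), n_bins)
}

#' Linearize a single trial
#'
#' @param tracking Tracking rows of one trial (`time_s`, `pos_cm`), times
#'   strictly increasing.
#' @param spike_times Spike times (s) of one unit, sorted.
#' @param start_s,lick_s Trial start and first-lick times bounding the
#'   analysis span.
#' @param track_length Track length (cm).
#' @param n_bins Number of position bins.
#' @param backward_tol Tolerance (cm) for backward position jumps before a
#'   validation error is raised; occupancy of a backward segment is split
#'   over its position range like any other.
#' @return A tibble with one row per bin: `bin`, `n_spikes`, `occupancy_s`,
#'   `speed_cms` (NA where the bin was never occupied).
#' @export
linearize_trial <- function(tracking, spike_times, start_s, lick_s,
                            track_length = 150, n_bins = 100,
                            backward_tol = 1) {
  tt <- tracking$time_s
  pp <- tracking$pos_cm
  if (any(diff(tt) <= 0)) {
    abort("tracking times must be strictly increasing within a trial")
  }
  if (any(diff(pp) < -backward_tol)) {
    abort("backward position jump beyond tolerance in tracking trace")
  }
  # clip inter-sample intervals to [start, lick), interpolating the
  # clipped endpoint positions on the interval's linear segment
  ta <- tt[-length(tt)]
  tb <- tt[-1]
  pa <- pp[-length(pp)]
  pb <- pp[-1]
  t0 <- pmax(ta, start_s)
  t1 <- pmin(tb, lick_s)
  keep <- t1 > t0
  occ <- rep(0, n_bins)
  if (any(keep)) {
    frac0 <- (t0[keep] - ta[keep]) / (tb[keep] - ta[keep])
    frac1 <- (t1[keep] - ta[keep]) / (tb[keep] - ta[keep])
    p0 <- pa[keep] + frac0 * (pb[keep] - pa[keep])
    p1 <- pa[keep] + frac1 * (pb[keep] - pa[keep])
    dt <- (t1 - t0)[keep]
    lo <- pmin(p0, p1)
    hi <- pmax(p0, p1)
    b_lo <- pos_to_bin(lo, track_length, n_bins)
    b_hi <- pos_to_bin(hi, track_length, n_bins)
    width <- track_length / n_bins
    same <- b_hi == b_lo
    if (any(same)) {
      acc <- rowsum(dt[same], b_lo[same])
      occ[as.integer(rownames(acc))] <- acc[, 1]
    }
    if (any(!same)) {
      # distribute dt over the covered bins by path-length overlap
      nbins_per <- (b_hi - b_lo + 1L)[!same]
      ival <- rep(which(!same), times = nbins_per)
      bins <- sequence(nbins_per, from = b_lo[!same])
      overlap <- pmin(hi[ival], bins * width) -
        pmax(lo[ival], (bins - 1) * width)
      overlap <- pmax(overlap, 0)
      contrib <- dt[ival] * overlap / (hi[ival] - lo[ival])
      acc <- rowsum(contrib, bins)
      occ2 <- rep(0, n_bins)
      occ2[as.integer(rownames(acc))] <- acc[, 1]
      occ <- occ + occ2
    }
  }
  cnt <- rep(0L, n_bins)
  sp <- spike_times[spike_times >= start_s & spike_times < lick_s]
  if (length(sp) > 0) {
    spos <- approx(tt, pp, xout = sp, rule = 2, ties = "ordered")$y
    tab <- table(pos_to_bin(spos, track_length, n_bins))
    cnt[as.integer(names(tab))] <- as.integer(tab)
  }
  width <- track_length / n_bins
  tibble::tibble(
    bin = seq_len(n_bins),
    n_spikes = cnt,
    occupancy_s = occ,
    speed_cms = ifelse(occ > 0, width / occ, NA_real_))
}

#' Linearize a session for all units
#'
#' Applies [linearize_trial()] to every (unit, trial) pair and returns one
#' long tibble carrying the trial covariates needed downstream.
#'
#' @param bundle A [session_bundle()].
#' @param n_bins Number of position bins.
#' @param units Unit ids to include (default: all units with spikes, plus
#'   any listed in `bundle$units`).
#' @return A tibble of class `lin_session` with columns `unit_id`,
#'   `trial_id`, `trial_index`, `task`, `trajectory`, `accuracy`, `bin`,
#'   `n_spikes`, `occupancy_s`, `speed_cms`.  Attributes `track_length` and
#'   `n_bins` record the geometry.
#' @export
linearize_session <- function(bundle, n_bins = 100, units = NULL) {
  L <- bundle$meta$track_length
  trials <- dplyr::arrange(bundle$trials, .data$start_time_s)
  trials$trial_index <- seq_len(nrow(trials))
  if (is.null(units)) {
    units <- sort(unique(c(bundle$spikes$unit_id,
                           if (!is.null(bundle$units)) bundle$units$unit_id)))
  }
  sp <- bundle$spikes[bundle$spikes$unit_id %in% units, ]
  sp <- sp[order(sp$time_s), ]
  width <- L / n_bins

  per_trial <- lapply(seq_len(nrow(trials)), function(k) {
    trial <- trials[k, ]
    tk <- bundle$tracking[bundle$tracking$trial_id == trial$trial_id, ]
    base <- linearize_trial(tk, numeric(0), trial$start_time_s,
                            trial$first_lick_s, L, n_bins)
    # bin all units' spikes for this trial in one pass
    in_tr <- sp$time_s >= trial$start_time_s & sp$time_s < trial$first_lick_s
    cnt <- matrix(0L, length(units), n_bins,
                  dimnames = list(as.character(units), NULL))
    if (any(in_tr)) {
      st <- sp[in_tr, ]
      spos <- approx(tk$time_s, tk$pos_cm, xout = st$time_s, rule = 2,
                     ties = "ordered")$y
      bin <- pos_to_bin(spos, L, n_bins)
      ui <- match(st$unit_id, units)
      idx <- (bin - 1L) * length(units) + ui
      tab <- tabulate(idx, nbins = length(units) * n_bins)
      cnt[] <- tab
    }
    tibble::tibble(
      unit_id = rep(units, each = n_bins),
      trial_id = trial$trial_id,
      trial_index = trial$trial_index,
      task = trial$task,
      trajectory = trial$trajectory,
      accuracy = trial$accuracy,
      bin = rep(seq_len(n_bins), times = length(units)),
      n_spikes = as.integer(t(cnt)),
      occupancy_s = rep(base$occupancy_s, times = length(units)),
      speed_cms = rep(base$speed_cms, times = length(units)))
  })
  out <- dplyr::bind_rows(per_trial)
  attr(out, "track_length") <- L
  attr(out, "n_bins") <- n_bins
  class(out) <- c("lin_session", class(out))
  out
}

# Matrices (trials x bins) for one unit: counts, occupancy, per-trial rate
# (NA where unoccupied), plus the matching trial-covariate tibble.
lin_matrices <- function(lin_unit, n_bins = attr(lin_unit, "n_bins") %||%
                           max(lin_unit$bin)) {
  lin_unit <- lin_unit[order(lin_unit$trial_index, lin_unit$bin), ]
  ids <- unique(lin_unit$trial_index)
  k <- length(ids)
  n <- matrix(lin_unit$n_spikes, nrow = k, ncol = n_bins, byrow = TRUE)
  t_ <- matrix(lin_unit$occupancy_s, nrow = k, ncol = n_bins, byrow = TRUE)
  s <- matrix(lin_unit$speed_cms, nrow = k, ncol = n_bins, byrow = TRUE)
  r <- ifelse(t_ > 0, n / ifelse(t_ > 0, t_, 1), NA_real_)
  info <- dplyr::distinct(
    lin_unit[, c("trial_index", "trial_id", "task", "trajectory",
                 "accuracy")])
  info <- info[match(ids, info$trial_index), ]
  list(counts = n, occupancy = t_, speed = s, rate = r, trials = info)
}

filter_lin <- function(lin, task = "memory", correct_only = TRUE) {
  keep <- rep(TRUE, nrow(lin))
  if (!is.null(task)) keep <- keep & lin$task %in% task
  if (correct_only) keep <- keep & lin$accuracy == "correct"
  out <- lin[keep, ]
  attributes(out)$track_length <- attr(lin, "track_length")
  attributes(out)$n_bins <- attr(lin, "n_bins")
  class(out) <- class(lin)
  out
}
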