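# Optogenetic tagging: classify units as light-responsive from
# pulse-aligned PSTHs against a resampled baseline confidence band, and
# check spontaneous/light-evoked waveform similarity.
#
# The PSTH counts spikes in 1 ms bins over the 12 ms pulse window; the
# 0-1 ms and 11-12 ms bins contain stimulation artifacts and are excluded
# from testing.  The baseline band is the (1 - alpha) quantile of the
# maximum non-artifact bin rate over surrogate PSTHs built from pulse-onset
# sets drawn uniformly from the inter-stimulus baseline period — a global
# band controlling the family-wise error across bins.

psth_bins_ms <- 12L
artifact_bins <- c(1L, 12L)

# counts per 1 ms bin pooled over pulses (vectorized over pulses)
pulse_window_counts <- function(spikes, onsets, width_s = 0.012) {
  nb <- as.integer(width_s * 1000)
  lo <- findInterval(onsets, spikes, left.open = TRUE)       # spikes > onset
  hi <- findInterval(onsets + width_s, spikes)               # spikes <= end
  n_in <- hi - lo
  if (sum(n_in) == 0) return(integer(nb))
  sp_idx <- sequence(n_in, from = lo + 1L)
  rel_ms <- (spikes[sp_idx] -
               rep(onsets, times = n_in)) * 1000
  tabulate(pmin(pmax(floor(rel_ms), 0), nb - 1L) + 1L, nbins = nb)
}

#' Pulse-aligned light PSTH
#'
#' Spike rate in 1 ms bins over the 12 ms pulse window, pooled across
#' pulses.
#'
#' @param spikes Sorted spike times (s).
#' @param pulses Pulse onset times (s); at least one.
#' @return Tibble with `bin` (1..12), `t_ms` (bin start), `rate` (Hz) and
#'   `artifact` (the 0-1 and 11-12 ms bins, excluded from testing).
#' @export
build_light_psth <- function(spikes, pulses) {
  if (length(pulses) < 1) abort("need at least one light pulse")
  cnt <- pulse_window_counts(spikes, pulses)
  tibble::tibble(
    bin = seq_len(psth_bins_ms),
    t_ms = seq_len(psth_bins_ms) - 1,
    rate = cnt / (length(pulses) * 0.001),
    artifact = seq_len(psth_bins_ms) %in% artifact_bins)
}

#' Baseline confidence limit for the light PSTH
#'
#' Draws `n_resamples` surrogate pulse-onset sets uniformly from the
#' baseline period (the session span around the stimulation blocks with
#' all real pulse windows excised), builds each surrogate's PSTH, records
#' its maximum non-artifact bin rate, and returns the `1 - alpha` quantile
#' of those maxima.
#'
#' @param spikes Sorted spike times (s).
#' @param pulses Real pulse onsets (s).
#' @param n_resamples Number of surrogate onset sets.
#' @param alpha Family-wise error rate of the band.
#' @param baseline_span Numeric length-2 vector bounding the baseline
#'   period; defaults to 5 s before the first pulse through 5 s after the
#'   last.
#' @param seed Seed.
#' @return The confidence limit (Hz).
#' @export
baseline_confidence_limit <- function(spikes, pulses, n_resamples = 1000,
                                      alpha = 0.01, baseline_span = NULL,
                                      seed = 1L) {
  width <- 0.012
  span <- baseline_span %||% c(min(pulses) - 5, max(pulses) + width + 5)
  # gaps between pulse windows, shrunk so a surrogate window fits inside
  pe <- sort(pulses)
  gap_lo <- pmax(c(span[1], pe + width), span[1])
  gap_hi <- pmin(c(pe, span[2]) - width, span[2] - width)
  keep <- gap_hi > gap_lo
  gap_lo <- gap_lo[keep]
  gap_hi <- gap_hi[keep]
  total <- sum(gap_hi - gap_lo)
  if (total < 10 * length(pulses) * width) {
    abort("insufficient baseline: need >= 10x the summed pulse-window duration")
  }
  set.seed(seed)
  n_p <- length(pulses)
  draw <- runif(n_resamples * n_p, 0, total)
  cum <- cumsum(gap_hi - gap_lo)
  gi <- findInterval(draw, c(0, cum), left.open = TRUE)
  onsets <- gap_lo[gi] + (draw - c(0, cum)[gi])
  grp <- rep(seq_len(n_resamples), each = n_p)
  # bin counts per surrogate set
  lo <- findInterval(onsets, spikes, left.open = TRUE)
  hi <- findInterval(onsets + width, spikes)
  n_in <- hi - lo
  maxima <- numeric(n_resamples)
  if (sum(n_in) > 0) {
    sp_idx <- sequence(n_in, from = lo + 1L)
    rel_ms <- (spikes[sp_idx] - rep(onsets, times = n_in)) * 1000
    bin <- pmin(pmax(floor(rel_ms), 0), psth_bins_ms - 1L) + 1L
    g <- rep(grp, times = n_in)
    ok <- !(bin %in% artifact_bins)
    idx <- (g[ok] - 1L) * psth_bins_ms + bin[ok]
    counts <- tabulate(idx, nbins = n_resamples * psth_bins_ms)
    cm <- matrix(counts, nrow = psth_bins_ms)
    maxima <- apply(cm, 2, max) / (n_p * 0.001)
  }
  quantile(maxima, 1 - alpha, names = FALSE, type = 1)
}

#' Waveform similarity
#'
#' Pearson correlation between two waveform matrices (channels x samples)
#' flattened channel-major.
#'
#' @param spont,light Equal-shape numeric matrices.
#' @return Pearson r, or `NA` when either matrix has zero variance.
#' @export
waveform_similarity <- function(spont, light) {
  if (!all(dim(spont) == dim(light))) {
    abort("waveform matrices must share their shape")
  }
  a <- as.numeric(t(spont))
  b <- as.numeric(t(light))
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Classify a unit as light-responsive
#'
#' A unit is responsive when any non-artifact bin of its light PSTH
#' exceeds the baseline confidence limit.  When both spontaneous and
#' light-evoked waveforms are supplied, their Pearson correlation is
#' attached (a correlation above ~0.9 supports that evoked and spontaneous
#' spikes come from the same unit).
#'
#' @param spikes Sorted spike times (s).
#' @param pulses Pulse onsets (s).
#' @param alpha,n_resamples,baseline_span,seed Passed to
#'   [baseline_confidence_limit()].
#' @param spont_waveform,light_waveform Optional waveform matrices.
#' @return One-row tibble: `responsive`, `peak_rate`, `baseline_limit`,
#'   `waveform_corr`, `n_pulses`.
#' @export
classify_light_responsive <- function(spikes, pulses, alpha = 0.01,
                                      n_resamples = 1000,
                                      baseline_span = NULL, seed = 1L,
                                      spont_waveform = NULL,
                                      light_waveform = NULL) {
  psth <- build_light_psth(spikes, pulses)
  limit <- baseline_confidence_limit(spikes, pulses, n_resamples, alpha,
                                     baseline_span, seed)
  test_rates <- psth$rate[!psth$artifact]
  wc <- if (!is.null(spont_waveform) && !is.null(light_waveform)) {
    waveform_similarity(spont_waveform, light_waveform)
  } else NA_real_
  tibble::tibble(
    responsive = any(test_rates > limit),
    peak_rate = max(test_rates),
    baseline_limit = limit,
    waveform_corr = wc,
    n_pulses = length(pulses))
}

#' Optotag every unit of a session
#'
#' Runs [classify_light_responsive()] on each unit against the session's
#' light-pulse table, attaching waveform correlations where waveforms are
#' stored.
#'
#' @param bundle A [session_bundle()] with a `light_pulses` table.
#' @param alpha,n_resamples Band parameters.
#' @param seed Seed (a per-unit stream is derived from it).
#' @return Tibble with one row per unit: `unit_id`, `responsive`,
#'   `peak_rate`, `baseline_limit`, `waveform_corr`, `n_pulses`.
#' @export
optotag_session <- function(bundle, alpha = 0.01, n_resamples = 1000,
                            seed = 1L) {
  if (is.null(bundle$light_pulses)) {
    abort("session has no light-pulse table")
  }
  pulses <- bundle$light_pulses$onset_s
  units <- sort(unique(c(bundle$spikes$unit_id,
                         if (!is.null(bundle$units))
                           bundle$units$unit_id)))
  dplyr::bind_rows(lapply(seq_along(units), function(i) {
    u <- units[i]
    dplyr::mutate(
      classify_light_responsive(
        unit_spikes(bundle, u), pulses, alpha, n_resamples,
        seed = derive_seed(seed, i),
        spont_waveform = waveform_matrix(bundle, u, "spont"),
        light_waveform = waveform_matrix(bundle, u, "light")),
      unit_id = u, .before = 1)
  }))
}
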