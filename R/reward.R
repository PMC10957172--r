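# Time-domain analysis of the reward-consumption epoch: the first second
# after the first lick at the waterspout.  Excitation/inhibition is judged
# per 100 ms post-delivery segment against the 100 ms pre-lick baseline;
# left/right reward preference compares per-trial epoch means; section
# differences link the reward epoch to the spatial trajectory differences.

reward_trials <- function(bundle, task = "memory", correct_only = TRUE,
                          window_s = 1) {
  tr <- bundle$trials
  keep <- tr$task %in% task
  if (correct_only) keep <- keep & tr$accuracy == "correct"
  tr <- tr[keep, ]
  long_enough <- tr$end_time_s >= tr$first_lick_s + window_s
  attr(tr, "excluded") <- tr$trial_id[!long_enough]
  tr[long_enough, ]
}

unit_spikes <- function(bundle, unit) {
  bundle$spikes$time_s[bundle$spikes$unit_id == unit]
}

# trials x bins matrix of binned rates aligned at the first lick
align_at_lick <- function(spikes, licks, bin_s, from, to) {
  edges <- seq(from, to, by = bin_s)
  nb <- length(edges) - 1
  out <- matrix(0, length(licks), nb)
  for (k in seq_along(licks)) {
    rel <- spikes[spikes >= licks[k] + from & spikes < licks[k] + to] -
      licks[k]
    if (length(rel) > 0) {
      out[k, ] <- tabulate(findInterval(rel, edges), nbins = nb)
    }
  }
  out / bin_s
}

#' Reward-epoch PSTH
#'
#' Bins each trial's spikes in `bin_s` time bins over the first `window_s`
#' seconds after the first lick, averages across trials per side, and
#' smooths with the same Gaussian kernel machinery as the spatial maps.
#' Trials shorter than `window_s` after the lick are excluded (reported in
#' the `excluded_trials` attribute).
#'
#' @param bundle A [session_bundle()].
#' @param units Unit ids (default: all units with spikes).
#' @param bin_s Time bin (s), default 10 ms.
#' @param window_s Epoch length (s).
#' @param sigma,half_width Smoothing kernel, in time bins.
#' @param task,correct_only Trial filter.
#' @return Tibble of class `reward_psth`: `unit_id`, `side`, `bin`, `t_s`
#'   (bin centre relative to the lick), `rate`, `rate_smooth`, `k_trials`.
#' @export
reward_psth <- function(bundle, units = NULL, bin_s = 0.01, window_s = 1,
                        sigma = 5, half_width = 10, task = "memory",
                        correct_only = TRUE) {
  tr <- reward_trials(bundle, task, correct_only, window_s)
  units <- units %||% sort(unique(bundle$spikes$unit_id))
  nb <- round(window_s / bin_s)
  out <- lapply(units, function(u) {
    st <- unit_spikes(bundle, u)
    dplyr::bind_rows(lapply(c("left", "right"), function(side) {
      licks <- tr$first_lick_s[tr$trajectory == side]
      if (length(licks) < 2) {
        abort(sprintf("unit %s: need at least 2 usable trials per side", u))
      }
      m <- align_at_lick(st, licks, bin_s, 0, window_s)
      rate <- colMeans(m)
      tibble::tibble(unit_id = u, side = side, bin = seq_len(nb),
                     t_s = (seq_len(nb) - 0.5) * bin_s, rate = rate,
                     rate_smooth = smooth_rate(rate, sigma, half_width),
                     k_trials = length(licks))
    }))
  })
  out <- dplyr::bind_rows(out)
  attr(out, "excluded_trials") <- attr(tr, "excluded")
  class(out) <- c("reward_psth", class(out))
  out
}

#' Classify reward-epoch excitation and inhibition
#'
#' For the preferred side of each unit (the side with the larger mean
#' epoch rate, unless supplied), compares each of the ten 100 ms
#' post-delivery segments, and the whole 1 s epoch, to the 100 ms pre-lick
#' baseline with paired t-tests across trials.
#'
#' @param bundle A [session_bundle()].
#' @param units Unit ids (default: all).
#' @param alpha Significance level.
#' @param seg_s Segment length (s).
#' @param window_s Epoch length (s).
#' @param preferred Optional named character vector (unit id to
#'   `"left"`/`"right"`) overriding the preferred-side choice.
#' @param task,correct_only Trial filter.
#' @return A list of class `reward_response`: `segments` (tibble:
#'   `unit_id`, `segment`, `t`, `p`, `flag` in excited/inhibited/ns) and
#'   `units` (tibble: `unit_id`, `preferred_side`, `class`, `t`, `p`,
#'   `degenerate`).
#' @export
classify_reward_response <- function(bundle, units = NULL, alpha = 0.05,
                                     seg_s = 0.1, window_s = 1,
                                     preferred = NULL, task = "memory",
                                     correct_only = TRUE) {
  tr <- reward_trials(bundle, task, correct_only, window_s)
  units <- units %||% sort(unique(bundle$spikes$unit_id))
  n_seg <- round(window_s / seg_s)
  seg_rows <- vector("list", length(units))
  unit_rows <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[i]
    st <- unit_spikes(bundle, u)
    epoch_mean <- vapply(c("left", "right"), function(side) {
      licks <- tr$first_lick_s[tr$trajectory == side]
      mean(align_at_lick(st, licks, window_s, 0, window_s))
    }, numeric(1))
    side <- if (!is.null(preferred) && !is.null(preferred[[as.character(u)]]))
      preferred[[as.character(u)]] else
        c("left", "right")[which.max(epoch_mean)]
    licks <- tr$first_lick_s[tr$trajectory == side]
    if (length(licks) < 5) {
      abort(sprintf("unit %s: need at least 5 trials on the preferred side",
                    u))
    }
    pre <- drop(align_at_lick(st, licks, seg_s, -seg_s, 0))
    segs <- align_at_lick(st, licks, seg_s, 0, window_s)
    ptest <- function(post) {
      d <- post - pre
      if (near_constant(d))

        return(tibble::tibble(t = 0, p = NA_real_, flag = "ns",
                              degenerate = TRUE))
      tt <- t.test(post, pre, paired = TRUE)
      flag <- if (tt$p.value < alpha) {
        if (unname(tt$statistic) > 0) "excited" else "inhibited"
      } else "ns"
      tibble::tibble(t = unname(tt$statistic), p = tt$p.value, flag = flag,
                     degenerate = FALSE)
    }
    seg_rows[[i]] <- dplyr::bind_rows(lapply(seq_len(n_seg), function(s) {
      dplyr::mutate(ptest(segs[, s]), unit_id = u, segment = s,
                    .before = 1)
    }))
    epoch <- rowMeans(segs)
    ut <- ptest(epoch)
    unit_rows[[i]] <- tibble::tibble(
      unit_id = u, preferred_side = side,
      class = c(excited = "excited", inhibited = "inhibited",
                ns = "none")[[ut$flag]],
      t = ut$t, p = ut$p, degenerate = ut$degenerate)
  }
  structure(list(segments = dplyr::bind_rows(seg_rows),
                 units = dplyr::bind_rows(unit_rows)),
            class = "reward_response")
}

#' @export
print.reward_response <- function(x, ...) {
  cat("<reward_response>\n")
  print(dplyr::count(x$units, .data$class))
  invisible(x)
}

#' @export
tidy.reward_response <- function(x, type = c("units", "segments"), ...) {
  x[[match.arg(type)]]
}

#' Left-right reward preference
#'
#' Compares per-trial reward-epoch mean rates between left and right
#' trials.  Left and right trial counts differ in general, so the default
#' is Welch's two-sample t-test; `method = "rank_paired"` pairs trials by
#' within-side rank for users wanting a literal paired reading.
#'
#' @param bundle A [session_bundle()].
#' @param units Unit ids (default: all).
#' @param alpha Significance level.
#' @param method `"welch"` or `"rank_paired"`.
#' @param window_s Epoch length (s).
#' @param task,correct_only Trial filter.
#' @return Tibble: `unit_id`, `mean_left`, `mean_right`, `t`, `p`,
#'   `side_pref` (`"left"`, `"right"`, `"ns"`), `degenerate`.
#' @export
reward_side_preference <- function(bundle, units = NULL, alpha = 0.05,
                                   method = c("welch", "rank_paired"),
                                   window_s = 1, task = "memory",
                                   correct_only = TRUE) {
  method <- match.arg(method)
  tr <- reward_trials(bundle, task, correct_only, window_s)
  units <- units %||% sort(unique(bundle$spikes$unit_id))
  licks_l <- tr$first_lick_s[tr$trajectory == "left"]
  licks_r <- tr$first_lick_s[tr$trajectory == "right"]
  if (min(length(licks_l), length(licks_r)) < 5) {
    abort("need at least 5 usable trials per side")
  }
  dplyr::bind_rows(lapply(units, function(u) {
    st <- unit_spikes(bundle, u)
    ml <- drop(align_at_lick(st, licks_l, window_s, 0, window_s))
    mr <- drop(align_at_lick(st, licks_r, window_s, 0, window_s))
    if (method == "rank_paired") {
      k <- min(length(ml), length(mr))
      ml2 <- sort(ml)[seq_len(k)]
      mr2 <- sort(mr)[seq_len(k)]
      if (near_constant(ml2 - mr2)) {
        return(tibble::tibble(unit_id = u, mean_left = mean(ml),
                              mean_right = mean(mr), t = 0, p = NA_real_,
                              side_pref = "ns", degenerate = TRUE))
      }
      tt <- t.test(ml2, mr2, paired = TRUE)
    } else {
      if (near_constant(ml) && near_constant(mr)) {
        return(tibble::tibble(unit_id = u, mean_left = mean(ml),
                              mean_right = mean(mr), t = 0, p = NA_real_,
                              side_pref = "ns", degenerate = TRUE))
      }
      tt <- t.test(ml, mr)
    }
    pref <- if (tt$p.value < alpha) {
      if (mean(ml) > mean(mr)) "left" else "right"
    } else "ns"
    tibble::tibble(unit_id = u, mean_left = mean(ml),
                   mean_right = mean(mr), t = unname(tt$statistic),
                   p = tt$p.value, side_pref = pref, degenerate = FALSE)
  }))
}

#' Per-unit left-right differences by maze section and reward epoch
#'
#' For each unit, the mean smoothed left-right rate difference over the
#' bins of each spatial section (start, cue, delay, side arms) and over
#' the reward-consumption epoch in the time domain.
#'
#' @param lin A `lin_session` tibble (for the spatial differences).
#' @param bundle The matching [session_bundle()] (for the reward epoch).
#' @param units Unit ids (default: all in `lin`).
#' @param sigma,half_width Smoothing kernel (bins).
#' @param window_s Reward-epoch length (s).
#' @param boundaries,track_length Section geometry.
#' @return Tibble: `unit_id`, `d_start`, `d_cue`, `d_delay`, `d_arms`,
#'   `d_reward` (all Hz).
#' @export
section_differences <- function(lin, bundle, units = NULL, sigma = 5,
                                half_width = 10, window_s = 1,
                                boundaries = c(50, 80, 120, 150),
                                track_length = attr(lin, "track_length") %||%
                                  150) {
  n_bins <- attr(lin, "n_bins") %||% max(lin$bin)
  units <- units %||% sort(unique(lin$unit_id))
  d0 <- observed_difference(lin[lin$unit_id %in% units, ],
                            sigma, half_width)
  secmap <- assign_sections(boundaries, track_length, n_bins)
  spatial <- d0 |>
    dplyr::left_join(secmap[, c("bin", "section")], by = "bin") |>
    dplyr::group_by(.data$unit_id, .data$section) |>
    dplyr::summarise(d = mean(.data$d0, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "section", values_from = "d") |>
    dplyr::rename(d_start = "start", d_cue = "cue", d_delay = "delay",
                  d_arms = "side_arms")
  psth <- reward_psth(bundle, units = units, window_s = window_s,
                      sigma = sigma, half_width = half_width)
  rew <- psth |>
    dplyr::group_by(.data$unit_id, .data$side) |>
    dplyr::summarise(m = mean(.data$rate), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "side", values_from = "m") |>
    dplyr::mutate(d_reward = .data$left - .data$right) |>
    dplyr::select("unit_id", "d_reward")
  dplyr::left_join(spatial, rew, by = "unit_id")
}

#' Correlate reward-epoch and maze-section rate differences
#'
#' Pearson correlation, across units, between the reward-epoch left-right
#' difference and the difference in each spatial maze section.
#'
#' @param secdiff Tibble from [section_differences()] (at least 10 units).
#' @return Tibble: `section`, `r`, `p`, `n`, `reason` (non-NA when a
#'   correlation is unavailable, e.g. zero variance).
#' @export
section_difference_correlation <- function(secdiff) {
  if (nrow(secdiff) < 10) abort("need at least 10 units")
  secs <- c(start = "d_start", cue = "d_cue", delay = "d_delay",
            side_arms = "d_arms")
  dplyr::bind_rows(lapply(names(secs), function(s) {
    x <- secdiff[[secs[[s]]]]
    y <- secdiff$d_reward
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble::tibble(section = s, r = NA_real_, p = NA_real_,
                            n = sum(ok),
                            reason = "zero variance or too few units"))
    }
    ct <- cor.test(x[ok], y[ok])
    tibble::tibble(section = s, r = unname(ct$estimate), p = ct$p.value,
                   n = sum(ok), reason = NA_character_)
  }))
}

#' Six-category delay x reward encoding classification
#'
#' Crosses each unit's trajectory preference in the memory delay (from the
#' permutation test) with its reward-side preference, yielding the six
#' cells (delay/reward x left/right/ns) and the derived counts: same side
#' in both, different, neither significant.
#'
#' @param delay_pref Tibble (`unit_id`, `preference`) from
#'   [section_preference()].
#' @param side_pref Tibble (`unit_id`, `side_pref`) from
#'   [reward_side_preference()].
#' @return A list of class `delay_reward_categories`: `per_unit` (tibble
#'   with `delay`, `reward`, `category`), `cells` (3 x 3 count table as a
#'   tibble) and `summary` (one-row tibble: `same_side`, `different`,
#'   `neither`).
#' @export
delay_reward_categories <- function(delay_pref, side_pref) {
  if (!all(c("unit_id", "preference") %in% names(delay_pref)) ||
      !all(c("unit_id", "side_pref") %in% names(side_pref))) {
    abort("upstream results missing: need delay preferences and reward side preferences")
  }
  per_unit <- dplyr::inner_join(
    dplyr::rename(delay_pref, delay = "preference"),
    dplyr::rename(side_pref[, c("unit_id", "side_pref")],
                  reward = "side_pref"),
    by = "unit_id")
  per_unit$category <- dplyr::case_when(
    per_unit$delay == "ns" & per_unit$reward == "ns" ~ "neither",
    per_unit$delay != "ns" & per_unit$delay == per_unit$reward ~
      "same_side",
    TRUE ~ "different")
  cells <- per_unit |>
    dplyr::count(delay = factor(.data$delay, c("left", "right", "ns")),
                 reward = factor(.data$reward, c("left", "right", "ns")),
                 .drop = FALSE)
  summary <- tibble::tibble(
    same_side = sum(per_unit$category == "same_side"),
    different = sum(per_unit$category == "different"),
    neither = sum(per_unit$category == "neither"))
  structure(list(per_unit = per_unit, cells = cells, summary = summary),
            class = "delay_reward_categories")
}

#' @export
print.delay_reward_categories <- function(x, ...) {
  cat("<delay_reward_categories>\n")
  print(x$summary)
  invisible(x)
}
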