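# Shared fixtures: small synthetic sessions and hand-built unit truths.

# One truth row for generate_spikes(), bypassing the cohort machinery.
unit_truth <- function(base_rate = 10, centers = numeric(0),
                       widths = numeric(0), gains = numeric(0),
                       sections = character(0), pref_side = "left",
                       traj_gain = 1, reward_response = "none",
                       reward_side_gain = 1, reward_pref_side = NA_character_) {
  tibble::tibble(
    cell_class = "untagged", base_rate = base_rate,
    field_centers = list(centers), field_widths = list(widths),
    field_gains = list(gains), traj_sections = list(sections),
    pref_side = pref_side, traj_gain = traj_gain,
    reward_response = reward_response,
    reward_side_gain = reward_side_gain,
    reward_pref_side = reward_pref_side,
    tagged = FALSE, p_evoke = 0, tag_latency_ms = 4, tag_jitter_ms = 1)
}

# Behaviour plus a set of hand-specified units in one bundle.
make_session <- function(truths, n_trials = 40, seed = 7, ...) {
  cfg <- synth_config(seed = seed, n_trials = n_trials, ...)
  beh <- generate_behavior(cfg)
  sp <- dplyr::bind_rows(lapply(seq_len(nrow(truths)), function(i) {
    tibble::tibble(
      unit_id = i,
      time_s = generate_spikes(truths[i, ], beh$trials, beh$tracking,
                               seed = seed + 100 + i))
  }))
  session_bundle(beh$trials, beh$tracking, sp,
                 meta = list(session_id = "test", track_length = 150))
}

# Deterministic hand-built trial: constant speed, exact event times.
constant_speed_session <- function(n_trials = 4, speed = 30, dwell = 2,
                                   rate_hz = 0, track_length = 150,
                                   dt = 0.02) {
  t_cursor <- 0
  trials <- list()
  tracking <- list()
  for (k in seq_len(n_trials)) {
    dur <- track_length / speed
    times <- seq(0, dur, by = dt)
    if (max(times) < dur) times <- c(times, dur)
    pos <- pmin(times * speed, track_length)
    trials[[k]] <- tibble::tibble(
      trial_id = k, task = "memory",
      trajectory = c("left", "right")[(k %% 2) + 1], accuracy = "correct",
      start_time_s = t_cursor, cue_onset_s = t_cursor + 50 / speed,
      delay_offset_s = t_cursor + 120 / speed,
      first_lick_s = t_cursor + dur, end_time_s = t_cursor + dur + dwell)
    tracking[[k]] <- tibble::tibble(trial_id = k, time_s = t_cursor + times,
                                    pos_cm = pos)
    t_cursor <- t_cursor + dur + dwell + 3
  }
  trials <- dplyr::bind_rows(trials)
  tracking <- dplyr::bind_rows(tracking)
  spikes <- if (rate_hz > 0) {
    withr::with_seed(1, tibble::tibble(
      unit_id = 1L,
      time_s = sort(runif(rpois(1, rate_hz * t_cursor), 0, t_cursor))))
  } else {
    tibble::tibble(unit_id = integer(), time_s = numeric())
  }
  session_bundle(trials, tracking, spikes,
                 meta = list(session_id = "const", track_length = 150,
                             session_end = t_cursor))
}
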