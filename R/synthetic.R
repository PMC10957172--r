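# Synthetic-session generator.  Emulates the behavioural statistics and
# spiking structure of the T-maze memory task so that every analysis stage
# has a recovery oracle with planted ground truth.

#' Configuration for the synthetic-session generator
#'
#' Defaults emulate the study conditions: 90 trials per session at an 87%
#' correct rate on a 150 cm linearized track, reward-consumption dwell of
#' 1-10 s, 50 Hz position tracking, slow-firing DA-like units (5 Hz) and
#' fast-firing GABA-like units (20 Hz) with position-tuned Gaussian fields,
#' planted trajectory-specific gain in chosen maze sections, reward
#' responders, and ChR2-tagged light responses (4 blocks of 150 12-ms
#' pulses at 1-10 Hz, 1-4 mW).
#'
#' Planted unit counts use deterministic rounding (half away from zero) of
#' `n_class * fraction`, so recovery tests have exact expected counts.
#' Delay-modulated and arms-modulated sets are disjoint; arms-modulated
#' units also receive a same-side reward gain (`reward_side_gain`), which
#' reproduces the observed coupling between side-arm and reward-epoch rate
#' differences while leaving the delay difference independent of reward.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_trials Trials per session.
#' @param p_correct Probability a memory trial is correct.
#' @param n_da,n_gaba,n_untagged Units per class.
#' @param base_rate_da,base_rate_gaba,base_rate_untagged Median spontaneous
#'   rates (Hz).
#' @param fraction_traj_delay Named fractions per class of delay-modulated
#'   units.
#' @param fraction_traj_arms Named fractions per class of side-arm
#'   modulated units (coupled to the reward side gain).
#' @param fraction_reward_responsive Named fractions per class of
#'   reward-excited/inhibited units.
#' @param traj_gain Multiplicative rate gain on the preferred trajectory in
#'   the modulated sections.
#' @param reward_side_gain Multiplicative gain for the preferred-side
#'   reward epoch of arms-modulated units.
#' @param reward_excite_gain,reward_inhibit_gain Step gain over the 1 s
#'   consumption epoch for excited/inhibited responders.
#' @param speed_mean,speed_sd Mean and SD of the per-trial lognormal mean
#'   running speed (cm/s).
#' @param reward_dwell_range Uniform range of reward-consumption dwell (s).
#' @param tracking_rate Position sampling rate (Hz).
#' @param track_length Track length (cm).
#' @param task_mix Named fractions of trial types; control-task trials are
#'   delivered as separate blocks.
#' @param n_fields_max Maximum number of Gaussian place-like fields per
#'   unit (each unit gets 1..n_fields_max).
#' @param p_evoke Per-pulse probability that a tagged unit fires an evoked
#'   spike.
#' @param tag_latency_ms,tag_jitter_ms Evoked-spike latency mean and SD
#'   (ms); latencies truncated to (1, 11) ms, outside the artifact windows.
#' @param light_freqs_hz Pulse frequencies of the four stimulation blocks.
#' @param light_pulses_per_block Pulses per block.
#' @param waveform_snr Amplitude SNR of stored mean waveforms.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_trials = 90,
                         p_correct = 0.87,
                         n_da = 100, n_gaba = 74, n_untagged = 0,
                         base_rate_da = 5, base_rate_gaba = 20,
                         base_rate_untagged = 8,
                         fraction_traj_delay =
                           c(DA = 0.20, GABA = 0.47, untagged = 0.2),
                         fraction_traj_arms =
                           c(DA = 0.25, GABA = 0.25, untagged = 0.25),
                         fraction_reward_responsive =
                           c(DA = 0.25, GABA = 0.25, untagged = 0.25),
                         traj_gain = 2,
                         reward_side_gain = 2,
                         reward_excite_gain = 3,
                         reward_inhibit_gain = 0.2,
                         speed_mean = 20, speed_sd = 5,
                         reward_dwell_range = c(1, 10),
                         tracking_rate = 50,
                         track_length = 150,
                         task_mix = c(memory = 1),
                         n_fields_max = 2,
                         p_evoke = 0.9,
                         tag_latency_ms = 4, tag_jitter_ms = 1,
                         light_freqs_hz = c(1, 2, 5, 10),
                         light_pulses_per_block = 150,
                         waveform_snr = 10) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_trials >= 1, cfg$tracking_rate > 0,
            cfg$p_correct >= 0, cfg$p_correct <= 1,
            all(unlist(cfg$fraction_traj_delay) >= 0),
            all(unlist(cfg$fraction_traj_delay) <= 1),
            cfg$traj_gain > 0,
            diff(cfg$reward_dwell_range) >= 0)
  structure(cfg, class = "synth_config")
}

# Smooth positive within-trial speed modulation, floored at 20% of the
# trial-mean speed.
speed_modulation <- function(n, floor_frac = 0.2) {
  raw <- rnorm(max(n, 3))
  k <- gaussian_kernel(sigma = 15, half_width = 45)
  sm <- stats::filter(c(rev(raw[1:45]), raw, rev(raw)[1:45]), k,
                      sides = 2)[45 + seq_len(length(raw))]
  pmax(1 + 0.3 * as.numeric(sm[seq_len(n)]), floor_frac)
}

#' Generate synthetic task behaviour
#'
#' Draws a trial table and a linearized position trace.  Trajectories are a
#' balanced pseudo-random left/right sequence, accuracy is
#' Bernoulli(`p_correct`), and each trial's trace is the integral of a
#' smooth strictly positive speed profile from 0 to the waterspout, sampled
#' at `tracking_rate`; reward-consumption dwell is uniform in
#' `reward_dwell_range`.  Control-task trials (if requested in `task_mix`)
#' are delivered as separate blocks after the memory block, and
#' no-cue-no-choice trials carry no cue onset.
#'
#' @param config A [synth_config()].
#' @param seed Seed; defaults to a stream derived from `config$seed`.
#' @return List with tibbles `trials` and `tracking`.
#' @export
generate_behavior <- function(config, seed = derive_seed(config$seed, 1)) {
  set.seed(seed)
  n <- config$n_trials
  mix <- config$task_mix / sum(config$task_mix)
  n_per_task <- round_half_away(n * mix)
  n_per_task[1] <- n - sum(n_per_task[-1])
  task <- rep(names(n_per_task), times = n_per_task)  # blockwise delivery

  # Balanced pseudo-random trajectory sequence per task block.
  traj <- unlist(lapply(n_per_task, function(k) {
    sample(rep(c("left", "right"), length.out = k))
  }), use.names = FALSE)
  accuracy <- ifelse(task == "memory",
                     ifelse(runif(n) < config$p_correct, "correct", "error"),
                     "correct")  # control tasks always end at the reward

  dt <- 1 / config$tracking_rate
  L <- config$track_length
  t_cursor <- 0
  trials <- vector("list", n)
  tracking <- vector("list", n)
  for (k in seq_len(n)) {
    v_mean <- rlnorm(1, log(config$speed_mean),
                     config$speed_sd / config$speed_mean)
    n_max <- ceiling(L / (0.15 * v_mean) / dt) + 10L
    v <- v_mean * speed_modulation(n_max)
    pos <- pmin(cumsum(c(0, v[-length(v)]) * dt), L)
    n_run <- which(pos >= L)[1]
    if (is.na(n_run)) n_run <- length(pos)   # defensive; floor prevents this
    pos <- pos[seq_len(n_run)]
    times <- t_cursor + (seq_len(n_run) - 1) * dt
    lick <- times[n_run]
    dwell <- runif(1, config$reward_dwell_range[1],
                   config$reward_dwell_range[2])
    end <- lick + dwell
    # hold position at the waterspout during consumption
    hold <- seq(lick + dt, end, by = dt)
    cross <- function(p) {
      i <- which(pos >= p)[1]
      if (i == 1) times[1] else
        approx(pos[(i - 1):i], times[(i - 1):i], xout = p, ties = "ordered")$y
    }
    task_k <- task[k]
    trials[[k]] <- tibble::tibble(
      trial_id = k,
      task = task_k,
      trajectory = traj[k],
      accuracy = accuracy[k],
      start_time_s = times[1],
      cue_onset_s = if (task_k == "no_cue_no_choice") NA_real_ else cross(50),
      delay_offset_s = cross(120),
      first_lick_s = lick,
      end_time_s = end)
    tracking[[k]] <- tibble::tibble(
      trial_id = k,
      time_s = c(times, hold),
      pos_cm = c(pos, rep(L, length(hold))))
    t_cursor <- end + runif(1, 2, 8)  # return run, untracked
  }
  list(trials = dplyr::bind_rows(trials),
       tracking = dplyr::bind_rows(tracking))
}

# Deterministic planted-truth table for one cohort.
generate_truth <- function(config, seed = derive_seed(config$seed, 2)) {
  set.seed(seed)
  classes <- rep(c("DA", "GABA", "untagged"),
                 times = c(config$n_da, config$n_gaba, config$n_untagged))
  n <- length(classes)
  base_med <- c(DA = config$base_rate_da, GABA = config$base_rate_gaba,
                untagged = config$base_rate_untagged)
  out <- vector("list", 3)
  uid0 <- 0L
  for (cl in unique(classes)) {
    k <- sum(classes == cl)
    if (k == 0) next
    ord <- sample.int(k)               # seed-fixed assignment order
    n_delay <- round_half_away(k * config$fraction_traj_delay[[cl]])
    n_arms <- min(round_half_away(k * config$fraction_traj_arms[[cl]]),
                  k - n_delay)
    delay_set <- ord[seq_len(n_delay)]
    arms_set <- ord[n_delay + seq_len(n_arms)]
    ord2 <- sample.int(k)              # independent order for reward class
    n_rew <- round_half_away(k * config$fraction_reward_responsive[[cl]])
    rew_set <- ord2[seq_len(n_rew)]
    n_fields <- sample.int(config$n_fields_max, k, replace = TRUE)
    tt <- tibble::tibble(
      unit_id = uid0 + seq_len(k),
      cell_class = cl,
      base_rate = rlnorm(k, log(base_med[[cl]]), 0.3),
      field_centers = lapply(n_fields, function(m)
        runif(m, 0, config$track_length)),
      field_widths = lapply(n_fields, function(m) runif(m, 8, 25)),
      field_gains = lapply(n_fields, function(m) runif(m, 0.5, 2.5)),
      traj_sections = replicate(k, character(0), simplify = FALSE),
      pref_side = sample(c("left", "right"), k, replace = TRUE),
      traj_gain = 1,
      reward_response = "none",
      reward_side_gain = 1,
      reward_pref_side = NA_character_,
      tagged = cl != "untagged",
      p_evoke = config$p_evoke,
      tag_latency_ms = config$tag_latency_ms,
      tag_jitter_ms = config$tag_jitter_ms)
    # arms-coupled modulation is planted in the outer half of the side
    # arms (135-150 cm): anticipatory build-up on the reward approach.
    # Because the smoothing kernel's support is 10 bins, this keeps the
    # delay-section difference of these units exactly zero.
    tt$traj_sections[delay_set] <- list("delay")
    tt$traj_sections[arms_set] <- list("arms_outer")
    tt$traj_gain[c(delay_set, arms_set)] <- config$traj_gain
    rtype <- sample(c("excited", "inhibited"), length(rew_set),
                    replace = TRUE, prob = c(0.7, 0.3))
    tt$reward_response[rew_set] <- rtype
    # arms-modulated units prefer the same side at the reward
    tt$reward_side_gain[arms_set] <- config$reward_side_gain
    tt$reward_pref_side[arms_set] <- tt$pref_side[arms_set]
    out[[length(out) + 1]] <- tt
    uid0 <- uid0 + k
  }
  dplyr::bind_rows(out)
}

# Instantaneous rate (Hz) of one unit on a time grid belonging to one trial.
unit_rate_on_grid <- function(truth, trial, times, pos, track_length) {
  fg <- rep(1, length(pos))
  for (j in seq_along(truth$field_centers[[1]])) {
    fg <- fg + truth$field_gains[[1]][j] *
      exp(-(pos - truth$field_centers[[1]][j])^2 /
            (2 * truth$field_widths[[1]][j]^2))
  }
  r <- truth$base_rate * fg
  secs <- truth$traj_sections[[1]]
  if (length(secs) > 0 && identical(trial$trajectory, truth$pref_side)) {
    lo <- c(start = 0, cue = 50, delay = 80, side_arms = 120,
            arms_outer = 135)
    hi <- c(start = 50, cue = 80, delay = 120, side_arms = track_length,
            arms_outer = track_length)
    in_mod <- Reduce(`|`, lapply(secs, function(s) {
      pos > lo[[s]] & pos <= hi[[s]]
    }))
    r[in_mod] <- r[in_mod] * truth$traj_gain
  }
  in_rew <- times >= trial$first_lick_s & times < trial$first_lick_s + 1
  if (any(in_rew)) {
    g <- switch(truth$reward_response,
                excited = 3, inhibited = 0.2, none = 1)
    if (!is.na(truth$reward_pref_side) &&
        identical(trial$trajectory, truth$reward_pref_side)) {
      g <- g * truth$reward_side_gain
    }
    r[in_rew] <- r[in_rew] * g
  }
  pmax(r, 0)
}

# Inhomogeneous-Poisson spikes on one piecewise-linear rate segment, by
# thinning against the segment maximum.
thin_segment <- function(times, rates) {
  span <- times[length(times)] - times[1]
  rmax <- max(rates)
  if (rmax <= 0 || span <= 0) return(numeric(0))
  n_cand <- rpois(1, rmax * span)
  if (n_cand == 0) return(numeric(0))
  tc <- sort(runif(n_cand, times[1], times[length(times)]))
  rc <- approx(times, rates, xout = tc, rule = 2, ties = "ordered")$y
  tc[runif(n_cand) * rmax < rc]
}

#' Generate a synthetic spike train for one unit
#'
#' Draws spikes from an inhomogeneous Poisson process by thinning.  The
#' instantaneous rate is `base_rate` times a Gaussian-field position gain,
#' times `traj_gain` when the trial's trajectory is the unit's preferred
#' one and the current position lies in a modulated section, times a step
#' reward factor for 1 s after the first lick (side-scaled by
#' `reward_side_gain`).  Between trials (and after `until`, if given,
#' through the light-stimulation period) the unit fires at `base_rate`.
#'
#' @param truth One row of the planted-truth table (as produced by the
#'   cohort generator), containing list-columns `field_centers`,
#'   `field_widths`, `field_gains`, `traj_sections`.
#' @param trials,tracking Behaviour tables from [generate_behavior()].
#' @param track_length Track length (cm).
#' @param until Optional end of the spontaneous-spiking span (s); defaults
#'   to the last trial end.
#' @param seed Seed.
#' @return Sorted numeric vector of spike times (s).
#' @export
generate_spikes <- function(truth, trials, tracking, track_length = 150,
                            until = NULL, seed = 1L) {
  set.seed(seed)
  spikes <- vector("list", nrow(trials) + 1L)
  prev_end <- 0
  for (k in seq_len(nrow(trials))) {
    trial <- trials[k, ]
    tk <- tracking[tracking$trial_id == trial$trial_id, ]
    # inter-trial gap at base rate
    if (trial$start_time_s > prev_end) {
      spikes[[k]] <- c(
        thin_segment(c(prev_end, trial$start_time_s),
                     rep(truth$base_rate, 2)),
        thin_segment(tk$time_s,
                     unit_rate_on_grid(truth, trial, tk$time_s, tk$pos_cm,
                                       track_length)))
    } else {
      spikes[[k]] <- thin_segment(
        tk$time_s, unit_rate_on_grid(truth, trial, tk$time_s, tk$pos_cm,
                                     track_length))
    }
    prev_end <- trial$end_time_s
  }
  until <- until %||% prev_end
  if (until > prev_end) {
    spikes[[nrow(trials) + 1L]] <-
      thin_segment(c(prev_end, until), rep(truth$base_rate, 2))
  }
  sort(unlist(spikes, use.names = FALSE))
}

#' Generate the optogenetic stimulation protocol and evoked spikes
#'
#' Builds four sequential blocks of square light pulses (one per power
#' level, 12 ms pulses, `light_pulses_per_block` pulses per block at
#' `light_freqs_hz`).  For each tagged unit, every pulse adds an evoked
#' spike with probability `p_evoke` at latency `tag_latency_ms` plus
#' Gaussian jitter, truncated to (1, 11) ms after pulse onset so evoked
#' spikes avoid the 0-1 and 11-12 ms artifact windows.  Untagged units are
#' unchanged.
#'
#' @param truth Planted-truth table (one row per unit).
#' @param config A [synth_config()].
#' @param start_s Onset of the first block (s).
#' @param seed Seed.
#' @return List with `light_pulses` (tibble) and `evoked` (named list of
#'   spike-time vectors keyed by unit id).
#' @export
generate_light_session <- function(truth, config, start_s,
                                   seed = derive_seed(config$seed, 3)) {
  set.seed(seed)
  blocks <- vector("list", length(config$light_freqs_hz))
  t0 <- start_s
  for (b in seq_along(config$light_freqs_hz)) {
    f <- config$light_freqs_hz[b]
    onsets <- t0 + (seq_len(config$light_pulses_per_block) - 1) / f
    blocks[[b]] <- tibble::tibble(
      block_id = b, power_mw = b, freq_hz = f, onset_s = onsets,
      width_ms = 12)
    t0 <- max(onsets) + 0.012 + 20  # inter-block gap
  }
  pulses <- dplyr::bind_rows(blocks)
  evoked <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    if (!isTRUE(tr$tagged)) return(numeric(0))
    hit <- runif(nrow(pulses)) < tr$p_evoke
    n <- sum(hit)
    if (n == 0) return(numeric(0))
    lat <- tr$tag_latency_ms + tr$tag_jitter_ms * rnorm(n)
    bad <- lat <= 1 | lat >= 11
    while (any(bad)) {                 # truncate to (1, 11) ms
      lat[bad] <- tr$tag_latency_ms + tr$tag_jitter_ms * rnorm(sum(bad))
      bad <- lat <= 1 | lat >= 11
    }
    sort(pulses$onset_s[hit] + lat / 1000)
  })
  names(evoked) <- as.character(truth$unit_id)
  list(light_pulses = pulses, evoked = evoked)
}

# Mean waveform template (channels x samples): a biphasic shape with a
# smooth amplitude profile across channels.
waveform_template <- function(n_channels = 8, n_samples = 32) {
  t <- seq(0, 1, length.out = n_samples)
  shape <- -exp(-((t - 0.3) / 0.08)^2) + 0.45 * exp(-((t - 0.55) / 0.15)^2)
  peak <- runif(1, 1, n_channels)
  amp <- exp(-((seq_len(n_channels) - peak)^2) / (2 * 2^2))
  outer(amp, shape) * runif(1, 50, 150)
}

waveform_long <- function(unit_id, condition, m) {
  tibble::tibble(
    unit_id = unit_id, condition = condition,
    channel = rep(seq_len(nrow(m)), each = ncol(m)),
    sample = rep(seq_len(ncol(m)), times = nrow(m)),
    value = as.numeric(t(m)))
}

#' Simulate a full recording session with planted ground truth
#'
#' Assembles behaviour, per-unit spike trains, the light-stimulation
#' protocol with evoked spikes for tagged units, and mean waveforms
#' (template plus independent noise for the spontaneous and light-evoked
#' conditions).  Identical seed and configuration give byte-identical
#' bundles after [write_session()].
#'
#' @param config A [synth_config()].
#' @param light Include the light-stimulation protocol.
#' @param waveforms Include mean waveforms.
#' @return List with elements `bundle` (a [session_bundle()]) and `truth`
#'   (tibble of planted ground truth keyed by `unit_id`).
#' @export
simulate_session <- function(config = synth_config(), light = TRUE,
                             waveforms = light) {
  beh <- generate_behavior(config)
  truth <- generate_truth(config)
  lt <- NULL
  until <- max(beh$trials$end_time_s)
  if (light) {
    lt <- generate_light_session(truth, config, start_s = until + 60)
    until <- max(lt$light_pulses$onset_s) + 30
  }
  spikes <- lapply(seq_len(nrow(truth)), function(i) {
    st <- generate_spikes(truth[i, ], beh$trials, beh$tracking,
                          track_length = config$track_length, until = until,
                          seed = derive_seed(config$seed, 100 + i))
    if (light) st <- sort(c(st, lt$evoked[[as.character(truth$unit_id[i])]]))
    tibble::tibble(unit_id = truth$unit_id[i], time_s = st)
  })
  wf <- NULL
  if (waveforms) {
    set.seed(derive_seed(config$seed, 4))
    wf <- dplyr::bind_rows(lapply(seq_len(nrow(truth)), function(i) {
      tpl <- waveform_template()
      nsd <- sd(tpl) / config$waveform_snr
      rows <- waveform_long(truth$unit_id[i], "spont",
                            tpl + matrix(rnorm(length(tpl), 0, nsd),
                                         nrow(tpl)))
      if (truth$tagged[i]) {
        rows <- dplyr::bind_rows(
          rows,
          waveform_long(truth$unit_id[i], "light",
                        tpl + matrix(rnorm(length(tpl), 0, nsd), nrow(tpl))))
      }
      rows
    }))
  }
  bundle <- session_bundle(
    trials = beh$trials,
    tracking = beh$tracking,
    spikes = dplyr::bind_rows(spikes),
    units = tibble::tibble(unit_id = truth$unit_id,
                           label = truth$cell_class),
    light_pulses = if (light) lt$light_pulses else NULL,
    waveforms = wf,
    meta = list(session_id = sprintf("synthetic-%d", config$seed),
                animal_id = "synthetic", genotype = "unknown",
                track_length = config$track_length,
                session_end = until, seed = config$seed))
  list(bundle = bundle, truth = truth)
}

#' Flatten the planted-truth table for TSV export
#'
#' List-columns (field parameters, modulated sections) are joined with
#' semicolons so the table can round-trip through a plain TSV file.
#'
#' @param truth Truth tibble from [simulate_session()].
#' @return A flat tibble.
#' @export
flatten_truth <- function(truth) {
  j <- function(col) vapply(col, function(v)
    paste(signif(as.numeric(v), 8), collapse = ";"), character(1))
  dplyr::mutate(
    truth,
    field_centers = j(.data$field_centers),
    field_widths = j(.data$field_widths),
    field_gains = j(.data$field_gains),
    traj_sections = vapply(.data$traj_sections, paste, character(1),
                           collapse = ";"))
}
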