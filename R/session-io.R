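# On-disk session bundle: a directory of TSV tables plus JSON metadata.
#
#   trials.tsv       trial_id task trajectory accuracy start_time_s
#                    cue_onset_s delay_offset_s first_lick_s end_time_s
#   tracking.tsv     trial_id time_s pos_cm
#   spikes.tsv       unit_id time_s
#   units.tsv        unit_id label                        (optional)
#   light_pulses.tsv block_id power_mw freq_hz onset_s width_ms (optional)
#   waveforms.tsv    unit_id condition channel sample value     (optional)
#   session.json     session_id animal_id genotype track_length session_end
#
# Times are seconds (float), positions cm.  The format is self-defined: it
# is not a reader for any published data deposit.

trial_tasks <- c("memory", "no_cue_no_choice", "cue_no_choice")

#' Construct a session bundle
#'
#' Assembles the in-memory representation of one recording session: a trial
#' table, linearized position tracking, spike times per unit and optional
#' unit labels, light-pulse events and mean waveforms.
#'
#' @param trials Tibble with columns `trial_id`, `task`, `trajectory`
#'   (`"left"`/`"right"`), `accuracy` (`"correct"`/`"error"`),
#'   `start_time_s`, `cue_onset_s` (NA when absent), `delay_offset_s`,
#'   `first_lick_s`, `end_time_s`.
#' @param tracking Tibble with `trial_id`, `time_s`, `pos_cm` (linearized
#'   position along the lap path).
#' @param spikes Tibble with `unit_id`, `time_s`.
#' @param units Optional tibble with `unit_id`, `label`.
#' @param light_pulses Optional tibble with `block_id`, `power_mw`,
#'   `freq_hz`, `onset_s`, `width_ms`.
#' @param waveforms Optional tibble with `unit_id`, `condition`
#'   (`"spont"`/`"light"`), `channel`, `sample`, `value`.
#' @param meta Named list; recognised entries `session_id`, `animal_id`,
#'   `genotype` (`"DAT-Cre"`, `"VGAT-Cre"` or `"unknown"`), `track_length`
#'   (cm, default 150) and `session_end` (s).
#' @return An object of class `session_bundle`.
#' @seealso [read_session()], [write_session()], [validate_session()]
#' @export
session_bundle <- function(trials, tracking, spikes, units = NULL,
                           light_pulses = NULL, waveforms = NULL,
                           meta = list()) {
  need <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    if (length(missing) > 0) {
      abort(sprintf("%s is missing column(s): %s", what,
                    paste(missing, collapse = ", ")))
    }
  }
  trials <- tibble::as_tibble(trials)
  tracking <- tibble::as_tibble(tracking)
  spikes <- tibble::as_tibble(spikes)
  need(trials, c("trial_id", "task", "trajectory", "accuracy",
                 "start_time_s", "cue_onset_s", "delay_offset_s",
                 "first_lick_s", "end_time_s"), "trials")
  need(tracking, c("trial_id", "time_s", "pos_cm"), "tracking")
  need(spikes, c("unit_id", "time_s"), "spikes")
  if (!is.null(units)) need(units <- tibble::as_tibble(units),
                            c("unit_id", "label"), "units")
  if (!is.null(light_pulses)) {
    need(light_pulses <- tibble::as_tibble(light_pulses),
         c("block_id", "power_mw", "freq_hz", "onset_s", "width_ms"),
         "light_pulses")
  }
  if (!is.null(waveforms)) {
    need(waveforms <- tibble::as_tibble(waveforms),
         c("unit_id", "condition", "channel", "sample", "value"),
         "waveforms")
  }
  meta$track_length <- meta$track_length %||% 150
  meta$session_id <- meta$session_id %||% "session"
  meta$animal_id <- meta$animal_id %||% "unknown"
  meta$genotype <- meta$genotype %||% "unknown"
  structure(
    list(trials = trials, tracking = tracking, spikes = spikes,
         units = units, light_pulses = light_pulses, waveforms = waveforms,
         meta = meta),
    class = "session_bundle"
  )
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %s (%s, %s)\n", x$meta$session_id,
              x$meta$animal_id, x$meta$genotype))
  cat(sprintf("  %d trials, %d tracking samples, %d spikes in %d units\n",
              nrow(x$trials), nrow(x$tracking), nrow(x$spikes),
              length(unique(x$spikes$unit_id))))
  if (!is.null(x$light_pulses)) {
    cat(sprintf("  %d light pulses in %d blocks\n", nrow(x$light_pulses),
                length(unique(x$light_pulses$block_id))))
  }
  invisible(x)
}

# End of the session span used to validate spike times.
session_end_time <- function(bundle) {
  ends <- c(bundle$trials$end_time_s, bundle$tracking$time_s)
  if (!is.null(bundle$light_pulses)) {
    ends <- c(ends, bundle$light_pulses$onset_s +
                bundle$light_pulses$width_ms / 1000)
  }
  bundle$meta$session_end %||% (max(ends) + 1)
}

#' Validate a session bundle
#'
#' Checks the bundle invariants and reports violations instead of raising:
#' unique trial ids, tracking rows referencing known trials with strictly
#' increasing times, event ordering within trials (`start < first lick <
#' end`), absent cue onset for no-cue trials, positions within the track,
#' sorted spike times inside the session span.
#'
#' @param bundle A [session_bundle()].
#' @return A tibble with columns `entity`, `rule`, `detail`; zero rows iff
#'   the bundle is valid.
#' @export
validate_session <- function(bundle) {
  v <- list()
  add <- function(entity, rule, detail) {
    v[[length(v) + 1]] <<- tibble::tibble(entity = entity, rule = rule,
                                          detail = detail)
  }
  tr <- bundle$trials
  if (anyDuplicated(tr$trial_id)) {
    add("trials", "unique_trial_ids",
        paste("duplicated trial_id:",
              paste(unique(tr$trial_id[duplicated(tr$trial_id)]),
                    collapse = ", ")))
  }
  bad_task <- !tr$task %in% trial_tasks
  if (any(bad_task)) {
    add(paste0("trial ", tr$trial_id[bad_task][1]), "known_task",
        paste("unknown task", tr$task[bad_task][1]))
  }
  for (i in seq_len(nrow(tr))) {
    ti <- tr[i, ]
    ent <- paste0("trial ", ti$trial_id)
    if (!(ti$start_time_s < ti$first_lick_s &&
            ti$first_lick_s < ti$end_time_s)) {
      add(ent, "event_order", "requires start < first lick < end")
    }
    if (identical(ti$task, "no_cue_no_choice") && is.finite(ti$cue_onset_s)) {
      add(ent, "no_cue_task_has_cue",
          "cue_onset_s must be absent in the no-cue-no-choice task")
    }
  }
  tk <- bundle$tracking
  orphan <- setdiff(unique(tk$trial_id), tr$trial_id)
  if (length(orphan) > 0) {
    add("tracking", "known_trial_ids",
        paste("unknown trial_id:", paste(orphan, collapse = ", ")))
  }
  for (id in unique(tk$trial_id)) {
    tt <- tk$time_s[tk$trial_id == id]
    if (any(diff(tt) <= 0)) {
      add(paste0("trial ", id), "tracking_time_increasing",
          "tracking times must be strictly increasing within a trial")
    }
  }
  L <- bundle$meta$track_length
  if (any(tk$pos_cm < -1e-9 | tk$pos_cm > L + 1e-9)) {
    add("tracking", "position_range",
        sprintf("positions must lie in [0, %g] cm", L))
  }
  end_t <- session_end_time(bundle)
  sp <- bundle$spikes
  for (u in unique(sp$unit_id)) {
    st <- sp$time_s[sp$unit_id == u]
    ent <- paste0("unit ", u)
    if (is.unsorted(st)) {
      add(ent, "spikes_sorted", "spike times must be sorted ascending")
    }
    if (any(st < -1e-9 | st > end_t + 1e-9)) {
      add(ent, "spikes_in_span",
          sprintf("spike times must fall within [0, %g] s", end_t))
    }
  }
  if (length(v) == 0) {
    return(tibble::tibble(entity = character(), rule = character(),
                          detail = character()))
  }
  dplyr::bind_rows(v)
}

#' Write a session bundle to a directory
#'
#' Serialises the bundle to tab-separated UTF-8 tables plus a JSON metadata
#' file.  Output is byte-deterministic for identical input.
#'
#' @param bundle A valid [session_bundle()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(bundle, path) {
  viol <- validate_session(bundle)
  if (nrow(viol) > 0) {
    abort(sprintf("refusing to write an invalid bundle (%d violation(s); first: %s / %s)",
                  nrow(viol), viol$entity[1], viol$rule[1]))
  }
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create session directory '%s'", path))
  }
  w <- function(df, file) {
    readr::write_tsv(df, file.path(path, file), progress = FALSE)
  }
  w(bundle$trials, "trials.tsv")
  w(bundle$tracking, "tracking.tsv")
  w(bundle$spikes, "spikes.tsv")
  if (!is.null(bundle$units)) w(bundle$units, "units.tsv")
  if (!is.null(bundle$light_pulses)) w(bundle$light_pulses, "light_pulses.tsv")
  if (!is.null(bundle$waveforms)) w(bundle$waveforms, "waveforms.tsv")
  jsonlite::write_json(bundle$meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a session bundle from a directory
#'
#' Reads the tables written by [write_session()] and validates all bundle
#' invariants; any violation is an error naming the offending trial or
#' unit.
#'
#' @param path Session directory.
#' @return A validated [session_bundle()].
#' @export
read_session <- function(path) {
  mandatory <- c("trials.tsv", "tracking.tsv", "spikes.tsv")
  for (f in mandatory) {
    if (!file.exists(file.path(path, f))) {
      abort(sprintf("session directory '%s' is missing mandatory file '%s'",
                    path, f))
    }
  }
  r <- function(file, types) {
    readr::read_tsv(file.path(path, file), col_types = types,
                    progress = FALSE)
  }
  trials <- r("trials.tsv", readr::cols(
    trial_id = "i", task = "c", trajectory = "c", accuracy = "c",
    start_time_s = "d", cue_onset_s = "d", delay_offset_s = "d",
    first_lick_s = "d", end_time_s = "d"))
  tracking <- r("tracking.tsv",
                readr::cols(trial_id = "i", time_s = "d", pos_cm = "d"))
  spikes <- r("spikes.tsv", readr::cols(unit_id = "i", time_s = "d"))
  units <- light <- wf <- NULL
  if (file.exists(file.path(path, "units.tsv"))) {
    units <- r("units.tsv", readr::cols(unit_id = "i", label = "c"))
  }
  if (file.exists(file.path(path, "light_pulses.tsv"))) {
    light <- r("light_pulses.tsv", readr::cols(
      block_id = "i", power_mw = "d", freq_hz = "d", onset_s = "d",
      width_ms = "d"))
  }
  if (file.exists(file.path(path, "waveforms.tsv"))) {
    wf <- r("waveforms.tsv", readr::cols(
      unit_id = "i", condition = "c", channel = "i", sample = "i",
      value = "d"))
  }
  meta <- list()
  if (file.exists(file.path(path, "session.json"))) {
    meta <- jsonlite::read_json(file.path(path, "session.json"),
                                simplifyVector = TRUE)
  }
  bundle <- session_bundle(trials, tracking, spikes, units, light, wf, meta)
  viol <- validate_session(bundle)
  if (nrow(viol) > 0) {
    abort(sprintf(
      "session '%s' violates %d invariant(s); first: %s: %s (%s)",
      path, nrow(viol), viol$entity[1], viol$rule[1], viol$detail[1]))
  }
  bundle
}

# Waveform matrix (channels x samples) for one unit/condition, or NULL.
waveform_matrix <- function(bundle, unit, condition) {
  wf <- bundle$waveforms
  if (is.null(wf)) return(NULL)
  sub <- wf[wf$unit_id == unit & wf$condition == condition, ]
  if (nrow(sub) == 0) return(NULL)
  sub <- sub[order(sub$channel, sub$sample), ]
  nch <- length(unique(sub$channel))
  matrix(sub$value, nrow = nch, byrow = TRUE)
}
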