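#' Maze section names
#'
#' The four spatial sections of the linearized T-maze track.  The reward
#' epoch is not a spatial section: it is defined in the time domain
#' (first second of consumption) and handled by the reward-analysis
#' functions.
#'
#' @export
maze_sections <- c("start", "cue", "delay", "side_arms")

#' Assign position bins to maze sections
#'
#' Maps each of `n_bins` equal-width position bins to a maze section by the
#' position of its bin centre, in cm.  Default boundaries follow the task
#' layout: start 0-50 cm, visual cue 50-80 cm, memory delay 80-120 cm,
#' side arms 120-150 cm.
#'
#' @param boundaries Increasing upper boundaries of the sections, in cm;
#'   the last must equal `track_length`.
#' @param track_length Track length in cm.
#' @param n_bins Number of position bins.
#' @return A tibble with columns `bin`, `pos_cm` (bin centre) and `section`
#'   (factor with levels [maze_sections]).
#' @examples
#' assign_sections() |> dplyr::count(section)
#' @export
assign_sections <- function(boundaries = c(50, 80, 120, 150),
                            track_length = 150, n_bins = 100) {
  if (any(diff(boundaries) <= 0)) {
    abort("section boundaries must be strictly increasing")
  }
  if (length(boundaries) != length(maze_sections)) {
    abort(sprintf("expected %d section boundaries", length(maze_sections)))
  }
  if (abs(boundaries[length(boundaries)] - track_length) > 1e-9) {
    abort("last section boundary must equal the track length")
  }
  centre <- (seq_len(n_bins) - 0.5) / n_bins * track_length
  idx <- findInterval(centre, boundaries, left.open = TRUE) + 1L
  tibble::tibble(
    bin = seq_len(n_bins),
    pos_cm = centre,
    section = factor(maze_sections[idx], levels = maze_sections)
  )
}

# Integer bin vector for a section (or 1..n_bins for "all").
section_bins <- function(section, boundaries = c(50, 80, 120, 150),
                         track_length = 150, n_bins = 100) {
  map <- assign_sections(boundaries, track_length, n_bins)
  if (identical(section, "all")) return(map$bin)
  if (!section %in% maze_sections) {
    abort(sprintf("unknown maze section '%s'", section))
  }
  map$bin[map$section == section]
}
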