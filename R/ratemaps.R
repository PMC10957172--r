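# Occupancy-normalized average firing-rate maps and population statistics.
#
# The estimator is the trial-averaged occupancy-normalized rate
#   lambda(x) = (1/K) * sum_k n_k(x) / t_k(x)
# over the K trials with occupancy at bin x; bins never occupied are
# flagged missing (K_used = 0).  Smoothing uses the unit-sum Gaussian
# kernel (default sigma 5 bins, half-width 10).

#' Occupancy-normalized average rate maps
#'
#' Computes, for each unit and trajectory, the per-bin average of the
#' per-trial rates `n_k(x) / t_k(x)` over trials that occupied the bin,
#' and its Gaussian-smoothed version.
#'
#' @param lin A `lin_session` tibble from [linearize_session()].
#' @param sigma,half_width Smoothing-kernel parameters, in bins.
#' @param task Task(s) whose trials enter the maps.
#' @param correct_only Use correct trials only (the default, matching the
#'   trajectory analyses).
#' @return A tibble of class `rate_map` with columns `unit_id`,
#'   `trajectory`, `bin`, `rate`, `rate_smooth`, `k_used`.  Bins with
#'   `k_used = 0` carry `NA` rates.
#' @export
average_rate_map <- function(lin, sigma = 5, half_width = 10,
                             task = "memory", correct_only = TRUE) {
  n_bins <- attr(lin, "n_bins") %||% max(lin$bin)
  lin <- filter_lin(lin, task, correct_only)
  if (nrow(lin) == 0) abort("no trials left after filtering")
  out <- lin |>
    dplyr::group_by(.data$unit_id, .data$trajectory, .data$bin) |>
    dplyr::summarise(
      k_used = sum(.data$occupancy_s > 0),
      rate = ifelse(k_used > 0,
                    mean((.data$n_spikes / .data$occupancy_s)[
                      .data$occupancy_s > 0]),
                    NA_real_),
      .groups = "drop_last") |>
    dplyr::mutate(rate_smooth = smooth_rate(.data$rate, sigma, half_width,
                                            keep_interpolated = FALSE)) |>
    dplyr::ungroup() |>
    dplyr::select("unit_id", "trajectory", "bin", "rate", "rate_smooth",
                  "k_used")
  attr(out, "n_bins") <- n_bins
  attr(out, "sigma") <- sigma
  attr(out, "half_width") <- half_width
  class(out) <- c("rate_map", class(out))
  out
}

#' Preferred/non-preferred trajectory heatmaps
#'
#' For each unit, the preferred trajectory is the one with the greater
#' maximum smoothed rate; both trajectory responses are divided by that
#' maximum (so the preferred row peaks at exactly 1 and the non-preferred
#' row is scaled by the same constant).  Rows are ordered by the position
#' of the preferred-row maximum, ties broken by unit id.  Units whose
#' smoothed maps are all zero are excluded and reported in the `excluded`
#' attribute.
#'
#' @param rmap A `rate_map` tibble from [average_rate_map()].
#' @return A tibble of class `heatmap_set` with columns `unit_id`,
#'   `preferred_side`, `row`, `bin`, `preferred`, `nonpreferred`.
#' @export
build_heatmaps <- function(rmap) {
  units <- split(rmap, rmap$unit_id)
  rows <- lapply(units, function(u) {
    sides <- split(u, u$trajectory)
    if (length(sides) < 2) return(NULL)
    mx <- vapply(sides, function(s) max(s$rate_smooth, na.rm = TRUE),
                 numeric(1))
    if (max(mx) <= 0) return(NULL)
    pref <- names(sides)[which.max(mx)]
    norm <- max(mx)
    p <- sides[[pref]]
    np <- sides[[setdiff(names(sides), pref)[1]]]
    tibble::tibble(
      unit_id = u$unit_id[1],
      preferred_side = pref,
      argmax = p$bin[which.max(p$rate_smooth)],
      bin = p$bin,
      preferred = p$rate_smooth / norm,
      nonpreferred = np$rate_smooth[match(p$bin, np$bin)] / norm)
  })
  excluded <- names(units)[vapply(rows, is.null, logical(1))]
  out <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out) == 0) abort("no unit has a nonzero smoothed rate map")
  ord <- out |>
    dplyr::distinct(.data$unit_id, .data$argmax) |>
    dplyr::arrange(.data$argmax, .data$unit_id)
  ord$row <- seq_len(nrow(ord))
  out <- out |>
    dplyr::left_join(ord[, c("unit_id", "row")], by = "unit_id") |>
    dplyr::select("unit_id", "preferred_side", "row", "bin", "preferred",
                  "nonpreferred") |>
    dplyr::arrange(.data$row, .data$bin)
  attr(out, "excluded") <- as.integer(excluded)
  class(out) <- c("heatmap_set", class(out))
  out
}

#' Population position statistics
#'
#' Computes (a) the population mean rate and its standard error per bin
#' (optionally per unit class) and (b) a per-unit ordinary least-squares
#' regression of the (smoothed) trial-averaged rate on maze position over
#' the requested range, expressed as the total rate change across that
#' range, with a one-sample t-test of the changes against zero.
#'
#' @param rmap A `rate_map` tibble.
#' @param range A maze section name (`"start"`, `"cue"`, `"delay"`,
#'   `"side_arms"`) or `"all"` for the full track.
#' @param classes Optional tibble (`unit_id`, `class`) to group the
#'   population profile and tests.
#' @param use `"smooth"` (default) or `"raw"` rates.
#' @param boundaries,track_length Section geometry (cm).
#' @return A list of class `population_stats` with tibbles `profile`
#'   (bin-wise mean and SEM), `per_unit` (rate change per unit) and `test`
#'   (one row per class: mean change, SEM, t, df, p).
#' @export
population_position_stats <- function(rmap, range = "all", classes = NULL,
                                      use = c("smooth", "raw"),
                                      boundaries = c(50, 80, 120, 150),
                                      track_length = 150) {
  use <- match.arg(use)
  n_bins <- attr(rmap, "n_bins") %||% max(rmap$bin)
  if (length(unique(rmap$unit_id)) < 2) abort("need at least two units")
  val <- if (use == "smooth") rmap$rate_smooth else rmap$rate
  df <- dplyr::mutate(tibble::as_tibble(rmap), value = val)
  if (is.null(classes)) {
    classes <- tibble::tibble(unit_id = unique(df$unit_id), class = "all")
  }
  df <- dplyr::left_join(df, classes, by = "unit_id")
  bins <- section_bins(range, boundaries, track_length, n_bins)

  # per-unit map averaged over trajectories, then over the population
  per_unit_map <- df |>
    dplyr::group_by(.data$class, .data$unit_id, .data$bin) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  profile <- per_unit_map |>
    dplyr::group_by(.data$class, .data$bin) |>
    dplyr::summarise(
      mean_rate = mean(.data$value, na.rm = TRUE),
      sem = sd(.data$value, na.rm = TRUE) /
        sqrt(sum(is.finite(.data$value))),
      .groups = "drop")

  # per-unit OLS of rate on position over the range, one observation per
  # bin of the trial-averaged map; slope scaled to total change over range
  per_unit <- per_unit_map |>
    dplyr::filter(.data$bin %in% bins) |>
    dplyr::group_by(.data$class, .data$unit_id) |>
    dplyr::summarise(rate_change = {
      x <- (.data$bin - min(bins)) / max(1L, (max(bins) - min(bins)))
      y <- .data$value
      ok <- is.finite(y)
      if (sum(ok) < 2 || var(x[ok]) == 0) NA_real_
      else unname(stats::coef(stats::lm.fit(cbind(1, x[ok]),
                                            y[ok]))[2])
    }, .groups = "drop")

  test <- per_unit |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise({
      ch <- .data$rate_change[is.finite(.data$rate_change)]
      if (length(ch) < 2) abort("need at least two units for the t-test")
      if (near_constant(ch)) {
        tibble::tibble(mean_change = mean(ch),
                       sem = 0, t = if (near_zero(mean(ch))) 0 else
                         Inf * sign(mean(ch)),
                       df = length(ch) - 1,
                       p = if (near_zero(mean(ch))) 1 else 0, n = length(ch))
      } else {
        tt <- t.test(ch)
        tibble::tibble(mean_change = mean(ch),
                       sem = sd(ch) / sqrt(length(ch)),
                       t = unname(tt$statistic), df = unname(tt$parameter),
                       p = tt$p.value, n = length(ch))
      }
    }, .groups = "drop")

  structure(list(profile = profile, per_unit = per_unit, test = test,
                 range = range, use = use),
            class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf("<population_stats> range '%s' (%s rates)\n", x$range, x$use))
  print(x$test)
  invisible(x)
}

#' @export
tidy.population_stats <- function(x, ...) x$per_unit

#' @export
glance.population_stats <- function(x, ...) x$test
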