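# Trajectory-specific coding via label permutation.
#
# For each unit the observed statistic is the per-bin difference between
# the smoothed left and right occupancy-normalized average rates,
# D0(x) = lambda_left(x) - lambda_right(x).  Trajectory labels are then
# randomly reassigned across trials (preserving the left/right counts) and
# the smoothed difference recomputed, giving a pointwise two-sided
# permutation p-value with the +1 correction.  A bin is flagged
# significant when its p-value is below alpha AND it belongs to a run of
# at least `min_run` consecutive sub-alpha bins — a short-run cluster
# criterion that controls the multiplicity of 100 pointwise tests.

perm_side_means <- function(sel, rate0, occ_ind) {
  # sel: perms x trials 0/1 selector; returns perms x bins mean rate
  num <- sel %*% rate0
  den <- sel %*% occ_ind
  num / ifelse(den > 0, den, NA_real_)
}

#' Observed left-right rate difference
#'
#' @param lin A `lin_session` tibble.
#' @param sigma,half_width Smoothing parameters (bins).
#' @param task,correct_only Trial filter (defaults: correct memory trials).
#' @return Tibble with `unit_id`, `bin`, `d0` (Hz).
#' @export
observed_difference <- function(lin, sigma = 5, half_width = 10,
                                task = "memory", correct_only = TRUE) {
  n_bins <- attr(lin, "n_bins") %||% max(lin$bin)
  lin <- filter_lin(lin, task, correct_only)
  dplyr::bind_rows(lapply(split(lin, lin$unit_id), function(u) {
    m <- lin_matrices(u, n_bins)
    for (side in c("left", "right")) {
      if (sum(m$trials$trajectory == side) < 2) {
        abort(sprintf("unit %s: need at least 2 correct trials per side",
                      u$unit_id[1]))
      }
    }
    rate0 <- ifelse(is.finite(m$rate), m$rate, 0)
    occ <- (m$occupancy > 0) * 1
    sel_l <- matrix(as.numeric(m$trials$trajectory == "left"), 1)
    sel_r <- matrix(as.numeric(m$trials$trajectory == "right"), 1)
    ml <- smooth_rows(perm_side_means(sel_l, rate0, occ), sigma, half_width)
    mr <- smooth_rows(perm_side_means(sel_r, rate0, occ), sigma, half_width)
    tibble::tibble(unit_id = u$unit_id[1], bin = seq_len(n_bins),
                   d0 = as.numeric(ml - mr))
  }))
}

#' Permutation test for trajectory-specific firing
#'
#' @param lin A `lin_session` tibble from [linearize_session()].
#' @param n_perms Number of label permutations (>= 200).
#' @param alpha Pointwise significance level.
#' @param min_run Minimum number of consecutive sub-alpha bins for a bin to
#'   be flagged (cluster criterion; `1` disables it).
#' @param sigma,half_width Smoothing parameters (bins).
#' @param seed Seed for the label shuffles (mandatory for reproducibility).
#' @param task,correct_only Trial filter (defaults: correct memory trials).
#' @param boundaries,track_length Section geometry (cm).
#' @return A list of class `perm_test`: `points` (tibble: `unit_id`,
#'   `bin`, `section`, `d0`, `p`, `sig`), `units` (tibble: `unit_id`,
#'   `section`, `n_sig_points`, `sig`) and the parameters used.  Units
#'   with no rate anywhere get an all-false mask.
#' @export
permutation_test <- function(lin, n_perms = 1000, alpha = 0.05,
                             min_run = 11, sigma = 5, half_width = 10,
                             seed = 1L, task = "memory",
                             correct_only = TRUE,
                             boundaries = c(50, 80, 120, 150),
                             track_length = attr(lin, "track_length") %||%
                               150) {
  if (n_perms < 200) abort("need at least 200 permutations")
  n_bins <- attr(lin, "n_bins") %||% max(lin$bin)
  lin <- filter_lin(lin, task, correct_only)
  secmap <- assign_sections(boundaries, track_length, n_bins)
  units <- sort(unique(lin$unit_id))
  set.seed(seed)
  by_unit <- split(lin, lin$unit_id)[as.character(units)]

  points <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- by_unit[[i]]
    m <- lin_matrices(u, n_bins)
    lab <- m$trials$trajectory
    if (sum(lab == "left") < 2 || sum(lab == "right") < 2) {
      abort(sprintf("unit %s: need at least 2 correct trials per side",
                    units[i]))
    }
    rate0 <- ifelse(is.finite(m$rate), m$rate, 0)
    occ <- (m$occupancy > 0) * 1
    if (all(rate0 == 0)) {        # degenerate all-zero unit
      points[[i]] <- tibble::tibble(
        unit_id = units[i], bin = seq_len(n_bins),
        d0 = 0, p = 1, sig = FALSE)
      next
    }
    k <- length(lab)
    n_left <- sum(lab == "left")
    obs_l <- matrix(as.numeric(lab == "left"), 1)
    # permutations preserve the left/right counts
    sel_l <- matrix(0, n_perms, k)
    for (j in seq_len(n_perms)) {
      sel_l[j, sample.int(k, n_left)] <- 1
    }
    sel <- rbind(obs_l, sel_l)
    ml <- smooth_rows(perm_side_means(sel, rate0, occ), sigma, half_width)
    mr <- smooth_rows(perm_side_means(1 - sel, rate0, occ), sigma,
                      half_width)
    d <- ml - mr
    d0 <- d[1, ]
    dp <- abs(d[-1, , drop = FALSE])
    exceed <- colSums(dp >= matrix(abs(d0), n_perms, n_bins, byrow = TRUE))
    p <- (1 + exceed) / (n_perms + 1)
    below <- p < alpha
    runs <- rle(below)
    keep <- rep(runs$values & runs$lengths >= min_run, runs$lengths)
    points[[i]] <- tibble::tibble(
      unit_id = units[i], bin = seq_len(n_bins), d0 = d0, p = p,
      sig = below & keep)
  }
  points <- dplyr::bind_rows(points) |>
    dplyr::left_join(secmap[, c("bin", "section")], by = "bin") |>
    dplyr::select("unit_id", "bin", "section", "d0", "p", "sig")

  unit_summary <- points |>
    dplyr::group_by(.data$unit_id, .data$section) |>
    dplyr::summarise(n_sig_points = sum(.data$sig), .groups = "drop") |>
    dplyr::mutate(sig = .data$n_sig_points >= 1)

  structure(list(points = points, units = unit_summary,
                 params = list(n_perms = n_perms, alpha = alpha,
                               min_run = min_run, sigma = sigma,
                               half_width = half_width, seed = seed)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  n_units <- length(unique(x$points$unit_id))
  cat(sprintf("<perm_test> %d unit(s), %d permutations, alpha %.3g, min run %d\n",
              n_units, x$params$n_perms, x$params$alpha, x$params$min_run))
  print(x$units |>
          dplyr::group_by(.data$section) |>
          dplyr::summarise(n_sig = sum(.data$sig), .groups = "drop"))
  invisible(x)
}

#' @export
tidy.perm_test <- function(x, type = c("points", "units"), ...) {
  type <- match.arg(type)
  x[[type]]
}

#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(
    n_units = length(unique(x$points$unit_id)),
    n_perms = x$params$n_perms, alpha = x$params$alpha,
    min_run = x$params$min_run, seed = x$params$seed)
}

#' Trajectory preference in one maze section
#'
#' For units flagged significant in `section`, the preferred side is the
#' sign of the mean observed difference over that section's significant
#' bins (`d0 > 0` means left-preferring); unflagged units are `"ns"`.
#'
#' @param perm A `perm_test` object.
#' @param section Maze section name.
#' @return Tibble with `unit_id`, `preference` (`"left"`, `"right"`,
#'   `"ns"`).
#' @export
section_preference <- function(perm, section = "delay") {
  pts <- perm$points[perm$points$section == section, ]
  pts |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(preference = {
      s <- .data$sig
      if (!any(s)) "ns" else if (mean(.data$d0[s]) > 0) "left" else "right"
    }, .groups = "drop")
}

#' Compare significant-point counts between two tasks
#'
#' Paired t-test, across units recorded in both tasks, of the number of
#' position points with a significant left-right rate difference in one
#' maze section.
#'
#' @param units_a,units_b `units` tibbles from two [permutation_test()]
#'   runs (e.g. memory task versus a control task) on the same units.
#' @param section Maze section to compare.
#' @return One-row tibble with per-task means and SDs, `t`, `df`, `p`,
#'   flagged-unit counts and a `degenerate` flag (zero-variance
#'   differences).
#' @export
task_point_comparison <- function(units_a, units_b, section = "delay") {
  a <- units_a[units_a$section == section, ]
  b <- units_b[units_b$section == section, ]
  common <- intersect(a$unit_id, b$unit_id)
  if (length(common) < 2) abort("need at least 2 units present in both tasks")
  a <- a[match(common, a$unit_id), ]
  b <- b[match(common, b$unit_id), ]
  d <- a$n_sig_points - b$n_sig_points
  base <- tibble::tibble(
    section = section, n_units = length(common),
    mean_a = mean(a$n_sig_points), sd_a = sd(a$n_sig_points),
    mean_b = mean(b$n_sig_points), sd_b = sd(b$n_sig_points),
    n_flagged_a = sum(a$sig), n_flagged_b = sum(b$sig))
  if (near_constant(d)) {
    return(dplyr::mutate(base,
                         t = if (near_zero(d)) 0 else Inf * sign(d[1]),
                         df = length(common) - 1,
                         p = if (near_zero(d)) 1 else 0, degenerate = TRUE))
  }
  tt <- t.test(a$n_sig_points, b$n_sig_points, paired = TRUE)
  dplyr::mutate(base, t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, degenerate = FALSE)
}
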