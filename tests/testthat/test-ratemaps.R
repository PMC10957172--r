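test_that("the occupancy-normalized estimator is forced by its definition", {
  # single trial: n = 2 spikes, t = 0.5 s in a bin -> 4 Hz
  lt1 <- tibble::tibble(unit_id = 1L, trial_id = 1L, trial_index = 1L,
                        task = "memory", trajectory = "left",
                        accuracy = "correct", bin = 1:2,
                        n_spikes = c(2L, 0L), occupancy_s = c(0.5, 0.5),
                        speed_cms = 3)
  # second trial: n = 3, t = 1.0 -> 3 Hz; mean of (4, wait per-bin) ...
  lt2 <- dplyr::mutate(lt1, trial_id = 2L, trial_index = 2L,
                       n_spikes = c(3L, 0L), occupancy_s = c(1, 1))
  lin <- dplyr::bind_rows(lt1, lt2)
  attr(lin, "n_bins") <- 2
  class(lin) <- c("lin_session", class(lin))
  rm1 <- average_rate_map(lt1 |> (\(x) {
    attr(x, "n_bins") <- 2; class(x) <- c("lin_session", class(x)); x
  })(), sigma = 0.5, half_width = 1)
  expect_equal(rm1$rate[rm1$bin == 1], 4)
  rm <- average_rate_map(lin, sigma = 0.5, half_width = 1)
  # trials contribute n/t each: (2/0.5 + 3/1) / 2 = 3.5
  expect_equal(rm$rate[rm$bin == 1], 3.5)
  expect_equal(rm$k_used[rm$bin == 1], 2L)
})

test_that("estimator is unbiased for a constant-rate unit with variable speed", {
  truths <- unit_truth(10)
  b <- make_session(truths, n_trials = 200, seed = 17)
  lin <- linearize_session(b)
  rm <- average_rate_map(lin, correct_only = FALSE)
  # per-bin estimates hover around 10 Hz; grand mean much tighter
  expect_lt(abs(mean(rm$rate, na.rm = TRUE) - 10), 0.3)
  # trial reordering leaves the map unchanged
  lin_rev <- lin[rev(seq_len(nrow(lin))), ]
  attr(lin_rev, "n_bins") <- attr(lin, "n_bins")
  class(lin_rev) <- class(lin)
  rm2 <- average_rate_map(lin_rev, correct_only = FALSE)
  expect_equal(rm2$rate, rm$rate)

  # uniform-occupancy coincidence: mean of n/t equals pooled n over pooled t
  # when every trial has identical occupancy in a bin
  lt <- tibble::tibble(unit_id = 1L, trial_id = 1:3, trial_index = 1:3,
                       task = "memory", trajectory = "left",
                       accuracy = "correct", bin = 1L,
                       n_spikes = c(1L, 2L, 3L), occupancy_s = 0.4,
                       speed_cms = 3.75)
  attr(lt, "n_bins") <- 1
  class(lt) <- c("lin_session", class(lt))
  rm3 <- suppressWarnings(average_rate_map(lt, sigma = 1, half_width = 0.5))
  expect_equal(rm3$rate, sum(1:3) / (3 * 0.4))
})

test_that("gaussian smoothing preserves constants, mass, and the kernel shape", {
  k <- gaussian_kernel(5, 10)
  expect_equal(sum(k), 1)
  expect_length(k, 21)

  expect_equal(smooth_rate(rep(3.3, 100)), rep(3.3, 100))

  delta <- c(rep(0, 49), 1, rep(0, 50))
  sm <- smooth_rate(delta)
  expect_equal(sm[40:60], k, tolerance = 1e-12)

  x <- withr::with_seed(5, runif(100, 0, 20))
  expect_lt(abs(sum(smooth_rate(x)) - sum(x)) / sum(x), 0.02)

  # missing bins are interpolated then re-flagged
  x[30] <- NA
  sm2 <- smooth_rate(x)
  expect_true(is.na(sm2[30]))
  expect_false(anyNA(sm2[-30]))
  expect_error(smooth_rate(rep(NA_real_, 10)), "all-missing")
})

test_that("heatmaps normalize by the preferred maximum and order by peak", {
  mk <- function(unit, left_peak, right_peak, argmax) {
    shape <- exp(-((1:100 - argmax)^2) / 50)
    dplyr::bind_rows(
      tibble::tibble(unit_id = unit, trajectory = "left", bin = 1:100,
                     rate = left_peak * shape,
                     rate_smooth = left_peak * shape, k_used = 10L),
      tibble::tibble(unit_id = unit, trajectory = "right", bin = 1:100,
                     rate = right_peak * shape,
                     rate_smooth = right_peak * shape, k_used = 10L))
  }
  rmap <- dplyr::bind_rows(mk(1, 10, 5, 90), mk(2, 4, 8, 10))
  class(rmap) <- c("rate_map", class(rmap))
  hm <- build_heatmaps(rmap)
  u1 <- hm[hm$unit_id == 1, ]
  expect_equal(unique(u1$preferred_side), "left")
  expect_equal(max(u1$preferred), 1)
  expect_equal(max(u1$nonpreferred), 0.5)
  # row order: unit 2 peaks at bin 10 -> first row
  expect_equal(unique(hm$row[hm$unit_id == 2]), 1)
  expect_equal(unique(hm$row[hm$unit_id == 1]), 2)
})

test_that("planted field centres reappear along the heatmap diagonal", {
  centers <- seq(10, 140, length.out = 12)
  truths <- dplyr::bind_rows(lapply(centers, function(cc)
    unit_truth(8, centers = cc, widths = 12, gains = 3)))
  b <- make_session(truths, n_trials = 60, seed = 23)
  lin <- linearize_session(b)
  hm <- build_heatmaps(average_rate_map(lin))
  peak <- hm |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(argmax = .data$bin[which.max(.data$preferred)])
  expect_gt(cor(peak$argmax, centers[peak$unit_id] / 1.5), 0.95)
})

test_that("population position statistics recover ramps and flat maps", {
  mkmap <- function(unit, rates) {
    dplyr::bind_rows(lapply(c("left", "right"), function(s)
      tibble::tibble(unit_id = unit, trajectory = s, bin = 1:100,
                     rate = rates, rate_smooth = rates, k_used = 10L)))
  }
  flat <- dplyr::bind_rows(mkmap(1, rep(5, 100)), mkmap(2, rep(7, 100)))
  class(flat) <- c("rate_map", class(flat))
  ps <- population_position_stats(flat)
  expect_equal(ps$per_unit$rate_change, c(0, 0))
  expect_equal(ps$test$t, 0)

  ramp <- dplyr::bind_rows(mkmap(1, seq(0, 10, length.out = 100)),
                           mkmap(2, rep(5, 100)))
  class(ramp) <- c("rate_map", class(ramp))
  ps2 <- population_position_stats(ramp)
  expect_equal(ps2$per_unit$rate_change[ps2$per_unit$unit_id == 1], 10,
               tolerance = 1e-9)

  # closed-form one-sample t oracle on a planted mixture of changes
  changes <- c(rep(4, 6), rep(0, 6))
  maps <- dplyr::bind_rows(lapply(seq_along(changes), function(i)
    mkmap(i, seq(5, 5 + changes[i], length.out = 100))))
  class(maps) <- c("rate_map", class(maps))
  ps3 <- population_position_stats(maps)
  t_oracle <- mean(changes) / (sd(changes) / sqrt(length(changes)))
  expect_equal(ps3$test$t, t_oracle, tolerance = 1e-9)
  expect_equal(ps3$test$mean_change, 2, tolerance = 1e-9)
})
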