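# Build a lin_session tibble directly from per-trial rate matrices so the
# permutation machinery can be checked against hand-computable cases.
lin_from_counts <- function(counts, occupancy, trajectory) {
  k <- nrow(counts); nb <- ncol(counts)
  out <- tibble::tibble(
    unit_id = 1L,
    trial_id = rep(seq_len(k), each = nb),
    trial_index = rep(seq_len(k), each = nb),
    task = "memory",
    trajectory = rep(trajectory, each = nb),
    accuracy = "correct",
    bin = rep(seq_len(nb), times = k),
    n_spikes = as.integer(t(counts)),
    occupancy_s = as.numeric(t(occupancy)),
    speed_cms = 1.5 / as.numeric(t(occupancy)))
  attr(out, "n_bins") <- nb
  class(out) <- c("lin_session", class(out))
  out
}

test_that("observed difference is zero for identical sides, constant for constant rates", {
  half <- matrix(rep(c(5L, 3L), each = 50), 4, 100, byrow = TRUE)
  counts <- rbind(half, half)                      # same trials both sides
  occ <- matrix(0.5, 8, 100)
  lin <- lin_from_counts(counts, occ, rep(c("left", "right"), each = 4))
  d0 <- observed_difference(lin)
  expect_true(all(abs(d0$d0) < 1e-12))

  # deterministic 10 vs 6 Hz -> difference 4 Hz everywhere
  counts2 <- rbind(matrix(5L, 4, 100), matrix(3L, 4, 100))
  lin2 <- lin_from_counts(counts2, occ, rep(c("left", "right"), each = 4))
  d02 <- observed_difference(lin2)
  expect_equal(d02$d0, rep(4, 100))

  pt <- permutation_test(lin, n_perms = 300, seed = 2)
  expect_false(any(pt$points$sig))
})

test_that("Monte-Carlo p matches the exhaustive 3+3 enumeration oracle", {
  # deterministic per-trial counts with clean separation
  withr::with_seed(41, {
    counts <- rbind(matrix(rpois(300, 8), 3, 100),
                    matrix(rpois(300, 2), 3, 100))
  })
  occ <- matrix(0.5, 6, 100)
  traj <- rep(c("left", "right"), each = 3)
  lin <- lin_from_counts(counts, occ, traj)
  pt <- permutation_test(lin, n_perms = 1000, seed = 3, min_run = 1)

  # independent oracle: all choose(6,3) = 20 assignments, smoothing by
  # direct kernel sums
  rates <- counts / occ
  sm <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1, i - 10):min(n, i + 10)
      w <- exp(-(j - i)^2 / (2 * 25))
      out[i] <- sum(w * v[j]) / sum(w)
    }
    out
  }
  diff_for <- function(left_idx) {
    sm(colMeans(rates[left_idx, , drop = FALSE])) -
      sm(colMeans(rates[-left_idx, , drop = FALSE]))
  }
  d0 <- diff_for(1:3)
  sets <- utils::combn(6, 3)
  dmat <- t(apply(sets, 2, diff_for))
  p_exact <- colMeans(abs(dmat) >= matrix(abs(d0), 20, 100, byrow = TRUE))
  expect_lt(max(abs(pt$points$p - p_exact)), 0.02)
})

test_that("permutation p-values are valid and the test is seed-deterministic", {
  truths <- unit_truth(12)
  b <- make_session(truths, n_trials = 30, seed = 19)
  lin <- linearize_session(b)
  pt1 <- permutation_test(lin, n_perms = 300, seed = 11)
  pt2 <- permutation_test(lin, n_perms = 300, seed = 11)
  expect_identical(pt1$points, pt2$points)
  expect_true(all(pt1$points$p >= 1 / 301))
  expect_true(all(pt1$points$p <= 1))
  # sig implies sub-alpha
  expect_true(all(pt1$points$p[pt1$points$sig] < 0.05))
  # points_per_section sums to the mask total
  expect_equal(sum(pt1$units$n_sig_points), sum(pt1$points$sig))
})

test_that("detection rate of a planted delay gain rises with the gain", {
  rates <- vapply(c(1.2, 1.5, 2.0), function(g) {
    truths <- dplyr::bind_rows(lapply(1:12, function(i)
      unit_truth(10, sections = "delay", pref_side = "left",
                 traj_gain = g)))
    b <- make_session(truths, n_trials = 60, seed = 29)
    lin <- linearize_session(b)
    pt <- permutation_test(lin, n_perms = 500, seed = 31)
    mean(pt$units$sig[pt$units$section == "delay"])
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
  expect_gt(rates[3], 0.8)
})

test_that("task comparison reports paired t statistics and degeneracies", {
  ua <- tibble::tibble(unit_id = 1:6, section = "delay",
                       n_sig_points = c(8, 6, 9, 4, 7, 5),
                       sig = TRUE)
  ub <- dplyr::mutate(ua, n_sig_points = c(1, 0, 2, 0, 1, 0),
                      sig = n_sig_points > 0)
  r <- task_point_comparison(ua, ub)
  d <- ua$n_sig_points - ub$n_sig_points
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(6)), tolerance = 1e-12)
  expect_equal(r$n_flagged_b, 3)

  expect_equal(task_point_comparison(ua, ua)$t, 0)
  ub2 <- dplyr::mutate(ua, n_sig_points = n_sig_points - 2)
  r2 <- task_point_comparison(ua, ub2)
  expect_true(r2$degenerate)
  expect_identical(r2$t, Inf)
})

test_that("memory-specific delay activity vanishes in a no-cue control task", {
  # same units recorded in both tasks within a session: modulated in the
  # memory task, unmodulated in the control task
  cfg <- synth_config(seed = 37, n_trials = 50)
  beh_mem <- generate_behavior(cfg)
  cfg2 <- synth_config(seed = 38, n_trials = 50,
                       task_mix = c(no_cue_no_choice = 1))
  beh_ctl <- generate_behavior(cfg2)
  mk_lin <- function(beh, gain) {
    truths <- dplyr::bind_rows(lapply(1:8, function(i)
      unit_truth(12, sections = "delay", pref_side = "left",
                 traj_gain = gain)))
    sp <- dplyr::bind_rows(lapply(1:8, function(i) tibble::tibble(
      unit_id = i,
      time_s = generate_spikes(truths[i, ], beh$trials, beh$tracking,
                               seed = 50 + i))))
    linearize_session(session_bundle(beh$trials, beh$tracking, sp))
  }
  lin_mem <- mk_lin(beh_mem, 2)
  lin_ctl <- mk_lin(beh_ctl, 1)
  pt_mem <- permutation_test(lin_mem, n_perms = 500, seed = 1)
  pt_ctl <- permutation_test(lin_ctl, n_perms = 500, seed = 1,
                             task = "no_cue_no_choice")
  r <- task_point_comparison(pt_mem$units, pt_ctl$units, "delay")
  expect_gt(r$mean_a, r$mean_b)
  expect_lt(r$p, 0.05)
})
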