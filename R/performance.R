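# Behavioural performance statistics.

#' Session performance summary
#'
#' Computes overall, left and right correct rates for the memory-task
#' trials of one or more sessions, a per-session 2x2 chi-squared test of
#' independence between arm choice and accuracy (threshold: the
#' chi-squared(1) critical value at alpha = 0.05, 3.841), and — when
#' several sessions are given — a paired t-test of left versus right
#' correct rates across sessions.
#'
#' @param trials A trial tibble (columns `task`, `trajectory`, `accuracy`),
#'   optionally with a `session_id` column; a single session is assumed
#'   when absent.
#' @return A list of class `performance_summary` with elements
#'   `per_session` (tibble: session, n trials, correct rates, chi-squared
#'   statistic and verdict), `left_right_test` (one-row tibble or NULL) and
#'   `chi2_critical` (the 3.841 threshold).
#' @export
session_performance <- function(trials) {
  trials <- tibble::as_tibble(trials)
  if (!"session_id" %in% names(trials)) trials$session_id <- "session"
  mem <- trials[trials$task == "memory", ]
  if (nrow(mem) == 0) abort("no memory-task trials to summarise")
  crit <- qchisq(0.95, df = 1)

  per_session <- mem |>
    dplyr::group_by(.data$session_id) |>
    dplyr::group_modify(function(df, key) {
      rate <- function(x) if (length(x) == 0) NA_real_ else
        mean(x == "correct")
      tab <- table(factor(df$trajectory, c("left", "right")),
                   factor(df$accuracy, c("correct", "error")))
      chi <- NA_real_
      chi_reason <- NA_character_
      if (any(rowSums(tab) == 0)) {
        chi_reason <- "a trajectory margin of the choice x accuracy table is zero"
      } else if (any(colSums(tab) == 0)) {
        # uniform accuracy: observed equals expected exactly
        chi <- 0
      } else {
        chi <- suppressWarnings(
          chisq.test(tab, correct = FALSE)$statistic)
      }
      tibble::tibble(
        n_trials = nrow(df),
        correct_rate = rate(df$accuracy),
        correct_rate_left = rate(df$accuracy[df$trajectory == "left"]),
        correct_rate_right = rate(df$accuracy[df$trajectory == "right"]),
        chi2 = as.numeric(chi),
        chi2_independent = if (is.na(chi)) NA else chi < crit,
        chi2_reason = chi_reason)
    }) |>
    dplyr::ungroup()

  lr <- NULL
  ok <- stats::complete.cases(per_session[, c("correct_rate_left",
                                              "correct_rate_right")])
  if (sum(ok) >= 2) {
    d <- per_session$correct_rate_left[ok] -
      per_session$correct_rate_right[ok]
    if (near_constant(d)) {
      lr <- tibble::tibble(t = if (near_zero(d)) 0 else Inf * sign(d[1]),
                           df = sum(ok) - 1,
                           p = if (near_zero(d)) 1 else 0,
                           mean_left = mean(per_session$correct_rate_left[ok]),
                           mean_right = mean(per_session$correct_rate_right[ok]),
                           degenerate = TRUE)
    } else {
      tt <- t.test(per_session$correct_rate_left[ok],
                   per_session$correct_rate_right[ok], paired = TRUE)
      lr <- tibble::tibble(t = unname(tt$statistic),
                           df = unname(tt$parameter), p = tt$p.value,
                           mean_left = mean(per_session$correct_rate_left[ok]),
                           mean_right = mean(per_session$correct_rate_right[ok]),
                           degenerate = FALSE)
    }
  }
  structure(list(per_session = per_session, left_right_test = lr,
                 chi2_critical = crit),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("<performance_summary> %d session(s); mean correct rate %.1f%%\n",
              nrow(x$per_session), 100 * mean(x$per_session$correct_rate)))
  cat(sprintf("  chi-squared(1) independence threshold: %.3f\n",
              x$chi2_critical))
  invisible(x)
}

#' @export
tidy.performance_summary <- function(x, ...) x$per_session

#' @export
glance.performance_summary <- function(x, ...) {
  tibble::tibble(
    n_sessions = nrow(x$per_session),
    mean_correct_rate = mean(x$per_session$correct_rate),
    sd_correct_rate = sd(x$per_session$correct_rate),
    lr_t = if (is.null(x$left_right_test)) NA_real_ else x$left_right_test$t,
    lr_p = if (is.null(x$left_right_test)) NA_real_ else x$left_right_test$p,
    chi2_critical = x$chi2_critical)
}

#' Memory-load comparison across sessions
#'
#' Paired t-test of low-load versus high-load correct-performance rates for
#' sessions that delivered two trial blocks with different memory demands.
#'
#' @param rates Tibble (or data frame) with columns `low` and `high`, one
#'   row per session.
#' @return One-row tibble with means, SDs, `t`, `df`, `p` and a
#'   `degenerate` flag (set when the per-session differences have zero
#'   variance, in which case `t` is 0 or signed infinity).
#' @export
memory_load_comparison <- function(rates) {
  rates <- tibble::as_tibble(rates)
  stopifnot(all(c("low", "high") %in% names(rates)))
  if (nrow(rates) < 2) abort("need at least two paired sessions")
  d <- rates$low - rates$high
  base <- tibble::tibble(
    n = nrow(rates),
    mean_low = mean(rates$low), sd_low = sd(rates$low),
    mean_high = mean(rates$high), sd_high = sd(rates$high))
  if (near_constant(d)) {
    return(dplyr::mutate(base,
                         t = if (near_zero(d)) 0 else Inf * sign(d[1]),
                         df = nrow(rates) - 1,
                         p = if (near_zero(d)) 1 else 0,
                         degenerate = TRUE))
  }
  tt <- t.test(rates$low, rates$high, paired = TRUE)
  dplyr::mutate(base, t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, degenerate = FALSE)
}
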