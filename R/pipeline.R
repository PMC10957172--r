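# End-to-end orchestration: simulate (or read) a session, optotag,
# linearize, build rate maps, run the permutation test, optionally the
# GLM, the reward analysis, and emit a report.  Every stochastic stage
# receives a seed derived from the master seed by a fixed per-stage
# offset, so stages can be rerun in isolation.

stage_offsets <- c(simulate = 0L, optotag = 11L, permtest = 12L,
                   glm = 13L, reward = 14L)

#' Pipeline configuration
#'
#' @param seed Master seed; per-stage seeds derive from it.
#' @param session_dir Directory of an existing session bundle (read with
#'   [read_session()]); omit to simulate.
#' @param simulate A [synth_config()] used when `session_dir` is `NULL`.
#' @param out_dir Output directory; `NULL` keeps results in memory only.
#' @param n_bins Position bins.
#' @param sigma,half_width Smoothing kernel (bins).
#' @param n_perms,alpha,min_run Permutation-test parameters.
#' @param glm_units `"flagged"` (delay-significant units only, the
#'   default), `"all"`, or `"none"`.
#' @param n_shuffles,glm_order,bonferroni_m GLM shuffle-test parameters.
#' @param optotag_alpha,optotag_resamples Optotagging parameters.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, session_dir = NULL, simulate = NULL,
                            out_dir = NULL, n_bins = 100, sigma = 5,
                            half_width = 10, n_perms = 1000, alpha = 0.05,
                            min_run = 11, glm_units = c("flagged", "all",
                                                       "none"),
                            n_shuffles = 500, glm_order = 6,
                            bonferroni_m = 6, optotag_alpha = 0.01,
                            optotag_resamples = 1000) {
  glm_units <- match.arg(glm_units)
  cfg <- as.list(environment())
  if (is.null(cfg$session_dir) && is.null(cfg$simulate)) {
    abort("configuration error: give `session_dir` or a `simulate` config",
          class = "vtamemcode_config_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read, optotag, linearize, rate maps, permutation
#' test, optional GLM, and reward analysis, then assembles the summary
#' report with [make_report()].  With `out_dir` set, every stage output is
#' written as TSV together with a `run_info.json` carrying the
#' configuration hash and all derived seeds; identical configuration and
#' seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with the stage outputs
#'   (`bundle`, `truth`, `optotag`, `lin`, `rate_maps`, `heatmaps`,
#'   `perm`, `glm`, `reward`, `report`, `seeds`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- vapply(stage_offsets, function(o) derive_seed(config$seed, o),
                  integer(1))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "vtamemcode_stage_error")
    })
  }
  truth <- NULL
  if (!is.null(config$session_dir)) {
    bundle <- stage("read", read_session(config$session_dir))
  } else {
    sim_cfg <- config$simulate
    sim_cfg$seed <- derive_seed(config$seed, stage_offsets[["simulate"]])
    sim <- stage("simulate", simulate_session(sim_cfg))
    bundle <- sim$bundle
    truth <- sim$truth
  }
  ot <- NULL
  if (!is.null(bundle$light_pulses)) {
    ot <- stage("optotag",
                optotag_session(bundle, alpha = config$optotag_alpha,
                                n_resamples = config$optotag_resamples,
                                seed = seeds[["optotag"]]))
  }
  lin <- stage("linearize", linearize_session(bundle, config$n_bins))
  rmap <- stage("ratemaps",
                average_rate_map(lin, config$sigma, config$half_width))
  hm <- stage("ratemaps", build_heatmaps(rmap))
  perm <- stage("permtest",
                permutation_test(lin, n_perms = config$n_perms,
                                 alpha = config$alpha,
                                 min_run = config$min_run,
                                 sigma = config$sigma,
                                 half_width = config$half_width,
                                 seed = seeds[["permtest"]]))
  glm_res <- NULL
  if (config$glm_units != "none") {
    flagged <- perm$units$unit_id[perm$units$section == "delay" &
                                    perm$units$sig]
    glm_set <- if (config$glm_units == "all")
      sort(unique(lin$unit_id)) else sort(flagged)
    glm_res <- stage("glm", dplyr::bind_rows(lapply(glm_set, function(u) {
      fit <- fit_glm(build_design(lin, u, order = config$glm_order))
      dplyr::mutate(
        shuffle_significance(fit, n_shuffles = config$n_shuffles,
                             alpha = config$alpha,
                             m = config$bonferroni_m,
                             seed = derive_seed(seeds[["glm"]], u)),
        unit_id = u, bic = fit$bic, .before = 1)
    })))
  }
  reward <- stage("reward", {
    resp <- classify_reward_response(bundle)
    side <- reward_side_preference(bundle)
    sd_ <- section_differences(lin, bundle, sigma = config$sigma,
                               half_width = config$half_width)
    dp <- section_preference(perm, "delay")
    list(response = resp, side_pref = side, secdiff = sd_,
         categories = delay_reward_categories(dp, side))
  })
  classes <- if (!is.null(bundle$units)) {
    dplyr::rename(bundle$units, class = "label")
  } else {
    tibble::tibble(unit_id = sort(unique(lin$unit_id)), class = "all")
  }
  report <- make_report(perm = perm, reward = reward, classes = classes,
                        trials = bundle$trials, optotag = ot)
  result <- structure(
    list(bundle = bundle, truth = truth, optotag = ot, lin = lin,
         rate_maps = rmap, heatmaps = hm, perm = perm, glm = glm_res,
         reward = reward, report = report, seeds = seeds,
         config_hash = rlang::hash(config[setdiff(names(config),
                                                  "out_dir")])),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline(result, config)
  result
}

write_pipeline <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file) readr::write_tsv(
    df, file.path(config$out_dir, file), progress = FALSE)
  if (!is.null(result$truth)) w(flatten_truth(result$truth), "truth.tsv")
  if (!is.null(result$optotag)) w(result$optotag, "optotag.tsv")
  w(result$rate_maps, "rate_maps.tsv")
  w(result$heatmaps, "heatmaps.tsv")
  w(result$perm$points, "perm_points.tsv")
  w(result$perm$units, "perm_units.tsv")
  if (!is.null(result$glm)) w(result$glm, "glm.tsv")
  w(result$reward$side_pref, "reward_side_pref.tsv")
  w(result$reward$secdiff, "section_differences.tsv")
  w(result$report$trajectory_counts, "report_trajectory_counts.tsv")
  w(result$report$reward_counts, "report_reward_counts.tsv")
  w(result$report$correlations, "report_correlations.tsv")
  jsonlite::write_json(
    list(config_hash = result$config_hash,
         seeds = as.list(result$seeds),
         timestamp = "fixed-for-determinism"),
    file.path(config$out_dir, "run_info.json"), auto_unbox = TRUE)
  invisible(NULL)
}

render_pct <- function(n, total) {
  ifelse(total > 0, paste0(round_half_away(100 * n / total), "%"), NA)
}

#' Assemble the summary report
#'
#' Builds the report tables: per-class, per-section counts and integer
#' percentages of trajectory-specific neurons; reward-response and
#' reward-preference counts; the six-category delay x reward summary; the
#' reward-versus-section correlation table; and behavioural performance.
#' Percentages are rendered as integers rounded half away from zero.
#'
#' @param perm A `perm_test` result.
#' @param reward The reward-stage output list (or `NULL`).
#' @param classes Tibble (`unit_id`, `class`).
#' @param trials Trial table for the performance summary (or `NULL`).
#' @param optotag Optotagging tibble (or `NULL`).
#' @return A list of class `pipeline_report` of tibbles.
#' @export
make_report <- function(perm, reward = NULL, classes = NULL,
                        trials = NULL, optotag = NULL) {
  units_in_perm <- unique(perm$units$unit_id)
  if (is.null(classes)) {
    classes <- tibble::tibble(unit_id = units_in_perm, class = "all")
  }
  missing_units <- setdiff(units_in_perm, classes$unit_id)
  if (length(missing_units) > 0) {
    abort(sprintf("inconsistent unit sets across stages: no class for unit(s) %s",
                  paste(missing_units, collapse = ", ")))
  }
  traj <- perm$units |>
    dplyr::left_join(classes, by = "unit_id") |>
    dplyr::group_by(.data$class, .data$section) |>
    dplyr::summarise(n_sig = sum(.data$sig), n_total = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(pct = render_pct(.data$n_sig, .data$n_total))

  reward_counts <- tibble::tibble(class = character(), n = integer())
  correlations <- tibble::tibble()
  if (!is.null(reward)) {
    reward_counts <- reward$response$units |>
      dplyr::rename(response = "class") |>
      dplyr::left_join(classes, by = "unit_id") |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(
        n_total = dplyr::n(),
        n_excited = sum(.data$response == "excited"),
        n_inhibited = sum(.data$response == "inhibited"),
        n_side_pref = sum(reward$side_pref$side_pref[
          match(.data$unit_id, reward$side_pref$unit_id)] != "ns"),
        .groups = "drop") |>
      dplyr::mutate(pct_excited = render_pct(.data$n_excited, .data$n_total),
                    pct_side_pref = render_pct(.data$n_side_pref,
                                               .data$n_total))
    correlations <- reward$secdiff |>
      dplyr::left_join(classes, by = "unit_id") |>
      dplyr::group_by(.data$class) |>
      dplyr::group_modify(function(df, key) {
        if (nrow(df) >= 10) section_difference_correlation(df) else
          tibble::tibble(section = character(), r = numeric(),
                         p = numeric(), n = integer(),
                         reason = character())
      }) |>
      dplyr::ungroup()
  }
  perf <- if (!is.null(trials) && any(trials$task == "memory")) {
    glance(session_performance(trials))
  } else NULL
  optotag_counts <- if (!is.null(optotag)) {
    dplyr::left_join(optotag, classes, by = "unit_id") |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(n_total = dplyr::n(),
                       n_responsive = sum(.data$responsive),
                       .groups = "drop")
  } else NULL
  structure(list(trajectory_counts = traj, reward_counts = reward_counts,
                 categories = if (!is.null(reward))
                   reward$categories$summary else NULL,
                 correlations = correlations, performance = perf,
                 optotag_counts = optotag_counts),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\nTrajectory-specific units by class and section:\n")
  print(x$trajectory_counts, n = Inf)
  if (!is.null(x$categories)) {
    cat("Delay x reward categories:\n")
    print(x$categories)
  }
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> config %s\n", x$config_hash))
  print(x$report)
  invisible(x)
}
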