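#' Experiment 1: effect of the DTW refinement step
#'
#' For single-template (`S1-1`) and, optionally, ten-template (`S1-10`)
#' random libraries, runs the detector with and without DTW refinement over
#' repeated independent template draws.  Trials that contributed a selected
#' template are removed from that simulation's test set.  Precision and
#' recall are averaged over simulations (mean and SD); per-step timing
#' errors are concatenated across simulations before summarising, the
#' standard protocol for randomised template selection.
#'
#' @param cohort A `gait_cohort` with ground-truth annotations.
#' @param sizes Library sizes to test (default `c(1, 10)`).
#' @param n_simulations Independent template draws per size (default 20).
#' @param config A [detector_config()].
#' @param seed Seed governing the template draws.
#'
#' @return A list of class `"gait_experiment"` with elements `summary`
#'   (one row per size x refinement), `per_simulation` and `errors`.
#' @export
run_experiment_1 <- function(cohort, sizes = c(1, 10), n_simulations = 20,
                             config = detector_config(), seed = 1) {
  collection <- steps_from_cohort(cohort)
  all_trials <- names(cohort$trials)
  rows <- list()
  errs <- list()
  for (size in sizes) {
    for (sim in seq_len(n_simulations)) {
      lib <- strategy_random(collection,
        n = size,
        seed = seed + 1009L * sim + size
      )
      used <- attr(lib, "selected_ids")
      excluded <- unique(collection$trial_id[collection$step_id %in% used])
      test_trials <- setdiff(all_trials, excluded)
      if (length(test_trials) == 0) {
        abort("Cohort too small: every trial contributed a template.")
      }
      for (criterion in c("none", "dtw")) {
        dets <- purrr::map(test_trials, function(tid) {
          detect_and_refine(cohort$trials[[tid]], lib, config, criterion)
        })
        names(dets) <- test_trials
        rep <- evaluate_cohort(
          dets,
          filter(cohort$annotations, .data$trial_id %in% test_trials),
          cohort$params$sampling_rate_hz
        )
        g <- glance(rep)
        rows[[length(rows) + 1L]] <- mutate(g,
          strategy = sprintf("S1-%d", size),
          refinement = criterion, simulation = sim, .before = 1
        )
        e <- rep$errors
        if (nrow(e)) {
          e$strategy <- sprintf("S1-%d", size)
          e$refinement <- criterion
          e$simulation <- sim
          errs[[length(errs) + 1L]] <- e
        }
      }
    }
  }
  per_sim <- bind_rows(rows)
  errors <- bind_rows(errs)
  summary <- per_sim |>
    group_by(.data$strategy, .data$refinement) |>
    summarise(
      n_simulations = dplyr::n(),
      precision_mean = mean(.data$precision),
      precision_sd = sd(.data$precision),
      recall_mean = mean(.data$recall),
      recall_sd = sd(.data$recall),
      n_correct = sum(.data$n_correct),
      .groups = "drop"
    )
  err_sum <- errors |>
    group_by(.data$strategy, .data$refinement) |>
    summarise(
      delta_start_sd_ms = sd(.data$delta_start_ms),
      delta_start_ms = mean(.data$delta_start_ms),
      delta_end_sd_ms = sd(.data$delta_end_ms),
      delta_end_ms = mean(.data$delta_end_ms),
      delta_duration_sd_ms = sd(.data$delta_duration_ms),
      delta_duration_ms = mean(.data$delta_duration_ms),
      .groups = "drop"
    )
  summary <- left_join(summary, err_sum, by = c("strategy", "refinement"))
  new_experiment("E1", summary,
    per_simulation = per_sim, errors = errors,
    config = config, seed = seed
  )
}

#' Experiment 2: comparison of the learned-template strategies
#'
#' Builds one template by each of the DTW-medoid (S2), linear-fusion (S3),
#' non-linear-fusion (S4) and piecewise-affine (S5) strategies from the
#' cohort's annotated steps, and scores the full detector (with DTW
#' refinement) for each on the whole cohort.
#'
#' @inheritParams run_experiment_1
#' @param strategies Subset of `c("S2", "S3", "S4", "S5")`.
#' @return A `"gait_experiment"` with a one-row-per-strategy summary.
#' @export
run_experiment_2 <- function(cohort, strategies = c("S2", "S3", "S4", "S5"),
                             config = detector_config()) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  collection <- steps_from_cohort(cohort)
  rows <- purrr::map(strategies, function(strat) {
    lib <- build_templates(collection, strategy = strat, maxsamp = config$maxsamp)
    dets <- purrr::map(cohort$trials, detect_and_refine,
      library = lib, config = config, criterion = "dtw"
    )
    rep <- evaluate_cohort(dets, cohort$annotations, cohort$params$sampling_rate_hz)
    mutate(rename_glance(glance(rep)), strategy = strat, refinement = "dtw", .before = 1)
  })
  new_experiment("E2", bind_rows(rows), config = config)
}

#' Experiment 3: influence of the refinement scan half-width z
#'
#' With the piecewise-affine (S5) template, detects once per trial and then
#' refines the same initial detections for each scan half-width in
#' `z_values`, reporting the mean absolute start/end/duration errors as a
#' curve against `z`.  `z = 0` reproduces the unrefined errors.  For
#' `z > maxsamp / 2` the corner lags of the scan violate the DTW band and
#' are skipped, as the detector documents.
#'
#' @inheritParams run_experiment_1
#' @param z_values Integer vector of scan half-widths (default `1:20`).
#' @return A `"gait_experiment"` whose summary has one row per `z`.
#' @export
run_experiment_3 <- function(cohort, z_values = 1:20,
                             config = detector_config()) {
  lib <- build_templates(NULL, strategy = "S5")
  initial <- purrr::map(cohort$trials, detect_steps, library = lib, config = config)
  rows <- purrr::map(z_values, function(z) {
    cfg <- suppressWarnings(detector_config(
      correlation_threshold = config$correlation_threshold, z = z,
      maxsamp = config$maxsamp, min_peak_separation = config$min_peak_separation
    ))
    dets <- purrr::map(names(cohort$trials), function(tid) {
      if (z == 0) {
        return(initial[[tid]])
      }
      refine_detections(cohort$trials[[tid]], initial[[tid]], lib, cfg, "dtw")
    })
    names(dets) <- names(cohort$trials)
    rep <- evaluate_cohort(dets, cohort$annotations, cohort$params$sampling_rate_hz)
    mutate(rename_glance(glance(rep)), z = as.integer(z), .before = 1)
  })
  new_experiment("E3", bind_rows(rows), config = config)
}

#' Experiment 4: DTW versus Pearson refinement criterion
#'
#' With the piecewise-affine (S5) template, refines the *same* initial
#' detections once with the DTW-distance criterion and once with the
#' linear-correlation (Pearson) criterion, and compares the absolute timing
#' errors step by step.  The per-step differences (DTW minus Pearson;
#' negative favours DTW) are returned sorted for plotting.
#'
#' @inheritParams run_experiment_1
#' @return A `"gait_experiment"` with `summary` (one row per criterion),
#'   `per_step` (paired errors) and `differences` (sorted per-step
#'   differences per metric).
#' @export
run_experiment_4 <- function(cohort, config = detector_config()) {
  lib <- build_templates(NULL, strategy = "S5")
  initial <- purrr::map(cohort$trials, detect_steps, library = lib, config = config)
  refined <- purrr::map(c(dtw = "dtw", pearson = "pearson"), function(crit) {
    dets <- purrr::map(names(cohort$trials), function(tid) {
      refine_detections(cohort$trials[[tid]], initial[[tid]], lib, config, crit)
    })
    names(dets) <- names(cohort$trials)
    dets
  })
  reports <- purrr::imap(refined, function(dets, crit) {
    evaluate_cohort(dets, cohort$annotations, cohort$params$sampling_rate_hz)
  })
  summary <- bind_rows(purrr::imap(reports, function(rep, crit) {
    mutate(rename_glance(glance(rep)), criterion = crit, .before = 1)
  }))
  keys <- c("trial_id", "det_step_id")
  metrics <- c("delta_start_ms", "delta_end_ms", "delta_duration_ms")
  per_step <- left_join(
    select(reports$dtw$errors, dplyr::all_of(c(keys, metrics))),
    select(reports$pearson$errors, dplyr::all_of(c(keys, metrics))),
    by = keys, suffix = c("_dtw", "_pearson")
  )
  per_step <- per_step[stats::complete.cases(per_step), ]
  differences <- purrr::map(metrics, function(m) {
    sort(per_step[[paste0(m, "_dtw")]] - per_step[[paste0(m, "_pearson")]])
  })
  names(differences) <- metrics
  new_experiment("E4", summary,
    per_step = per_step, differences = differences,
    reports = reports, config = config
  )
}

new_experiment <- function(which, summary, ...) {
  structure(
    c(list(which = which, summary = summary), list(...)),
    class = "gait_experiment"
  )
}

# per-pooled-report column names used in experiment summaries
rename_glance <- function(g) {
  dplyr::rename(g,
    delta_start_ms = "delta_start_mean_ms",
    delta_end_ms = "delta_end_mean_ms",
    delta_duration_ms = "delta_duration_mean_ms"
  )
}

#' @export
print.gait_experiment <- function(x, ...) {
  cat(sprintf("<gait_experiment %s>\n", x$which))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.gait_experiment <- function(x, ...) {
  x$summary
}
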