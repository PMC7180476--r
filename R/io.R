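#' Read and write gait signals as CSV
#'
#' Signals travel as comma-separated text with a header row
#' (`sample_index,gyro_y`) preceded by `#`-prefixed comment lines carrying
#' the sampling rate and identifiers.  Sample indices are 1-based; values
#' are written with shortest round-trip formatting, so write-then-read
#' reproduces a signal to full double precision.
#'
#' @param path File path.
#' @return `read_signal()` returns a [gait_signal()].
#' @export
read_signal <- function(path) {
  hdr <- read_comment_header(path)
  df <- readr::read_csv(path,
    comment = "#", col_types = readr::cols(
      sample_index = readr::col_double(), gyro_y = readr::col_double()
    ), progress = FALSE
  )
  if (nrow(readr::problems(df)) > 0) {
    abort(sprintf("Non-numeric rows in signal file '%s'.", path))
  }
  if (!all(c("sample_index", "gyro_y") %in% names(df))) {
    abort(sprintf("Signal file '%s' must have columns sample_index, gyro_y.", path))
  }
  if (nrow(df) == 0) {
    abort(sprintf("Signal file '%s' contains no samples.", path))
  }
  if (anyNA(df$gyro_y)) {
    abort(sprintf("Non-numeric cells in signal file '%s'.", path))
  }
  df <- df[order(df$sample_index), ]
  gait_signal(
    df$gyro_y,
    sampling_rate_hz = as.numeric(hdr$sampling_rate_hz %||% 100),
    trial_id = hdr$trial_id %||% "trial",
    subject_id = hdr$subject_id %||% NA_character_
  )
}

#' @rdname read_signal
#' @param signal A `gait_signal`.
#' @export
write_signal <- function(signal, path) {
  header <- c(
    "# gaitwarp_signal v1",
    sprintf("# sampling_rate_hz: %s", format(sampling_rate(signal), digits = 15)),
    sprintf("# trial_id: %s", trial_id(signal)),
    sprintf("# subject_id: %s", attr(signal, "subject_id")),
    "# index_base: 1"
  )
  body <- readr::format_csv(tibble(
    sample_index = signal$sample_index, gyro_y = signal$gyro_y
  ))
  writeLines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' Read and write step annotations as CSV
#'
#' Annotation files are comma-separated text with columns
#' `step_id,ic,fc` (1-based inclusive stance intervals) and `#` comment
#' lines.  Annotations are validated (`ic < fc`, non-overlapping, inside
#' the signal when one is supplied) and returned sorted by `ic`.
#'
#' @param path File path.
#' @param signal Optional `gait_signal` to validate indices against.
#' @return `read_annotations()` returns an annotations tibble.
#' @export
read_annotations <- function(path, signal = NULL) {
  df <- readr::read_csv(path,
    comment = "#", col_types = readr::cols(
      step_id = readr::col_character(),
      ic = readr::col_integer(), fc = readr::col_integer()
    ), progress = FALSE
  )
  if (nrow(df) == 0) {
    return(tibble(step_id = character(0), ic = integer(0), fc = integer(0)))
  }
  validate_annotations(df, signal)
}

#' @rdname read_annotations
#' @param annotations Annotations tibble.
#' @export
write_annotations <- function(annotations, path) {
  ann <- validate_annotations(annotations)
  header <- c("# gaitwarp_annotations v1", "# index_base: 1 (ic/fc inclusive)")
  body <- readr::format_csv(select(ann, "step_id", "ic", "fc"))
  writeLines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' Read and write templates as JSON
#'
#' A single template is stored as a JSON object with fields `id`,
#' `strategy`, `source` and `samples`; a library as `{"templates": [...]}`.
#' `read_template()` accepts either form and returns the corresponding
#' object.
#'
#' @param path File path.
#' @return A `step_template` or `template_library`.
#' @export
read_template <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$templates)) {
    tpls <- obj$templates
    lst <- purrr::map(seq_len(nrow(tpls)), function(i) {
      step_template(
        unlist(tpls$samples[[i]]),
        strategy = tpls$strategy[[i]],
        source = tpls$source[[i]], id = tpls$id[[i]]
      )
    })
    return(template_library(lst))
  }
  step_template(unlist(obj$samples),
    strategy = obj$strategy,
    source = obj$source, id = obj$id
  )
}

#' @rdname read_template
#' @param x A `step_template` or `template_library`.
#' @export
write_template <- function(x, path) {
  as_list <- function(t) {
    list(id = t$id, strategy = t$strategy, source = t$source, samples = t$samples)
  }
  obj <- if (inherits(x, "template_library")) {
    list(templates = purrr::map(x$templates, as_list))
  } else {
    as_list(x)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' Mirrors the standard results-table structure: precision, recall, and
#' `mean (sd)` of the absolute start/end/duration errors in milliseconds,
#' plus the per-step error lists.
#'
#' @param report An `eval_report`.
#' @param path File path.
#' @export
write_report <- function(report, path) {
  g <- glance(report)
  obj <- list(
    precision = g$precision,
    recall = g$recall,
    n_detected = g$n_detected,
    n_annotated = g$n_annotated,
    n_correct = g$n_correct,
    delta_start_ms = list(mean = g$delta_start_mean_ms, sd = g$delta_start_sd_ms),
    delta_end_ms = list(mean = g$delta_end_mean_ms, sd = g$delta_end_sd_ms),
    delta_duration_ms = list(mean = g$delta_duration_mean_ms, sd = g$delta_duration_sd_ms),
    errors = list(
      delta_start_ms = report$errors$delta_start_ms,
      delta_end_ms = report$errors$delta_end_ms,
      delta_duration_ms = report$errors$delta_duration_ms,
      start_error_ms = report$errors$start_error_ms,
      end_error_ms = report$errors$end_error_ms,
      duration_error_ms = report$errors$duration_error_ms
    ),
    sampling_rate_hz = report$sampling_rate_hz
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write or read a synthetic cohort directory
#'
#' Lays a cohort out as plain text: `signals/<trial>.csv`,
#' `annotations/<trial>.csv` and a `manifest.json` recording every
#' generator parameter, so a dataset can be reconstructed or shipped.
#'
#' @param cohort A `gait_cohort`.
#' @param dir Directory path (created if missing).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "signals"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), recursive = TRUE, showWarnings = FALSE)
  for (tid in names(cohort$trials)) {
    write_signal(cohort$trials[[tid]], file.path(dir, "signals", paste0(tid, ".csv")))
    ann <- filter(cohort$annotations, .data$trial_id == tid)
    write_annotations(
      select(ann, "step_id", "ic", "fc"),
      file.path(dir, "annotations", paste0(tid, ".csv"))
    )
  }
  manifest <- unclass(cohort$params)
  jsonlite::write_json(
    list(params = manifest, trials = names(cohort$trials)),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  p <- man$params
  params <- synth_params(
    n_trials = p$n_trials, steps_per_trial = p$steps_per_trial,
    sampling_rate_hz = p$sampling_rate_hz,
    stance_len_median = p$stance_len_median,
    stance_len_spread = p$stance_len_spread,
    warp_intensity = p$warp_intensity, warp_mode = p$warp_mode,
    amp_scale_range = p$amp_scale_range, offset_range = p$offset_range,
    noise_sd = p$noise_sd, swing_len_range = p$swing_len_range,
    swing_noise_sd = p$swing_noise_sd,
    subject_len_spread = p$subject_len_spread, n_subjects = p$n_subjects,
    prototype = p$prototype, seed = p$seed
  )
  tids <- man$trials
  trials <- purrr::map(tids, function(tid) {
    read_signal(file.path(dir, "signals", paste0(tid, ".csv")))
  })
  names(trials) <- tids
  anns <- purrr::map(tids, function(tid) {
    ann <- read_annotations(
      file.path(dir, "annotations", paste0(tid, ".csv")),
      signal = trials[[tid]]
    )
    mutate(ann,
      trial_id = tid,
      subject_id = attr(trials[[tid]], "subject_id"), .before = 1
    )
  })
  structure(
    list(
      trials = trials, annotations = bind_rows(anns),
      subjects = NULL, params = params
    ),
    class = "gait_cohort"
  )
}

read_comment_header <- function(path) {
  lines <- readr::read_lines(path, n_max = 20)
  lines <- lines[startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", lines))
  kv <- kv[lengths(kv) == 3]
  stats::setNames(
    as.list(purrr::map_chr(kv, 3)),
    purrr::map_chr(kv, 2)
  )
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
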