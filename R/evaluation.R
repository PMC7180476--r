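#' Match detections to annotations by the midpoint rule
#'
#' A detected step is correct if the mean of its start and end indices lies
#' inside an annotated stance interval (both endpoints inclusive; midpoints
#' are compared as reals, so half-integer midpoints need no rounding).  An
#' annotated step can be detected only once: when several detections fall
#' inside the same annotation, the one whose midpoint is closest to the
#' annotation midpoint is kept and the others are counted false, ties going
#' to the earlier detection.
#'
#' @param detected Detections tibble (columns `step_id`, `ic`, `fc`).
#' @param annotated Annotations tibble (columns `step_id`, `ic`, `fc`),
#'   non-overlapping.
#'
#' @return A list of class `"step_matching"`: `pairs` (tibble with one row
#'   per correct detection: `det_step_id`, `ann_step_id`, `det_ic`,
#'   `det_fc`, `ann_ic`, `ann_fc`), `false_detections` and
#'   `missed_annotations` (character/int vectors of ids).
#' @export
match_detections <- function(detected, annotated) {
  ann <- validate_annotations(annotated)
  det <- arrange(as_tibble(detected), .data$ic)
  pairs <- match_midpoints_one_to_one(
    points = det, intervals = ann
  )
  matched_det <- pairs$point_row
  matched_ann <- pairs$interval_row
  out <- tibble(
    det_step_id = det$step_id[matched_det],
    ann_step_id = ann$step_id[matched_ann],
    det_ic = det$ic[matched_det],
    det_fc = det$fc[matched_det],
    ann_ic = ann$ic[matched_ann],
    ann_fc = ann$fc[matched_ann]
  )
  structure(
    list(
      pairs = out,
      false_detections = setdiff(det$step_id, out$det_step_id),
      missed_annotations = setdiff(ann$step_id, out$ann_step_id)
    ),
    class = "step_matching"
  )
}

# One-to-one assignment: the midpoint of each `points` interval must lie in
# a `intervals` interval (inclusive); candidate pairs are ranked by the
# distance between the two midpoints, ties by earlier point ic then row,
# and accepted greedily while both sides are unused.
match_midpoints_one_to_one <- function(points, intervals) {
  if (nrow(points) == 0 || nrow(intervals) == 0) {
    return(tibble(point_row = integer(0), interval_row = integer(0)))
  }
  pm <- (points$ic + points$fc) / 2
  im <- (intervals$ic + intervals$fc) / 2
  cand <- purrr::map(seq_len(nrow(points)), function(p) {
    hit <- which(intervals$ic <= pm[[p]] & pm[[p]] <= intervals$fc)
    if (length(hit) == 0) {
      return(NULL)
    }
    tibble(
      point_row = p, interval_row = hit,
      dist = abs(pm[[p]] - im[hit]), point_ic = points$ic[[p]]
    )
  })
  cand <- bind_rows(cand)
  if (nrow(cand) == 0) {
    return(tibble(point_row = integer(0), interval_row = integer(0)))
  }
  cand <- cand[order(cand$dist, cand$point_ic, cand$point_row), ]
  used_p <- logical(nrow(points))
  used_i <- logical(nrow(intervals))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    p <- cand$point_row[[r]]
    i <- cand$interval_row[[r]]
    if (!used_p[[p]] && !used_i[[i]]) {
      keep[[r]] <- TRUE
      used_p[[p]] <- TRUE
      used_i[[i]] <- TRUE
    }
  }
  kept <- cand[keep, ]
  kept <- kept[order(kept$point_row), ]
  tibble(point_row = kept$point_row, interval_row = kept$interval_row)
}

#' Precision and recall of a detection set
#'
#' Precision uses the detection-midpoint rule of [match_detections()]:
#' correct detections divided by all detections.  Recall uses the symmetric
#' rule — an annotated step is detected if *its* midpoint lies inside a
#' detected interval, each detection usable once — giving detected
#' annotations divided by all annotations.  With no detections the
#' precision is undefined (`NA`); with no annotations the recall is `NA`.
#'
#' @inheritParams match_detections
#' @return A one-row tibble: `precision`, `recall`, `n_detected`,
#'   `n_annotated`, `n_correct`, `n_detected_annotations`.
#' @export
precision_recall <- function(detected, annotated) {
  ann <- validate_annotations(annotated)
  det <- arrange(as_tibble(detected), .data$ic)
  m_prec <- match_detections(det, ann)
  # symmetric rule: annotation midpoints inside detected intervals
  m_rec <- match_midpoints_one_to_one(points = ann, intervals = det)
  n_det <- nrow(det)
  n_ann <- nrow(ann)
  tibble(
    precision = if (n_det == 0) NA_real_ else nrow(m_prec$pairs) / n_det,
    recall = if (n_ann == 0) NA_real_ else nrow(m_rec) / n_ann,
    n_detected = n_det,
    n_annotated = n_ann,
    n_correct = nrow(m_prec$pairs),
    n_detected_annotations = nrow(m_rec)
  )
}

#' Timing errors of correct detections
#'
#' For every correct detection, the differences between detected and
#' annotated initial contact (start), final contact (end), and stance
#' duration, converted to milliseconds (`ms = samples * 1000 / rate`; 10 ms
#' per sample at 100 Hz).  Both signed and absolute errors are returned;
#' summaries report the mean and standard deviation of the absolute
#' errors.
#'
#' @param matching A `"step_matching"` from [match_detections()].
#' @param sampling_rate_hz Sampling rate of the underlying signal.
#' @return Tibble with one row per correct detection: ids plus
#'   `start_error_ms`, `end_error_ms`, `duration_error_ms` (signed) and
#'   `delta_start_ms`, `delta_end_ms`, `delta_duration_ms` (absolute).
#' @export
timing_errors <- function(matching, sampling_rate_hz = 100) {
  if (!inherits(matching, "step_matching")) {
    abort("`matching` must come from match_detections().")
  }
  p <- matching$pairs
  ms <- 1000 / sampling_rate_hz
  start_err <- (p$det_ic - p$ann_ic) * ms
  end_err <- (p$det_fc - p$ann_fc) * ms
  dur_err <- ((p$det_fc - p$det_ic) - (p$ann_fc - p$ann_ic)) * ms
  tibble(
    det_step_id = p$det_step_id,
    ann_step_id = p$ann_step_id,
    start_error_ms = start_err,
    end_error_ms = end_err,
    duration_error_ms = dur_err,
    delta_start_ms = abs(start_err),
    delta_end_ms = abs(end_err),
    delta_duration_ms = abs(dur_err)
  )
}

#' Evaluate detections against ground truth
#'
#' Full event-level evaluation of one trial (or of pooled per-trial
#' results via [evaluate_cohort()]): precision, recall, and the
#' distributions of the absolute start/end/duration timing errors in
#' milliseconds.
#'
#' @inheritParams match_detections
#' @param sampling_rate_hz Sampling rate used for the ms conversion.
#' @return An object of class `"eval_report"`; see [glance.eval_report()]
#'   for the one-row summary and [tidy.eval_report()] for per-step errors.
#' @export
evaluate_detections <- function(detected, annotated, sampling_rate_hz = 100) {
  pr <- precision_recall(detected, annotated)
  errs <- timing_errors(match_detections(detected, annotated), sampling_rate_hz)
  new_eval_report(pr, errs, sampling_rate_hz)
}

new_eval_report <- function(pr, errors, sampling_rate_hz) {
  structure(
    list(
      precision = pr$precision,
      recall = pr$recall,
      counts = pr,
      errors = errors,
      sampling_rate_hz = sampling_rate_hz
    ),
    class = "eval_report"
  )
}

#' Pool per-trial evaluations over a cohort
#'
#' Counts (detections, annotations, correct detections) are summed across
#' trials before forming precision and recall, and per-step timing errors
#' are concatenated, matching how a whole recording database is scored.
#'
#' @param detections_by_trial Named list of detections tibbles, one per
#'   trial.
#' @param annotations Annotations tibble with a `trial_id` column covering
#'   the same trials.
#' @param sampling_rate_hz Sampling rate used for the ms conversion.
#' @return An `"eval_report"`.
#' @export
evaluate_cohort <- function(detections_by_trial, annotations,
                            sampling_rate_hz = 100) {
  ids <- names(detections_by_trial)
  if (is.null(ids)) {
    abort("`detections_by_trial` must be a named list (names = trial ids).")
  }
  parts <- purrr::map(ids, function(tid) {
    ann <- filter(annotations, .data$trial_id == tid)
    det <- detections_by_trial[[tid]]
    pr <- precision_recall(det, ann)
    errs <- timing_errors(match_detections(det, ann), sampling_rate_hz)
    errs$trial_id <- if (nrow(errs)) tid else character(0)
    list(pr = pr, errs = errs)
  })
  counts <- bind_rows(purrr::map(parts, "pr"))
  errors <- bind_rows(purrr::map(parts, "errs"))
  tot <- tibble(
    precision = if (sum(counts$n_detected) == 0) NA_real_ else sum(counts$n_correct) / sum(counts$n_detected),
    recall = if (sum(counts$n_annotated) == 0) NA_real_ else sum(counts$n_detected_annotations) / sum(counts$n_annotated),
    n_detected = sum(counts$n_detected),
    n_annotated = sum(counts$n_annotated),
    n_correct = sum(counts$n_correct),
    n_detected_annotations = sum(counts$n_detected_annotations)
  )
  new_eval_report(tot, errors, sampling_rate_hz)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> precision %.3f, recall %.3f (%d/%d detections correct, %d annotations)\n",
    x$precision, x$recall, x$counts$n_correct, x$counts$n_detected,
    x$counts$n_annotated
  ))
  g <- glance(x)
  cat(sprintf(
    "  |dStart| %.1f (%.1f) ms, |dEnd| %.1f (%.1f) ms, |dDuration| %.1f (%.1f) ms\n",
    g$delta_start_mean_ms, g$delta_start_sd_ms,
    g$delta_end_mean_ms, g$delta_end_sd_ms,
    g$delta_duration_mean_ms, g$delta_duration_sd_ms
  ))
  invisible(x)
}

#' @describeIn evaluate_detections per-step timing errors of the correct
#'   detections (one row each).
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) {
  x$errors
}

#' @describeIn evaluate_detections one-row summary: precision, recall,
#'   counts, and mean/SD of the absolute timing errors in ms.
#' @export
glance.eval_report <- function(x, ...) {
  e <- x$errors
  msd <- function(v) {
    if (length(v) == 0) c(NA_real_, NA_real_) else c(mean(v), sd(v))
  }
  s <- msd(e$delta_start_ms)
  en <- msd(e$delta_end_ms)
  d <- msd(e$delta_duration_ms)
  tibble(
    precision = x$precision,
    recall = x$recall,
    n_detected = x$counts$n_detected,
    n_annotated = x$counts$n_annotated,
    n_correct = x$counts$n_correct,
    delta_start_mean_ms = s[[1]], delta_start_sd_ms = s[[2]],
    delta_end_mean_ms = en[[1]], delta_end_sd_ms = en[[2]],
    delta_duration_mean_ms = d[[1]], delta_duration_sd_ms = d[[2]]
  )
}
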