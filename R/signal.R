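#' Construct a gait signal
#'
#' A gait signal is one trial's single-axis angular-velocity series (the
#' sagittal-plane y-axis channel of a foot-mounted gyrometer, in deg/s),
#' stored as a tibble with columns `sample_index` (1-based) and `gyro_y`,
#' carrying the sampling rate and trial/subject identifiers as attributes.
#' All sample indices in this package, including stance intervals
#' `[ic, fc]`, are 1-based and inclusive at both ends, so a stance duration
#' is `fc - ic + 1` samples.
#'
#' @param gyro_y Numeric vector of angular-velocity samples; length >= 1,
#'   all finite.
#' @param sampling_rate_hz Positive sampling rate (default 100 Hz).
#' @param trial_id,subject_id Identifier strings.
#'
#' @return A tibble of class `"gait_signal"` with columns `sample_index`
#'   and `gyro_y`.
#'
#' @examples
#' sig <- gait_signal(sin(1:200 / 10), trial_id = "demo")
#' sampling_rate(sig)
#' @export
gait_signal <- function(gyro_y, sampling_rate_hz = 100, trial_id = "trial",
                        subject_id = NA_character_) {
  check_series(gyro_y, min_len = 1L, arg = "gyro_y")
  if (length(sampling_rate_hz) != 1 || !is.finite(sampling_rate_hz) ||
      sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be a single positive number.")
  }
  out <- tibble(sample_index = seq_along(gyro_y), gyro_y = as.numeric(gyro_y))
  structure(
    out,
    sampling_rate_hz = as.numeric(sampling_rate_hz),
    trial_id = as.character(trial_id),
    subject_id = as.character(subject_id),
    class = c("gait_signal", class(out))
  )
}

#' @rdname gait_signal
#' @param x A `gait_signal`.
#' @export
sampling_rate <- function(x) {
  attr(x, "sampling_rate_hz")
}

#' @rdname gait_signal
#' @export
trial_id <- function(x) {
  attr(x, "trial_id")
}

#' @rdname gait_signal
#' @export
signal_samples <- function(x) {
  x$gyro_y
}

#' @export
print.gait_signal <- function(x, ...) {
  cat(sprintf(
    "<gait_signal> trial '%s' (subject %s): %d samples @ %g Hz\n",
    attr(x, "trial_id"), attr(x, "subject_id"), nrow(x),
    attr(x, "sampling_rate_hz")
  ))
  NextMethod()
}

#' Construct and validate step annotations
#'
#' Step annotations mark stance intervals `[ic, fc]` (initial contact to
#' final contact, 1-based inclusive sample indices).  Annotations within one
#' trial must be non-overlapping; they are returned sorted by `ic`.
#'
#' @param ic,fc Integer vectors of equal length: stance start and end
#'   sample indices, with `ic < fc`.
#' @param step_id Optional identifiers (default `"step1"`, `"step2"`, ... in
#'   `ic` order).
#'
#' @return A tibble with columns `step_id`, `ic`, `fc`, sorted by `ic`.
#'
#' @examples
#' step_annotations(ic = c(10, 120), fc = c(72, 180))
#' @export
step_annotations <- function(ic, fc, step_id = NULL) {
  if (length(ic) != length(fc)) {
    abort("`ic` and `fc` must have the same length.")
  }
  ann <- tibble(
    step_id = if (is.null(step_id)) paste0("step", seq_along(ic)) else as.character(step_id),
    ic = as.integer(ic),
    fc = as.integer(fc)
  )
  ann <- arrange(ann, .data$ic)
  if (is.null(step_id)) ann$step_id <- paste0("step", seq_len(nrow(ann)))
  validate_annotations(ann)
}

#' @rdname step_annotations
#' @param annotations A tibble with columns `step_id`, `ic`, `fc`.
#' @param signal Optional `gait_signal`; when supplied, indices are checked
#'   against the signal length.
#' @export
validate_annotations <- function(annotations, signal = NULL) {
  required <- c("step_id", "ic", "fc")
  if (!all(required %in% names(annotations))) {
    abort("Annotations need columns `step_id`, `ic`, `fc`.")
  }
  ann <- arrange(as_tibble(annotations), .data$ic)
  if (nrow(ann) == 0) {
    return(ann)
  }
  if (anyNA(ann$ic) || anyNA(ann$fc)) {
    abort("Annotation indices must not be missing.")
  }
  if (any(ann$ic < 1)) {
    abort("Annotation `ic` indices must be >= 1.")
  }
  bad <- ann$ic >= ann$fc
  if (any(bad)) {
    abort(
      sprintf(
        "Annotation(s) %s have fc <= ic; a stance needs duration >= 2 samples.",
        paste(ann$step_id[bad], collapse = ", ")
      ),
      class = "gaitwarp_error_annotation"
    )
  }
  if (nrow(ann) > 1 && any(ann$ic[-1] <= ann$fc[-nrow(ann)])) {
    abort(
      "Annotated stance intervals overlap within the trial.",
      class = "gaitwarp_error_annotation"
    )
  }
  if (!is.null(signal) && any(ann$fc > nrow(signal))) {
    abort(
      "Annotation indices fall outside the signal.",
      class = "gaitwarp_error_annotation"
    )
  }
  ann
}

#' Extract annotated step waveforms from a signal
#'
#' Cuts each annotated stance interval out of the signal and returns a step
#' collection: one row per step with the raw waveform in a list-column.
#' Step collections are the training input of the template-building
#' strategies ([build_templates()]).
#'
#' @param signal A `gait_signal`.
#' @param annotations Annotation tibble for that signal (validated).
#'
#' @return A tibble with columns `step_id`, `trial_id`, `subject_id`, `ic`,
#'   `fc`, `length` and list-column `samples`.
#'
#' @export
extract_steps <- function(signal, annotations) {
  ann <- validate_annotations(annotations, signal)
  x <- signal_samples(signal)
  waves <- purrr::map2(ann$ic, ann$fc, function(i, f) x[i:f])
  degenerate <- purrr::map_lgl(waves, function(w) max(w) == min(w))
  if (any(degenerate)) {
    abort(
      sprintf(
        "Step(s) %s are constant (zero variance) and cannot be used as templates.",
        paste(ann$step_id[degenerate], collapse = ", ")
      ),
      class = "gaitwarp_error_degenerate"
    )
  }
  tibble(
    step_id = paste0(trial_id(signal), ":", ann$step_id),
    trial_id = trial_id(signal),
    subject_id = attr(signal, "subject_id"),
    ic = ann$ic,
    fc = ann$fc,
    length = ann$fc - ann$ic + 1L,
    samples = waves
  )
}
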