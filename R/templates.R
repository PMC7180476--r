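#' Step templates and template libraries
#'
#' A step template is a prototype stance waveform together with the strategy
#' that produced it (`"S1"` random pick, `"S2"` DTW medoid, `"S3"` linear
#' fusion, `"S4"` DTW-aligned non-linear fusion, `"S5"` knowledge-based
#' piecewise-affine) and its source (origin step id or `"analytic"`).  A
#' template library is an ordered, uniquely-identified collection of
#' templates used by the detector.
#'
#' @param samples Numeric waveform, length >= 2, non-constant.
#' @param strategy One of `"S1"` ... `"S5"`.
#' @param source Provenance string.
#' @param id Template identifier (default derived from strategy and source).
#'
#' @return `step_template()` returns an object of class `"step_template"`;
#'   `template_library()` an object of class `"template_library"`.
#'
#' @export
step_template <- function(samples, strategy, source = "unknown", id = NULL) {
  check_series(samples, min_len = 2L, arg = "samples")
  if (max(samples) == min(samples)) {
    abort("Template waveform is constant (zero variance).",
      class = "gaitwarp_error_degenerate"
    )
  }
  strategy <- match.arg(strategy, c("S1", "S2", "S3", "S4", "S5"))
  structure(
    list(
      id = if (is.null(id)) paste0(strategy, ":", source) else as.character(id),
      samples = as.numeric(samples),
      strategy = strategy,
      source = as.character(source)
    ),
    class = "step_template"
  )
}

#' @rdname step_template
#' @param templates A list of `step_template` objects (non-empty, unique ids).
#' @export
template_library <- function(templates) {
  if (inherits(templates, "step_template")) templates <- list(templates)
  if (length(templates) == 0) {
    abort("A template library must contain at least one template.")
  }
  ok <- purrr::map_lgl(templates, inherits, "step_template")
  if (!all(ok)) {
    abort("All elements must be `step_template` objects.")
  }
  ids <- purrr::map_chr(templates, "id")
  if (anyDuplicated(ids)) {
    abort("Template ids must be unique within a library.")
  }
  structure(list(templates = templates), class = "template_library")
}

#' @export
print.step_template <- function(x, ...) {
  cat(sprintf(
    "<step_template> %s (%s, source %s): %d samples in [%.3g, %.3g]\n",
    x$id, x$strategy, x$source, length(x$samples),
    min(x$samples), max(x$samples)
  ))
  invisible(x)
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library> %d template(s)\n", length(x$templates)))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.template_library <- function(x, ...) {
  tibble(
    template_id = purrr::map_chr(x$templates, "id"),
    strategy = purrr::map_chr(x$templates, "strategy"),
    source = purrr::map_chr(x$templates, "source"),
    length = purrr::map_int(x$templates, function(t) length(t$samples))
  )
}

#' @export
tidy.step_template <- function(x, ...) {
  tibble(
    template_id = x$id,
    sample_index = seq_along(x$samples),
    value = x$samples
  )
}

# ---- strategies -------------------------------------------------------------

#' Build a template library from a step collection
#'
#' Dispatches to one of the five template-construction strategies.  `steps`
#' is a step collection as produced by [extract_steps()] (rows may be bound
#' across trials).
#'
#' @param steps Step-collection tibble with columns `step_id` and `samples`.
#' @param strategy `"S1"` (random selection), `"S2"` (DTW medoid), `"S3"`
#'   (linear fusion), `"S4"` (non-linear fusion) or `"S5"` (piecewise-affine
#'   prototype; ignores `steps`).
#' @param n Number of templates for `"S1"`.
#' @param seed RNG seed for `"S1"` (required there, ignored elsewhere).
#' @param maxsamp DTW band half-width for `"S2"`/`"S4"`.
#' @param n_samples Template length for `"S5"` (default 63).
#'
#' @return A `template_library`.
#' @export
build_templates <- function(steps, strategy = c("S5", "S1", "S2", "S3", "S4"),
                            n = 1, seed = NULL, maxsamp = 20, n_samples = 63) {
  strategy <- match.arg(strategy)
  switch(strategy,
    S1 = strategy_random(steps, n = n, seed = seed),
    S2 = template_library(strategy_dtw_medoid(steps, maxsamp = maxsamp)),
    S3 = template_library(strategy_linear_fusion(steps)),
    S4 = template_library(strategy_nonlinear_fusion(steps, maxsamp = maxsamp)),
    S5 = template_library(strategy_piecewise(n_samples))
  )
}

check_collection <- function(steps, min_rows = 1L) {
  if (!is.data.frame(steps) || !all(c("step_id", "samples") %in% names(steps))) {
    abort("`steps` must be a step collection with columns `step_id` and `samples`.")
  }
  if (nrow(steps) < min_rows) {
    abort(sprintf("Step collection must contain at least %d step(s).", min_rows))
  }
  invisible(steps)
}

#' Strategy S1: random template selection
#'
#' Draws `n` distinct steps uniformly without replacement from the training
#' collection and uses their raw waveforms as templates.  The selection is
#' reproducible from `seed`, and the selected step ids are recorded in the
#' library's `"selected_ids"` attribute so callers can hold the source
#' trials out of the test set.
#'
#' @inheritParams build_templates
#' @return A `template_library` of `n` templates (strategy tag `"S1"`).
#' @export
strategy_random <- function(steps, n = 1, seed = NULL) {
  check_collection(steps, min_rows = 1L)
  if (is.null(seed)) {
    abort("`seed` is required for strategy S1 (reproducible random selection).")
  }
  n <- as.integer(n)
  if (n < 1 || n > nrow(steps)) {
    abort(sprintf(
      "`n` must be between 1 and the collection size (%d).", nrow(steps)
    ))
  }
  idx <- withr::with_seed(seed, sample.int(nrow(steps), n, replace = FALSE))
  tpls <- purrr::map(idx, function(i) {
    step_template(steps$samples[[i]],
      strategy = "S1", source = steps$step_id[[i]],
      id = paste0("S1:", steps$step_id[[i]])
    )
  })
  lib <- template_library(tpls)
  attr(lib, "selected_ids") <- steps$step_id[idx]
  lib
}

#' Pairwise DTW distance matrix of a step collection
#'
#' @inheritParams build_templates
#' @return Symmetric matrix of DTW distances with zero diagonal.
#' @keywords internal
pairwise_dtw <- function(steps, maxsamp = 20) {
  k <- nrow(steps)
  dm <- matrix(0, k, k)
  if (k < 2) {
    return(dm)
  }
  for (a in seq_len(k - 1)) {
    for (b in seq((a + 1), k)) {
      sa <- steps$samples[[a]]
      sb <- steps$samples[[b]]
      if (abs(length(sa) - length(sb)) > maxsamp) {
        abort(
          sprintf(
            "Steps %s and %s differ in length by %d > maxsamp = %s; no warping path exists.",
            steps$step_id[[a]], steps$step_id[[b]],
            abs(length(sa) - length(sb)), format(maxsamp)
          ),
          class = "gaitwarp_error_band_infeasible"
        )
      }
      dm[a, b] <- dm[b, a] <- dtw_distance(sa, sb, maxsamp)
    }
  }
  dm
}

#' Strategy S2: DTW medoid
#'
#' Selects the step that minimises the sum of DTW distances to every step in
#' the collection (its own zero self-distance included).  Ties are broken by
#' the lexicographically smallest step id, which also makes the result
#' invariant to the ordering of the collection.
#'
#' @inheritParams build_templates
#' @return A `step_template` with strategy tag `"S2"`.
#' @export
strategy_dtw_medoid <- function(steps, maxsamp = 20) {
  check_collection(steps)
  steps <- arrange(steps, .data$step_id)
  sums <- rowSums(pairwise_dtw(steps, maxsamp))
  best <- which.min(sums) # first minimum = lowest id after the sort
  step_template(steps$samples[[best]],
    strategy = "S2", source = steps$step_id[[best]],
    id = paste0("S2:", steps$step_id[[best]])
  )
}

#' Median step length
#'
#' Median of the step lengths in a collection; for an even number of steps
#' the lower middle value is used, so the result is always one of the
#' observed (integer) lengths.
#'
#' @inheritParams build_templates
#' @return Positive integer.
#' @examples
#' # lengths 60, 63, 70 -> 63; lengths 60, 64 -> 60
#' @export
median_length <- function(steps) {
  check_collection(steps)
  lens <- sort(purrr::map_int(steps$samples, length))
  lens[[ceiling(length(lens) / 2)]]
}

#' Linear resampling to a fixed length
#'
#' Resamples a series to `n_out` points by linear interpolation on a uniform
#' grid over `[0, 1]`; the endpoints map to the endpoints.
#'
#' @param x Numeric vector, length >= 2.
#' @param n_out Target length (>= 2).
#' @return Numeric vector of length `n_out`.
#' @export
resample_linear <- function(x, n_out) {
  check_series(x, min_len = 2L, arg = "x")
  n_out <- as.integer(n_out)
  if (n_out < 2) {
    abort("`n_out` must be >= 2.")
  }
  grid_in <- seq(0, 1, length.out = length(x))
  approx(grid_in, x, xout = seq(0, 1, length.out = n_out))$y
}

#' Strategy S3: linear fusion
#'
#' z-normalises every step, linearly resamples each to the collection's
#' median length, and averages sample-wise.
#'
#' @inheritParams build_templates
#' @return A `step_template` with strategy tag `"S3"` and length
#'   `median_length(steps)`.
#' @export
strategy_linear_fusion <- function(steps) {
  check_collection(steps)
  m <- median_length(steps)
  mat <- purrr::map(steps$samples, function(s) resample_linear(znorm(s), m))
  avg <- Reduce(`+`, mat) / length(mat)
  if (max(avg) == min(avg)) {
    abort(
      "Linear fusion produced a constant template (steps cancel out).",
      class = "gaitwarp_error_degenerate"
    )
  }
  step_template(avg, strategy = "S3", source = sprintf("fusion_of_%d", nrow(steps)), id = "S3:linear")
}

#' Non-linear re-alignment of a step onto a calibration step
#'
#' Warps `step` onto the time base of `calibration` using the optimal DTW
#' path `P*(calibration, step)`: output sample `i` is the arithmetic mean of
#' all `step` samples matched to calibration sample `i` on that path.  The
#' output therefore always has the calibration's length.
#'
#' @param step Numeric step waveform.
#' @param calibration Numeric calibration waveform (the target time base).
#' @inheritParams build_templates
#' @return Numeric vector of length `length(calibration)`.
#' @export
align_to_calibration <- function(step, calibration, maxsamp = 20) {
  al <- dtw_align(calibration, step, maxsamp)
  path <- al$path
  vapply(
    seq_along(calibration),
    function(i) mean(step[path$j[path$i == i]]),
    numeric(1)
  )
}

#' Strategy S4: non-linear (DTW-aligned) fusion
#'
#' All steps are z-normalised; among the steps whose length equals the
#' collection's median length, the one with the smallest mean DTW distance
#' to all steps is chosen as the calibration step; every step is then warped
#' onto the calibration's time base ([align_to_calibration()]) and the
#' warped steps are averaged sample-wise.  When no step has exactly the
#' median length (possible on small synthetic collections), the candidates
#' are the steps whose length is closest to the median, ties going to the
#' shorter length.
#'
#' @inheritParams build_templates
#' @return A `step_template` with strategy tag `"S4"` and length
#'   `median_length(steps)` (or the closest available candidate length).
#' @export
strategy_nonlinear_fusion <- function(steps, maxsamp = 20) {
  check_collection(steps)
  steps <- arrange(steps, .data$step_id)
  normed <- purrr::map(steps$samples, znorm)
  m <- median_length(steps)
  lens <- purrr::map_int(normed, length)
  gap <- abs(lens - m)
  best_gap <- min(gap)
  cand <- which(gap == best_gap)
  if (best_gap > 0) {
    # fallback: closest length, tie to the shorter
    cand_lens <- lens[cand]
    cand <- cand[cand_lens == min(cand_lens)]
  }
  # medoid among candidates: minimum mean DTW distance to ALL steps
  mean_d <- vapply(cand, function(ci) {
    mean(vapply(normed, function(s) {
      dtw_distance(normed[[ci]], s, maxsamp)
    }, numeric(1)))
  }, numeric(1))
  calib_idx <- cand[[which.min(mean_d)]] # ties: lowest id (sorted order)
  calibration <- normed[[calib_idx]]
  aligned <- purrr::map(normed, align_to_calibration,
    calibration = calibration, maxsamp = maxsamp
  )
  avg <- Reduce(`+`, aligned) / length(aligned)
  if (max(avg) == min(avg)) {
    abort("Non-linear fusion produced a constant template.",
      class = "gaitwarp_error_degenerate"
    )
  }
  step_template(avg,
    strategy = "S4",
    source = sprintf("calibration_%s", steps$step_id[[calib_idx]]),
    id = "S4:nonlinear"
  )
}

#' Strategy S5: knowledge-based piecewise-affine template
#'
#' An idealised stance waveform assembled from biomechanical landmarks of
#' the sagittal-plane foot angular velocity: a brief positive deflection at
#' heel strike, the drop to the large negative loading peak, the recovery to
#' the flat-foot plateau, the plateau itself, the steep pre-swing drop to
#' the toe-off minimum, and the final rise at toe off.  Between landmarks
#' the waveform is affine; the breakpoints are continuous.  The default
#' length is 63 samples (the median stance duration at 100 Hz this model
#' was designed for); the function is evaluated at integer abscissae
#' 1..63, or on a uniformly rescaled abscissa for other lengths.
#'
#' @param n_samples Template length (default 63; must be >= 6, the number
#'   of affine segments).
#' @return A `step_template` with strategy tag `"S5"`.
#' @examples
#' tpl <- strategy_piecewise()
#' length(tpl$samples) # 63
#' tpl$samples[30]     # 0.8 (mid-stance plateau)
#' @export
strategy_piecewise <- function(n_samples = 63) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 6) {
    abort("`n_samples` must be >= 6 (fewer samples than affine segments).")
  }
  x <- if (n_samples == 63L) 1:63 else seq(1, 63, length.out = n_samples)
  step_template(piecewise_template_fn(x),
    strategy = "S5", source = "analytic", id = "S5:analytic"
  )
}

#' @rdname strategy_piecewise
#' @param x Abscissa values in `[1, 63]`.
#' @return `piecewise_template_fn()` returns the template ordinates.
#' @export
piecewise_template_fn <- function(x) {
  # affine segments over [1,3], [3,5], [5,16], [16,44], [44,54], [54,63];
  # first-matching-interval evaluation (the function is continuous at the
  # shared breakpoints, so the value there is unambiguous)
  vapply(x, function(xi) {
    if (xi >= 1 && xi <= 3) {
      0.3 * xi - 0.7
    } else if (xi <= 5) {
      -0.8 * xi + 2.6
    } else if (xi <= 16) {
      0.2 * xi - 2.4
    } else if (xi <= 44) {
      0.8
    } else if (xi <= 54) {
      -0.34 * xi + 15.76
    } else if (xi <= 63) {
      0.2 * xi - 13.4
    } else {
      abort("Abscissa outside [1, 63].")
    }
  }, numeric(1))
}
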