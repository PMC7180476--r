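#' Detector configuration
#'
#' Parameters of the two-stage detector: the Pearson threshold of the greedy
#' template-matching stage, the half-width `z` of the DTW refinement lag
#' scan, the DTW band half-width `maxsamp`, and an optional minimum
#' separation between correlation peaks of one template.
#'
#' Defaults are `z = 10` samples and `maxsamp = 20` samples (100 ms and
#' 200 ms at 100 Hz).  With these, every refinement lag pair keeps the
#' window-template length difference within the band; a warning is issued
#' when `2 * z > maxsamp`, since corner lags then become infeasible and are
#' skipped during the scan.
#'
#' @param correlation_threshold Peak acceptance threshold in (0, 1)
#'   (default 0.7).
#' @param z Non-negative integer scan half-width, in samples.
#' @param maxsamp Positive integer DTW band half-width, in samples.
#' @param min_peak_separation Non-negative integer; candidate peaks of the
#'   same template closer than this to a stronger peak are dropped
#'   (default 0 = keep all local maxima).
#'
#' @return A list of class `"detector_config"`.
#' @export
detector_config <- function(correlation_threshold = 0.7, z = 10, maxsamp = 20,
                            min_peak_separation = 0) {
  if (correlation_threshold <= 0 || correlation_threshold >= 1) {
    abort("`correlation_threshold` must lie strictly between 0 and 1.")
  }
  z <- as.integer(z)
  maxsamp <- as.integer(maxsamp)
  min_peak_separation <- as.integer(min_peak_separation)
  if (z < 0) abort("`z` must be >= 0.")
  if (maxsamp < 1) abort("`maxsamp` must be >= 1.")
  if (min_peak_separation < 0) abort("`min_peak_separation` must be >= 0.")
  if (2L * z > maxsamp) {
    warn(sprintf(
      "2 * z = %d exceeds maxsamp = %d: corner lags of the refinement scan are infeasible and will be skipped.",
      2L * z, maxsamp
    ))
  }
  structure(
    list(
      correlation_threshold = correlation_threshold,
      z = z,
      maxsamp = maxsamp,
      min_peak_separation = min_peak_separation
    ),
    class = "detector_config"
  )
}

#' Sliding-window Pearson correlation profile
#'
#' Correlation between a template of length `L` and every length-`L` window
#' of the signal.  Element `start = t` is the Pearson coefficient between
#' the template and `signal[t : (t + L - 1)]`; windows with zero variance
#' are flagged degenerate and given correlation 0.
#'
#' Implemented with rolling sums, so it is exactly the two-pass per-window
#' Pearson coefficient up to floating-point rounding.
#'
#' @param signal A `gait_signal` (or numeric vector).
#' @param template A `step_template` (or numeric vector), no longer than the
#'   signal.
#'
#' @return A tibble with columns `start`, `correlation`, `degenerate`,
#'   with `nrow = length(signal) - L + 1`.
#' @export
correlation_profile <- function(signal, template) {
  x <- if (is.numeric(signal)) signal else signal_samples(signal)
  p <- if (is.numeric(template)) template else template$samples
  check_series(x, min_len = 2L, arg = "signal")
  check_series(p, min_len = 2L, arg = "template")
  L <- length(p)
  n <- length(x)
  if (L > n) {
    abort("Template is longer than the signal.")
  }
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  starts <- seq_len(n - L + 1)
  sx <- cs[starts + L] - cs[starts]
  sxx <- cs2[starts + L] - cs2[starts]
  # cross products via a one-sided linear filter
  f <- stats::filter(x, rev(p), method = "convolution", sides = 1)
  sxy <- as.numeric(f)[starts + L - 1]
  sp <- sum(p)
  spp <- sum(p^2)
  den_p <- L * spp - sp^2
  den_x <- L * sxx - sx^2
  tol <- 1e-10 * pmax(L * sxx, 1)
  degenerate <- den_x <= tol
  r <- rep(0, length(starts))
  ok <- !degenerate
  r[ok] <- (L * sxy[ok] - sx[ok] * sp) / sqrt(den_x[ok] * den_p)
  r <- pmin(1, pmax(-1, r))
  tibble(start = starts, correlation = r, degenerate = degenerate)
}

# strict local maxima (greater than both neighbours); endpoints excluded
local_maxima <- function(r) {
  if (length(r) < 3) {
    return(integer(0))
  }
  which(r[-c(1, length(r))] > r[-c(length(r) - 1, length(r))] &
    r[-c(1, length(r))] > r[-(1:2)]) + 1L
}

#' Greedy template-matching step detection
#'
#' First detection stage.  For every template in the library the Pearson
#' correlation profile over the signal is computed; strict local maxima
#' exceeding the correlation threshold form a candidate pool across all
#' templates.  Candidates are visited in decreasing correlation order and
#' accepted greedily if the template can be placed, i.e. if the window
#' `[t, t + L - 1]` does not overlap an already accepted detection.  Each
#' accepted detection records the generating template; its provisional
#' stance interval has exactly the template's length.
#'
#' @param signal A `gait_signal`.
#' @param library A `template_library`.
#' @param config A [detector_config()].
#'
#' @return A detections tibble sorted by `ic`, with columns `step_id`, `ic`,
#'   `fc`, `template_id`, `correlation`, `dtw_cost` (`NA` before
#'   refinement) and `refined` (`FALSE`).
#' @export
detect_steps <- function(signal, library, config = detector_config()) {
  if (!inherits(library, "template_library")) {
    abort("`library` must be a `template_library`.")
  }
  x <- signal_samples(signal)
  n <- length(x)
  cand <- purrr::imap(library$templates, function(tpl, k) {
    if (length(tpl$samples) > n) {
      abort(sprintf("Template %s is longer than the signal.", tpl$id))
    }
    prof <- correlation_profile(x, tpl$samples)
    peaks <- local_maxima(prof$correlation)
    peaks <- peaks[prof$correlation[peaks] > config$correlation_threshold &
      !prof$degenerate[peaks]]
    if (config$min_peak_separation > 0 && length(peaks) > 1) {
      ord <- peaks[order(-prof$correlation[peaks], peaks)]
      kept <- integer(0)
      for (p in ord) {
        if (all(abs(kept - p) >= config$min_peak_separation)) kept <- c(kept, p)
      }
      peaks <- sort(kept)
    }
    tibble(
      template_pos = k,
      template_id = tpl$id,
      tlen = length(tpl$samples),
      start = prof$start[peaks],
      correlation = prof$correlation[peaks]
    )
  })
  cand <- bind_rows(cand)
  if (nrow(cand) == 0) {
    return(empty_detections())
  }
  cand <- cand[order(-cand$correlation, cand$start, cand$template_pos), ]
  acc_ic <- integer(0)
  acc_fc <- integer(0)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    ic <- cand$start[[r]]
    fc <- ic + cand$tlen[[r]] - 1L
    if (!any(ic <= acc_fc & fc >= acc_ic)) {
      keep[[r]] <- TRUE
      acc_ic <- c(acc_ic, ic)
      acc_fc <- c(acc_fc, fc)
    }
  }
  out <- cand[keep, ]
  out <- tibble(
    ic = as.integer(out$start),
    fc = as.integer(out$start + out$tlen - 1L),
    template_id = out$template_id,
    correlation = out$correlation
  )
  out <- arrange(out, .data$ic)
  tibble(
    step_id = seq_len(nrow(out)),
    out,
    dtw_cost = NA_real_,
    refined = FALSE
  )
}

empty_detections <- function() {
  tibble(
    step_id = integer(0), ic = integer(0), fc = integer(0),
    template_id = character(0), correlation = numeric(0),
    dtw_cost = numeric(0), refined = logical(0)
  )
}

# lag grid ordered for the argmin tie-break: smallest |k| + |l|, then (k, l)
lag_grid <- function(z) {
  g <- expand.grid(l = -z:z, k = -z:z)
  g <- g[order(abs(g$k) + abs(g$l), g$k, g$l), c("k", "l")]
  g
}

#' Refine one detection by a DTW lag scan
#'
#' Second detection stage.  Scans all `(2z + 1)^2` lag pairs
#' `(k, l)` in `[-z, z]^2` around a provisional detection, computing the DTW
#' distance between the shifted window `signal[ic + k : fc + l]` and the
#' generating template; the lag minimising that distance gives the refined
#' boundaries `ic* = ic + k*`, `fc* = fc + l*`.  Lags whose window leaves
#' the signal, has fewer than 2 samples, is constant, or violates the DTW
#' band are skipped.  Ties in the minimisation prefer the smallest
#' `|k| + |l|`, then lexicographic `(k, l)`, so the least perturbation wins.
#'
#' @param signal A `gait_signal`.
#' @param detection One row of a detections tibble.
#' @param template The `step_template` that generated the detection.
#' @param config A [detector_config()].
#'
#' @return The detection row with refined `ic`, `fc`, populated `dtw_cost`
#'   and `refined = TRUE`.
#' @export
refine_detection_dtw <- function(signal, detection, template,
                                 config = detector_config()) {
  x <- signal_samples(signal)
  n <- length(x)
  pz <- znorm(template$samples)
  L <- length(pz)
  grid <- lag_grid(config$z)
  best <- Inf
  best_k <- NA_integer_
  best_l <- NA_integer_
  for (r in seq_len(nrow(grid))) {
    k <- grid$k[[r]]
    l <- grid$l[[r]]
    ic2 <- detection$ic + k
    fc2 <- detection$fc + l
    len <- fc2 - ic2 + 1L
    if (ic2 < 1L || fc2 > n || len < 2L || abs(len - L) > config$maxsamp) next
    w <- x[ic2:fc2]
    mu <- mean(w)
    s <- sqrt(mean((w - mu)^2))
    if (s == 0) next
    d <- dtw_distance_znormed((w - mu) / s, pz, config$maxsamp)
    if (d < best) {
      best <- d
      best_k <- k
      best_l <- l
    }
  }
  if (!is.finite(best)) {
    abort("All refinement lags are invalid for this detection.",
      class = "gaitwarp_error_refinement"
    )
  }
  detection$ic <- as.integer(detection$ic + best_k)
  detection$fc <- as.integer(detection$fc + best_l)
  detection$dtw_cost <- best
  detection$refined <- TRUE
  detection
}

#' Refine one detection by a Pearson lag scan
#'
#' Comparator variant of [refine_detection_dtw()]: the same lag scan, but
#' each candidate window is linearly resampled to the template length and
#' the lag *maximising* the Pearson correlation with the template is
#' applied.  This replaces the non-linear DTW alignment by a purely linear
#' rescaling, and serves as the linear-correlation baseline in the
#' distance-criterion experiment.
#'
#' @inheritParams refine_detection_dtw
#' @return The detection row with refined boundaries, updated `correlation`
#'   and `refined = TRUE` (`dtw_cost` stays `NA`).
#' @export
refine_detection_pearson <- function(signal, detection, template,
                                     config = detector_config()) {
  x <- signal_samples(signal)
  n <- length(x)
  p <- template$samples
  L <- length(p)
  grid <- lag_grid(config$z)
  best <- -Inf
  best_k <- NA_integer_
  best_l <- NA_integer_
  for (r in seq_len(nrow(grid))) {
    k <- grid$k[[r]]
    l <- grid$l[[r]]
    ic2 <- detection$ic + k
    fc2 <- detection$fc + l
    len <- fc2 - ic2 + 1L
    if (ic2 < 1L || fc2 > n || len < 2L) next
    w <- x[ic2:fc2]
    if (max(w) == min(w)) next
    rw <- resample_linear(w, L)
    if (max(rw) == min(rw)) next
    r2 <- cor(rw, p)
    if (is.finite(r2) && r2 > best) {
      best <- r2
      best_k <- k
      best_l <- l
    }
  }
  if (!is.finite(best)) {
    abort("All refinement lags are invalid for this detection.",
      class = "gaitwarp_error_refinement"
    )
  }
  detection$ic <- as.integer(detection$ic + best_k)
  detection$fc <- as.integer(detection$fc + best_l)
  detection$correlation <- best
  detection$refined <- TRUE
  detection
}

#' Detect and refine all steps in a trial
#'
#' Composition of the two stages: greedy template matching
#' ([detect_steps()]) followed by per-detection refinement with the chosen
#' criterion.  Refinement may re-introduce small overlaps between adjacent
#' detections; these are permitted and counted in the result's
#' `"n_overlaps"` attribute.
#'
#' @inheritParams detect_steps
#' @param criterion `"dtw"` (default), `"pearson"`, or `"none"` (skip
#'   refinement).
#'
#' @return Detections tibble sorted by `ic` (see [detect_steps()]).
#' @export
detect_and_refine <- function(signal, library, config = detector_config(),
                              criterion = c("dtw", "pearson", "none")) {
  criterion <- match.arg(criterion)
  det <- detect_steps(signal, library, config)
  if (criterion == "none" || nrow(det) == 0) {
    return(det)
  }
  out <- refine_detections(signal, det, library, config, criterion)
  out <- arrange(out, .data$ic)
  out$step_id <- seq_len(nrow(out))
  out
}

#' Refine a whole detections tibble
#'
#' Applies [refine_detection_dtw()] or [refine_detection_pearson()] to each
#' row of a detections tibble, keeping the original `step_id`s and row
#' order, so refined variants produced from the same initial detections
#' stay pairable row by row.
#'
#' @inheritParams detect_steps
#' @param detections Detections tibble from [detect_steps()].
#' @param criterion `"dtw"` or `"pearson"`.
#' @return Detections tibble with refined boundaries.
#' @export
refine_detections <- function(signal, detections, library,
                              config = detector_config(),
                              criterion = c("dtw", "pearson")) {
  criterion <- match.arg(criterion)
  if (nrow(detections) == 0) {
    return(detections)
  }
  tpl_by_id <- stats::setNames(
    library$templates,
    purrr::map_chr(library$templates, "id")
  )
  refiner <- if (criterion == "dtw") refine_detection_dtw else refine_detection_pearson
  out <- bind_rows(purrr::map(seq_len(nrow(detections)), function(r) {
    refiner(signal, detections[r, ], tpl_by_id[[detections$template_id[[r]]]], config)
  }))
  n_overlap <- if (nrow(out) > 1) {
    o <- arrange(out, .data$ic)
    sum(o$ic[-1] <= o$fc[-nrow(o)])
  } else {
    0L
  }
  attr(out, "n_overlaps") <- n_overlap
  out
}
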