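#' Parameters of the synthetic gait generator
#'
#' The generator emulates the statistical structure of foot-mounted
#' gyrometer walking trials sampled at 100 Hz: about eight stance phases
#' per straight-line passage, stance durations centred on a median of 63
#' samples, quiescent swing segments between stances (stance is roughly 60%
#' of the gait cycle, so default swings are 30-54 samples), subject-level
#' duration/amplitude variability, non-linear within-step time warps
#' bounded so they stay inside the DTW band used downstream, positive
#' amplitude scaling, a baseline offset, and additive white noise.
#'
#' @param n_trials Number of trials in a cohort.
#' @param steps_per_trial Stances per trial (default 8).
#' @param sampling_rate_hz Sampling rate (default 100).
#' @param stance_len_median Median stance duration in samples (default 63).
#' @param stance_len_spread Half-width of the symmetric discretised stance
#'   length law (a centred binomial on `median + (-spread .. spread)`;
#'   default 6).
#' @param warp_intensity Maximum deviation of the within-step monotone time
#'   warp from the diagonal, in samples (default 8; keep `<= maxsamp` of
#'   the detector).
#' @param warp_mode `"nonlinear"` (random monotone warp, the default) or
#'   `"linear"` (pure linear resampling to the drawn stance length).
#' @param amp_scale_range Range of the uniform positive amplitude factor.
#' @param offset_range Range of the uniform additive baseline offset.
#' @param noise_sd Standard deviation of the white noise added to stances
#'   (template units; the prototype spans about 3.4 units peak to peak).
#' @param swing_len_range Integer range of swing-segment lengths, samples.
#' @param swing_noise_sd Standard deviation of the smoothed swing-segment
#'   noise (default 0.08).
#' @param subject_len_spread Per-subject stance-duration offset is drawn
#'   uniformly from `-subject_len_spread .. subject_len_spread` samples.
#' @param n_subjects Subjects the trials are cycled over (default 13).
#' @param prototype Prototype stance waveform (numeric); defaults to the
#'   piecewise-affine template of [strategy_piecewise()].
#' @param seed Cohort RNG seed (mandatory for [synth_cohort()]).
#'
#' @return A list of class `"synth_params"`.
#' @export
synth_params <- function(n_trials = 20, steps_per_trial = 8,
                         sampling_rate_hz = 100, stance_len_median = 63,
                         stance_len_spread = 6, warp_intensity = 8,
                         warp_mode = c("nonlinear", "linear"),
                         amp_scale_range = c(0.8, 1.25),
                         offset_range = c(-0.2, 0.2), noise_sd = 0.05,
                         swing_len_range = c(30, 54), swing_noise_sd = 0.08,
                         subject_len_spread = 2, n_subjects = 13,
                         prototype = NULL, seed = 1) {
  warp_mode <- match.arg(warp_mode)
  if (n_trials < 1 || steps_per_trial < 1) {
    abort("`n_trials` and `steps_per_trial` must be positive.")
  }
  if (stance_len_spread < 0 || warp_intensity < 0) {
    abort("`stance_len_spread` and `warp_intensity` must be >= 0.")
  }
  if (length(amp_scale_range) != 2 || any(amp_scale_range <= 0) ||
      diff(amp_scale_range) < 0) {
    abort("`amp_scale_range` must be a positive non-degenerate interval.")
  }
  if (length(swing_len_range) != 2 || swing_len_range[[1]] < 1 ||
      diff(swing_len_range) < 0) {
    abort("`swing_len_range` must be an increasing positive interval.")
  }
  if (is.null(prototype)) prototype <- strategy_piecewise(63)$samples
  check_series(prototype, min_len = 6L, arg = "prototype")
  structure(
    list(
      n_trials = as.integer(n_trials),
      steps_per_trial = as.integer(steps_per_trial),
      sampling_rate_hz = sampling_rate_hz,
      stance_len_median = as.integer(stance_len_median),
      stance_len_spread = as.integer(stance_len_spread),
      warp_intensity = as.integer(warp_intensity),
      warp_mode = warp_mode,
      amp_scale_range = amp_scale_range,
      offset_range = offset_range,
      noise_sd = noise_sd,
      swing_len_range = as.integer(swing_len_range),
      swing_noise_sd = swing_noise_sd,
      subject_len_spread = as.integer(subject_len_spread),
      n_subjects = as.integer(n_subjects),
      prototype = as.numeric(prototype),
      seed = as.integer(seed)
    ),
    class = "synth_params"
  )
}

#' Random monotone time warp
#'
#' Draws a monotone non-decreasing index map from an output grid of
#' `length_out` samples onto an input grid of `length_in` samples, with
#' `map(1) = 1`, `map(length_out) = length_in`, and deviation from the
#' (rescaled) diagonal bounded by `warp_intensity` samples.  When the
#' output is at least as long as the input the increments are 0 or 1 (the
#' map is surjective and duplicates samples); when it is shorter the
#' increments are 1 or 2 (the map subsamples).  With `warp_intensity = 0`
#' and equal lengths the map is the identity.  Uses the current RNG state.
#'
#' @param length_in,length_out Grid lengths (`>= 2`), with
#'   `abs(length_in - length_out) <= warp_intensity` unless equal.
#' @param warp_intensity Maximum deviation from the diagonal, samples.
#' @return Integer vector of length `length_out` with values in
#'   `1..length_in`.
#' @export
random_monotone_warp <- function(length_in, length_out, warp_intensity) {
  length_in <- as.integer(length_in)
  length_out <- as.integer(length_out)
  if (length_in < 2 || length_out < 2) {
    abort("Grid lengths must be >= 2.")
  }
  if (abs(length_in - length_out) > max(warp_intensity, 0)) {
    abort(
      sprintf(
        "Length difference %d exceeds warp_intensity = %d.",
        abs(length_in - length_out), warp_intensity
      ),
      class = "gaitwarp_error_band_infeasible"
    )
  }
  a <- if (length_in <= length_out) 0L else 1L # base increment
  slots <- length_out - 1L
  ones <- (length_in - 1L) - a * slots # slots taking increment a + 1
  diagonal <- 1 + (seq_len(length_out) - 1) * (length_in - 1) / (length_out - 1)
  map <- integer(length_out)
  map[[1]] <- 1L
  ones_left <- ones
  for (i in seq_len(slots)) {
    slots_left <- slots - i + 1L
    take <- ones_left > 0 && stats::runif(1) < ones_left / slots_left
    step <- a + as.integer(take)
    nxt <- map[[i]] + step
    # clamp to the diagonal corridor and to end-point feasibility
    lo <- max(
      map[[i]] + a, ceiling(diagonal[[i + 1]] - warp_intensity),
      length_in - (a + 1L) * (slots - i)
    )
    hi <- min(
      map[[i]] + a + 1L, floor(diagonal[[i + 1]] + warp_intensity),
      length_in - a * (slots - i)
    )
    nxt <- min(max(nxt, lo), hi)
    ones_left <- ones_left - (nxt - map[[i]] - a)
    map[[i + 1]] <- nxt
  }
  map
}

# symmetric discretised stance-length law: median + centred binomial
draw_stance_length <- function(n, median_len, spread, subject_offset = 0L) {
  if (spread == 0) {
    return(rep(median_len + subject_offset, n))
  }
  median_len + subject_offset + stats::rbinom(n, 2L * spread, 0.5) - spread
}

#' Synthesise one stance-step waveform
#'
#' Draws a stance duration from the symmetric length law, warps the
#' prototype to that duration (randomly and monotonically, or linearly in
#' `warp_mode = "linear"`), applies a positive amplitude factor and a
#' baseline offset, and adds white noise.  Uses the current RNG state.
#'
#' @param params A [synth_params()] object.
#' @param subject_len_offset Per-subject stance-duration offset, samples.
#' @param subject_amp Per-subject amplitude factor.
#' @return A list with `waveform` (numeric) and `length` (its duration).
#' @export
synth_step <- function(params, subject_len_offset = 0L, subject_amp = 1) {
  proto <- params$prototype
  np <- length(proto)
  len <- draw_stance_length(
    1L, params$stance_len_median, params$stance_len_spread, subject_len_offset
  )
  # the warp (and downstream DTW band) must be able to absorb the length change
  len <- min(max(len, np - params$warp_intensity, 2L), np + params$warp_intensity)
  base <- if (params$warp_mode == "linear" || params$warp_intensity == 0) {
    if (len == np) proto else resample_linear(proto, len)
  } else {
    proto[random_monotone_warp(np, len, params$warp_intensity)]
  }
  amp <- subject_amp * stats::runif(1, params$amp_scale_range[[1]], params$amp_scale_range[[2]])
  off <- stats::runif(1, params$offset_range[[1]], params$offset_range[[2]])
  noise <- if (params$noise_sd > 0) stats::rnorm(len, 0, params$noise_sd) else 0
  list(waveform = amp * base + off + noise, length = len)
}

# smoothed low-variance noise standing in for the swing (airborne) phase
synth_swing <- function(len, sd) {
  if (sd == 0) {
    return(rep(0, len))
  }
  raw <- stats::rnorm(len + 6L, 0, sd)
  sm <- as.numeric(stats::filter(raw, rep(1 / 7, 7), sides = 2))
  sm <- sm[!is.na(sm)][seq_len(len)]
  sm * sd / max(sd(sm), 1e-12)
}

#' Synthesise one annotated trial
#'
#' Alternates swing segments (smooth low-variance noise around zero) with
#' synthesised stances and records each stance's exact `[ic, fc]` interval,
#' so the ground truth is known by construction.  Uses the current RNG
#' state; seed at the cohort level ([synth_cohort()]) for reproducibility.
#'
#' @inheritParams synth_step
#' @param trial_id,subject_id Identifiers stored on the signal.
#' @return A list with `signal` (a [gait_signal()]) and `annotations`
#'   (tibble `step_id`, `ic`, `fc`).
#' @export
synth_trial <- function(params, trial_id = "trial1", subject_id = "subj1",
                        subject_len_offset = 0L, subject_amp = 1) {
  pieces <- list()
  ic <- integer(params$steps_per_trial)
  fc <- integer(params$steps_per_trial)
  cursor <- 0L
  for (s in seq_len(params$steps_per_trial)) {
    swing_len <- sample(params$swing_len_range[[1]]:params$swing_len_range[[2]], 1L)
    pieces <- c(pieces, list(synth_swing(swing_len, params$swing_noise_sd)))
    cursor <- cursor + swing_len
    st <- synth_step(params, subject_len_offset, subject_amp)
    ic[[s]] <- cursor + 1L
    fc[[s]] <- cursor + st$length
    cursor <- cursor + st$length
    pieces <- c(pieces, list(st$waveform))
  }
  tail_len <- sample(params$swing_len_range[[1]]:params$swing_len_range[[2]], 1L)
  pieces <- c(pieces, list(synth_swing(tail_len, params$swing_noise_sd)))
  sig <- gait_signal(
    unlist(pieces),
    sampling_rate_hz = params$sampling_rate_hz,
    trial_id = trial_id, subject_id = subject_id
  )
  list(signal = sig, annotations = step_annotations(ic = ic, fc = fc))
}

#' Synthesise an annotated cohort
#'
#' Generates `n_trials` independent trials, cycling trials over
#' `n_subjects` synthetic subjects that each carry a fixed stance-duration
#' offset and amplitude factor.  The whole cohort is reproducible from
#' `params$seed`: the same parameters always give an identical dataset.
#'
#' @param params A [synth_params()] object.
#' @return An object of class `"gait_cohort"`: `trials` (named list of
#'   [gait_signal()]s), `annotations` (one tibble with `trial_id`,
#'   `subject_id`, `step_id`, `ic`, `fc`), `subjects` (per-subject factors)
#'   and `params`.
#' @export
synth_cohort <- function(params) {
  if (!inherits(params, "synth_params")) {
    abort("`params` must come from synth_params().")
  }
  withr::with_seed(params$seed, {
    ns <- min(params$n_subjects, params$n_trials)
    subjects <- tibble(
      subject_id = paste0("subj", seq_len(ns)),
      len_offset = sample(
        seq(-params$subject_len_spread, params$subject_len_spread),
        ns,
        replace = TRUE
      ),
      amp_factor = stats::runif(ns, 0.9, 1.1)
    )
    trials <- vector("list", params$n_trials)
    anns <- vector("list", params$n_trials)
    tids <- sprintf("trial%02d", seq_len(params$n_trials))
    for (t in seq_len(params$n_trials)) {
      si <- ((t - 1L) %% ns) + 1L
      tr <- synth_trial(
        params,
        trial_id = tids[[t]],
        subject_id = subjects$subject_id[[si]],
        subject_len_offset = subjects$len_offset[[si]],
        subject_amp = subjects$amp_factor[[si]]
      )
      trials[[t]] <- tr$signal
      anns[[t]] <- mutate(tr$annotations,
        trial_id = tids[[t]],
        subject_id = subjects$subject_id[[si]], .before = 1
      )
    }
    names(trials) <- tids
    structure(
      list(
        trials = trials,
        annotations = bind_rows(anns),
        subjects = subjects,
        params = params
      ),
      class = "gait_cohort"
    )
  })
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf(
    "<gait_cohort> %d trial(s), %d annotated steps, %d subject(s), seed %d\n",
    length(x$trials), nrow(x$annotations), nrow(x$subjects), x$params$seed
  ))
  invisible(x)
}

#' Pool all annotated steps of a cohort into a step collection
#'
#' @param cohort A `gait_cohort`.
#' @return A step-collection tibble (see [extract_steps()]).
#' @export
steps_from_cohort <- function(cohort) {
  bind_rows(purrr::map(names(cohort$trials), function(tid) {
    ann <- filter(cohort$annotations, .data$trial_id == tid)
    extract_steps(cohort$trials[[tid]], select(ann, "step_id", "ic", "fc"))
  }))
}
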