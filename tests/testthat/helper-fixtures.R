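# Shared fixtures, built in code at test time.

proto63 <- strategy_piecewise()$samples

# A warped instance of the prototype made by duplicating interior samples:
# monotone, within-band, strictly increasing at the edges so the true
# window boundaries are unambiguous.
spliced_instance <- function(dups = c(20, 25, 30, 35, 40)) {
  map <- sort(c(seq_along(proto63), dups))
  proto63[map]
}

# Quiet-baseline signal with instances placed at given start indices.
embed_instances <- function(instances, starts, total_len, rate = 100) {
  x <- rep(0, total_len)
  for (i in seq_along(instances)) {
    w <- instances[[i]]
    x[starts[[i]]:(starts[[i]] + length(w) - 1)] <- w
  }
  gait_signal(x, sampling_rate_hz = rate, trial_id = "fixture")
}

# One-row detections tibble in the detector's schema.
detection_row <- function(ic, fc, template_id = "S5:analytic",
                          correlation = NA_real_) {
  tibble::tibble(
    step_id = 1L, ic = as.integer(ic), fc = as.integer(fc),
    template_id = template_id, correlation = correlation,
    dtw_cost = NA_real_, refined = FALSE
  )
}

# Small random step collection (non-constant waveforms of varying length).
random_collection <- function(n, len_range = c(58, 68), seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      step_id = sprintf("s%02d", seq_len(n)),
      trial_id = sprintf("t%02d", seq_len(n)),
      samples = lapply(seq_len(n), function(i) {
        len <- sample(len_range[[1]]:len_range[[2]], 1)
        proto63[round(seq(1, 63, length.out = len))] + rnorm(len, 0, 0.1)
      })
    )
  })
}

quick_params <- function(...) {
  synth_params(n_trials = 4, steps_per_trial = 4, ...)
}

detect_cohort <- function(cohort, lib, config = detector_config(),
                          criterion = "dtw") {
  dets <- lapply(names(cohort$trials), function(tid) {
    detect_and_refine(cohort$trials[[tid]], lib, config, criterion)
  })
  names(dets) <- names(cohort$trials)
  dets
}
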