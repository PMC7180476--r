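test_that("the monotone warp is the identity at zero intensity and equal lengths", {
  expect_equal(random_monotone_warp(63, 63, 0), 1:63)
})

test_that("monotone warps are non-decreasing, surjective where possible, and band-bounded", {
  withr::with_seed(5, {
    for (rep in 1:200) {
      w <- sample(1:10, 1)
      n_in <- sample(40:80, 1)
      n_out <- n_in + sample(-min(w, 8):min(w, 8), 1)
      if (n_out < 2) next
      map <- random_monotone_warp(n_in, n_out, w)
      expect_equal(map[[1]], 1L)
      expect_equal(map[[length(map)]], n_in)
      expect_true(all(diff(map) >= 0))
      if (n_out >= n_in) {
        expect_true(all(diff(map) <= 1))
        expect_setequal(unique(map), 1:n_in) # surjective: duplication only
      }
      diagonal <- 1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
      expect_true(all(abs(map - diagonal) <= w))
    }
  })
  expect_error(random_monotone_warp(80, 60, 5),
    class = "gaitwarp_error_band_infeasible"
  )
})

test_that("the stance-length law has the configured median", {
  withr::with_seed(2, {
    lens <- gaitwarp:::draw_stance_length(10000, 63L, 6L)
  })
  expect_equal(median(lens), 63)
  expect_true(all(abs(lens - 63) <= 6))
  expect_equal(gaitwarp:::draw_stance_length(5, 63L, 0L), rep(63, 5))
})

test_that("a noiseless unwarped unit-scale step is the prototype itself", {
  p <- synth_params(
    stance_len_spread = 0, warp_intensity = 0, noise_sd = 0,
    amp_scale_range = c(1, 1), offset_range = c(0, 0)
  )
  withr::with_seed(1, st <- synth_step(p))
  expect_equal(st$waveform, p$prototype)
  expect_equal(st$length, 63L)
})

test_that("noiseless warped steps stay DTW-close to the prototype", {
  # the warp duplicates samples, which slightly shifts the warped series'
  # own mean/sd; the z-normalised pointwise distance is therefore small
  # but not exactly zero
  p <- synth_params(
    noise_sd = 0, warp_intensity = 8, stance_len_spread = 6,
    offset_range = c(0, 0)
  )
  withr::with_seed(17, {
    for (rep in 1:20) {
      st <- synth_step(p)
      d <- dtw_distance(st$waveform, p$prototype, 20)
      d_mismatch <- dtw_distance(st$waveform, rev(p$prototype), 20)
      expect_lt(d, 0.5)
      expect_lt(d, 0.05 * d_mismatch)
    }
  })
})

test_that("trials alternate swing and stance with exact annotations", {
  p1 <- synth_params(steps_per_trial = 1, seed = 3)
  withr::with_seed(3, tr <- synth_trial(p1))
  expect_equal(nrow(tr$annotations), 1)

  p <- synth_params(steps_per_trial = 6)
  withr::with_seed(9, {
    for (rep in 1:10) {
      tr <- synth_trial(p)
      ann <- tr$annotations
      expect_equal(nrow(ann), 6)
      expect_true(all(diff(ann$ic) > 0))
      expect_true(all(ann$ic[-1] > ann$fc[-6])) # non-overlapping
      expect_true(all(ann$fc <= nrow(tr$signal)))
      expect_true(all(ann$fc - ann$ic + 1 >= 2))
    }
  })
})

test_that("cohorts are reproducible from their seed", {
  p <- quick_params(seed = 1234)
  a <- synth_cohort(p)
  b <- synth_cohort(p)
  expect_identical(a, b)
  c2 <- synth_cohort(quick_params(seed = 1235))
  expect_false(identical(
    signal_samples(a$trials[[1]]),
    signal_samples(c2$trials[[1]])
  ))
})

test_that("cohort structure matches the configured study conditions", {
  p <- synth_params(n_trials = 12, steps_per_trial = 8, seed = 6)
  co <- synth_cohort(p)
  expect_length(co$trials, 12)
  expect_equal(nrow(co$annotations), 12 * 8)
  durations <- co$annotations$fc - co$annotations$ic + 1
  expect_lte(abs(median(durations) - 63), 2) # subject offsets perturb slightly
  expect_true(all(abs(durations - 63) <= p$warp_intensity))
  steps <- steps_from_cohort(co)
  expect_equal(nrow(steps), 96)
  expect_equal(median_length(steps), sort(steps$length)[ceiling(96 / 2)])
})
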