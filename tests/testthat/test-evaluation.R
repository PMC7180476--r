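test_that("midpoint matching accepts exact detections and enforces one-to-one", {
  ann <- step_annotations(ic = 10, fc = 72)
  m <- match_detections(detection_row(10, 72), ann)
  expect_equal(nrow(m$pairs), 1)
  expect_length(m$false_detections, 0)

  # two detections inside one annotation: all but one are false
  det2 <- dplyr::bind_rows(detection_row(10, 72), detection_row(14, 76))
  det2$step_id <- 1:2
  m2 <- match_detections(det2, ann)
  expect_equal(nrow(m2$pairs), 1)
  expect_equal(m2$pairs$det_step_id, 1L) # midpoint-closest survives
  expect_equal(m2$false_detections, 2L)

  # midpoint exactly at fc is inside; one sample past fc is outside
  expect_equal(nrow(match_detections(detection_row(40, 104), ann)$pairs), 1)
  expect_equal(nrow(match_detections(detection_row(42, 104), ann)$pairs), 0)
})

test_that("the toy sets give precision 2/3 and recall 1/2", {
  ann <- step_annotations(ic = c(10, 50, 90, 130), fc = c(40, 80, 120, 160))
  det <- dplyr::bind_rows(
    detection_row(10, 40), # correct
    detection_row(12, 42), # duplicate inside annotation 1 -> false
    detection_row(50, 80) # correct
  )
  det$step_id <- 1:3
  pr <- precision_recall(det, ann)
  expect_equal(pr$precision, 2 / 3)
  expect_equal(pr$recall, 1 / 2)
  expect_equal(pr$n_correct, 2)
})

test_that("degenerate detection sets yield NA precision or zero recall", {
  ann <- step_annotations(ic = c(10, 50), fc = c(40, 80))
  none <- detection_row(10, 40)[0, ]
  pr <- precision_recall(none, ann)
  expect_true(is.na(pr$precision))
  expect_equal(pr$recall, 0)
  pr2 <- precision_recall(detection_row(10, 40), ann[0, ])
  expect_true(is.na(pr2$recall))
})

test_that("precision and recall are invariant to input ordering", {
  withr::with_seed(8, {
    ann <- step_annotations(ic = seq(10, 370, by = 120), fc = seq(80, 440, by = 120))
    det <- dplyr::bind_rows(lapply(seq_len(nrow(ann)), function(i) {
      detection_row(ann$ic[i] + sample(-3:3, 1), ann$fc[i] + sample(-3:3, 1))
    }))
    det$step_id <- seq_len(nrow(det))
    base <- precision_recall(det, ann)
    perm <- sample(nrow(det))
    again <- precision_recall(det[perm, ], ann[sample(nrow(ann)), ])
    expect_equal(again$precision, base$precision)
    expect_equal(again$recall, base$recall)
  })
})

test_that("timing errors convert sample offsets to milliseconds", {
  ann <- step_annotations(ic = 10, fc = 72)
  m <- match_detections(detection_row(12, 72), ann)
  e <- timing_errors(m, sampling_rate_hz = 100)
  expect_equal(e$delta_start_ms, 20)
  expect_equal(e$delta_end_ms, 0)
  expect_equal(e$delta_duration_ms, 20)
  expect_equal(e$start_error_ms, 20) # signed: detected late
  expect_equal(e$duration_error_ms, -20) # detected shorter

  e2 <- timing_errors(match_detections(detection_row(12, 72), ann),
    sampling_rate_hz = 200
  )
  expect_equal(e2$delta_start_ms, 10)
})

test_that("exact detections give unit scores and all-zero error distributions", {
  ann <- step_annotations(ic = c(10, 100, 200), fc = c(72, 165, 260))
  det <- dplyr::bind_rows(
    detection_row(10, 72), detection_row(100, 165), detection_row(200, 260)
  )
  det$step_id <- 1:3
  rep <- evaluate_detections(det, ann)
  g <- glance(rep)
  expect_equal(g$precision, 1)
  expect_equal(g$recall, 1)
  expect_true(all(tidy(rep)$delta_start_ms == 0))
  expect_true(all(tidy(rep)$delta_end_ms == 0))
  expect_true(all(tidy(rep)$delta_duration_ms == 0))
})

test_that("duration error obeys the triangle inequality on signed errors", {
  withr::with_seed(77, {
    ann <- step_annotations(ic = seq(10, 1210, by = 120), fc = seq(80, 1280, by = 120))
    det <- dplyr::bind_rows(lapply(seq_len(nrow(ann)), function(i) {
      detection_row(ann$ic[i] + sample(-8:8, 1), ann$fc[i] + sample(-8:8, 1))
    }))
    det$step_id <- seq_len(nrow(det))
    e <- timing_errors(match_detections(det, ann))
    expect_true(all(e$delta_duration_ms <= e$delta_start_ms + e$delta_end_ms + 1e-9))
  })
})

test_that("cohort evaluation pools counts and concatenates errors", {
  co <- synth_cohort(quick_params(seed = 33))
  lib <- build_templates(NULL, "S5")
  dets <- detect_cohort(co, lib)
  pooled <- evaluate_cohort(dets, co$annotations)
  per_trial <- lapply(names(dets), function(tid) {
    evaluate_detections(
      dets[[tid]],
      dplyr::filter(co$annotations, trial_id == tid)
    )
  })
  expect_equal(
    pooled$counts$n_correct,
    sum(vapply(per_trial, function(r) r$counts$n_correct, 0))
  )
  expect_equal(
    nrow(pooled$errors),
    sum(vapply(per_trial, function(r) nrow(r$errors), 0))
  )
})
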