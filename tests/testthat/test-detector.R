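test_that("correlation profile matches a naive per-window Pearson oracle", {
  withr::with_seed(31, {
    x <- rnorm(150)
    p <- rnorm(20)
  })
  prof <- correlation_profile(x, p)
  expect_equal(nrow(prof), 150 - 20 + 1)
  naive <- vapply(prof$start, function(t) cor(x[t:(t + 19)], p), 0)
  expect_equal(prof$correlation, naive, tolerance = 1e-10)
})

test_that("correlation profile flags degenerate windows and exact copies", {
  tpl <- proto63
  sig <- embed_instances(list(3.2 * tpl + 1), starts = 41, total_len = 200)
  prof <- correlation_profile(sig, tpl)
  expect_equal(prof$correlation[prof$start == 41], 1, tolerance = 1e-8)

  flat <- correlation_profile(rep(2, 80), tpl)
  expect_true(all(flat$degenerate))
  expect_true(all(flat$correlation == 0))

  expect_error(correlation_profile(rnorm(10), tpl), "longer")
})

test_that("greedy matching finds isolated instances and respects non-overlap", {
  lib <- build_templates(NULL, "S5")
  sig1 <- embed_instances(list(proto63), starts = 51, total_len = 170)
  det1 <- detect_steps(sig1, lib)
  expect_equal(nrow(det1), 1)
  expect_equal(det1$ic, 51L)
  expect_equal(det1$fc, 113L)
  expect_equal(det1$correlation, 1, tolerance = 1e-8)
  expect_false(det1$refined)

  sig2 <- embed_instances(list(proto63, proto63), starts = c(31, 181), total_len = 300)
  expect_equal(nrow(detect_steps(sig2, lib)), 2)

  # two overlapping candidates: the higher-correlation template wins and
  # the weaker one cannot be placed
  tpl_b <- step_template(resample_linear(proto63, 58),
    strategy = "S5", source = "variant", id = "S5:short"
  )
  lib2 <- template_library(list(lib$templates[[1]], tpl_b))
  det2 <- detect_steps(sig1, lib2)
  expect_equal(nrow(det2), 1)
  expect_equal(det2$template_id, "S5:analytic")
})

test_that("refinement with z = 0 only populates the cost", {
  sig <- embed_instances(list(proto63), starts = 51, total_len = 170)
  tpl <- strategy_piecewise()
  d0 <- detection_row(51, 113)
  cfg <- detector_config(z = 0)
  r <- refine_detection_dtw(sig, d0, tpl, cfg)
  expect_equal(r$ic, 51L)
  expect_equal(r$fc, 113L)
  expect_true(r$refined)
  expect_equal(r$dtw_cost, 0, tolerance = 1e-12)
})

test_that("refined cost is the grid minimum and never exceeds the lag-(0,0) cost", {
  sig <- embed_instances(list(spliced_instance()), starts = 51, total_len = 170)
  tpl <- strategy_piecewise()
  cfg <- detector_config()
  d0 <- detection_row(46, 121)
  r <- refine_detection_dtw(sig, d0, tpl, cfg)
  cost_lag0 <- dtw_distance(signal_samples(sig)[46:121], tpl$samples, cfg$maxsamp)
  expect_lte(r$dtw_cost, cost_lag0)
  expect_lte(abs(r$ic - d0$ic), cfg$z)
  expect_lte(abs(r$fc - d0$fc), cfg$z)

  # independent exhaustive re-scan of the lag grid
  x <- signal_samples(sig)
  costs <- c()
  for (k in -cfg$z:cfg$z) {
    for (l in -cfg$z:cfg$z) {
      ic2 <- 46 + k
      fc2 <- 121 + l
      len <- fc2 - ic2 + 1
      if (ic2 < 1 || fc2 > length(x) || len < 2 || abs(len - 63) > cfg$maxsamp) next
      w <- x[ic2:fc2]
      if (max(w) == min(w)) next
      costs <- c(costs, dtw_distance(w, tpl$samples, cfg$maxsamp))
    }
  }
  expect_equal(r$dtw_cost, min(costs), tolerance = 1e-12)
})

test_that("refinement recovers exact boundaries of a spliced warped instance", {
  inst <- spliced_instance() # 68 samples, warp within the band
  true_ic <- 51L
  true_fc <- true_ic + length(inst) - 1L
  sig <- embed_instances(list(inst), starts = true_ic, total_len = 220)
  tpl <- strategy_piecewise()
  cfg <- detector_config()
  for (perturb in list(c(-5L, 3L), c(4L, -2L), c(0L, 7L))) {
    d0 <- detection_row(true_ic + perturb[[1]], true_fc + perturb[[2]])
    r <- refine_detection_dtw(sig, d0, tpl, cfg)
    expect_equal(r$ic, true_ic)
    expect_equal(r$fc, true_fc)
  }
})

test_that("Pearson refinement matches DTW refinement on a linearly rescaled instance", {
  inst <- resample_linear(proto63, 70)
  true_ic <- 41L
  true_fc <- true_ic + 69L
  sig <- embed_instances(list(inst), starts = true_ic, total_len = 200)
  tpl <- strategy_piecewise()
  cfg <- detector_config()
  d0 <- detection_row(true_ic - 4L, true_fc + 5L)
  r_p <- refine_detection_pearson(sig, d0, tpl, cfg)
  r_d <- refine_detection_dtw(sig, d0, tpl, cfg)
  expect_equal(r_p$ic, true_ic)
  expect_equal(r_p$fc, true_fc)
  expect_lte(abs(r_d$ic - true_ic) + abs(r_d$fc - true_fc),
    abs(r_p$ic - true_ic) + abs(r_p$fc - true_fc) + 2)

  r0 <- refine_detection_pearson(sig, detection_row(true_ic, true_fc), tpl,
    detector_config(z = 0))
  expect_equal(r0$ic, true_ic)
  expect_equal(r0$fc, true_fc)
})

test_that("detect_and_refine composes the stages deterministically", {
  co <- synth_cohort(quick_params(seed = 21))
  lib <- build_templates(NULL, "S5")
  sig <- co$trials[[1]]
  expect_equal(
    detect_and_refine(sig, lib, criterion = "none"),
    detect_steps(sig, lib)
  )
  a <- detect_and_refine(sig, lib, criterion = "dtw")
  b <- detect_and_refine(sig, lib, criterion = "dtw")
  expect_identical(a, b)
  expect_true(all(a$refined))
  expect_true(all(diff(a$ic) > 0))
})

test_that("detector configuration validates its parameters", {
  expect_error(detector_config(correlation_threshold = 1.2))
  expect_error(detector_config(z = -1))
  expect_warning(detector_config(z = 15, maxsamp = 20), "infeasible")
})
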