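# Breakpoints of the piecewise-affine stance prototype with the affine
# coefficients of the adjoining segments, used as an independent check.
affine_branches <- list(
  list(x = 3, left = c(0.3, -0.7), right = c(-0.8, 2.6)),
  list(x = 5, left = c(-0.8, 2.6), right = c(0.2, -2.4)),
  list(x = 16, left = c(0.2, -2.4), right = c(0, 0.8)),
  list(x = 44, left = c(0, 0.8), right = c(-0.34, 15.76)),
  list(x = 54, left = c(-0.34, 15.76), right = c(0.2, -13.4))
)

test_that("the piecewise-affine template matches its defining function", {
  tpl <- strategy_piecewise()
  expect_s3_class(tpl, "step_template")
  expect_equal(tpl$strategy, "S5")
  expect_length(tpl$samples, 63)
  expect_equal(tpl$samples[30], 0.8)
  # mid-stance plateau: sample 16 comes from the first-matching affine
  # branch, so it equals 0.8 only up to floating point
  expect_equal(tpl$samples[16:44], rep(0.8, 29), tolerance = 1e-12)
  expect_true(all(tpl$samples[17:44] == 0.8))
  for (br in affine_branches) {
    left <- br$left[[1]] * br$x + br$left[[2]]
    right <- br$right[[1]] * br$x + br$right[[2]]
    expect_equal(left, right, tolerance = 1e-9) # continuity of the formula
    expect_equal(tpl$samples[br$x], left, tolerance = 1e-9)
  }
  expect_error(strategy_piecewise(5), ">= 6")
  expect_length(strategy_piecewise(31)$samples, 31)
})

test_that("median_length uses the lower middle value", {
  mk <- function(lens) {
    tibble::tibble(
      step_id = paste0("s", seq_along(lens)),
      samples = lapply(lens, function(l) sin(seq_len(l)))
    )
  }
  expect_equal(median_length(mk(c(60, 63, 70))), 63)
  expect_equal(median_length(mk(c(60, 64))), 60)
  withr::with_seed(4, {
    lens <- sample(50:80, 9, replace = TRUE)
    expect_equal(median_length(mk(lens)), sort(lens)[ceiling(9 / 2)])
  })
})

test_that("linear resampling follows closed-form interpolation", {
  expect_equal(resample_linear(1:8, 4), c(1, 10 / 3, 17 / 3, 8))
  expect_equal(resample_linear(c(2, 9), 3), c(2, 5.5, 9)) # endpoints fixed
  expect_equal(resample_linear(1:5, 5), as.numeric(1:5))
})

test_that("random selection is uniform, reproducible, and exhaustive at n = size", {
  coll <- random_collection(10)
  lib_all <- strategy_random(coll, n = 10, seed = 3)
  expect_length(lib_all$templates, 10)
  expect_setequal(attr(lib_all, "selected_ids"), coll$step_id)

  expect_equal(
    tidy(strategy_random(coll, n = 3, seed = 99)),
    tidy(strategy_random(coll, n = 3, seed = 99))
  )
  expect_error(strategy_random(coll, n = 11, seed = 1))
  expect_error(strategy_random(coll, n = 1), "seed")

  picks <- vapply(
    1:500,
    function(s) attr(strategy_random(coll, 1, seed = s), "selected_ids"),
    character(1)
  )
  counts <- table(factor(picks, levels = coll$step_id))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("the DTW medoid equals the row-sum argmin and ignores ordering", {
  coll1 <- random_collection(1)
  med1 <- strategy_dtw_medoid(coll1)
  expect_equal(med1$samples, coll1$samples[[1]])

  # {u, u, w}: a duplicated step always wins
  u <- proto63
  w <- rev(proto63)
  coll3 <- tibble::tibble(
    step_id = c("a", "b", "c"),
    samples = list(u, u, w)
  )
  expect_equal(strategy_dtw_medoid(coll3)$source, "a")

  coll <- random_collection(8, seed = 6)
  med <- strategy_dtw_medoid(coll, maxsamp = 20)
  dm <- outer(seq_len(8), seq_len(8), Vectorize(function(a, b) {
    if (a == b) 0 else dtw_distance(coll$samples[[a]], coll$samples[[b]], 20)
  }))
  expect_equal(med$source, coll$step_id[[which.min(rowSums(dm))]])

  shuffled <- coll[sample(8), ]
  expect_equal(strategy_dtw_medoid(shuffled, 20)$samples, med$samples)
})

test_that("infeasible pairs in medoid computation name the offending pair", {
  coll <- tibble::tibble(
    step_id = c("short", "long"),
    samples = list(sin(1:10), sin(1:60))
  )
  expect_error(strategy_dtw_medoid(coll, maxsamp = 20),
    class = "gaitwarp_error_band_infeasible"
  )
})

test_that("linear fusion returns the z-normalised step for identical copies", {
  coll <- tibble::tibble(
    step_id = paste0("s", 1:5),
    samples = rep(list(proto63), 5)
  )
  tpl <- strategy_linear_fusion(coll)
  expect_equal(tpl$samples, znorm(proto63), tolerance = 1e-12)
  expect_equal(tpl$strategy, "S3")

  mirror <- tibble::tibble(
    step_id = c("a", "b"),
    samples = list(znorm(proto63), -znorm(proto63))
  )
  expect_error(strategy_linear_fusion(mirror),
    class = "gaitwarp_error_degenerate"
  )
})

test_that("alignment to a calibration step averages matched samples", {
  s <- sin(1:20)
  expect_equal(align_to_calibration(s, s, 20), s)
  # band 0 forces the diagonal
  a <- c(0.3, -1, 2)
  b <- c(1, 0, -2)
  expect_equal(align_to_calibration(b, a, maxsamp = 0), b, tolerance = 1e-12)
  # one-to-many match: both middle samples of the step map onto the
  # calibration peak, so the output is their mean
  expect_equal(
    align_to_calibration(c(0, 1, 1, 0), c(0, 1, 0), 20),
    c(0, 1, 0)
  )
})

test_that("non-linear fusion reproduces a scripted recomputation", {
  coll_same <- tibble::tibble(
    step_id = paste0("s", 1:4),
    samples = rep(list(proto63), 4)
  )
  expect_equal(strategy_nonlinear_fusion(coll_same)$samples, znorm(proto63),
    tolerance = 1e-12
  )

  coll <- random_collection(6, seed = 9)
  tpl <- strategy_nonlinear_fusion(coll, maxsamp = 20)
  m <- median_length(coll)
  expect_length(tpl$samples, m)

  # independent scripted recomputation: normalise, pick the calibration
  # among median-length steps by minimum mean DTW distance, align, average
  coll_s <- coll[order(coll$step_id), ]
  normed <- lapply(coll_s$samples, znorm)
  lens <- lengths(normed)
  cand <- which(abs(lens - m) == min(abs(lens - m)))
  if (min(abs(lens - m)) > 0) cand <- cand[lens[cand] == min(lens[cand])]
  mean_d <- vapply(cand, function(ci) {
    mean(vapply(normed, function(s) dtw_distance(normed[[ci]], s, 20), 0))
  }, 0)
  calib <- normed[[cand[which.min(mean_d)]]]
  aligned <- lapply(normed, function(s) {
    al <- dtw_align(calib, s, 20)
    vapply(seq_along(calib), function(i) mean(s[al$path$j[al$path$i == i]]), 0)
  })
  expect_equal(tpl$samples, Reduce(`+`, aligned) / length(aligned),
    tolerance = 1e-12
  )
})

test_that("fusion strategies are invariant to collection order", {
  coll <- random_collection(6, seed = 13)
  shuffled <- coll[c(4, 1, 6, 2, 5, 3), ]
  expect_equal(
    strategy_linear_fusion(coll)$samples,
    strategy_linear_fusion(shuffled)$samples
  )
  expect_equal(
    strategy_nonlinear_fusion(coll)$samples,
    strategy_nonlinear_fusion(shuffled)$samples
  )
})

test_that("build_templates dispatches to every strategy", {
  coll <- random_collection(5, seed = 2)
  expect_equal(build_templates(coll, "S1", n = 2, seed = 1) |> tidy() |> nrow(), 2)
  expect_equal(tidy(build_templates(coll, "S2"))$strategy, "S2")
  expect_equal(tidy(build_templates(coll, "S3"))$strategy, "S3")
  expect_equal(tidy(build_templates(coll, "S4"))$strategy, "S4")
  expect_equal(tidy(build_templates(NULL, "S5"))$length, 63)
})
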