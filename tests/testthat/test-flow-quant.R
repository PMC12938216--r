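make_vs <- function(v_array, venc = 150, times = NULL) {
  if (is.null(times)) times <- (seq_len(dim(v_array)[3]) - 0.5) * 44
  structure(list(v = v_array, frame_times_ms = times, venc = venc,
                 wrap_corrected = TRUE, mask_low = NULL),
            class = "velocity_series")
}

test_that("flow extraction follows the unit arithmetic", {
  ## uniform 10 cm/s over 100 pixels of 5.29 mm^2 -> 52.9 mL/s
  n <- 20
  mask <- matrix(FALSE, n, n); mask[1:10, 1:10] <- TRUE
  v <- array(0, dim = c(n, n, 3))
  for (f in 1:3) v[, , f][mask] <- 10
  vs <- make_vs(v)
  roi <- vessel_roi(mask, "AO", 5.29)
  q <- extract_flow_curve(vs, roi)
  expect_equal(q$q_ml_s, rep(52.9, 3), tolerance = 1e-12)
  ## zero velocity -> zero flow; doubling the mask doubles flow
  expect_equal(extract_flow_curve(make_vs(array(0, c(n, n, 3))), roi)$q_ml_s,
               rep(0, 3))
  mask2 <- matrix(FALSE, n, n); mask2[1:10, 1:20] <- TRUE
  v2 <- array(0, dim = c(n, n, 3))
  for (f in 1:3) v2[, , f][mask2] <- 10
  q2 <- extract_flow_curve(make_vs(v2), vessel_roi(mask2, "AO", 5.29))
  expect_equal(q2$q_ml_s, 2 * q$q_ml_s)
  ## linearity in the velocity field
  q3 <- extract_flow_curve(make_vs(3 * v), roi)
  expect_equal(q3$q_ml_s, 3 * q$q_ml_s)
  expect_error(vessel_roi(matrix(FALSE, n, n), "AO", 5.29), "empty")
})

test_that("beat segmentation with triggers counts complete beats", {
  times <- seq(22, 4000 - 22, by = 44)
  curve <- tibble::tibble(t_ms = times, q_ml_s = sin(times / 100)^2,
                          v_max_cm_s = 0, vessel = "AO")
  class(curve) <- c("flow_curve", class(curve))
  b1 <- segment_beats(curve, trigger_times_ms = seq(0, 4000, by = 1000))
  expect_equal(nrow(b1), 4)
  b2 <- segment_beats(curve, trigger_times_ms = seq(200, 4800, by = 1500))
  expect_equal(nrow(b2), 2)
  short <- curve[curve$t_ms < 800, ]
  class(short) <- class(curve)
  expect_warning(b3 <- segment_beats(short,
                                     trigger_times_ms = c(0, 1000, 2000)),
                 "no complete beat")
  expect_equal(nrow(b3), 0)
})

test_that("trigger-free detection matches the generating onsets", {
  cfg <- phantom_preset_arrhythmia(scan_time_s = 8, seed = 21)
  onsets <- phantom_beat_onsets(cfg)
  times <- seq(22, 8000, by = 44)
  ao <- cfg$vessels[[1]]
  q <- velocity_waveform(times, onsets, ao) * pi * (ao$radius_mm / 10)^2 / 2
  curve <- tibble::tibble(t_ms = times, q_ml_s = q, v_max_cm_s = 0,
                          vessel = "AO")
  class(curve) <- c("flow_curve", class(curve))
  det <- segment_beats(curve)
  truth <- segment_beats(curve, trigger_times_ms = onsets)
  expect_equal(nrow(det), nrow(truth))
  ## detected onsets within one frame duration of the generating ones
  matched <- sapply(det$t_start_ms, function(x) min(abs(onsets - x)))
  expect_lt(max(matched), 44 + 1e-9)
  rr_det <- det$t_end_ms - det$t_start_ms
  rr_truth <- truth$t_end_ms - truth$t_start_ms
  expect_equal(rr_det, rr_truth, tolerance = 44 / min(rr_truth))
})

test_that("beat measures integrate, peak and average correctly", {
  times <- seq(22, 4000, by = 44)
  q <- rep(300, length(times))
  curve <- tibble::tibble(t_ms = times, q_ml_s = q,
                          v_max_cm_s = rep(100, length(times)), vessel = "AO")
  class(curve) <- c("flow_curve", class(curve))
  beats <- segment_beats(curve, trigger_times_ms = c(0, 1000, 2000))
  bm <- beat_measures(curve, beats)
  ## constant q = 300 mL/s over 1000 ms -> ~300 mL (trapezoid over frames
  ## inside the window; endpoints clipped by half a frame each side)
  expect_equal(bm$net_flow_ml, c(300, 300), tolerance = 0.05)
  expect_equal(bm$peak_flow_ml_s, c(300, 300))
  expect_equal(bm$rr_ms, c(1000, 1000))
  ## single-frame spike sets the peak
  q2 <- q; q2[10] <- 1234
  curve2 <- curve; curve2$q_ml_s <- q2
  bm2 <- beat_measures(curve2, beats[1, ])
  expect_equal(bm2$peak_flow_ml_s, 1234)
  ## averaging
  avg <- average_over_beats(bm)
  expect_equal(avg$net_flow_ml, mean(bm$net_flow_ml))
  expect_equal(avg$n_beats, 2L)
  single <- average_over_beats(bm[1, ])
  expect_equal(single$net_flow_ml, bm$net_flow_ml[1])
  ## permutation invariance
  avg2 <- average_over_beats(bm[2:1, ])
  expect_equal(avg$net_flow_ml, avg2$net_flow_ml)
})

test_that("Qp/Qs is the MPA/AO ratio with guarded input", {
  expect_equal(qp_qs(80, 80), 1)
  expect_equal(qp_qs(85.1, 89.2), 0.954, tolerance = 1e-3)
  expect_equal(qp_qs(100, 50), 2)
  expect_error(qp_qs(80, 0), "positive")
  expect_error(qp_qs(80, -5), "positive")
})

test_that("coefficient of variation matches the direct formula", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(90, 110)),
               100 * sqrt(200) / 100, tolerance = 1e-9)   # 14.142...
  x <- c(3, 9, 4, 7)
  expect_equal(coefficient_of_variation(10 * x),
               coefficient_of_variation(x))
  expect_equal(coefficient_of_variation(x), 100 * stats::sd(x) / mean(x))
  expect_error(coefficient_of_variation(c(1)), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("threshold ROI helper recovers a bright disc", {
  n <- 32
  x <- (seq_len(n) - 1 - n / 2)
  img <- 0.2 + outer(x, x, function(a, b) as.numeric(a^2 + b^2 < 36)) +
    matrix(0.01 * sin(seq_len(n^2)), n, n)
  roi <- otsu_roi(img, c(n / 2 + 1, n / 2 + 1), "AO", 4)
  truth <- outer(x, x, function(a, b) a^2 + b^2 < 36)
  expect_gt(sum(roi$mask & truth) / sum(roi$mask | truth), 0.9)
})
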