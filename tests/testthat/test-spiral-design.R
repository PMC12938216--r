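test_that("designed interleaf reaches k_max and respects the readout window", {
  il <- table1_interleaf()
  expect_equal(il$k_max, 1 / (2 * 2.3), tolerance = 0.01)
  expect_lte(il$duration_ms, 5.32)
  expect_equal(Mod(il$k[1]), 0, tolerance = 1e-12)
  ## spiral-out: radial envelope monotonically non-decreasing
  expect_true(all(diff(Mod(il$k)) > -1e-9))
})

test_that("gradient amplitude and slew limits hold at every sample", {
  for (il in list(table1_interleaf(), small_interleaf())) {
    lim <- il$spec$limits
    gmag <- Mod(il$g)
    expect_lte(max(gmag), lim$g_max * 1.01)
    dt_s <- il$dwell_us * 1e-6
    slew <- Mod(diff(il$g)) / dt_s / 1e3        # T/m/s
    expect_lte(max(slew), lim$s_max * 1.05)
    ## finite-differencing k reproduces the stored gradients
    gfd <- diff(il$k) / (spiralflow:::GAMMA_BAR * dt_s)
    expect_lt(max(Mod(gfd - il$g[-length(il$g)])) / max(gmag), 0.02)
  }
})

test_that("relaxing gradient limits shortens the design but keeps k_max", {
  tight <- design_dual_density_spiral(small_spec())
  loose <- design_dual_density_spiral(
    small_spec(limits = gradient_limits(60, 220)))
  expect_lt(loose$duration_ms, tight$duration_ms)
  expect_equal(loose$k_max, tight$k_max, tolerance = 0.01)
})

test_that("infeasible specs raise errors naming the binding constraint", {
  expect_error(
    design_dual_density_spiral(
      spiral_spec(readout_ms = 0.05, limits = gradient_limits(5, 45))),
    "amplitude")
  expect_error(gradient_limits(-1, 45), "g_max")
  expect_error(gradient_limits(26, 0), "s_max")
  expect_error(spiral_spec(center_fraction = 1.2), "center_fraction")
  expect_error(spiral_spec(res_mm = 400), "resolution")
})

test_that("Table-1 protocol yields the published undersampling factor", {
  il <- table1_interleaf()
  expect_equal(il$n_full, 12L)
  expect_equal(il$n_full_raw, 12, tolerance = 0.03)
  expect_equal(acceleration_factor(il, 2), 6, tolerance = 0.03)
  expect_equal(acceleration_factor(il, il$n_full), 1, tolerance = 0.03)
  expect_equal(acceleration_factor(il, 1), 12, tolerance = 0.03)
})

test_that("interleaf rotation is a pointwise counterclockwise rotation", {
  il <- small_interleaf()
  expect_equal(rotate_interleaf(il, 0)$k, il$k)
  r360 <- rotate_interleaf(il, 360)
  expect_equal(r360$k, il$k, tolerance = 1e-10)
  r180 <- rotate_interleaf(il, 180)
  expect_equal(r180$k, -il$k, tolerance = 1e-12)
  expect_equal(r180$g, -il$g, tolerance = 1e-12)
  ## 90 deg counterclockwise maps +x to +y
  r90 <- rotate_interleaf(il, 90)
  j <- which.max(Re(il$k))
  expect_gt(Im(r90$k[j]), 0)
  expect_lt(abs(Re(r90$k[j])), 1e-6 + abs(Im(r90$k[j])))
  ## duration and dwell unchanged
  expect_identical(r90$duration_ms, il$duration_ms)
  expect_identical(r90$dwell_us, il$dwell_us)
})

test_that("golden-angle schedule has the documented structure", {
  sched <- build_schedule(4, 11)
  expect_equal(attr(sched, "n_frames"), 90)
  expect_equal(attr(sched, "frame_duration_ms"), 44)
  ## per frame: exactly 2 FC + 2 FE; second pair at base + 180
  counts <- table(sched$frame, sched$encoding)
  expect_true(all(counts == 2))
  f1 <- sched[sched$frame == 2, ]
  expect_equal(f1$encoding, c("FC", "FE", "FC", "FE"))
  expect_equal(f1$angle[3], (f1$base_angle[1] + 180) %% 360)
  ## frame-to-frame golden angle increment
  base <- sched$base_angle[sched$readout == 1]
  inc <- diff(base) %% 360
  expect_equal(inc, rep(spiralflow:::GOLDEN_ANGLE, length(inc)),
               tolerance = 1e-9)
  expect_equal(base[1:3], c(0, 137.50776, 275.01553), tolerance = 1e-4)
  ## start times contiguous at TR spacing
  expect_equal(diff(sched$start_time_ms), rep(11, nrow(sched) - 1))
})

test_that("schedule covers the scan window and rejects too-short scans", {
  sched <- build_schedule(0.044, 11)
  expect_equal(attr(sched, "n_frames"), 1)
  expect_error(build_schedule(0.01, 11), "shorter than one")
  for (st in c(1, 2.5, 4)) {
    s <- build_schedule(st, 11)
    nf <- attr(s, "n_frames")
    expect_lte(44 * nf, st * 1000)
    expect_gt(44 * (nf + 1), st * 1000)
  }
})

test_that("any 90-frame window of golden angles is nearly uniform", {
  sched <- build_schedule(4, 11)
  base <- sort(unique(sched$base_angle) %% 360)
  gaps <- diff(c(base, base[1] + 360))
  expect_lt(max(gaps), 8)
})
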