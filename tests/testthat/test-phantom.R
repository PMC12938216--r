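test_that("velocity waveform hits its systolic peak and diastolic baseline", {
  vs <- phantom_vessel("AO", peak_cm_s = 100, systole_ms = 400)
  onsets <- c(0, 1000, 2000)
  expect_equal(velocity_waveform(200, onsets, vs), 100)   # systolic peak
  expect_equal(velocity_waveform(1200, onsets, vs), 100)
  expect_equal(velocity_waveform(700, onsets, vs), 0)     # diastole
  expect_equal(velocity_waveform(-50, onsets, vs), 0)     # before first beat
  ## identical RR, no respiration: per-beat peaks identical (CV = 0)
  peaks <- vapply(onsets + 200, velocity_waveform, numeric(1),
                  beat_onsets = onsets, vessel = vs)
  expect_equal(stats::sd(peaks), 0)
})

test_that("respiratory modulation produces bounded peak-velocity variation", {
  vs <- phantom_vessel("AO", peak_cm_s = 100, systole_ms = 300)
  onsets <- seq(0, 10000, by = 900)
  tpk <- onsets[-length(onsets)] + 150
  peaks <- velocity_waveform(tpk, onsets, vs, resp_amp = 0.1, resp_period_s = 4)
  cv <- 100 * stats::sd(peaks) / mean(peaks)
  expect_gt(cv, 0)
  expect_lte(cv, 8)   # |0.1 sin| modulation: population CV <= ~7.1%
  ## direct-evaluation oracle
  oracle <- 100 * (1 + 0.1 * sin(2 * pi * tpk / 4000))
  expect_equal(peaks, oracle, tolerance = 1e-12)
  expect_equal(cv, 100 * stats::sd(oracle) / mean(oracle), tolerance = 1e-12)
})

test_that("FC/FE pair encodes the phase-contrast model", {
  cfg <- small_phantom(maxwell = FALSE)
  onsets <- phantom_beat_onsets(cfg)
  ## find a systolic frame time
  tsys <- onsets[1] + cfg$vessels[[1]]$systole_ms / 2
  pair <- render_frame_pair(tsys, cfg)
  expect_equal(Mod(pair$fc), Mod(pair$fe), tolerance = 1e-12)
  dphi <- Arg(pair$fe * Conj(pair$fc))
  geo <- spiralflow:::phantom_geometry(cfg)
  static <- geo$torso & !Reduce(`|`, lapply(geo$vessels, `[[`, "mask"))
  expect_equal(max(abs(dphi[static])), 0, tolerance = 1e-12)
  inside <- geo$vessels$AO$mask
  expect_equal(dphi[inside], pi * pair$v[inside] / cfg$venc, tolerance = 1e-9)
})

test_that("velocities beyond VENC wrap as acquired data would", {
  cfg <- small_phantom(maxwell = FALSE)
  cfg$venc <- 80  # below the 120 cm/s aortic peak
  onsets <- phantom_beat_onsets(cfg)
  tsys <- onsets[1] + cfg$vessels[[1]]$systole_ms / 2
  pair <- render_frame_pair(tsys, cfg, beat_onsets = onsets)
  geo <- spiralflow:::phantom_geometry(cfg)
  ctr_v <- max(pair$v)
  expect_gt(ctr_v, cfg$venc)
  dphi <- Arg(pair$fe * Conj(pair$fc))
  ## apparent phase of a 1.5 venc pixel wraps to -0.5 pi
  j <- which.max(pair$v)
  expected <- pi * ctr_v / cfg$venc
  expected <- ((expected + pi) %% (2 * pi)) - pi
  expect_equal(dphi[j], expected, tolerance = 1e-9)
})

test_that("coil maps are smooth, supported and deterministic", {
  m1 <- simulate_coils(4, 32, 160, seed = 5)
  m2 <- simulate_coils(4, 32, 160, seed = 5)
  expect_identical(unclass(m1), unclass(m2))
  rss <- sqrt(apply(Mod(unclass(m1))^2, c(1, 2), sum))
  expect_gt(min(rss), 0)
  m3 <- simulate_coils(4, 32, 160, seed = 6)
  expect_false(identical(unclass(m1), unclass(m3)))
})

test_that("simulated acquisition is Fourier-consistent and reproducible", {
  cfg <- small_phantom(noise_sigma = 0, scan_time_s = 0.2)
  sched <- build_schedule(0.2, 11)
  il <- small_interleaf()
  maps <- simulate_coils(4, 32, 160, seed = cfg$seed + 1L)
  ks <- simulate_acquisition(sched, cfg, maps, il)
  ## DC consistency: the first sample of each readout sits at k = (0,0), so
  ## it must equal the spatial sum of the coil-weighted image
  onsets <- phantom_beat_onsets(cfg)
  pair <- render_frame_pair(frame_times(sched)[1], cfg, onsets)
  for (cc in 1:2) {
    dc_expect <- sum(pair$fc * unclass(maps)[, , cc])
    expect_equal(ks$samples[1, 1, cc], dc_expect, tolerance = 1e-4)
  }
  ## determinism
  ks2 <- simulate_acquisition(sched, cfg, maps, il)
  expect_identical(ks$samples, ks2$samples)
  cfgN <- small_phantom(noise_sigma = 50, scan_time_s = 0.2)
  ksn1 <- simulate_acquisition(sched, cfgN, maps, il)
  ksn2 <- simulate_acquisition(sched, cfgN, maps, il)
  expect_identical(ksn1$samples, ksn2$samples)
  expect_false(identical(ks$samples, ksn1$samples))
})

## restrict an image to the spiral's sampled k-disc (what a disc-covering
## trajectory can represent of a sharp-edged object)
disc_bandlimit <- function(img, kmax, fov) {
  n <- nrow(img)
  f <- spiralflow:::fftshift2(stats::fft(spiralflow:::ifftshift2(img)))
  kk <- (seq_len(n) - 1 - n / 2) / fov
  D <- outer(kk, kk, function(a, b) sqrt(a^2 + b^2)) <= kmax
  spiralflow:::fftshift2(
    stats::fft(spiralflow:::ifftshift2(f * D), inverse = TRUE)) / n^2
}

test_that("forward-then-gridded-adjoint recovers the true image", {
  ## densely sampled rotated set at 32x32 against the disc-bandlimited truth
  cfg <- small_phantom(noise_sigma = 0, scan_time_s = 0.2)
  il <- small_interleaf()
  onsets <- phantom_beat_onsets(cfg)
  pair <- render_frame_pair(100, cfg, onsets)
  ncop <- 2 * ceiling(il$n_arms / il$spec$outer_density)
  traj <- unlist(lapply((0:(ncop - 1)) * 360 / ncop,
                        function(a) il$k * exp(1i * a * pi / 180)))
  plan <- nufft_plan(traj, 32, 160)
  w <- density_compensation_weights(traj, 32, 160)
  rec <- nufft_adjoint(nufft_forward(pair$fc, plan), plan, weights = w)
  truth <- disc_bandlimit(pair$fc, il$k_max, 160)
  corr <- abs(sum(Conj(rec) * truth)) /
    sqrt(sum(Mod(rec)^2) * sum(Mod(truth)^2))
  expect_gt(corr, 0.99)
})

test_that("noise-free fully-sampled phase difference passes the null test", {
  ## finer 48x48 grid: the 32-pixel variant leaves the steep systolic phase
  ## gradient under-resolved at the lumen edge
  cfg <- phantom_config(
    fov_mm = 160, res_mm = 10 / 3, matrix = 48,
    vessels = small_phantom()$vessels,
    noise_sigma = 0, n_coils = 4, maxwell = FALSE, scan_time_s = 0.2,
    seed = 7)
  il <- fixture("interleaf48",
                design_dual_density_spiral(spiral_spec(fov_mm = 160,
                                                       res_mm = 10 / 3)))
  onsets <- phantom_beat_onsets(cfg)
  tsys <- onsets[1] + 180
  pair <- render_frame_pair(tsys, cfg, onsets)
  ncop <- 2 * ceiling(il$n_arms / il$spec$outer_density)
  traj <- unlist(lapply((0:(ncop - 1)) * 360 / ncop,
                        function(a) il$k * exp(1i * a * pi / 180)))
  plan <- nufft_plan(traj, 48, 160)
  w <- density_compensation_weights(traj, 48, 160)
  rec_fc <- nufft_adjoint(nufft_forward(pair$fc, plan), plan, weights = w)
  rec_fe <- nufft_adjoint(nufft_forward(pair$fe, plan), plan, weights = w)
  dphi <- Arg(rec_fe * Conj(rec_fc))
  truth <- Arg(disc_bandlimit(pair$fe, il$k_max, 160) *
               Conj(disc_bandlimit(pair$fc, il$k_max, 160)))
  geo <- spiralflow:::phantom_geometry(cfg)
  vessels <- Reduce(`|`, lapply(geo$vessels, `[[`, "mask"))
  rmse <- sqrt(mean((dphi[vessels] - truth[vessels])^2))
  expect_lt(rmse, 0.02)
})

test_that("analytic ground truth obeys its closed forms", {
  cfg <- small_phantom(resp_amp = 0)
  gt <- ground_truth_measures(cfg)
  ## parabolic profile: Q_peak = v_peak * pi r^2 / 2 (in mL/s)
  ao <- cfg$vessels[[1]]
  qpk <- ao$peak_cm_s / 2 * pi * (ao$radius_mm / 10)^2
  expect_equal(max(gt$peak_flow_ml_s[gt$vessel == "AO"]), qpk,
               tolerance = 1e-6)
  ## raised-cosine bump: net flow = Q_peak * systole / 2
  net <- qpk * ao$systole_ms / 2 / 1000
  expect_equal(gt$net_flow_ml[gt$vessel == "AO"][1], net, tolerance = 1e-4)
  expect_equal(max(gt$peak_velocity_cm_s[gt$vessel == "AO"]), ao$peak_cm_s,
               tolerance = 1e-9)
})

test_that("configured and analytic Qp/Qs agree (conservation consistency)", {
  cfg <- small_phantom(resp_amp = 0)
  gt <- ground_truth_measures(cfg, dt_ms = 0.05)
  ao <- cfg$vessels[[1]]; mpa <- cfg$vessels[[2]]
  configured <- (mpa$peak_cm_s * mpa$radius_mm^2 * mpa$systole_ms) /
    (ao$peak_cm_s * ao$radius_mm^2 * ao$systole_ms)
  expect_equal(attr(gt, "qp_qs"), configured, tolerance = 1e-6)
})

test_that("plug-profile vessels integrate to v * area", {
  cfg <- small_phantom(resp_amp = 0)
  cfg$vessels[[1]]$profile <- "plug"
  gt <- ground_truth_measures(cfg)
  ao <- cfg$vessels[[1]]
  qpk <- ao$peak_cm_s * pi * (ao$radius_mm / 10)^2
  expect_equal(max(gt$peak_flow_ml_s[gt$vessel == "AO"]), qpk,
               tolerance = 1e-6)
})

test_that("bimodal RR preset generates two RR clusters", {
  cfg <- phantom_preset_arrhythmia(scan_time_s = 30, seed = 11)
  onsets <- phantom_beat_onsets(cfg)
  rr <- diff(onsets)
  expect_gt(length(rr), 10)
  short <- rr < cfg$rr_mean * 0.9
  expect_gt(sum(short), 2)
  expect_gt(sum(!short), 2)
  expect_lt(mean(rr[short]), 0.75 * mean(rr[!short]))
})
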