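test_that("phase difference is the conjugate-product argument", {
  set.seed(2)
  n <- 8; nf <- 3
  fc <- array(complex(real = rnorm(n * n * nf), imaginary = rnorm(n * n * nf)),
              dim = c(n, n, nf))
  expect_equal(phase_difference(fc, fc)$phase, array(0, dim(fc)))
  fe <- fc * exp(1i * pi / 2)
  expect_equal(phase_difference(fc, fe)$phase,
               array(pi / 2, dim(fc)), tolerance = 1e-12)
  ## zero-magnitude pixels: phase 0 with the low-confidence bit set
  fc0 <- fc; fc0[1, 1, ] <- 0
  fe0 <- fe; fe0[1, 1, ] <- 0
  pd <- phase_difference(fc0, fe0)
  expect_equal(pd$phase[1, 1, ], rep(0, nf))
  expect_true(all(pd$mask_low[1, 1, ]))
  expect_error(phase_difference(fc, fe[, , 1:2]), "mismatch")
})

test_that("velocity scaling follows the VENC convention", {
  dphi <- array(c(pi, 0, pi / 2, -pi / 4), dim = c(2, 2, 1))
  vs <- to_velocity(dphi, 200)
  expect_equal(vs$v[1, 1, 1], 200)
  expect_equal(vs$v[2, 1, 1], 0)
  expect_equal(vs$v[1, 2, 1], 100)
  ## linear and odd
  vneg <- to_velocity(-dphi, 200)
  expect_equal(vneg$v, -vs$v)
  v2 <- to_velocity(dphi / 2, 200)
  expect_equal(v2$v, vs$v / 2)
})

test_that("Maxwell correction matches brute-force time integration", {
  wf <- venc_waveforms(200)
  ## brute-force numeric integral of the concomitant term
  num_sq <- function(w, dt = 1e-9) {
    tt <- seq(0, max(w$t), by = dt)
    gg <- stats::approx(w$t, w$g, xout = tt, rule = 2, ties = "ordered")$y
    sum((utils::head(gg, -1)^2 + utils::tail(gg, -1)^2) / 2) * dt
  }
  dsq_num <- num_sq(wf$fe) - num_sq(wf$fc)
  n <- 16; fov <- 300; b0 <- 0.55
  pos <- (seq_len(n) - 1 - n / 2) * fov / n
  X <- matrix(pos, n, n); Y <- matrix(pos, n, n, byrow = TRUE)
  phi_oracle <- spiralflow:::GAMMA_RAD * dsq_num * ((X^2 + Y^2) * 1e-6) / (8 * b0)
  dphi <- array(0, dim = c(n, n, 2))
  corr <- maxwell_correction(dphi, wf, fov, b0_T = b0)
  expect_equal(attr(corr, "maxwell_phase"), phi_oracle, tolerance = 1e-8)
  expect_equal(corr[, , 1], -phi_oracle, tolerance = 1e-8)
  ## doubling B0 halves the correction
  corr2 <- maxwell_correction(dphi, wf, fov, b0_T = 2 * b0)
  expect_equal(attr(corr2, "maxwell_phase"), phi_oracle / 2, tolerance = 1e-8)
  ## correction vanishes at isocenter
  expect_equal(attr(corr, "maxwell_phase")[n / 2 + 1, n / 2 + 1], 0,
               tolerance = 1e-15)
})

test_that("missing slice geometry skips the correction with a warning", {
  wf <- venc_waveforms(150)
  dphi <- array(0.3, dim = c(8, 8, 2))
  expect_warning(out <- maxwell_correction(dphi, wf, 300,
                                           slice_offset_mm = NULL),
                 "skipped")
  expect_false(attr(out, "maxwell_corrected"))
  expect_equal(as.vector(out), as.vector(dphi))
})

test_that("temporal unwrapping restores beyond-VENC velocities", {
  venc <- 100
  ## truth ramps 0.9 venc -> 1.5 venc; acquisition wraps the latter
  truth <- c(50, 90, 150, 150, 90, 40)
  wrapped <- ifelse(truth > venc, truth - 2 * venc, truth)
  arr <- array(rep(wrapped, each = 4), dim = c(2, 2, length(truth)))
  vs <- to_velocity(arr * pi / venc, venc)
  un <- unwrap_temporal(vs)
  expect_equal(un$v[1, 1, ], truth, tolerance = 1e-9)
  expect_true(un$wrap_corrected)
  ## oracle: exhaustive +-2venc candidate search minimizing total variation
  cands <- expand.grid(rep(list(-1:1), length(truth)))
  best <- NULL; best_tv <- Inf
  for (i in seq_len(nrow(cands))) {
    x <- wrapped + 2 * venc * as.numeric(cands[i, ])
    tv <- sum(abs(diff(x)))
    if (tv < best_tv && x[1] == wrapped[1]) { best_tv <- tv; best <- x }
  }
  expect_equal(un$v[1, 1, ], best)
})

test_that("unwrapping is idempotent and changes values by 2 venc multiples", {
  set.seed(6)
  venc <- 120
  arr <- array(runif(4 * 4 * 10, -0.5, 0.5) * venc, dim = c(4, 4, 10))
  vs <- to_velocity(arr * pi / venc, venc)
  un1 <- unwrap_temporal(vs)
  ## smooth sub-venc series unchanged
  expect_equal(un1$v, vs$v)
  ## an artificially wrapped series: all changes are 2 venc multiples
  arr2 <- arr; arr2[, , 5] <- arr2[, , 5] + 2 * venc
  vs2 <- vs
  vs2$v <- arr2 - 2 * venc * (arr2 > venc)   # re-wrapped into (-venc, venc]
  un2 <- unwrap_temporal(vs2)
  k <- (un2$v - vs2$v) / (2 * venc)
  expect_equal(k, round(k), tolerance = 1e-9)
  expect_equal(unwrap_temporal(un2)$v, un2$v)
})
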