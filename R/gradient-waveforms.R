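## Through-plane velocity-encoding gradient waveforms.
##
## Two-point phase-contrast encoding: the flow-compensated (FC) readout uses
## a first-moment-nulled (1,-2,1) trapezoid triplet on the slice axis, the
## flow-encoded (FE) readout adds a bipolar pair whose first moment maps the
## VENC velocity to a phase of pi. Waveforms are piecewise linear, so their
## moments and squared integrals have closed forms; they drive both the
## phantom's simulated concomitant phase and the Maxwell correction.

GAMMA_RAD <- 2 * pi * 42.5774688e6  # rad/s/T

## trapezoid lobe breakpoints: amplitude g (T/m), flat-top tf (s), ramps tr
trap_lobe <- function(t0, g, tf, tr) {
  data.frame(t = t0 + c(0, tr, tr + tf, 2 * tr + tf),
             g = c(0, g, g, 0))
}

## append lobes into one piecewise-linear waveform (t strictly increasing)
cat_lobes <- function(...) {
  lobes <- list(...)
  out <- lobes[[1]]
  for (lb in lobes[-1]) {
    if (abs(out$t[nrow(out)] - lb$t[1]) < 1e-12) lb <- lb[-1, ]
    out <- rbind(out, lb)
  }
  out
}

## exact integrals over a piecewise-linear waveform
pwl_moment0 <- function(w) {
  dt <- diff(w$t)
  sum(dt * (utils::head(w$g, -1) + utils::tail(w$g, -1)) / 2)
}
pwl_moment1 <- function(w) {
  ## int t g(t) dt, exact for linear segments
  t1 <- utils::head(w$t, -1); t2 <- utils::tail(w$t, -1)
  g1 <- utils::head(w$g, -1); g2 <- utils::tail(w$g, -1)
  dt <- t2 - t1
  slope <- ifelse(dt > 0, (g2 - g1) / dt, 0)
  ## g(t) = g1 + slope (t - t1); int over [t1, t2]
  sum(g1 * (t2^2 - t1^2) / 2 +
      slope * ((t2^3 - t1^3) / 3 - t1 * (t2^2 - t1^2) / 2))
}
pwl_sq_integral <- function(w) {
  ## int g(t)^2 dt, exact: Simpson on linear segments
  g1 <- utils::head(w$g, -1); g2 <- utils::tail(w$g, -1)
  dt <- diff(w$t)
  sum(dt * (g1^2 + g1 * g2 + g2^2) / 3)
}

#' Velocity-encoding waveform pair for a given VENC
#'
#' @param venc_cm_s Velocity encoding limit, cm/s (phase pi at `venc`).
#' @param limits A [gradient_limits()] record (lobe amplitude/ramps respect
#'   them).
#' @param amp_frac Fraction of `g_max` used for the encoding lobes.
#' @return List with piecewise-linear `fc` and `fe` waveforms (`t` seconds,
#'   `g` T/m on the slice axis), the bipolar first-moment increment
#'   `delta_m1` (T s^2/m), and `venc_cm_s`.
#' @export
venc_waveforms <- function(venc_cm_s, limits = gradient_limits(),
                           amp_frac = 0.8) {
  stopifnot(venc_cm_s > 0)
  g <- limits$g_max * 1e-3 * amp_frac          # T/m
  slew <- limits$s_max                          # T/m/s
  tr <- g / slew                                # ramp time
  venc <- venc_cm_s / 100                       # m/s
  dm1 <- pi / (GAMMA_RAD * venc)                # required first moment, T s^2/m
  ## bipolar (-g, +g) back-to-back trapezoids, flat-top tf: lobe area
  ## a = g (tf + tr), centre separation tf + 2 tr, so
  ## m1 = + g (tf + tr)(tf + 2 tr); solve the quadratic for tf
  tf <- (-3 * tr + sqrt(tr^2 + 4 * dm1 / g)) / 2
  if (tf < 0) {                                # ramp-limited: shrink amplitude
    g <- (dm1 * slew^2 / 2)^(1 / 3)
    tr <- g / slew
    tf <- 0
  }
  ## flow-compensated triplet (+a, -2a, +a), palindromic segments
  ## [tr tf tr][tr (2tf+tr) tr][tr tf tr]: zeroth and first moments null
  fc <- cat_lobes(
    trap_lobe(0, g, tf, tr),
    trap_lobe(2 * tr + tf, -g, 2 * tf + tr, tr),
    trap_lobe(5 * tr + 3 * tf, g, tf, tr)
  )
  t_end <- fc$t[nrow(fc)]
  ## flow-encoded: compensated triplet followed by the encoding bipolar;
  ## (-g, +g) order gives positive phase for positive through-plane velocity
  fe <- cat_lobes(
    fc,
    trap_lobe(t_end, -g, tf, tr),
    trap_lobe(t_end + 2 * tr + tf, g, tf, tr)
  )
  list(fc = fc, fe = fe, delta_m1 = g * (tf + tr) * (tf + 2 * tr),
       venc_cm_s = venc_cm_s, bipolar_amp = g, bipolar_flat = tf, ramp = tr)
}
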