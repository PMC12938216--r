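#' Gradient hardware limits
#'
#' @param g_max_mT_m Maximum gradient amplitude per the vector magnitude, mT/m.
#' @param s_max_T_m_s Maximum slew rate, T/m/s.
#' @return A `gradient_limits` record.
#' @export
gradient_limits <- function(g_max_mT_m = 26, s_max_T_m_s = 45) {
  if (!is_scalar_num(g_max_mT_m) || g_max_mT_m <= 0) {
    stopf("g_max must be a positive number (mT/m), got %s", format(g_max_mT_m))
  }
  if (!is_scalar_num(s_max_T_m_s) || s_max_T_m_s <= 0) {
    stopf("s_max must be a positive number (T/m/s), got %s", format(s_max_T_m_s))
  }
  structure(list(g_max = g_max_mT_m, s_max = s_max_T_m_s),
            class = "gradient_limits")
}

#' Dual-density spiral design specification
#'
#' Describes a spiral-out readout whose radial sampling density is a multiple
#' of the Nyquist arm spacing `1/fov`: `center_density` over the first
#' `center_fraction` of the readout window and `outer_density` over the rest,
#' with a smooth cosine taper between the two zones.
#'
#' @param fov_mm Field of view, mm.
#' @param res_mm Nominal resolution, mm (sets `k_max = 1/(2 res)`).
#' @param readout_ms ADC readout window, ms.
#' @param center_fraction Fraction of the readout window sampled at
#'   `center_density` (measured along readout time).
#' @param center_density,outer_density Sampling density as a multiple of the
#'   Nyquist rate (1 = arm spacing `1/fov`).
#' @param taper_fraction Width of the cosine density taper, as a fraction of
#'   the readout window, centred on `center_fraction`.
#' @param dwell_us ADC dwell time, microseconds. Default `NULL` derives it
#'   from `bw_px` and the even matrix size.
#' @param bw_px Receiver bandwidth per pixel, Hz/px (used when `dwell_us` is
#'   `NULL`).
#' @param limits A [gradient_limits()] record.
#' @return A `spiral_spec` record.
#' @export
spiral_spec <- function(fov_mm = 300, res_mm = 2.3, readout_ms = 5.32,
                        center_fraction = 0.30, center_density = 2.0,
                        outer_density = 0.6, taper_fraction = 0.05,
                        dwell_us = NULL, bw_px = 1116,
                        limits = gradient_limits()) {
  stopifnot(inherits(limits, "gradient_limits"))
  if (!(center_fraction > 0 && center_fraction < 1)) {
    stopf("center_fraction must lie in (0, 1), got %g", center_fraction)
  }
  if (center_density <= 0 || outer_density <= 0) {
    stopf("sampling densities must be positive")
  }
  if (!(res_mm > 0 && res_mm < fov_mm)) {
    stopf("need 0 < resolution < fov, got res=%g fov=%g", res_mm, fov_mm)
  }
  matrix <- matrix_size(fov_mm, res_mm)
  if (is.null(dwell_us)) dwell_us <- 1e6 / (bw_px * matrix)
  structure(list(
    fov = fov_mm, res = res_mm, readout_ms = readout_ms,
    center_fraction = center_fraction, center_density = center_density,
    outer_density = outer_density, taper_fraction = taper_fraction,
    dwell_us = dwell_us, matrix = matrix, limits = limits
  ), class = "spiral_spec")
}

## density profile along the readout window, s in [0, 1]
spiral_density_profile <- function(spec, s) {
  lo <- spec$center_fraction - spec$taper_fraction / 2
  hi <- spec$center_fraction + spec$taper_fraction / 2
  w <- ifelse(s <= lo, 1,
       ifelse(s >= hi, 0, 0.5 * (1 + cos(pi * (s - lo) / (hi - lo)))))
  spec$outer_density + (spec$center_density - spec$outer_density) * w
}

## analytic d(density)/ds of the cosine taper
spiral_density_slope <- function(spec, s) {
  lo <- spec$center_fraction - spec$taper_fraction / 2
  hi <- spec$center_fraction + spec$taper_fraction / 2
  inside <- s > lo & s < hi
  out <- numeric(length(s))
  out[inside] <- (spec$center_density - spec$outer_density) *
    (-0.5 * pi / (hi - lo)) * sin(pi * (s[inside] - lo) / (hi - lo))
  out
}

## Time-optimal variable-density Archimedean integration for a given integer
## design multiplicity n (number of uniformly rotated copies the interleaf is
## designed to tile with). Greedy slew-/amplitude-limited stepping of the
## angular state; vector-norm limits. Returns the (t, theta, r) path on the
## integration raster, stopping when r reaches kmax.
spiral_integrate <- function(spec, n, dt = 5e-7, t_cap_ms = 60) {
  kmax <- 1 / (2 * spec$res)
  Gk <- GAMMA_BAR * spec$limits$g_max          # cycles/mm/s
  Sk <- GAMMA_BAR * spec$limits$s_max * 1e3    # cycles/mm/s^2
  t_read <- spec$readout_ms * 1e-3
  nstep <- ceiling(t_cap_ms * 1e-3 / dt)
  th <- numeric(nstep + 1); r <- numeric(nstep + 1); tt <- numeric(nstep + 1)
  om <- 0
  reached <- FALSE
  i <- 0L
  dens_scale <- n / (2 * pi * spec$fov)
  while (i < nstep) {
    i <- i + 1L
    s <- min(tt[i] / t_read, 1)
    d <- spiral_density_profile(spec, s)
    rp <- dens_scale / d
    ## analytic dr'/dt (through the density taper); rpp = (dr'/dt) / omega
    rho <- -dens_scale * spiral_density_slope(spec, s) / d^2 / t_read
    rpp <- if (om > 1e-9) rho / om else 0
    a <- complex(real = rp, imaginary = r[i])
    b <- om^2 * complex(real = rpp - r[i], imaginary = 2 * rp)
    aa <- Re(a)^2 + Im(a)^2
    ab <- Re(Conj(a) * b)
    disc <- ab^2 - aa * (Mod(b)^2 - Sk^2)
    if (disc >= 0) {
      alpha <- (-ab + sqrt(disc)) / aa
      ## lookahead braking: if accelerating would make the slew constraint
      ## infeasible at the next state, take the braking root instead
      om_try <- om + alpha * dt
      s2 <- min((tt[i] + dt) / t_read, 1)
      d2 <- spiral_density_profile(spec, s2)
      rho2 <- -dens_scale * spiral_density_slope(spec, s2) / d2^2 / t_read
      b2 <- complex(real = om_try * rho2 - om_try^2 * r[i],
                    imaginary = 2 * om_try^2 * dens_scale / d2)
      if (Mod(b2) > 0.92 * Sk) alpha <- (-ab - sqrt(disc)) / aa
    } else {
      alpha <- -ab / aa
    }
    om <- min(om + alpha * dt, Gk / sqrt(rp^2 + r[i]^2))
    om <- max(om, 0)
    th[i + 1] <- th[i] + om * dt
    r[i + 1] <- r[i] + rp * om * dt
    tt[i + 1] <- tt[i] + dt
    if (r[i + 1] >= kmax) { reached <- TRUE; break }
  }
  idx <- seq_len(i + 1)
  list(t = tt[idx], theta = th[idx], r = r[idx],
       duration = tt[i + 1], reached = reached, kmax = kmax)
}

#' Design a dual-density spiral-out interleaf
#'
#' Integrates a time-optimal variable-density Archimedean spiral under the
#' vector-magnitude gradient amplitude and slew-rate limits. The interleaf is
#' designed as one of `n_arms` uniformly rotated copies, `n_arms` being the
#' smallest integer for which the spiral reaches `k_max = 1/(2 res)` within
#' the readout window; the reported `n_full` is the Nyquist-weighted sampling
#' requirement of the whole k-space disc divided by the number of ADC samples
#' one interleaf delivers, i.e. the number of interleaves a fully sampled
#' acquisition at the prescribed density would need.
#'
#' @param spec A [spiral_spec()].
#' @return A `spiral_interleaf` record with fields `k` (complex, cycles/mm),
#'   `g` (complex, mT/m), `dwell_us`, `duration_ms`, `n_arms`, `n_full`,
#'   `n_full_raw`, `k_max`, and the generating `spec`.
#' @export
design_dual_density_spiral <- function(spec) {
  stopifnot(inherits(spec, "spiral_spec"))
  kmax <- 1 / (2 * spec$res)
  ## quick feasibility screen: straight-line traversal at the amplitude limit
  Gk <- GAMMA_BAR * spec$limits$g_max
  if (kmax / Gk > spec$readout_ms * 1e-3) {
    stopf(paste0(
      "infeasible spiral spec: even a straight radial line at the amplitude ",
      "limit (%.1f mT/m) needs %.2f ms to reach k_max = %.4f cycles/mm, ",
      "longer than the %.2f ms readout (binding constraint: gradient ",
      "amplitude)"), spec$limits$g_max, 1e3 * kmax / Gk, kmax, spec$readout_ms)
  }
  path <- NULL; n_arms <- NA_integer_
  for (n in 1:512) {
    cand <- spiral_integrate(spec, n)
    if (cand$reached && cand$duration <= spec$readout_ms * 1e-3 + 1e-12) {
      path <- cand; n_arms <- n; break
    }
  }
  if (is.null(path)) {
    stopf(paste0(
      "infeasible spiral spec: no interleaf multiplicity up to 512 reaches ",
      "k_max within the %.2f ms readout under the slew-rate limit %.1f T/m/s ",
      "(binding constraint: slew rate)"),
      spec$readout_ms, spec$limits$s_max)
  }
  ## resample the path at the ADC dwell
  dwell_s <- spec$dwell_us * 1e-6
  ts <- seq(0, path$duration, by = dwell_s)
  th <- stats::approx(path$t, path$theta, xout = ts)$y
  rr <- stats::approx(path$t, path$r, xout = ts)$y
  k <- complex(modulus = rr, argument = th)
  g <- c(diff(k) / (GAMMA_BAR * dwell_s), complex(1, 0, 0))
  g[length(g)] <- g[length(g) - 1]

  ## Nyquist-weighted sampling requirement of the k-space disc, using the
  ## design's own time->radius map to place the density transition in radius
  dens_t <- spiral_density_profile(spec, pmin(path$t / (spec$readout_ms * 1e-3), 1))
  integrand <- 2 * pi * path$r * dens_t
  n_req <- spec$fov^2 *
    sum(diff(path$r) * (utils::head(integrand, -1) + utils::tail(integrand, -1)) / 2)
  n_full_raw <- n_req / length(k)

  structure(list(
    k = k, g = g, dwell_us = spec$dwell_us,
    duration_ms = path$duration * 1e3,
    n_arms = n_arms,
    n_full = as.integer(round(n_full_raw)),
    n_full_raw = n_full_raw,
    k_max = max(Mod(k)),
    spec = spec
  ), class = "spiral_interleaf")
}

#' @export
print.spiral_interleaf <- function(x, ...) {
  cat(sprintf(
    paste0("<spiral_interleaf> %d samples, dwell %.3f us, duration %.3f ms\n",
           "  k_max %.5f cycles/mm; design multiplicity %d arms;\n",
           "  Nyquist-weighted requirement n_full = %d (%.2f raw)\n"),
    length(x$k), x$dwell_us, x$duration_ms, x$k_max, x$n_arms,
    x$n_full, x$n_full_raw))
  invisible(x)
}

#' Rotate a spiral interleaf in the k-plane
#'
#' Counterclockwise pointwise rotation of the k-space samples and gradient
#' waveform; dwell and duration are untouched.
#'
#' @param interleaf A `spiral_interleaf`.
#' @param angle_deg Rotation angle in degrees, counterclockwise positive.
#' @return The rotated `spiral_interleaf`.
#' @export
rotate_interleaf <- function(interleaf, angle_deg) {
  stopifnot(inherits(interleaf, "spiral_interleaf"), is.finite(angle_deg))
  rot <- exp(1i * angle_deg * pi / 180)
  interleaf$k <- interleaf$k * rot
  interleaf$g <- interleaf$g * rot
  interleaf
}

#' Undersampling (acceleration) factor of an acquisition
#'
#' Ratio of the interleaf count a fully sampled acquisition at the prescribed
#' dual-density would need (`n_full`) to the number of interleaves actually
#' acquired per velocity encoding.
#'
#' @param design A `spiral_interleaf` from [design_dual_density_spiral()], or
#'   a `spiral_spec` (designed on the fly).
#' @param acquired_per_encoding Interleaves acquired per encoding (>= 1).
#' @return Acceleration factor R (unitless).
#' @export
acceleration_factor <- function(design, acquired_per_encoding) {
  if (inherits(design, "spiral_spec")) design <- design_dual_density_spiral(design)
  stopifnot(inherits(design, "spiral_interleaf"))
  if (!is_scalar_num(acquired_per_encoding) || acquired_per_encoding < 1) {
    stopf("acquired_per_encoding must be >= 1")
  }
  design$n_full / acquired_per_encoding
}
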