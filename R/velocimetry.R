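#' Phase difference of a flow-encoded / flow-compensated series pair
#'
#' Magnitude-robust conjugate product: `arg(fe conj(fc))`, in (-pi, pi].
#' Pixels where both magnitudes vanish get phase 0 and are flagged in the
#' returned low-confidence mask.
#'
#' @param fc,fe `image_series` objects (or plain complex arrays) with
#'   matching geometry and frame counts.
#' @return List `phase` (radians array), `mask_low` (logical array, TRUE
#'   where magnitude is negligible), `frame_times_ms`.
#' @export
phase_difference <- function(fc, fe) {
  fcx <- if (inherits(fc, "image_series")) fc$frames else fc
  fex <- if (inherits(fe, "image_series")) fe$frames else fe
  if (!identical(dim(fcx), dim(fex))) {
    stopf("FC/FE series shape mismatch: %s vs %s",
          paste(dim(fcx), collapse = "x"), paste(dim(fex), collapse = "x"))
  }
  prod <- fex * Conj(fcx)
  phase <- Arg(prod)
  magthr <- 1e-9 * max(Mod(prod))
  low <- Mod(prod) <= magthr
  phase[low] <- 0
  list(phase = phase, mask_low = low,
       frame_times_ms = if (inherits(fc, "image_series")) fc$frame_times_ms else NULL)
}

#' Concomitant-field (Maxwell) correction of a phase-difference series
#'
#' Subtracts the lowest-order concomitant phase accrued between the
#' flow-compensated and flow-encoded slice-axis waveforms. For a transverse
#' slice the self-squared term of the through-plane gradient produces
#' `phi_c(x, y) = gamma (x^2 + y^2) / (8 B0) * (int Gz_fe^2 dt - int Gz_fc^2 dt)`,
#' evaluated here with the exact piecewise-linear closed form of the
#' waveform integrals. The correction scales as 1/B0.
#'
#' @param dphi Phase-difference array (from [phase_difference()]`$phase`) or
#'   the full list returned by [phase_difference()].
#' @param waveforms A [venc_waveforms()] pair.
#' @param fov_mm Field of view, mm.
#' @param b0_T Main field, Tesla.
#' @param slice_offset_mm In-plane isocenter offset (x, y) of the image
#'   centre, mm. `NULL` means unknown geometry: the correction is skipped
#'   with a warning and the result is flagged `maxwell_corrected = FALSE`.
#' @return The corrected array with attributes `maxwell_corrected` and
#'   `maxwell_phase` (the subtracted map).
#' @export
maxwell_correction <- function(dphi, waveforms, fov_mm, b0_T = 0.55,
                               slice_offset_mm = c(0, 0)) {
  arr <- if (is.list(dphi)) dphi$phase else dphi
  if (is.null(slice_offset_mm)) {
    warnf("slice geometry unknown: Maxwell correction skipped")
    attr(arr, "maxwell_corrected") <- FALSE
    return(arr)
  }
  dsq <- pwl_sq_integral(waveforms$fe) - pwl_sq_integral(waveforms$fc)
  n <- dim(arr)[1]
  pos <- (seq_len(n) - 1 - n / 2) * fov_mm / n
  X <- matrix(pos + slice_offset_mm[1], n, n)
  Y <- matrix(pos + slice_offset_mm[2], n, n, byrow = TRUE)
  phi_c <- GAMMA_RAD * dsq * ((X^2 + Y^2) * 1e-6) / (8 * b0_T)
  out <- sweep_frames(arr, phi_c, `-`)
  attr(out, "maxwell_corrected") <- TRUE
  attr(out, "maxwell_phase") <- phi_c
  out
}

## apply a 2D map to every frame of a 2D or 3D array
sweep_frames <- function(arr, map2d, op) {
  if (length(dim(arr)) == 2L) return(op(arr, map2d))
  out <- arr
  for (f in seq_len(dim(arr)[3])) out[, , f] <- op(arr[, , f], map2d)
  out
}

#' Convert a phase-difference series to velocities
#'
#' `v = venc * dphi / pi` (phase pi maps to the VENC velocity). Linear and
#' odd in the phase.
#'
#' @param dphi Phase array or [phase_difference()] list.
#' @param venc_cm_s VENC, cm/s.
#' @param frame_times_ms Frame times (taken from `dphi` when it is a list).
#' @return A `velocity_series`: fields `v` (cm/s), `frame_times_ms`, `venc`,
#'   `wrap_corrected`, `mask_low`.
#' @export
to_velocity <- function(dphi, venc_cm_s, frame_times_ms = NULL) {
  stopifnot(venc_cm_s > 0)
  arr <- if (is.list(dphi)) dphi$phase else dphi
  if (is.list(dphi) && is.null(frame_times_ms)) {
    frame_times_ms <- dphi$frame_times_ms
  }
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (is.null(frame_times_ms)) {
    frame_times_ms <- seq_len(dim(arr)[3])
  }
  structure(list(
    v = arr * venc_cm_s / pi,
    frame_times_ms = frame_times_ms,
    venc = venc_cm_s,
    wrap_corrected = FALSE,
    mask_low = if (is.list(dphi)) dphi$mask_low else NULL
  ), class = "velocity_series")
}

#' Temporal phase unwrapping of a velocity series
#'
#' Pixelwise along time: whenever the jump between consecutive frames
#' exceeds VENC, an integer multiple of `2 venc` is added to minimize the
#' jump. Idempotent, and only ever changes values by multiples of `2 venc`.
#'
#' @param vs A `velocity_series`.
#' @return The unwrapped series (`wrap_corrected = TRUE`).
#' @export
unwrap_temporal <- function(vs) {
  stopifnot(inherits(vs, "velocity_series"))
  v <- vs$v
  nf <- dim(v)[3]
  if (nf < 2) stopf("need at least 2 frames to unwrap along time")
  two_venc <- 2 * vs$venc
  for (f in 2:nf) {
    jump <- v[, , f] - v[, , f - 1]
    kwrap <- round(jump / two_venc)
    v[, , f] <- v[, , f] - kwrap * two_venc
  }
  vs$v <- v
  vs$wrap_corrected <- TRUE
  vs
}

#' @export
print.velocity_series <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf("<velocity_series> %d x %d x %d frames, VENC %g cm/s, %s\n",
              d[1], d[2], d[3], x$venc,
              if (x$wrap_corrected) "unwrapped" else "wrapped"))
  invisible(x)
}
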