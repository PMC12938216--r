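#' Golden-angle FC/FE acquisition schedule
#'
#' Builds the per-readout schedule of a real-time phase-contrast scan: each
#' 4-TR frame holds two flow-compensated (FC) and two flow-encoded (FE)
#' readouts ordered FC(theta), FE(theta), FC(theta+180), FE(theta+180), and
#' the base angle theta advances by the golden angle (~137.508 deg) from one
#' frame to the next.
#'
#' @param scan_time_s Total scan time, seconds.
#' @param tr_ms Repetition time of one readout, ms.
#' @return A tibble with one row per readout: `frame` (1-based), `readout`
#'   (1..4 within frame), `encoding` ("FC"/"FE"), `base_angle`, `angle`
#'   (degrees, mod 360), `start_time_ms`. Attributes `tr_ms`,
#'   `frame_duration_ms`, `n_frames`; class `acq_schedule`.
#' @export
build_schedule <- function(scan_time_s = 4, tr_ms = 11) {
  stopifnot(scan_time_s > 0, tr_ms > 0)
  frame_ms <- 4 * tr_ms
  n_frames <- floor(scan_time_s * 1000 / frame_ms)
  if (n_frames < 1) {
    stopf("scan time %.3f s is shorter than one %g ms frame",
          scan_time_s, frame_ms)
  }
  frame <- rep(seq_len(n_frames), each = 4L)
  readout <- rep(1:4, n_frames)
  base <- ((frame - 1) * GOLDEN_ANGLE) %% 360
  offs <- rep(c(0, 0, 180, 180), n_frames)
  out <- tibble::tibble(
    frame = frame,
    readout = readout,
    encoding = rep(c("FC", "FE", "FC", "FE"), n_frames),
    base_angle = base,
    angle = (base + offs) %% 360,
    start_time_ms = (frame - 1) * frame_ms + (readout - 1) * tr_ms
  )
  structure(out, tr_ms = tr_ms, frame_duration_ms = frame_ms,
            n_frames = n_frames, scan_time_s = scan_time_s,
            class = c("acq_schedule", class(out)))
}

#' Frame mid-times of a schedule
#'
#' @param schedule An `acq_schedule`.
#' @return Numeric vector of frame mid-times, ms.
#' @export
frame_times <- function(schedule) {
  fd <- attr(schedule, "frame_duration_ms")
  (seq_len(attr(schedule, "n_frames")) - 0.5) * fd
}
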