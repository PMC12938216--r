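#' Vessel region of interest
#'
#' @param mask Logical matrix (static) matching the velocity grid.
#' @param label Vessel label (`"AO"`, `"MPA"`, or free text).
#' @param pixel_area_mm2 Area of one pixel, mm^2.
#' @return A `vessel_roi` record.
#' @export
vessel_roi <- function(mask, label, pixel_area_mm2) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) stopf("empty ROI mask for %s", label)
  structure(list(mask = mask, label = label, pixel_area = pixel_area_mm2),
            class = "vessel_roi")
}

#' Flow curve over a vessel ROI
#'
#' `q(t) = sum_{pixels in mask} v(pixel, t) * pixel_area`, converted from
#' cm/s * mm^2 to mL/s: 1 cm/s * 1 mm^2 = 0.01 cm^3/s = 0.01 mL/s.
#'
#' @param vs A `velocity_series`.
#' @param roi A [vessel_roi()].
#' @return A tibble (class `flow_curve`): `t_ms`, `q_ml_s`, `vessel`; peak
#'   pixel velocity per frame as column `v_max_cm_s`.
#' @export
extract_flow_curve <- function(vs, roi) {
  stopifnot(inherits(vs, "velocity_series"), inherits(roi, "vessel_roi"))
  d <- dim(vs$v)
  if (!identical(dim(roi$mask), d[1:2])) {
    stopf("ROI geometry %s does not match velocity grid %s",
          paste(dim(roi$mask), collapse = "x"), paste(d[1:2], collapse = "x"))
  }
  nf <- d[3]
  vmat <- matrix(vs$v, d[1] * d[2], nf)[as.vector(roi$mask), , drop = FALSE]
  q <- colSums(vmat) * roi$pixel_area * 0.01        # mL/s
  vmax <- apply(vmat, 2, max)
  out <- tibble::tibble(t_ms = vs$frame_times_ms, q_ml_s = q,
                        v_max_cm_s = vmax, vessel = roi$label)
  class(out) <- c("flow_curve", class(out))
  out
}

#' Segment a flow curve into complete beats
#'
#' With trigger times (phantom truth or recorded ECG), beats are the windows
#' between consecutive triggers, discarding any beat not fully covered by
#' the record. Without triggers, onsets are detected as local minima of the
#' curve smoothed with a centred moving average (width `smooth_frames`),
#' subject to a minimum beat separation.
#'
#' @param curve A `flow_curve`.
#' @param trigger_times_ms Optional increasing trigger times, ms.
#' @param smooth_frames Moving-average width (frames) for detection.
#' @param min_rr_ms Minimum accepted RR for detected onsets.
#' @return Tibble of beat windows: `beat`, `t_start_ms`, `t_end_ms`.
#' @export
segment_beats <- function(curve, trigger_times_ms = NULL, smooth_frames = 3,
                          min_rr_ms = 350) {
  t <- curve$t_ms
  dt <- stats::median(diff(t))
  t_lo <- t[1] - dt / 2
  t_hi <- t[length(t)] + dt / 2
  if (is.null(trigger_times_ms)) {
    q <- as.numeric(stats::filter(curve$q_ml_s,
                                  rep(1 / smooth_frames, smooth_frames),
                                  sides = 2))
    q[is.na(q)] <- curve$q_ml_s[is.na(q)]
    ## systolic upstroke detection: find upward crossings of a low
    ## threshold, then walk back to the last near-baseline frame, which
    ## marks the beat onset to within one frame
    lo <- stats::quantile(q, 0.1, names = FALSE)
    hi <- stats::quantile(q, 0.95, names = FALSE)
    th_up <- lo + 0.25 * (hi - lo)
    th_base <- lo + 0.05 * (hi - lo)
    above <- q > th_up
    cross <- which(!utils::head(above, -1) & utils::tail(above, -1)) + 1L
    ons <- numeric(0)
    for (ci in cross) {
      j <- ci
      while (j > 1 && q[j - 1] > th_base) j <- j - 1L
      onset <- t[max(j - 1, 1)]
      if (length(ons) == 0 || onset - utils::tail(ons, 1) >= min_rr_ms) {
        ons <- c(ons, onset)
      }
    }
    trigger_times_ms <- ons
  }
  trig <- sort(trigger_times_ms)
  trig <- trig[trig >= t_lo - dt & trig <= t_hi + dt]
  if (length(trig) < 2) {
    warnf("no complete beat in the record")
    return(tibble::tibble(beat = integer(), t_start_ms = numeric(),
                          t_end_ms = numeric()))
  }
  starts <- utils::head(trig, -1)
  ends <- utils::tail(trig, -1)
  keep <- starts >= t_lo - dt & ends <= t_hi + dt
  if (!any(keep)) {
    warnf("no complete beat in the record")
    return(tibble::tibble(beat = integer(), t_start_ms = numeric(),
                          t_end_ms = numeric()))
  }
  tibble::tibble(beat = seq_len(sum(keep)), t_start_ms = starts[keep],
                 t_end_ms = ends[keep])
}

#' Per-beat haemodynamic measures
#'
#' Net flow is the trapezoidal integral of the flow curve over the beat
#' window (mL), peak flow rate the maximum of the curve (mL/s), peak
#' velocity the maximum single-pixel ROI velocity over the window's frames
#' (configurable percentile), RR the window length.
#'
#' @param curve A `flow_curve` (with `v_max_cm_s`).
#' @param beats Beat windows from [segment_beats()].
#' @param peak_velocity_percentile Percentile of the per-frame ROI maximum
#'   velocity used as "peak velocity" (1 = single-pixel maximum).
#' @return Tibble (class `beat_measures`): `vessel`, `beat`, `rr_ms`,
#'   `net_flow_ml`, `peak_flow_ml_s`, `peak_velocity_cm_s`.
#' @export
beat_measures <- function(curve, beats, peak_velocity_percentile = 1) {
  stopifnot(nrow(beats) >= 1)
  t <- curve$t_ms
  rows <- lapply(seq_len(nrow(beats)), function(i) {
    w <- beats[i, ]
    sel <- which(t >= w$t_start_ms & t <= w$t_end_ms)
    if (length(sel) < 2) {
      stopf("beat %d covers fewer than two frames", w$beat)
    }
    ## integrate over the full window: interpolate the curve to the window
    ## edges (constant extrapolation at record boundaries)
    edge <- stats::approx(t, curve$q_ml_s, xout = c(w$t_start_ms, w$t_end_ms),
                          rule = 2)$y
    ts <- c(w$t_start_ms, t[sel], w$t_end_ms)
    qs <- c(edge[1], curve$q_ml_s[sel], edge[2])
    keepi <- !duplicated(ts)
    ts <- ts[keepi]; qs <- qs[keepi]
    net <- sum(diff(ts) * (utils::head(qs, -1) + utils::tail(qs, -1)) / 2) / 1000
    pv <- stats::quantile(curve$v_max_cm_s[sel], peak_velocity_percentile,
                          names = FALSE)
    tibble::tibble(vessel = curve$vessel[1], beat = w$beat,
                   rr_ms = w$t_end_ms - w$t_start_ms,
                   net_flow_ml = net, peak_flow_ml_s = max(qs),
                   peak_velocity_cm_s = pv)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("beat_measures", class(out))
  out
}

#' Pulmonary-to-systemic flow ratio
#'
#' @param mpa_net_flow_ml,ao_net_flow_ml Beat-averaged net flows, mL.
#' @return Qp/Qs ratio.
#' @export
qp_qs <- function(mpa_net_flow_ml, ao_net_flow_ml) {
  if (!is_scalar_num(ao_net_flow_ml) || ao_net_flow_ml <= 0) {
    stopf("aortic net flow must be positive, got %s", format(ao_net_flow_ml))
  }
  mpa_net_flow_ml / ao_net_flow_ml
}

#' Coefficient of variation (percent)
#'
#' `100 sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stopf("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stopf("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Average beat measures over all complete beats
#'
#' @param measures A `beat_measures` tibble (possibly several vessels).
#' @return One row per vessel with arithmetic means of every measure and the
#'   beat count.
#' @export
average_over_beats <- function(measures) {
  if (nrow(measures) < 1) stopf("no beats to average")
  dplyr::summarise(
    dplyr::group_by(measures, .data$vessel),
    n_beats = dplyr::n(),
    rr_ms = mean(.data$rr_ms),
    net_flow_ml = mean(.data$net_flow_ml),
    peak_flow_ml_s = mean(.data$peak_flow_ml_s),
    peak_velocity_cm_s = mean(.data$peak_velocity_cm_s),
    .groups = "drop")
}

#' Threshold-based ROI helper
#'
#' Otsu threshold on a magnitude image followed by connected-component
#' selection around a seed point. A convenience stand-in for manual
#' contouring; not equivalent to clinical auto-contouring software.
#'
#' @param magnitude Magnitude image (matrix).
#' @param seed_px Integer (x, y) pixel inside the target vessel.
#' @param label,pixel_area_mm2 Passed to [vessel_roi()].
#' @return A [vessel_roi()].
#' @export
otsu_roi <- function(magnitude, seed_px, label, pixel_area_mm2) {
  v <- as.vector(magnitude)
  ## Otsu: maximize between-class variance over a 256-bin histogram
  br <- seq(min(v), max(v), length.out = 257)
  h <- graphics::hist(v, breaks = br, plot = FALSE)$counts
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_along(p))
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  thr <- br[which.max(sigma_b) + 1]
  bin <- magnitude > thr
  ## flood fill from the seed
  n1 <- nrow(bin); n2 <- ncol(bin)
  if (!bin[seed_px[1], seed_px[2]]) {
    stopf("seed pixel (%d, %d) is below the Otsu threshold", seed_px[1], seed_px[2])
  }
  lab <- matrix(FALSE, n1, n2)
  stack <- list(seed_px)
  while (length(stack) > 0) {
    px <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- px[1]; j <- px[2]
    if (i < 1 || j < 1 || i > n1 || j > n2 || lab[i, j] || !bin[i, j]) next
    lab[i, j] <- TRUE
    stack <- c(stack, list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1)))
  }
  vessel_roi(lab, label, pixel_area_mm2)
}
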