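## Raw-data and image I/O.
##
## K-space bundles follow the logical layout of the ISMRM raw-data format:
## one record per readout carrying samples for every coil, the attached
## trajectory, the encoding label (FC/FE), frame index and timestamp, plus a
## header with geometry and protocol parameters. The container is a
## directory of Arrow Parquet tables plus a JSON header, a columnar layout
## readable from any Arrow binding. Image and velocity series are written
## as NIfTI with the temporal dimension as volumes.

#' Write a k-space bundle
#'
#' @param kspace A `kspace_data`.
#' @param path Output directory (created; must not be an existing file).
#' @return `path`, invisibly.
#' @export
write_kspace <- function(kspace, path) {
  stopifnot(inherits(kspace, "kspace_data"))
  if (file.exists(path) && !dir.exists(path)) {
    stopf("path %s exists and is not a directory", path)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  h <- kspace$header
  h$n_samples <- nrow(kspace$samples)
  h$n_readouts <- ncol(kspace$samples)
  jsonlite::write_json(h, file.path(path, "header.json"), auto_unbox = TRUE,
                       digits = NA)
  arrow::write_parquet(kspace$readouts, file.path(path, "readouts.parquet"))
  traj <- tibble::tibble(sample = seq_along(kspace$interleaf$k),
                         kx = Re(kspace$interleaf$k),
                         ky = Im(kspace$interleaf$k),
                         gx = Re(kspace$interleaf$g),
                         gy = Im(kspace$interleaf$g))
  attr_tbl <- tibble::tibble(
    dwell_us = kspace$interleaf$dwell_us,
    duration_ms = kspace$interleaf$duration_ms,
    n_arms = kspace$interleaf$n_arms,
    n_full = kspace$interleaf$n_full,
    n_full_raw = kspace$interleaf$n_full_raw,
    k_max = kspace$interleaf$k_max)
  arrow::write_parquet(traj, file.path(path, "trajectory.parquet"))
  arrow::write_parquet(attr_tbl, file.path(path, "trajectory_meta.parquet"))
  d <- dim(kspace$samples)
  samp <- tibble::tibble(
    readout = rep(rep(seq_len(d[2]), each = d[1]), d[3]),
    coil = rep(seq_len(d[3]), each = d[1] * d[2]),
    sample = rep(seq_len(d[1]), d[2] * d[3]),
    re = as.vector(Re(kspace$samples)),
    im = as.vector(Im(kspace$samples)))
  arrow::write_parquet(samp, file.path(path, "samples.parquet"))
  invisible(path)
}

#' Read a k-space bundle
#'
#' Validates the container structure; a bundle without an attached
#' trajectory or with inconsistent sample counts is rejected with an error
#' naming the offending record.
#'
#' @param path Bundle directory written by [write_kspace()].
#' @return A `kspace_data`.
#' @export
read_kspace <- function(path) {
  if (!dir.exists(path)) stopf("no k-space bundle at %s", path)
  need <- c("header.json", "readouts.parquet", "trajectory.parquet",
            "samples.parquet", "trajectory_meta.parquet")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stopf("malformed k-space bundle: missing record %s", f)
    }
  }
  h <- jsonlite::read_json(file.path(path, "header.json"), simplifyVector = TRUE)
  readouts <- tibble::as_tibble(
    arrow::read_parquet(file.path(path, "readouts.parquet")))
  traj <- arrow::read_parquet(file.path(path, "trajectory.parquet"))
  tm <- arrow::read_parquet(file.path(path, "trajectory_meta.parquet"))
  if (nrow(traj) != h$n_samples) {
    stopf("malformed k-space bundle: trajectory has %d samples, header says %d",
          nrow(traj), h$n_samples)
  }
  samp <- arrow::read_parquet(file.path(path, "samples.parquet"))
  expect_rows <- h$n_samples * h$n_readouts * h$n_coils
  if (nrow(samp) != expect_rows) {
    stopf("malformed k-space bundle: samples table has %d rows, expected %d",
          nrow(samp), expect_rows)
  }
  samples <- array(complex(real = samp$re, imaginary = samp$im),
                   dim = c(h$n_samples, h$n_readouts, h$n_coils))
  interleaf <- structure(list(
    k = complex(real = traj$kx, imaginary = traj$ky),
    g = complex(real = traj$gx, imaginary = traj$gy),
    dwell_us = tm$dwell_us, duration_ms = tm$duration_ms,
    n_arms = tm$n_arms, n_full = tm$n_full, n_full_raw = tm$n_full_raw,
    k_max = tm$k_max), class = "spiral_interleaf")
  h$n_samples <- NULL; h$n_readouts <- NULL
  structure(list(header = h, readouts = readouts, samples = samples,
                 interleaf = interleaf), class = "kspace_data")
}

#' Write an image or velocity series as NIfTI
#'
#' Magnitude/phase pairs are written for complex series; velocity series are
#' written as a single float volume in cm/s. Frame timing, VENC and units
#' are carried in a JSON sidecar (NIfTI headers have no standard slot for
#' them).
#'
#' @param series An `image_series` or `velocity_series`.
#' @param path Output stem (files `<stem>_mag.nii.gz` / `<stem>_phase.nii.gz`
#'   or `<stem>_vel.nii.gz`, plus `<stem>.json`).
#' @return Vector of written files, invisibly.
#' @export
write_image_series <- function(series, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  meta <- list()
  files <- character(0)
  if (inherits(series, "image_series")) {
    arr <- series$frames
    d <- dim(arr)
    dim4 <- c(d[1], d[2], 1L, d[3])
    mag <- array(Mod(arr), dim4)
    ph <- array(Arg(arr), dim4)
    f1 <- paste0(path, "_mag.nii.gz"); f2 <- paste0(path, "_phase.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(mag), f1)
    RNifti::writeNifti(RNifti::asNifti(ph), f2)
    files <- c(f1, f2)
    meta <- list(kind = "image_series", encoding = series$encoding,
                 frame_times_ms = series$frame_times_ms,
                 units = list(magnitude = "a.u.", phase = "rad"))
  } else if (inherits(series, "velocity_series")) {
    d <- dim(series$v)
    f1 <- paste0(path, "_vel.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(array(series$v, c(d[1], d[2], 1L, d[3]))), f1)
    files <- f1
    meta <- list(kind = "velocity_series", venc_cm_s = series$venc,
                 wrap_corrected = series$wrap_corrected,
                 frame_times_ms = series$frame_times_ms,
                 units = list(velocity = "cm/s"))
    if (!is.null(series$mask_low)) {
      f2 <- paste0(path, "_lowmag.nii.gz")
      RNifti::writeNifti(
        RNifti::asNifti(array(series$mask_low * 1, c(d[1], d[2], 1L, d[3]))), f2)
      files <- c(files, f2)
    }
  } else stopf("unsupported series class: %s", paste(class(series), collapse = "/"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(files)
}

#' Read back a series written by [write_image_series()]
#'
#' @param path The stem used when writing.
#' @return An `image_series` or `velocity_series`.
#' @export
read_image_series <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  drop4 <- function(a) {
    d <- dim(a)
    array(a, dim = c(d[1], d[2], d[4]))
  }
  if (identical(meta$kind, "image_series")) {
    mag <- drop4(RNifti::readNifti(paste0(path, "_mag.nii.gz")))
    ph <- drop4(RNifti::readNifti(paste0(path, "_phase.nii.gz")))
    structure(list(frames = mag * exp(1i * ph),
                   frame_times_ms = meta$frame_times_ms,
                   encoding = meta$encoding),
              class = "image_series")
  } else {
    v <- drop4(RNifti::readNifti(paste0(path, "_vel.nii.gz")))
    structure(list(v = v, frame_times_ms = meta$frame_times_ms,
                   venc = meta$venc_cm_s,
                   wrap_corrected = meta$wrap_corrected,
                   mask_low = NULL),
              class = "velocity_series")
  }
}

#' Write per-beat measures as CSV
#'
#' @param measures A `beat_measures` tibble.
#' @param path CSV file path.
#' @export
write_beat_csv <- function(measures, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(measures), path, row.names = FALSE)
  invisible(path)
}

#' Write a flow/statistics report as JSON
#'
#' @param report A named list (e.g. from the pipeline's quantify stage).
#' @param path JSON file path.
#' @export
write_stats_json <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
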