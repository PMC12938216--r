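#' ESPIRiT coil sensitivity maps from flow-compensated k-space
#'
#' Autocalibrated sensitivity estimation: all flow-compensated readouts are
#' pooled and gridded (with Pipe-Menon density compensation) into a
#' time-averaged image whose central Cartesian k-space provides the
#' calibration region. A Hankel calibration matrix is built from sliding
#' kernel windows, its SVD row space (singular values above
#' `sigma_thresh` times the largest) is mapped to image space, and the
#' per-pixel eigendecomposition of the resulting operator yields the
#' sensitivity vector wherever the leading eigenvalue is close to one.
#' Maps are phase-normalized to the first coil, making the estimate
#' deterministic (SVD/eigenvector sign ambiguity removed).
#'
#' @param kspace A `kspace_data` object.
#' @param calib Calibration region size (pixels, even).
#' @param kernel ESPIRiT kernel size (pixels).
#' @param sigma_thresh Relative singular-value cutoff for the calibration
#'   row space.
#' @param eig_thresh Eigenvalue threshold below which a pixel is treated as
#'   outside the coil-supported region (maps set to the RSS-normalized
#'   gridded estimate there).
#' @param osf,width Gridding parameters for the pooled adjoint NUFFT.
#' @return A `coil_maps` array (`matrix x matrix x n_coils`), RSS-normalized.
#' @export
estimate_coil_maps <- function(kspace, calib = 24, kernel = 6,
                               sigma_thresh = 0.02, eig_thresh = 0.9,
                               osf = 1.6, width = 5) {
  stopifnot(inherits(kspace, "kspace_data"))
  n <- kspace$header$matrix
  fov <- kspace$header$fov
  nc <- dim(kspace$samples)[3]
  fc_rows <- which(kspace$readouts$encoding == "FC")
  if (length(fc_rows) < 1) stopf("no flow-compensated readouts to calibrate from")
  ## pooled FC trajectory and data
  nk <- nrow(kspace$samples)
  traj <- unlist(lapply(fc_rows, function(r) {
    kspace$interleaf$k * exp(1i * kspace$readouts$angle[r] * pi / 180)
  }))
  dat <- matrix(aperm(kspace$samples[, fc_rows, , drop = FALSE], c(1, 2, 3)),
                nk * length(fc_rows), nc)
  plan <- nufft_plan(traj, n, fov, osf = osf, width = width)
  w <- density_compensation_weights(traj, n, fov)
  avg <- nufft_adjoint(dat, plan, weights = w)     # time-averaged coil images
  avg <- array(avg, dim = c(n, n, nc))
  ## central calibration k-space of the averaged images
  kfull <- fft2_batch(ifftshift2(avg))
  kfull <- fftshift2(kfull)
  ctr <- n / 2 + 1
  half <- calib / 2
  idx <- (ctr - half):(ctr + half - 1)
  if (min(idx) < 1 || max(idx) > n) {
    stopf("calibration region %d exceeds the gridded matrix %d", calib, n)
  }
  C <- kfull[idx, idx, , drop = FALSE]
  ## Hankel calibration matrix: sliding kernel windows
  nwin <- calib - kernel + 1
  A <- matrix(0i, nwin * nwin, kernel * kernel * nc)
  rowi <- 1L
  for (jy in seq_len(nwin)) {
    for (jx in seq_len(nwin)) {
      blk <- C[jx:(jx + kernel - 1), jy:(jy + kernel - 1), , drop = FALSE]
      A[rowi, ] <- as.vector(blk)
      rowi <- rowi + 1L
    }
  }
  sv <- svd(A)
  keep <- which(sv$d > sigma_thresh * sv$d[1])
  V <- sv$v[, keep, drop = FALSE]                  # kernel space basis
  ## map kernels to image space with an explicit small DFT (exact, cheap:
  ## the kernel support is tiny); normalization by the window size puts the
  ## leading eigenvalue at 1 inside the coil-supported region
  nk2 <- length(keep)
  xs <- seq_len(n) - 1 - n / 2
  E <- exp(-2i * pi * outer(xs, seq_len(kernel) - 1) / n)   # n x kernel
  G <- array(0i, dim = c(n * n, nc, nk2))
  for (j in seq_len(nk2)) {
    ker <- array(V[, j], dim = c(kernel, kernel, nc))
    for (cc in seq_len(nc)) {
      G[, cc, j] <- as.vector(E %*% ker[, , cc] %*% t(E))
    }
  }
  G <- G / kernel
  ## per-pixel eigendecomposition of G(x) G(x)^H (nc x nc); the sensitivity
  ## vector is the conjugated dominant eigenvector
  maps <- array(0i, dim = c(n, n, nc))
  ev1 <- matrix(0, n, n)
  for (p in seq_len(n * n)) {
    M <- matrix(G[p, , ], nc, nk2)
    H <- M %*% Conj(t(M))
    e <- eigen(H, symmetric = TRUE)
    ev1[p] <- Re(e$values[1])
    vec <- Conj(e$vectors[, 1])
    ## phase-normalize to coil 1 (deterministic tie-break)
    ph <- Arg(vec[1])
    maps[p + (seq_len(nc) - 1) * n * n] <- vec * exp(-1i * ph)
  }
  ## outside the supported region fall back to the RSS-normalized average
  rss <- sqrt(apply(Mod(avg)^2, c(1, 2), sum))
  fallback <- unclass(avg) / array(pmax(rss, max(rss) * 1e-6), dim = dim(avg))
  low <- ev1 < eig_thresh
  for (cc in seq_len(nc)) {
    mc <- maps[, , cc]
    mc[low] <- fallback[, , cc][low]
    maps[, , cc] <- mc
  }
  structure(maps, eigenvalues = ev1, class = c("coil_maps", "array"))
}

## centred FFT helpers for 2D (+coil) arrays
fftshift2 <- function(x) {
  d <- dim(x); n1 <- d[1]; n2 <- d[2]
  i1 <- c((n1 / 2 + 1):n1, 1:(n1 / 2))
  i2 <- c((n2 / 2 + 1):n2, 1:(n2 / 2))
  if (length(d) == 2L) x[i1, i2] else x[i1, i2, , drop = FALSE]
}
ifftshift2 <- fftshift2  # even sizes: shift is its own inverse
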