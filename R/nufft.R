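## Non-uniform FFT by Kaiser-Bessel gridding.
##
## Type-2 (forward: image -> non-Cartesian samples) and its exact adjoint.
## The forward operator is: deapodize, zero-pad to an oversampled grid, FFT,
## then interpolate onto the sample locations with a separable Kaiser-Bessel
## kernel. The interpolation is precomputed as a real sparse matrix, so the
## adjoint is its transpose followed by the inverse FFT and deapodization.

kb_beta <- function(width, osf) {
  ## Beatty et al. choice of the Kaiser-Bessel shape parameter
  pi * sqrt(width^2 / osf^2 * (osf - 0.5)^2 - 0.8)
}

kb_kernel <- function(u, width, beta) {
  ## u in grid units, support |u| <= width/2
  x <- 1 - (2 * u / width)^2
  out <- numeric(length(u))
  ok <- x > 0
  out[ok] <- besselI(beta * sqrt(x[ok]), 0) / besselI(beta, 0)
  out
}

kb_apodization <- function(n, ngrid, width, beta) {
  ## closed-form 1D Fourier transform of the KB kernel, evaluated at the
  ## image positions of the final n-grid (centre-aligned):
  ## C(f) = (W / I0(beta)) * sinh(sqrt(beta^2 - (pi W f)^2)) / sqrt(...)
  x <- (seq_len(n) - 1 - n / 2) / ngrid
  arg <- (pi * width * x)^2 - beta^2
  f <- ifelse(arg > 0, sin(sqrt(arg)) / sqrt(arg), sinh(sqrt(-arg)) / sqrt(-arg))
  f * width / besselI(beta, 0)
}

#' Plan a 2D NUFFT for a fixed trajectory
#'
#' @param traj Complex vector (or 2-column matrix) of k-space sample
#'   coordinates in cycles/mm.
#' @param matrix Image matrix size (pixels, even).
#' @param fov_mm Field of view in mm (maps cycles/mm to cycles/FOV).
#' @param osf Grid oversampling factor.
#' @param width Kaiser-Bessel kernel width in oversampled grid units.
#' @return A `nufft_plan` holding the sparse interpolator and apodization.
#' @export
nufft_plan <- function(traj, matrix, fov_mm, osf = 2, width = 7) {
  if (is.matrix(traj)) traj <- complex(real = traj[, 1], imaginary = traj[, 2])
  n <- as.integer(matrix)
  stopifnot(n %% 2L == 0L, osf > 1, width >= 2)
  ## normalized coordinates in cycles per FOV: integer values are the
  ## Cartesian grid; Nyquist band is [-n/2, n/2)
  ku <- Re(traj) * fov_mm
  kv <- Im(traj) * fov_mm
  if (any(abs(ku) > n / 2 + 1e-9) || any(abs(kv) > n / 2 + 1e-9)) {
    stopf("trajectory exceeds the Nyquist band |k| <= %d/(2 fov): max |ku|=%.2f |kv|=%.2f",
          n, max(abs(ku)), max(abs(kv)))
  }
  ng <- nextn(ceiling(n * osf), c(2L, 3L, 5L))
  beta <- kb_beta(width, ng / n)
  m <- length(ku)
  hw <- width / 2
  ## oversampled-grid coordinates (0-based, wrapped)
  gu <- ku * ng / n
  gv <- kv * ng / n
  offs <- seq_len(ceiling(width)) - 1
  iu0 <- ceiling(gu - hw)
  iv0 <- ceiling(gv - hw)
  nk <- length(offs)
  ## row/col/weight triplets of the separable interpolation matrix
  iu <- outer(iu0, offs, "+")            # m x nk
  iv <- outer(iv0, offs, "+")
  wu <- kb_kernel(iu - gu, width, beta)  # recycles gu down columns
  wv <- kb_kernel(iv - gv, width, beta)
  dim(wu) <- dim(iu); dim(wv) <- dim(iv)
  iu <- iu %% ng
  iv <- iv %% ng
  rows <- rep.int(seq_len(m), nk * nk)
  cols <- integer(m * nk * nk)
  vals <- numeric(m * nk * nk)
  idx <- 1L
  for (a in seq_len(nk)) {
    for (b in seq_len(nk)) {
      sl <- idx:(idx + m - 1L)
      cols[sl] <- iu[, a] + ng * iv[, b] + 1L
      vals[sl] <- wu[, a] * wv[, b]
      idx <- idx + m
    }
  }
  interp <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                                 dims = c(m, ng * ng))
  apod <- kb_apodization(n, ng, width, beta)
  structure(list(
    n = n, ng = ng, m = m, width = width, beta = beta, fov = fov_mm,
    interp = interp, interp_t = Matrix::t(interp),
    deapod = 1 / outer(apod, apod)
  ), class = "nufft_plan")
}

## batched 2D FFT over the 3rd array dimension (one C-level mvfft per pass)
fft2_batch <- function(x, inverse = FALSE) {
  d <- dim(x)
  if (length(d) == 2L) d <- c(d, 1L)
  m <- matrix(x, d[1], d[2] * d[3])
  m <- stats::mvfft(m, inverse = inverse)
  x <- aperm(array(m, d), c(2L, 1L, 3L))
  m <- matrix(x, d[2], d[1] * d[3])
  m <- stats::mvfft(m, inverse = inverse)
  aperm(array(m, c(d[2], d[1], d[3])), c(2L, 1L, 3L))
}

## wrapped oversampled-grid indices of the centred n-pixel image axis:
## pixel j (1-based) sits at position j - 1 - n/2 in FOV-grid units
grid_indices <- function(n, ng) {
  ((seq_len(n) - 1L - n %/% 2L) %% ng) + 1L
}

#' Forward NUFFT: image to non-Cartesian k-space samples
#'
#' Approximates `s_j = sum_x img(x) exp(-2 pi i k_j . x)` with image
#' coordinates in FOV-normalized units (pixel p at position (p-1-n/2)/n FOV).
#'
#' @param img Complex matrix `n x n`, or `n x n x c` stack (e.g. coils).
#' @param plan A [nufft_plan()]; alternatively pass `traj`, `matrix`,
#'   `fov_mm` to plan on the fly.
#' @param traj,matrix,fov_mm Used when `plan` is missing.
#' @param ... Passed to [nufft_plan()] when planning on the fly.
#' @return Complex matrix `m x c` (dropped to a vector for a single slice).
#' @export
nufft_forward <- function(img, plan = NULL, traj = NULL, matrix = NULL,
                          fov_mm = NULL, ...) {
  if (is.null(plan)) plan <- nufft_plan(traj, matrix, fov_mm, ...)
  n <- plan$n; ng <- plan$ng
  d <- dim(img)
  nc <- if (length(d) == 3L) d[3] else 1L
  img <- array(img, dim = c(n, n, nc))
  img <- img * as.vector(plan$deapod)     # broadcast over coils
  gi <- grid_indices(n, ng)
  grid <- array(0i, dim = c(ng, ng, nc))
  grid[gi, gi, ] <- img
  grid <- fft2_batch(grid)
  gm <- matrix(grid, ng * ng, nc)
  out <- as.matrix(plan$interp %*% Re(gm)) + 1i * as.matrix(plan$interp %*% Im(gm))
  if (nc == 1L) out <- out[, 1]
  out
}

#' Adjoint NUFFT: non-Cartesian samples to image
#'
#' Exact adjoint of [nufft_forward()]; with density-compensation weights it is
#' the standard gridding reconstruction.
#'
#' @param samples Complex vector `m` or matrix `m x c`.
#' @param plan A [nufft_plan()].
#' @param weights Optional positive density-compensation weights (length `m`).
#' @return Complex `n x n` matrix (or `n x n x c`).
#' @export
nufft_adjoint <- function(samples, plan, weights = NULL) {
  n <- plan$n; ng <- plan$ng
  s <- as.matrix(samples)
  nc <- ncol(s)
  if (!is.null(weights)) s <- s * weights
  gm <- as.matrix(plan$interp_t %*% Re(s)) + 1i * as.matrix(plan$interp_t %*% Im(s))
  grid <- array(gm, dim = c(ng, ng, nc))
  grid <- fft2_batch(grid, inverse = TRUE)
  gi <- grid_indices(n, ng)
  img <- grid[gi, gi, , drop = FALSE]
  img <- img * as.vector(plan$deapod)
  if (nc == 1L) img <- img[, , 1]
  img
}
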