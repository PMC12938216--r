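#' Density compensation weights for a non-Cartesian sample set
#'
#' Pipe-Menon iterative density compensation: starting from unit weights,
#' each iteration divides by the gridding-convolution density
#' `(C^T C) w` evaluated at the samples, until the local density seen through
#' the gridding kernel is flat. Coincident (duplicate) samples share their
#' cell weight rather than producing infinities, and the method needs no
#' geometric tessellation of the sample cloud.
#'
#' @param interleaves A `spiral_interleaf`, a list of them, or a complex
#'   vector of k-space coordinates (cycles/mm).
#' @param matrix Image matrix size the weights are intended for.
#' @param fov_mm Field of view, mm.
#' @param iters Fixed-point iterations (default 20).
#' @param osf,width Gridding kernel parameters used for the density estimate.
#' @return Positive numeric weights, one per sample, normalized so that a
#'   gridding reconstruction preserves the DC level of a fully sampled set.
#' @export
density_compensation_weights <- function(interleaves, matrix, fov_mm,
                                         iters = 20, osf = 2, width = 5) {
  k <- dcf_collect_k(interleaves)
  if (length(k) < 1) stopf("need at least one interleaf / sample")
  plan <- nufft_plan(k, matrix, fov_mm, osf = osf, width = width)
  ## C^T C applied through the interpolation matrix only (no FFT needed):
  ## density at sample j = sum_i w_i * (kernel overlap between samples i, j)
  w <- rep(1, length(k))
  for (it in seq_len(iters)) {
    d <- as.numeric(plan$interp %*% (plan$interp_t %*% w))
    d[d <= 0] <- min(d[d > 0])
    w <- w / d
  }
  ## normalize: unit total weight per Nyquist cell over the covered disc
  ## (degenerate single-point clouds fall back to unit total weight)
  area <- pi * max(Mod(k))^2 * fov_mm^2   # Nyquist cells in the k-disc
  if (area <= 0) area <- 1
  w * area / sum(w)
}

dcf_collect_k <- function(x) {
  if (inherits(x, "spiral_interleaf")) return(x$k)
  if (is.complex(x)) return(x)
  if (is.list(x)) {
    return(unlist(lapply(x, function(el) {
      if (inherits(el, "spiral_interleaf")) el$k else as.complex(el)
    })))
  }
  stopf("cannot interpret `interleaves` as k-space samples")
}
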