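## Non-decimated (undecimated, a-trous) wavelet transforms.
##
## Shift-invariant transforms used as the sparsity operator of the
## compressed-sensing reconstruction. Filters are orthonormal QMF pairs
## scaled by 1/sqrt(2) per level, which makes every level a Parseval tight
## frame: ||W u||^2 = ||u||^2 and the synthesis operator is the exact
## adjoint, giving perfect reconstruction to machine precision.

wavelet_filters <- function(family = c("haar", "d2")) {
  family <- match.arg(family)
  h <- switch(family,
    haar = c(1, 1) / sqrt(2),
    d2   = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  )
  g <- rev(h) * (-1)^(seq_along(h) - 1)   # QMF highpass
  list(h = h, g = g)
}

## circular convolution of array x with short filter f along dimension `dim`,
## with taps spaced by 2^(level-1) (a-trous upsampling); filters scaled by
## 1/sqrt(2) here to keep the frame tight
atrous_filter <- function(x, f, dimn, level, adjoint = FALSE) {
  d <- dim(x)
  n <- d[dimn]
  step <- 2L^(level - 1L)
  out <- array(0i, dim = d)
  idx_all <- seq_len(n)
  f <- f / sqrt(2)
  for (j in seq_along(f)) {
    shift <- (j - 1L) * step
    src <- if (adjoint) ((idx_all - 1L - shift) %% n) + 1L
           else         ((idx_all - 1L + shift) %% n) + 1L
    out <- out + f[j] * index_dim(x, src, dimn)
  }
  out
}

## x indexed along dimension dimn by idx (generic-dimension slice shuffle)
index_dim <- function(x, idx, dimn) {
  d <- dim(x)
  args <- rep(list(quote(expr = )), length(d))
  args[[dimn]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

#' Non-decimated wavelet transform (forward)
#'
#' Undecimated (a-trous) wavelet analysis of a 2D+t array. Spatial levels use
#' the `spatial_family` filters along x and y (subbands LH, HL, HH per level
#' plus the final LL); temporal levels filter along the third dimension only.
#' Spatial and temporal transforms are independent operators (one is applied
#' to the input, not to the other's output), matching their use as separate
#' regularization terms.
#'
#' @param x Numeric or complex array: `nx x ny` or `nx x ny x nt`.
#' @param levels_spatial,levels_temporal Decomposition depths (0 disables).
#' @param spatial_family,temporal_family Filter families (`"d2"`, `"haar"`).
#' @return A `nwt` object: list of coefficient arrays plus bookkeeping.
#' @export
nwt_forward <- function(x, levels_spatial = 2, levels_temporal = 2,
                        spatial_family = "d2", temporal_family = "haar") {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  sf <- wavelet_filters(spatial_family)
  tf <- wavelet_filters(temporal_family)
  if (levels_spatial > 0) {
    need <- 2^levels_spatial
    if (min(d[1], d[2]) < need) {
      stopf("spatial dimensions %dx%d too small for %d levels (need >= %d)",
            d[1], d[2], levels_spatial, need)
    }
  }
  if (levels_temporal > 0 && d[3] < 2^levels_temporal) {
    stopf("temporal axis length %d too small for %d levels (need >= %d)",
          d[3], levels_temporal, 2^levels_temporal)
  }
  coefs <- list()
  ## spatial pyramid on the input
  ll <- x
  for (lev in seq_len(levels_spatial)) {
    lx <- atrous_filter(ll, sf$h, 1L, lev)
    hx <- atrous_filter(ll, sf$g, 1L, lev)
    coefs[[paste0("s", lev, "_LH")]] <- atrous_filter(lx, sf$g, 2L, lev)
    coefs[[paste0("s", lev, "_HL")]] <- atrous_filter(hx, sf$h, 2L, lev)
    coefs[[paste0("s", lev, "_HH")]] <- atrous_filter(hx, sf$g, 2L, lev)
    ll <- atrous_filter(lx, sf$h, 2L, lev)
  }
  if (levels_spatial > 0) coefs[["s_LL"]] <- ll
  ## temporal pyramid on the input
  lt <- x
  for (lev in seq_len(levels_temporal)) {
    coefs[[paste0("t", lev, "_H")]] <- atrous_filter(lt, tf$g, 3L, lev)
    lt <- atrous_filter(lt, tf$h, 3L, lev)
  }
  if (levels_temporal > 0) coefs[["t_L"]] <- lt
  structure(list(
    coefs = coefs, dim = d,
    levels_spatial = levels_spatial, levels_temporal = levels_temporal,
    spatial_family = spatial_family, temporal_family = temporal_family
  ), class = "nwt")
}

#' Non-decimated wavelet transform (inverse)
#'
#' Tight-frame synthesis (the adjoint of [nwt_forward()]); when both spatial
#' and temporal pyramids are present the two independent reconstructions are
#' averaged, preserving `nwt_inverse(nwt_forward(x)) == x`.
#'
#' @param w A `nwt` object.
#' @return The reconstructed array (third dimension dropped if singleton).
#' @export
nwt_inverse <- function(w) {
  stopifnot(inherits(w, "nwt"))
  sf <- wavelet_filters(w$spatial_family)
  tf <- wavelet_filters(w$temporal_family)
  parts <- 0L
  out <- array(0i, dim = w$dim)
  if (w$levels_spatial > 0) {
    ll <- w$coefs[["s_LL"]]
    for (lev in rev(seq_len(w$levels_spatial))) {
      lx <- atrous_filter(ll, sf$h, 2L, lev, adjoint = TRUE) +
            atrous_filter(w$coefs[[paste0("s", lev, "_LH")]], sf$g, 2L, lev, adjoint = TRUE)
      hx <- atrous_filter(w$coefs[[paste0("s", lev, "_HL")]], sf$h, 2L, lev, adjoint = TRUE) +
            atrous_filter(w$coefs[[paste0("s", lev, "_HH")]], sf$g, 2L, lev, adjoint = TRUE)
      ll <- atrous_filter(lx, sf$h, 1L, lev, adjoint = TRUE) +
            atrous_filter(hx, sf$g, 1L, lev, adjoint = TRUE)
    }
    out <- out + ll
    parts <- parts + 1L
  }
  if (w$levels_temporal > 0) {
    lt <- w$coefs[["t_L"]]
    for (lev in rev(seq_len(w$levels_temporal))) {
      lt <- atrous_filter(lt, tf$h, 3L, lev, adjoint = TRUE) +
            atrous_filter(w$coefs[[paste0("t", lev, "_H")]], tf$g, 3L, lev, adjoint = TRUE)
    }
    out <- out + lt
    parts <- parts + 1L
  }
  if (parts == 0L) stopf("empty transform: no spatial or temporal levels")
  out <- out / parts
  if (w$dim[3] == 1L) dim(out) <- w$dim[1:2]
  out
}

## threshold the detail coefficients in place (complex magnitude soft
## thresholding); LL/L approximation bands are left untouched
nwt_soft_threshold <- function(w, tau_spatial, tau_temporal) {
  for (nm in names(w$coefs)) {
    if (nm %in% c("s_LL", "t_L")) next
    tau <- if (startsWith(nm, "s")) tau_spatial else tau_temporal
    if (tau <= 0) next
    cc <- w$coefs[[nm]]
    mag <- Mod(cc)
    shrink <- pmax(mag - tau, 0) / pmax(mag, .Machine$double.eps)
    w$coefs[[nm]] <- cc * shrink
  }
  w
}

## l1 norm of the detail bands (for the CS objective)
nwt_l1 <- function(w, which = c("spatial", "temporal")) {
  which <- match.arg(which)
  pre <- if (which == "spatial") "s" else "t"
  tot <- 0
  for (nm in names(w$coefs)) {
    if (nm %in% c("s_LL", "t_L")) next
    if (startsWith(nm, pre)) tot <- tot + sum(Mod(w$coefs[[nm]]))
  }
  tot
}
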