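## Internal constants and small helpers shared across modules.

# gyromagnetic ratio of 1H, gamma/2pi, in cycles/mm/s per mT/m
# (42.5774688 MHz/T scaled to the package's k-space units of cycles/mm)
GAMMA_BAR <- 42.5774688

# golden angle in degrees, 360 - 360/phi, full precision
GOLDEN_ANGLE <- 360 - 360 / ((1 + sqrt(5)) / 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Even image matrix size for a field of view and resolution
#'
#' The reconstruction grid is `fov/resolution` rounded up to the next even
#' integer; even sizes keep wavelet and Fourier bookkeeping simple.
#'
#' @param fov_mm Field of view in mm.
#' @param res_mm Nominal in-plane resolution in mm.
#' @return Even integer matrix size (pixels per side).
#' @export
matrix_size <- function(fov_mm, res_mm) {
  stopifnot(fov_mm > 0, res_mm > 0, res_mm < fov_mm)
  2L * as.integer(ceiling(fov_mm / res_mm / 2))
}

## run expr with a local RNG state seeded by `seed` (restores global state)
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## complex standard normal array
crnorm <- function(n, sd = 1) {
  complex(real = stats::rnorm(n, sd = sd / sqrt(2)),
          imaginary = stats::rnorm(n, sd = sd / sqrt(2)))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
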