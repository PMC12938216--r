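## Shared small-scale fixtures. Everything is generated in code; the heavy
## full-protocol pipeline is built lazily once (in test-acceptance.R) and
## cached in this environment for reuse across assertions.

.fixtures <- new.env(parent = emptyenv())

## small two-vessel phantom: 32x32, short scan, 4 coils
small_phantom <- function(noise_sigma = 0, scan_time_s = 2, seed = 7,
                          maxwell = FALSE, n_coils = 4, ...) {
  phantom_config(
    fov_mm = 160, res_mm = 5, matrix = 32,
    vessels = list(
      phantom_vessel("AO", center = c(-25, 5), radius_mm = 14,
                     peak_cm_s = 120, systole_ms = 360),
      phantom_vessel("MPA", center = c(18, 18), radius_mm = 15,
                     peak_cm_s = 80, systole_ms = 400)),
    noise_sigma = noise_sigma, n_coils = n_coils, maxwell = maxwell,
    scan_time_s = scan_time_s, seed = seed, ...)
}

small_spec <- function(...) {
  spiral_spec(fov_mm = 160, res_mm = 5, readout_ms = 5.32, ...)
}

## memoise an expensive fixture across test files
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

## dense non-uniform DFT oracle (brute force)
dense_ndft <- function(img, traj, fov) {
  n <- nrow(img)
  x <- (seq_len(n) - 1 - n / 2) / n
  vapply(seq_along(traj), function(j) {
    e1 <- exp(-2i * pi * Re(traj[j]) * fov * x)
    e2 <- exp(-2i * pi * Im(traj[j]) * fov * x)
    sum(img * outer(e1, e2))
  }, complex(1))
}

table1_interleaf <- function() {
  fixture("table1_interleaf", design_dual_density_spiral(spiral_spec()))
}

small_interleaf <- function() {
  fixture("small_interleaf", design_dual_density_spiral(small_spec()))
}
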