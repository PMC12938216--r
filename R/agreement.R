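#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`; bias is their mean and the limits of agreement
#' are `bias +/- 1.96 sd(d)` with the sample standard deviation and the
#' exact 1.96 multiplier.
#'
#' @param a,b Paired measurements (equal length, n >= 2).
#' @return A `bland_altman` record: `bias`, `loa_low`, `loa_high`, `sd_d`,
#'   `n`, and the pair means/differences for plotting.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) {
    stopf("paired vectors differ in length (%d vs %d)", length(a), length(b))
  }
  if (length(a) < 2) stopf("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * sd_d,
                 loa_high = bias + 1.96 * sd_d, sd_d = sd_d,
                 n = length(d), means = (a + b) / 2, diffs = d),
            class = "bland_altman")
}

#' Paired t-test p-value
#'
#' Two-sided p from `t = mean(d) / (sd(d)/sqrt(n))` with `n - 1` degrees of
#' freedom. A degenerate all-zero difference vector (zero variance, zero
#' mean) returns p = 1 by convention.
#'
#' @param a,b Paired measurements.
#' @return Two-sided p-value.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stopf("length mismatch")
  n <- length(a)
  if (n < 2) stopf("need at least 2 pairs")
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) {
    return(if (mean(d) == 0) 1 else 0)
  }
  tstat <- mean(d) / (s / sqrt(n))
  2 * stats::pt(-abs(tstat), df = n - 1)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects model, absolute agreement, single measures
#' (Shrout-Fleiss ICC(2,1)), from the mean squares of the subject x method
#' decomposition, with the standard F-based 95% confidence interval and the
#' agreement band (>0.9 excellent, 0.6-0.9 good, <0.6 moderate).
#'
#' @param a,b Paired measurements of the same subjects by two methods
#'   (n >= 3).
#' @param model `"ICC2"` (two-way random, absolute agreement; default) or
#'   `"ICC3"` (two-way mixed, consistency).
#' @param conf_level Confidence level of the interval.
#' @return An `icc_agreement` record: `icc`, `ci_low`, `ci_high`, `band`,
#'   `model`, `n`.
#' @export
icc_agreement <- function(a, b, model = c("ICC2", "ICC3"),
                          conf_level = 0.95) {
  model <- match.arg(model)
  if (length(a) != length(b)) stopf("length mismatch")
  n <- length(a)
  if (n < 3) stopf("ICC needs at least 3 pairs")
  x <- cbind(a, b)
  k <- 2
  if (stats::var(as.vector(x)) == 0) stopf("degenerate (constant) data: ICC undefined")
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  grand <- mean(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)              # between-subject
  msc <- ss_cols / (k - 1)              # between-method
  mse <- ss_err / ((n - 1) * (k - 1))   # residual
  if (model == "ICC2") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
  }
  alpha <- 1 - conf_level
  if (model == "ICC2") {
    ## F-based interval with Satterthwaite degrees of freedom
    ## (Shrout & Fleiss / McGraw & Wong)
    fj <- msc / mse
    vn <- (k - 1) * (n - 1) *
      (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
    vd <- (n - 1) * k^2 * icc^2 * fj^2 +
      (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
    f_low <- stats::qf(1 - alpha / 2, n - 1, v)
    f_up <- stats::qf(1 - alpha / 2, v, n - 1)
    ci_low <- (n * (msr - f_low * mse)) /
      (f_low * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci_high <- (n * (f_up * msr - mse)) /
      (k * msc + (k * n - k - n) * mse + n * f_up * msr)
  } else {
    fobs <- msr / mse
    f1 <- stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    f2 <- stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci_low <- (fobs / f1 - 1) / (fobs / f1 + k - 1)
    ci_high <- (fobs * f2 - 1) / (fobs * f2 + k - 1)
  }
  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 band = icc_band(icc), model = model, n = n,
                 msr = msr, msc = msc, mse = mse),
            class = "icc_agreement")
}

#' Agreement band of an ICC value
#'
#' @param icc ICC value.
#' @return `"excellent"` (> 0.9), `"good"` (0.6-0.9) or `"moderate"` (< 0.6).
#' @export
icc_band <- function(icc) {
  ifelse(icc > 0.9, "excellent", ifelse(icc >= 0.6, "good", "moderate"))
}

#' Mean absolute error of paired measurements
#'
#' @param a,b Paired measurements.
#' @return `mean(|a - b|)`.
#' @export
mean_absolute_error <- function(a, b) {
  if (length(a) != length(b)) stopf("length mismatch")
  mean(abs(a - b))
}

#' Full method-comparison summary for one parameter
#'
#' @param a,b Paired measurements (method A = e.g. real-time, method B =
#'   reference).
#' @param parameter Optional parameter name carried into the output.
#' @return An `agreement_result` combining Bland-Altman, paired t-test,
#'   ICC(2,1) with CI and band, and MAE.
#' @export
agreement_summary <- function(a, b, parameter = NULL) {
  ba <- bland_altman(a, b)
  icc <- icc_agreement(a, b)
  structure(list(parameter = parameter, bias = ba$bias,
                 loa_low = ba$loa_low, loa_high = ba$loa_high,
                 p_value = paired_t_test(a, b),
                 icc = icc$icc, icc_ci_low = icc$ci_low,
                 icc_ci_high = icc$ci_high, icc_band = icc$band,
                 mae = mean_absolute_error(a, b), n = ba$n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    paste0("<agreement%s> n=%d bias=%.3g LOA [%.3g, %.3g] p=%.3g\n",
           "  ICC %.3f (95%% CI %.3f-%.3f, %s) MAE %.3g\n"),
    if (is.null(x$parameter)) "" else paste0(": ", x$parameter),
    x$n, x$bias, x$loa_low, x$loa_high, x$p_value,
    x$icc, x$icc_ci_low, x$icc_ci_high, x$icc_band, x$mae))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy agreement_result
#' @export
tidy.agreement_result <- function(x, ...) {
  tibble::tibble(
    term = c("bias", "loa_low", "loa_high", "icc", "icc_ci_low",
             "icc_ci_high", "mae"),
    estimate = c(x$bias, x$loa_low, x$loa_high, x$icc, x$icc_ci_low,
                 x$icc_ci_high, x$mae))
}

#' @method glance agreement_result
#' @export
glance.agreement_result <- function(x, ...) {
  tibble::tibble(parameter = x$parameter %||% NA_character_, n = x$n,
                 bias = x$bias, loa_low = x$loa_low, loa_high = x$loa_high,
                 p_value = x$p_value, icc = x$icc, icc_band = x$icc_band,
                 mae = x$mae)
}

#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(term = c("bias", "loa_low", "loa_high"),
                 estimate = c(x$bias, x$loa_low, x$loa_high))
}

#' No-reference perceptual blur metric
#'
#' Crete-Roffet construction: the image is re-blurred with a strong 1D
#' averaging kernel horizontally and vertically; the attenuation of
#' neighbouring-pixel absolute differences measures how much sharpness the
#' re-blur removed. Values near 0 mean sharp, near 1 blurred. A constant
#' image (no edges) is defined as 1.
#'
#' @param image Magnitude image (matrix, at least 8x8).
#' @param kernel_size Width of the re-blur averaging kernel.
#' @return Blur value in (0, 1).
#' @export
blur_metric <- function(image, kernel_size = 9) {
  stopifnot(is.matrix(image))
  if (nrow(image) < 8 || ncol(image) < 8) stopf("image must be at least 8x8")
  f <- image
  if (max(f) > min(f)) f <- (f - min(f)) / (max(f) - min(f)) else return(1)
  k <- rep(1 / kernel_size, kernel_size)
  blur_ver <- apply_1d_kernel(f, k, along = 1)
  blur_hor <- apply_1d_kernel(f, k, along = 2)
  dv <- abs(diff(f))                 # vertical neighbour differences
  dh <- abs(t(diff(t(f))))           # horizontal
  dbv <- abs(diff(blur_ver))
  dbh <- abs(t(diff(t(blur_hor))))
  sv <- sum(pmax(dv - dbv, 0))
  sh <- sum(pmax(dh - dbh, 0))
  tv <- sum(dv); th <- sum(dh)
  if (tv == 0 && th == 0) return(1)
  bv <- if (tv > 0) (tv - sv) / tv else 1
  bh <- if (th > 0) (th - sh) / th else 1
  max(bv, bh)
}

## reflective-boundary 1D moving average along rows (1) or columns (2)
apply_1d_kernel <- function(f, k, along) {
  if (along == 2) return(t(apply_1d_kernel(t(f), k, 1)))
  half <- (length(k) - 1) / 2
  n <- nrow(f)
  idx <- seq_len(n)
  out <- matrix(0, n, ncol(f))
  for (j in seq_along(k)) {
    src <- idx + (j - 1 - half)
    src <- pmin(pmax(src, 1), n)     # clamp at the border
    out <- out + k[j] * f[src, , drop = FALSE]
  }
  out
}
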