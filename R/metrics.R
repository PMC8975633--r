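# Image-quality metrics between an estimated slice x and a reference slice y:
#
#   NRMSE = sqrt( sum (x - y)^2 / sum y^2 ) * 100
#   PSNR  = 20 * log10( MAX / sqrt(MSE) ),  MAX = peak intensity of the
#           reference (default convention)
#   SSIM  = mean over local windows of
#           (2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#           ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))
#
# Metrics are intended for physical-scale (denormalized) intensities, since
# MAX and sum(y^2) are scale-dependent.

#' Metric configuration
#'
#' @param ssim_window odd local-window size (default 11).
#' @param ssim_sigma Gaussian window width (default 1.5); `0` selects a
#'   uniform window.
#' @param k1,k2 SSIM stabiliser factors giving `C1 = (k1*L)^2`,
#'   `C2 = (k2*L)^2` for dynamic range `L` (defaults 0.01, 0.03).
#' @param max_convention how PSNR's MAX (and SSIM's L) is chosen:
#'   `"peak"` (peak/range of the reference image, default) or `"fixed"`
#'   (use `fixed_range`).
#' @param fixed_range dynamic range used when `max_convention = "fixed"`.
#' @param nrmse_percent keep the x100 factor of the normalized error
#'   (default TRUE); FALSE gives the unscaled ratio.
#' @return an object of class `metric_config`.
#' @export
metric_config <- function(ssim_window = 11L, ssim_sigma = 1.5,
                          k1 = 0.01, k2 = 0.03,
                          max_convention = c("peak", "fixed"),
                          fixed_range = 1, nrmse_percent = TRUE) {
  ssim_window <- check_count(ssim_window, "ssim_window", min = 3L)
  if (ssim_window %% 2L == 0L) stopf("'ssim_window' must be odd")
  check_scalar(ssim_sigma, "ssim_sigma")
  if (ssim_sigma < 0) stopf("'ssim_sigma' must be >= 0")
  check_scalar(k1, "k1"); check_scalar(k2, "k2")
  if (k1 <= 0 || k2 <= 0) stopf("'k1' and 'k2' must be > 0")
  max_convention <- match.arg(max_convention)
  check_scalar(fixed_range, "fixed_range")
  check_flag(nrmse_percent, "nrmse_percent")
  structure(list(ssim_window = ssim_window, ssim_sigma = ssim_sigma,
                 k1 = k1, k2 = k2, max_convention = max_convention,
                 fixed_range = fixed_range, nrmse_percent = nrmse_percent),
            class = "metric_config")
}

metric_input <- function(x, y, what) {
  x <- slice_pixels(x); y <- slice_pixels(y)
  if (!identical(dim(x), dim(y)))
    stopf("%s: images must have identical dimensions", what)
  list(x = x, y = y)
}

#' Normalized root-mean-square error
#'
#' `sqrt(sum((x - y)^2) / sum(y^2)) * 100` (the factor 100 can be disabled
#' in the [metric_config()]).
#'
#' @param x estimated slice ([image_slice()] or matrix).
#' @param y reference slice, same dimensions, not all zero.
#' @param cfg a [metric_config()].
#' @return nonnegative scalar; 0 iff `x == y`.
#' @export
nrmse <- function(x, y, cfg = metric_config()) {
  z <- metric_input(x, y, "nrmse")
  ss_y <- sum(z$y^2)
  if (ss_y == 0) stopf("nrmse undefined for an all-zero reference")
  out <- sqrt(sum((z$x - z$y)^2) / ss_y)
  if (cfg$nrmse_percent) out * 100 else out
}

#' Peak signal-to-noise ratio in dB
#'
#' `20 * log10(MAX / sqrt(MSE))` where MAX is the peak intensity of the
#' reference image (default convention) and MSE the mean squared error.
#' Identical images give `Inf` (flagged in [evaluate_pairs()] reports).
#'
#' @inheritParams nrmse
#' @return scalar in dB; `Inf` when `x == y`.
#' @export
psnr <- function(x, y, cfg = metric_config()) {
  z <- metric_input(x, y, "psnr")
  mse <- mean((z$x - z$y)^2)
  mx <- if (cfg$max_convention == "peak") max(z$y) else cfg$fixed_range
  if (mx <= 0) stopf("psnr requires a positive peak intensity")
  if (mse == 0) return(Inf)
  20 * log10(mx / sqrt(mse))
}

ssim_kernel <- function(w, sigma) {
  if (sigma > 0) {
    r <- (w - 1L) / 2
    k <- exp(-((-r:r)^2) / (2 * sigma^2))
    k / sum(k)
  } else rep(1 / w, w)
}

# Separable valid-mode correlation of an H x W image with a 1D kernel applied
# along rows then columns.
filter_valid <- function(img, k) {
  w <- length(k)
  H <- nrow(img); W <- ncol(img)
  tmp <- matrix(0, H - w + 1L, W)
  for (i in seq_len(w))
    tmp <- tmp + k[i] * img[i:(H - w + i), , drop = FALSE]
  out <- matrix(0, H - w + 1L, W - w + 1L)
  for (i in seq_len(w))
    out <- out + k[i] * tmp[, i:(W - w + i), drop = FALSE]
  out
}

#' Structural similarity index
#'
#' Local means, variances and covariance are computed on the window centred
#' at each pixel (Gaussian-weighted by default), the local similarity map is
#' formed, and its mean over all valid window centres is returned. The
#' dynamic range is `max(y) - min(y)` (or the configured fixed range).
#'
#' @inheritParams nrmse
#' @return scalar in (-1, 1]; exactly 1 iff the two images are the same.
#' @export
ssim <- function(x, y, cfg = metric_config()) {
  z <- metric_input(x, y, "ssim")
  w <- cfg$ssim_window
  if (nrow(z$x) < w || ncol(z$x) < w)
    stopf("image (%dx%d) smaller than the %dx%d SSIM window",
          nrow(z$x), ncol(z$x), w, w)
  L <- if (cfg$max_convention == "fixed") cfg$fixed_range
       else diff(range(z$y))
  if (L <= 0) L <- max(abs(z$y), 1e-12)   # constant reference fallback
  c1 <- (cfg$k1 * L)^2
  c2 <- (cfg$k2 * L)^2
  k <- ssim_kernel(w, cfg$ssim_sigma)
  mu_x <- filter_valid(z$x, k)
  mu_y <- filter_valid(z$y, k)
  xx <- filter_valid(z$x * z$x, k) - mu_x^2
  yy <- filter_valid(z$y * z$y, k) - mu_y^2
  xy <- filter_valid(z$x * z$y, k) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + c1) * (2 * xy + c2)
  den <- (mu_x^2 + mu_y^2 + c1) * (xx + yy + c2)
  mean(num / den)
}

#' Evaluate metrics over aligned slice sequences
#'
#' @param estimates,references equal-length lists of slices (or matrices).
#' @param cfg a [metric_config()].
#' @return an object of class `metric_report`: per-slice data frame plus
#'   mean and standard deviation per metric (`Inf` PSNR entries are flagged
#'   and excluded from the PSNR mean/sd).
#' @export
evaluate_pairs <- function(estimates, references, cfg = metric_config()) {
  if (length(estimates) != length(references))
    stopf("estimates (%d) and references (%d) differ in length",
          length(estimates), length(references))
  if (!length(estimates)) stopf("no slices to evaluate")
  per <- data.frame(
    slice = seq_along(estimates),
    nrmse = mapply(function(a, b) nrmse(a, b, cfg), estimates, references),
    psnr_db = mapply(function(a, b) psnr(a, b, cfg), estimates, references),
    ssim = mapply(function(a, b) ssim(a, b, cfg), estimates, references))
  fin <- is.finite(per$psnr_db)
  summary <- data.frame(
    metric = c("nrmse", "psnr_db", "ssim"),
    mean = c(mean(per$nrmse), if (any(fin)) mean(per$psnr_db[fin]) else Inf,
             mean(per$ssim)),
    sd = c(stats::sd(per$nrmse),
           if (sum(fin) > 1) stats::sd(per$psnr_db[fin]) else NA_real_,
           stats::sd(per$ssim)))
  structure(list(per_slice = per, summary = summary,
                 n_infinite_psnr = sum(!fin), cfg = cfg),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("metric_report over %d slices\n", nrow(x$per_slice)))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s %8.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  if (x$n_infinite_psnr > 0)
    cat(sprintf("  (%d identical pair(s) with infinite PSNR excluded from the PSNR mean)\n",
                x$n_infinite_psnr))
  invisible(x)
}

#' Write a metric report as CSV (one row per slice plus a summary row)
#'
#' @param report a [evaluate_pairs()] result.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_metric_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  per <- report$per_slice
  per$slice <- as.character(per$slice)
  s <- report$summary
  per <- rbind(per,
               data.frame(slice = "mean", nrmse = s$mean[1],
                          psnr_db = s$mean[2], ssim = s$mean[3]),
               data.frame(slice = "sd", nrmse = s$sd[1],
                          psnr_db = s$sd[2], ssim = s$sd[3]))
  utils::write.csv(per, path, row.names = FALSE)
  invisible(path)
}
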