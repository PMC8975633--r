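test_that("nrmse matches its closed forms and the loop oracle", {
  y1 <- matrix(1, 6, 7)
  expect_equal(nrmse(y1, y1), 0)
  expect_equal(nrmse(y1 + 0.1, y1), 10, tolerance = 1e-12)
  set.seed(1)
  for (i in 1:5) {
    x <- matrix(runif(64, 0, 3), 8); y <- matrix(runif(64, 0.1, 3), 8)
    expect_equal(nrmse(x, y), oracle_nrmse(x, y), tolerance = 1e-10)
  }
  # the x100 factor can be disabled
  cfg <- metric_config(nrmse_percent = FALSE)
  expect_equal(nrmse(y1 + 0.1, y1, cfg), 0.1, tolerance = 1e-12)
  expect_error(nrmse(y1, 0 * y1), "all-zero")
})

test_that("psnr follows the peak-of-reference convention", {
  y <- matrix(0.5, 16, 16); y[1, 1] <- 1        # peak 1
  x <- y + 0.1
  expect_equal(psnr(x, y), 20, tolerance = 1e-12)   # 20*log10(1/0.1)
  # doubling both images leaves psnr unchanged under the peak convention
  expect_equal(psnr(2 * x, 2 * y), psnr(x, y), tolerance = 1e-12)
  # strictly decreasing in mse at fixed peak
  expect_gt(psnr(y + 0.05, y), psnr(y + 0.2, y))
  expect_identical(psnr(y, y), Inf)
  set.seed(2)
  for (i in 1:5) {
    a <- matrix(runif(64, 0, 2), 8); b <- matrix(runif(64, 0.1, 2), 8)
    expect_equal(psnr(a, b), oracle_psnr(a, b), tolerance = 1e-10)
  }
})

test_that("ssim is 1 on identical images and matches the windowed loop oracle", {
  set.seed(3)
  for (i in 1:5) {
    x <- matrix(runif(256, 0, 2), 16)
    expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  }
  cfg_fixed <- metric_config(max_convention = "fixed", fixed_range = 2)
  for (i in 1:5) {
    x <- matrix(runif(256, 0, 2), 16); y <- matrix(runif(256, 0, 2), 16)
    expect_equal(ssim(x, y), oracle_ssim(x, y), tolerance = 1e-8)
    # symmetric once the dynamic range is fixed (the default takes L from
    # the reference image, which breaks exact symmetry)
    expect_equal(ssim(x, y, cfg_fixed), ssim(y, x, cfg_fixed),
                 tolerance = 1e-12)
    expect_lte(ssim(x, y), 1)
  }
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
  # smaller windows work on small images
  cfg5 <- metric_config(ssim_window = 5L)
  x <- matrix(runif(64), 8)
  expect_equal(ssim(x, x, cfg5), 1, tolerance = 1e-12)
})

test_that("constant images reduce ssim to the luminance term", {
  cfg <- metric_config(ssim_window = 5L)
  x <- matrix(2, 8, 8); y <- matrix(2.5, 8, 8)
  L <- max(abs(y))                        # constant-reference fallback range
  c1 <- (cfg$k1 * L)^2
  expect_equal(ssim(x, y, cfg), (2 * 2 * 2.5 + c1) / (2^2 + 2.5^2 + c1),
               tolerance = 1e-12)
})

test_that("evaluate_pairs aggregates per-slice metrics with mean and sd", {
  set.seed(4)
  refs <- lapply(1:6, function(i) matrix(runif(256, 0, 2), 16))
  ests <- lapply(refs, function(r) r + rnorm(256, 0, 0.1))
  rep <- evaluate_pairs(ests, refs)
  expect_equal(nrow(rep$per_slice), 6L)
  expect_equal(rep$summary$mean[1], mean(rep$per_slice$nrmse))
  expect_equal(rep$summary$sd[3], sd(rep$per_slice$ssim))
  # loop recomputation of the means
  m_ssim <- mean(vapply(1:6, function(i) ssim(ests[[i]], refs[[i]]), 1))
  expect_equal(rep$summary$mean[3], m_ssim, tolerance = 1e-12)
  # identical single pair: nrmse 0, infinite psnr flagged, ssim 1
  rep1 <- evaluate_pairs(refs[1], refs[1])
  expect_equal(rep1$per_slice$nrmse, 0)
  expect_identical(rep1$per_slice$psnr_db, Inf)
  expect_equal(rep1$per_slice$ssim, 1, tolerance = 1e-12)
  expect_equal(rep1$n_infinite_psnr, 1L)
  expect_error(evaluate_pairs(ests, refs[1:3]), "differ in length")
  # CSV round trip keeps one row per slice plus mean and sd rows
  path <- tempfile(fileext = ".csv")
  write_metric_report(rep, path)
  csv <- read.csv(path)
  expect_equal(nrow(csv), 8L)
  expect_equal(csv$slice[7:8], c("mean", "sd"))
})
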