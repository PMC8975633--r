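test_that("phantom and degradation specs validate their fields by name", {
  expect_error(phantom_spec(n_organs = 0), "n_organs")
  expect_error(phantom_spec(grid_size = 8), "grid_size")
  expect_error(phantom_spec(activity_range = c(2, 1)), "activity_range")
  expect_error(phantom_spec(lesion_contrast = 1), "lesion_contrast")
  expect_error(phantom_spec(background_activity = -1), "background_activity")
  expect_error(degradation_spec(sensitivity = 0), "sensitivity")
  expect_error(degradation_spec(sensitivity = 1.2), "sensitivity")
  expect_error(degradation_spec(psf_sigma_lq = -1), "psf_sigma_lq")
  expect_error(degradation_spec(count_scale = 0), "count_scale")
  expect_error(degradation_spec(gauss_sigma = -0.1), "gauss_sigma")
})

test_that("phantom generation is seeded-deterministic and nonnegative", {
  spec <- phantom_spec(grid_size = 32L, n_organs = 3L,
                       background_activity = 0.1, seed = 7L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$pixels, b$pixels)
  expect_true(all(a$pixels >= 0))
  expect_equal(dim(a$pixels), c(32L, 32L))
  # lesions exceed the contrast-scaled background somewhere
  expect_gte(max(a$pixels), spec$lesion_contrast * spec$background_activity)
  # different seed gives a different phantom
  spec2 <- spec; spec2$seed <- 8L
  expect_false(identical(generate_phantom(spec2)$pixels, a$pixels))
})

test_that("degradation approaches the identity in the noise-free limit", {
  hq <- generate_phantom(phantom_spec(grid_size = 32L, seed = 1L))
  d0 <- degradation_spec(sensitivity = 1, psf_sigma_lq = 0,
                         count_scale = 1e8, gauss_sigma = 0, seed = 5L)
  lq <- degrade(hq, d0)
  expect_equal(dim(lq$pixels), dim(hq$pixels))
  rel <- sqrt(mean((lq$pixels - hq$pixels)^2)) / mean(hq$pixels)
  expect_lt(rel, 5e-3)
  # and a smaller count budget is visibly noisier
  d1 <- degradation_spec(sensitivity = 1, psf_sigma_lq = 0,
                         count_scale = 10, gauss_sigma = 0, seed = 5L)
  expect_gt(mean((degrade(hq, d1)$pixels - hq$pixels)^2),
            10 * mean((lq$pixels - hq$pixels)^2))
  expect_error(degrade(matrix(c(-1, 1, 1, 1), 2), d0), "nonnegative")
})

test_that("degradation error grows monotonically as sensitivity drops", {
  hq <- generate_phantom(phantom_spec(grid_size = 32L, seed = 2L))
  mse_at <- function(s) mean(sapply(1:20, function(i) {
    d <- degradation_spec(sensitivity = s, seed = i)
    mean((degrade(hq, d)$pixels - hq$pixels)^2)
  }))
  m <- vapply(c(1.0, 0.3, 0.1), mse_at, 1)
  expect_lt(m[1], m[2])
  expect_lt(m[2], m[3])
})

test_that("datasets split 9:1, are reproducible and pixel-aligned", {
  spec <- phantom_spec(grid_size = 32L, seed = 3L)
  d <- degradation_spec(sensitivity = 0.5, seed = 4L)
  ds <- make_dataset(spec, d, 100L, split_seed = 9L)
  expect_length(ds$train, 90L)
  expect_length(ds$test, 10L)
  ds_min <- make_dataset(spec, d, 10L, split_seed = 9L)
  expect_length(ds_min$train, 9L)
  expect_length(ds_min$test, 1L)
  expect_error(make_dataset(spec, d, 9L), "n_pairs")
  # identical split seed -> identical membership and content
  ds2 <- make_dataset(spec, d, 100L, split_seed = 9L)
  expect_identical(ds$test_idx, ds2$test_idx)
  expect_identical(ds$train[[5]]$lq$pixels, ds2$train[[5]]$lq$pixels)
  # different split seed moves membership
  ds3 <- make_dataset(spec, d, 100L, split_seed = 10L)
  expect_false(identical(ds$test_idx, ds3$test_idx))
  # alignment: each pair's LQ regenerates from its own HQ
  k <- ds$test_idx[1]
  spec_k <- spec; spec_k$seed <- petcycle:::derive_seed(spec$seed, k)
  d_k <- d; d_k$seed <- petcycle:::derive_seed(d$seed, k, 7L)
  hq_k <- generate_phantom(spec_k)
  expect_identical(ds$test[[1]]$hq$pixels, hq_k$pixels)
  expect_identical(ds$test[[1]]$lq$pixels, degrade(hq_k, d_k)$pixels)
})

test_that("paired datasets round-trip through NIfTI volumes plus manifest", {
  ds <- tiny_dataset(n_pairs = 10L, seed = 5L)
  dir <- tempfile()
  write_paired_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "lq.nii.gz")))
  back <- read_paired_dataset(dir)
  expect_length(back$train, length(ds$train))
  expect_length(back$test, length(ds$test))
  expect_equal(back$train[[2]]$hq$pixels, ds$train[[2]]$hq$pixels,
               tolerance = 1e-12)
  expect_equal(back$test[[1]]$lq$pixels, ds$test[[1]]$lq$pixels,
               tolerance = 1e-12)
})
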