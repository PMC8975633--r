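test_that("learning rate is constant then decays linearly to zero", {
  cfg <- train_config()                      # 200 epochs, constant for 100
  expect_equal(lr_schedule(0, cfg), 2e-4)
  expect_equal(lr_schedule(99, cfg), 2e-4)
  expect_equal(lr_schedule(150, cfg), 1e-4)  # midpoint of the decay
  expect_equal(lr_schedule(199, cfg), 2e-6)  # one linear step above zero
  lrs <- vapply(0:199, lr_schedule, 1, cfg = cfg)
  expect_true(all(diff(lrs) <= 0))
  # epochs 0-99 constant; epoch 100 is the anchor of the decay line
  expect_equal(sum(lrs == 2e-4), 101L)
  expect_true(all(lrs[1:100] == 2e-4))
  expect_error(lr_schedule(200, cfg), "out of range")
  expect_error(lr_schedule(-1, cfg), "epoch")
  expect_error(train_config(lr_constant_epochs = 200), "lr_constant_epochs")
  expect_error(train_config(epochs = 1), "epochs")
})

test_that("a short run keeps books correctly and leaves the data untouched", {
  ds <- tiny_dataset(n_pairs = 10L, seed = 31L)
  norm <- lapply(ds$train[1:8], function(p) normalize_pair(p)$pair)
  before <- lapply(norm, function(p) p$lq$pixels)
  cfg <- train_config(epochs = 2L, batch_size = 4L, seed = 5L)
  m <- train_cycleagan(norm, cfg, loss_weights(),
                       small_gen_cfg(base = 4L, blocks = 1L),
                       small_disc_cfg(base = 4L))
  expect_s3_class(m, "petcycle_model")
  expect_equal(nrow(m$history), 2L * ceiling(8 / 4))
  expect_true(all(is.finite(m$history$total)))
  expect_identical(lapply(norm, function(p) p$lq$pixels), before)
  # the loss identity holds at every logged step
  with(m$history, expect_equal(total, adv + 10 * cyc + 0.5 * id + 0.5 * sup,
                               tolerance = 1e-12))
  expect_error(train_cycleagan(list(), cfg), "empty")
})

test_that("identical seeds reproduce the loss history bit for bit", {
  ds <- tiny_dataset(n_pairs = 10L, seed = 32L)
  norm <- lapply(ds$train[1:6], function(p) normalize_pair(p)$pair)
  cfg <- train_config(epochs = 2L, batch_size = 3L, seed = 42L)
  m1 <- train_cycleagan(norm, cfg, loss_weights(),
                        small_gen_cfg(base = 4L, blocks = 1L),
                        small_disc_cfg(base = 4L))
  m2 <- train_cycleagan(norm, cfg, loss_weights(),
                        small_gen_cfg(base = 4L, blocks = 1L),
                        small_disc_cfg(base = 4L))
  expect_identical(m1$history, m2$history)
  # and a different seed diverges
  cfg2 <- train_config(epochs = 2L, batch_size = 3L, seed = 43L)
  m3 <- train_cycleagan(norm, cfg2, loss_weights(),
                        small_gen_cfg(base = 4L, blocks = 1L),
                        small_disc_cfg(base = 4L))
  expect_false(identical(m1$history$total, m3$history$total))
})

test_that("training requires normalized input", {
  ds <- tiny_dataset(n_pairs = 10L, seed = 33L)
  cfg <- train_config(epochs = 2L, batch_size = 4L, seed = 1L)
  expect_error(train_cycleagan(ds$train, cfg), "normalized")
})

test_that("inference is slice-wise, deterministic and shape-preserving", {
  ds <- tiny_dataset(n_pairs = 10L, seed = 34L)
  norm <- lapply(ds$train[1:6], function(p) normalize_pair(p)$pair)
  cfg <- train_config(epochs = 2L, batch_size = 3L, seed = 2L)
  m <- train_cycleagan(norm, cfg, loss_weights(),
                       small_gen_cfg(base = 4L, blocks = 1L),
                       small_disc_cfg(base = 4L))
  lq_slices <- lapply(ds$test, function(p) p$lq)
  est1 <- infer(m, lq_slices)
  est2 <- infer(m, lq_slices)
  expect_length(est1, length(lq_slices))
  expect_equal(dim(est1[[1]]$pixels), dim(lq_slices[[1]]$pixels))
  expect_identical(lapply(est1, function(s) s$pixels),
                   lapply(est2, function(s) s$pixels))
  # a zero-weight generator emits tanh(0) = 0, denormalized to the midpoint
  zero_all_params(m$g_ab)
  vmin <- 1; vmax <- 3
  est0 <- infer(m, lq_slices, vmin = vmin, vmax = vmax)
  expect_true(all(est0[[1]]$pixels == (vmin + vmax) / 2))
})

test_that("checkpoints restore a model that infers identically", {
  ds <- tiny_dataset(n_pairs = 10L, seed = 35L)
  norm <- lapply(ds$train[1:6], function(p) normalize_pair(p)$pair)
  cfg <- train_config(epochs = 2L, batch_size = 3L, seed = 3L)
  m <- train_cycleagan(norm, cfg, loss_weights(),
                       small_gen_cfg(base = 4L, blocks = 1L),
                       small_disc_cfg(base = 4L))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  lq <- lapply(ds$test, function(p) p$lq)
  expect_identical(lapply(infer(m, lq), function(s) s$pixels),
                   lapply(infer(m2, lq), function(s) s$pixels))
  expect_identical(m2$epoch, m$epoch)
  # volume-level round trip through files
  vol_in <- tempfile(fileext = ".nii.gz")
  vol_out <- tempfile(fileext = ".nii.gz")
  write_volume(lq, vol_in)
  infer_volume(path, vol_in, vol_out)
  est_files <- read_volume(vol_out)
  expect_length(est_files, length(lq))
  # a checkpoint cannot restore into a mismatched architecture
  ck <- readRDS(path)
  ck$gen_cfg <- small_gen_cfg(base = 8L, blocks = 1L)
  path2 <- tempfile(fileext = ".rds")
  saveRDS(ck, path2)
  expect_error(load_checkpoint(path2), "incompatible")
})
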