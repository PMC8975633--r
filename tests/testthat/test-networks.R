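test_that("generator structure matches the stated architecture", {
  g <- build_generator(generator_config(), seed = 1)
  audit <- network_audit(g)
  expect_equal(audit$n_conv_outside_blocks, 6L)
  expect_equal(audit$n_cbam, 2L)
  expect_equal(audit$n_res_blocks, 9L)
  expect_equal(audit$first_kernel, 7L)
  expect_equal(audit$first_out_channels, 64L)
  expect_equal(audit$output_activation, "tanh")
  # parameter count pinned for regression
  expect_equal(audit$n_parameters, 11377359L)
  expect_equal(count_parameters(g), 11377359L)
})

test_that("generator preserves shape and bounds its output by tanh", {
  g <- build_generator(small_gen_cfg(), seed = 2)
  set.seed(3)
  x <- matrix(runif(64 * 64, -1, 1), 64)
  y <- generator_forward(g, x)
  expect_equal(dim(y), c(64L, 64L))
  expect_true(all(y > -1 & y < 1))
  expect_true(all(is.finite(y)))
  # batch form
  xb <- array(runif(2 * 32 * 32, -1, 1), c(1L, 32L, 32L, 2L))
  yb <- generator_forward(g, xb)
  expect_equal(dim(yb), dim(xb))
  # divisibility contract: no silent padding
  expect_error(generator_forward(g, matrix(0, 30, 30)), "divisible by 4")
})

test_that("zero-weight generator maps everything to tanh(0) = 0", {
  g <- build_generator(small_gen_cfg(base = 4L, blocks = 1L), seed = 4)
  zero_all_params(g)
  set.seed(5)
  y <- generator_forward(g, matrix(runif(32 * 32, -1, 1), 32), mode = "train")
  expect_true(all(y == 0))
})

test_that("discriminator follows the C4S2/C4S1 ladder with slope-0.2 activations", {
  cfg <- discriminator_config()
  d <- build_discriminator(cfg, seed = 5)
  audit <- network_audit(d)
  expect_equal(audit$channel_trace, c(1L, 64L, 128L, 256L, 512L, 1L))
  expect_equal(audit$strides, c(2L, 2L, 2L, 1L, 1L))
  expect_equal(audit$kernel, 4L)
  expect_equal(audit$leaky_slope, 0.2)
  expect_false(audit$has_bn_first_stage)
  # the activation itself: -1 -> -0.2
  act <- petcycle:::new_act("lrelu", 0.2)
  out <- petcycle:::act_forward(act, array(c(-1, 2), c(1, 2, 1, 1)))$y
  expect_equal(as.vector(out), c(-0.2, 2))
  expect_error(discriminator_config(channel_ladder = c(64, 32, 128, 256)),
               "increasing")
})

test_that("score-map size matches an independent shape-trace oracle", {
  d <- build_discriminator(discriminator_config(), seed = 6)
  stages <- list(c(4L, 2L, 1L), c(4L, 2L, 1L), c(4L, 2L, 1L),
                 c(4L, 1L, 1L), c(4L, 1L, 1L))
  for (sz in c(32L, 70L, 150L)) {
    expect_equal(discriminator_trace(d, sz, sz),
                 rep(oracle_conv_trace(sz, stages), 2L))
  }
  set.seed(7)
  sm <- discriminator_forward(build_discriminator(small_disc_cfg(), seed = 1),
                              matrix(runif(70 * 70, -1, 1), 70))
  expect_equal(dim(sm)[2:3], rep(oracle_conv_trace(70L, stages), 2L))
  expect_true(all(is.finite(sm)))
  # raw scores: unbounded sign allowed (no squashing)
  expect_error(discriminator_forward(build_discriminator(small_disc_cfg(), seed = 1),
                                     matrix(0, 8, 8)), "too small")
})

test_that("count_parameters is exact on analytic cases", {
  conv <- petcycle:::new_conv(1L, 1L, 3L)       # 9 weights + 1 bias
  expect_equal(count_parameters(list(conv)), 10L)
  empty <- petcycle:::new_act("relu")
  expect_equal(count_parameters(list(empty)), 0L)
  bn <- petcycle:::new_bn(7L)                   # gamma + beta
  expect_equal(count_parameters(list(bn)), 14L)
})
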