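test_that("L1 losses obey identity, offset and additivity relations", {
  set.seed(1)
  a <- array(rnorm(2 * 8 * 8 * 3), c(2, 8, 8, 3))
  b <- array(rnorm(2 * 8 * 8 * 3), c(2, 8, 8, 3))
  expect_equal(cycle_loss(a, a, b, b), 0)
  expect_equal(cycle_loss(a, a + 0.1, b, b), 0.1)
  expect_equal(cycle_loss(a, a + 0.05, b, b - 0.05), 0.1)
  expect_equal(identity_loss(a, a, b, b), 0)
  expect_equal(identity_loss(a, a + 0.3, b, b), 0.3)
  expect_equal(supervised_loss(b, b, a, a), 0)
  expect_equal(supervised_loss(b + 0.2, b, a, a), 0.2)
  # the three losses share one L1 kernel: same tensors, same value
  expect_equal(cycle_loss(a, b, b, a), identity_loss(a, b, b, a))
  expect_error(cycle_loss(a, a[, 1:4, , , drop = FALSE], b, b), "mismatch")
})

test_that("supervised loss equals the explicit loop oracle", {
  set.seed(2)
  for (i in 1:3) {
    ga <- array(rnorm(48), c(1, 4, 4, 3)); xb <- array(rnorm(48), c(1, 4, 4, 3))
    gb <- array(rnorm(48), c(1, 4, 4, 3)); xa <- array(rnorm(48), c(1, 4, 4, 3))
    expect_equal(supervised_loss(ga, xb, gb, xa),
                 oracle_supervised(ga, xb, gb, xa), tolerance = 1e-10)
  }
})

test_that("the total objective recomposes exactly from its components", {
  w <- loss_weights()                 # 10, 0.5, 0.5
  bd <- total_loss(list(adv = 1, cyc = 1, id = 1, sup = 1), w)
  expect_identical(bd$total, 12)
  expect_equal(total_loss(list(adv = 0, cyc = 0, id = 0, sup = 0), w)$total, 0)
  w0 <- loss_weights(0, 0, 0, 0)
  expect_equal(total_loss(list(adv = 0.7, cyc = 3, id = 4, sup = 5), w0)$total, 0.7)
  set.seed(3)
  for (i in 1:10) {
    comp <- as.list(setNames(runif(4, 0, 5), c("adv", "cyc", "id", "sup")))
    bd <- total_loss(comp, w)
    expect_identical(bd$total,
                     comp$adv + 10 * comp$cyc + 0.5 * comp$id + 0.5 * comp$sup)
  }
  expect_error(total_loss(list(adv = NaN, cyc = 0, id = 0, sup = 0), w), "adv")
  expect_error(total_loss(list(adv = 0, cyc = Inf, id = 0, sup = 0), w), "cyc")
  expect_error(loss_weights(lambda_c = -1), "lambda_c")
})

test_that("gradient penalty is lambda for a constant critic, 0 for a unit-norm linear critic", {
  set.seed(4)
  real <- array(runif(32), c(1, 4, 8, 1))
  fake <- array(runif(32), c(1, 4, 8, 1))
  const <- linear_critic(array(0, c(1, 4, 8)), b = 3.2)
  w <- loss_weights(lambda_gp = 10)
  out <- adversarial_loss(const, real, fake, w, seed = 1)
  expect_equal(out$penalty, 1)                      # (||0|| - 1)^2
  expect_equal(out$critic_loss, 10)                 # -c + c + lambda * 1
  expect_equal(out$generator_term, -3.2)
  wvec <- array(rnorm(32), c(1, 4, 8))
  unit <- linear_critic(wvec / sqrt(sum(wvec^2)))
  expect_equal(gradient_penalty(unit, real, fake, seed = 2)$penalty, 0,
               tolerance = 1e-14)
  # adding a constant to the critic leaves the penalty unchanged
  shifted <- linear_critic(unit$w, b = 57)
  expect_equal(gradient_penalty(shifted, real, fake, seed = 2)$penalty, 0,
               tolerance = 1e-14)
  expect_error(adversarial_loss(const, real, fake[, , 1:4, , drop = FALSE], w),
               "mismatch")
})

test_that("critic input gradients match finite differences at the interpolates", {
  d <- build_discriminator(small_disc_cfg(base = 4L), seed = 8)
  set.seed(9)
  real <- array(runif(2 * 32 * 32, -1, 1), c(1, 32, 32, 2))
  fake <- array(runif(2 * 32 * 32, -1, 1), c(1, 32, 32, 2))
  gp <- gradient_penalty(d, real, fake, seed = 3)
  y <- gp$y
  fw <- petcycle:::critic_frozen_forward(d, y)
  # finite-difference recomputation of the per-sample gradient at 60 random
  # pixels, replaying the frozen normalisation statistics
  score_sum <- function(x) {
    s <- petcycle:::critic_frozen_forward(d, x, stats = fw$stats)$score_map
    m <- s; dim(m) <- c(length(s) / dim(s)[4], dim(s)[4])
    sum(colMeans(m))
  }
  eps <- 1e-5
  idx <- sample(length(y), 60)
  for (i in idx) {
    yp <- y; yp[i] <- yp[i] + eps
    ym <- y; ym[i] <- ym[i] - eps
    fd <- (score_sum(yp) - score_sum(ym)) / (2 * eps)
    expect_equal(fd, gp$g[i], tolerance = 1e-4)
  }
  # the norm itself then matches to the same tolerance
  norms_fd <- gp$norms
  expect_equal(mean((norms_fd - 1)^2), gp$penalty, tolerance = 1e-12)
})

test_that("penalty parameter-gradients match finite differences of the frozen objective", {
  d <- build_discriminator(small_disc_cfg(base = 4L), seed = 10)
  set.seed(11)
  y <- array(runif(2 * 32 * 32, -1, 1), c(1, 32, 32, 2))
  petcycle:::zero_grads(d)
  pen <- petcycle:::critic_penalty_with_grads(d, y, scale = 1)
  fw <- petcycle:::critic_frozen_forward(d, y)
  pen_at <- function(layer, nm, i, v) {
    old <- layer$params[[nm]][i]
    layer$params[[nm]][i] <- v
    f <- petcycle:::critic_frozen_forward(d, y, stats = fw$stats)
    g <- petcycle:::net_backward(d, f$tape,
                                 petcycle:::per_sample_mean_seed(f$score_map),
                                 accumulate = FALSE)
    r <- petcycle:::per_sample_norms(g)
    layer$params[[nm]][i] <- old
    mean((r - 1)^2)
  }
  eps <- 1e-7
  checked <- 0
  for (li in c(1, 3, 4)) {
    l <- d$layers[[li]]
    for (nm in names(l$params)) {
      i <- ((li * 7L) %% length(l$params[[nm]])) + 1L
      fd <- (pen_at(l, nm, i, l$params[[nm]][i] + eps) -
             pen_at(l, nm, i, l$params[[nm]][i] - eps)) / (2 * eps)
      expect_equal(fd, l$grads[[nm]][i], tolerance = 1e-3)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 4)
  expect_gte(pen, 0)
})
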