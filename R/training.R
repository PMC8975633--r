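# Optimization loop: alternating critic / generator updates with Adam, a
# constant-then-linear learning-rate schedule, per-iteration loss logging,
# checkpointing and slice-by-slice inference.

#' Training configuration
#'
#' @param epochs total training epochs (default 200, >= 2).
#' @param batch_size pairs per iteration (default 32).
#' @param lr_initial initial learning rate (default 2e-4).
#' @param lr_constant_epochs epochs at the constant rate before the linear
#'   decay to zero (default `epochs / 2`).
#' @param adam_beta1,adam_beta2 Adam moment coefficients (defaults 0.5 and
#'   0.999).
#' @param n_critic critic updates per generator update (default 1, i.e.
#'   strict alternation).
#' @param seed master seed; weight initialisation, batch shuffling and the
#'   penalty interpolation draws are all derived from it.
#' @param checkpoint_every write a checkpoint every this many epochs
#'   (0 = only at the end when a directory is given).
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 32L, lr_initial = 2e-4,
                         lr_constant_epochs = NULL, adam_beta1 = 0.5,
                         adam_beta2 = 0.999, n_critic = 1L, seed = 1L,
                         checkpoint_every = 0L) {
  epochs <- check_count(epochs, "epochs", min = 2L)
  batch_size <- check_count(batch_size, "batch_size", min = 1L)
  check_scalar(lr_initial, "lr_initial")
  if (lr_initial <= 0) stopf("'lr_initial' must be > 0")
  if (is.null(lr_constant_epochs)) lr_constant_epochs <- epochs %/% 2L
  lr_constant_epochs <- check_count(lr_constant_epochs, "lr_constant_epochs")
  if (lr_constant_epochs <= 0L || lr_constant_epochs >= epochs)
    stopf("'lr_constant_epochs' must satisfy 0 < value < epochs")
  check_scalar(adam_beta1, "adam_beta1"); check_scalar(adam_beta2, "adam_beta2")
  n_critic <- check_count(n_critic, "n_critic", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  checkpoint_every <- check_count(checkpoint_every, "checkpoint_every", min = 0L)
  structure(list(epochs = epochs, batch_size = batch_size,
                 lr_initial = lr_initial,
                 lr_constant_epochs = lr_constant_epochs,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 n_critic = n_critic, seed = seed,
                 checkpoint_every = checkpoint_every),
            class = "train_config")
}

#' Two-phase learning-rate schedule
#'
#' Constant `lr_initial` for the first `lr_constant_epochs` epochs, then a
#' linear decay reaching 0 at the final epoch boundary.
#'
#' @param epoch 0-based epoch index in `[0, cfg$epochs)`.
#' @param cfg a [train_config()].
#' @return the learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  epoch <- check_count(epoch, "epoch", min = 0L)
  if (epoch >= cfg$epochs)
    stopf("'epoch' (%d) out of range [0, %d)", epoch, cfg$epochs)
  if (epoch < cfg$lr_constant_epochs) return(cfg$lr_initial)
  cfg$lr_initial * (cfg$epochs - epoch) / (cfg$epochs - cfg$lr_constant_epochs)
}

pairs_to_tensors <- function(pairs) {
  if (!length(pairs)) stopf("empty training set")
  mats_lq <- lapply(pairs, function(p) p$lq$pixels)
  mats_hq <- lapply(pairs, function(p) p$hq$pixels)
  d <- dim(mats_lq[[1]])
  if (!all(vapply(c(mats_lq, mats_hq), function(m) identical(dim(m), d), TRUE)))
    stopf("all training slices must share one size")
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stopf("slice size %dx%d not divisible by 4", d[1], d[2])
  n <- length(pairs)
  a <- array(unlist(mats_lq, use.names = FALSE), c(1L, d, n))
  b <- array(unlist(mats_hq, use.names = FALSE), c(1L, d, n))
  rng <- range(a, b)
  if (rng[1] < -1 - 1e-6 || rng[2] > 1 + 1e-6)
    stopf("training slices must be normalized to [-1, 1] (found range [%.3g, %.3g]); see normalize_pair()",
          rng[1], rng[2])
  list(a = a, b = b, n = n, d = d)
}

# unlist() flattens H*W*n column-major; each matrix becomes one (1,H,W) slab.

take_batch <- function(x, idx) x[, , , idx, drop = FALSE]

critic_update <- function(disc, opt, real, fake, weights, lr, eps_seed) {
  zero_grads(disc)
  fr <- net_forward(disc, real, "train")
  nr <- length(fr$y)
  net_backward(disc, fr$tape, array(-1 / nr, dim(fr$y)))
  ff <- net_forward(disc, fake, "train")
  net_backward(disc, ff$tape, array(1 / nr, dim(ff$y)))
  n <- dim(real)[4]
  eps <- with_seed(eps_seed, stats::runif(n))
  ef <- rep(eps, each = length(real) / n); dim(ef) <- dim(real)
  yhat <- ef * real + (1 - ef) * fake
  pen <- critic_penalty_with_grads(disc, yhat, scale = weights$lambda_gp)
  loss <- mean(ff$y) - mean(fr$y) + weights$lambda_gp * pen
  adam_step(opt, lr)
  loss
}

l1_grad <- function(x, target, weight) weight * sign(x - target) / length(x)

#' Train the cycle translation model
#'
#' Per iteration: sample a batch of pairs, update both critics on the
#' gradient-penalty critic loss (`n_critic` times), then update both
#' generators jointly on the total objective (adversarial + weighted cycle,
#' identity and supervised terms), logging the loss breakdown. The learning
#' rate follows [lr_schedule()]. Fully reproducible under `cfg$seed`.
#'
#' @param train_pairs list of [paired_sample()]s, all normalized to
#'   \[-1, 1\] (see [normalize_pair()]) and of one common size divisible
#'   by 4.
#' @param cfg a [train_config()].
#' @param weights a [loss_weights()].
#' @param gen_cfg a [generator_config()] shared by both generators.
#' @param disc_cfg a [discriminator_config()] shared by both critics.
#' @param checkpoint_dir optional directory for periodic checkpoints.
#' @param verbose print a line per epoch.
#' @return an object of class `petcycle_model`: both generators (`g_ab`,
#'   `g_ba`), both critics (`d_a`, `d_b`), the per-iteration `history`
#'   data frame and the configurations.
#' @export
train_cycleagan <- function(train_pairs, cfg = train_config(),
                            weights = loss_weights(),
                            gen_cfg = generator_config(),
                            disc_cfg = discriminator_config(),
                            checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"), inherits(weights, "loss_weights"))
  tens <- pairs_to_tensors(train_pairs)

  g_ab <- build_generator(gen_cfg, seed = derive_seed(cfg$seed, 1L))
  g_ba <- build_generator(gen_cfg, seed = derive_seed(cfg$seed, 2L))
  d_a <- build_discriminator(disc_cfg, seed = derive_seed(cfg$seed, 3L))
  d_b <- build_discriminator(disc_cfg, seed = derive_seed(cfg$seed, 4L))
  opt_gen <- new_adam(list(g_ab, g_ba), cfg$adam_beta1, cfg$adam_beta2)
  opt_da <- new_adam(d_a, cfg$adam_beta1, cfg$adam_beta2)
  opt_db <- new_adam(d_b, cfg$adam_beta1, cfg$adam_beta2)

  hist <- list()
  it_global <- 0L
  for (epoch in 0:(cfg$epochs - 1L)) {
    lr <- lr_schedule(epoch, cfg)
    order <- with_seed(derive_seed(cfg$seed, epoch, 3L), sample.int(tens$n))
    batches <- split(order, ceiling(seq_along(order) / cfg$batch_size))
    for (bi in seq_along(batches)) {
      it_global <- it_global + 1L
      idx <- batches[[bi]]
      a <- take_batch(tens$a, idx)
      b <- take_batch(tens$b, idx)

      loss_da <- loss_db <- NA_real_
      for (j in seq_len(cfg$n_critic)) {
        fake_b <- net_forward(g_ab, a, "train_noupdate")$y
        fake_a <- net_forward(g_ba, b, "train_noupdate")$y
        loss_db <- critic_update(d_b, opt_db, b, fake_b, weights, lr,
                                 derive_seed(cfg$seed, it_global, j, 11L))
        loss_da <- critic_update(d_a, opt_da, a, fake_a, weights, lr,
                                 derive_seed(cfg$seed, it_global, j, 13L))
      }

      zero_grads(g_ab); zero_grads(g_ba)
      f_b <- net_forward(g_ab, a, "train")       # G_AB(a)
      f_a <- net_forward(g_ba, b, "train")       # G_BA(b)
      c_a <- net_forward(g_ba, f_b$y, "train")   # G_BA(G_AB(a))
      c_b <- net_forward(g_ab, f_a$y, "train")   # G_AB(G_BA(b))
      i_a <- net_forward(g_ba, a, "train")       # G_BA(a)
      i_b <- net_forward(g_ab, b, "train")       # G_AB(b)

      s_b <- net_forward(d_b, f_b$y, "train_noupdate")
      s_a <- net_forward(d_a, f_a$y, "train_noupdate")
      adv <- 0.5 * (-mean(s_b$y) - mean(s_a$y))
      cyc <- cycle_loss(a, c_a$y, b, c_b$y)
      idl <- identity_loss(a, i_a$y, b, i_b$y)
      sup <- supervised_loss(f_b$y, b, f_a$y, a)
      breakdown <- tryCatch(
        total_loss(list(adv = adv, cyc = cyc, id = idl, sup = sup), weights),
        error = function(e) stopf("iteration %d (epoch %d): %s",
                                  it_global, epoch, conditionMessage(e)))
      if (!all(is.finite(c(loss_da, loss_db))))
        stopf("iteration %d (epoch %d): critic loss not finite", it_global, epoch)

      # cycle branches first: they add gradient into the primary translations
      d_fb <- net_backward(g_ba, c_a$tape,
                           l1_grad(c_a$y, a, weights$lambda_c))
      d_fa <- net_backward(g_ab, c_b$tape,
                           l1_grad(c_b$y, b, weights$lambda_c))
      d_fb <- d_fb + net_backward(d_b, s_b$tape,
                                  array(-0.5 / length(s_b$y), dim(s_b$y)),
                                  accumulate = FALSE)
      d_fa <- d_fa + net_backward(d_a, s_a$tape,
                                  array(-0.5 / length(s_a$y), dim(s_a$y)),
                                  accumulate = FALSE)
      d_fb <- d_fb + l1_grad(f_b$y, b, weights$lambda_s)
      d_fa <- d_fa + l1_grad(f_a$y, a, weights$lambda_s)
      net_backward(g_ab, f_b$tape, d_fb)
      net_backward(g_ba, f_a$tape, d_fa)
      net_backward(g_ba, i_a$tape, l1_grad(i_a$y, a, weights$lambda_i))
      net_backward(g_ab, i_b$tape, l1_grad(i_b$y, b, weights$lambda_i))
      adam_step(opt_gen, lr)

      hist[[it_global]] <- data.frame(
        epoch = epoch, iteration = it_global, lr = lr,
        critic_a = loss_da, critic_b = loss_db,
        adv = breakdown$adv, cyc = breakdown$cyc, id = breakdown$id,
        sup = breakdown$sup, total = breakdown$total)
    }
    if (verbose) {
      last <- hist[[it_global]]
      message(sprintf("epoch %3d  lr %.2e  total %.4f  (adv %.4f cyc %.4f id %.4f sup %.4f)",
                      epoch, lr, last$total, last$adv, last$cyc, last$id, last$sup))
    }
    if (!is.null(checkpoint_dir) && cfg$checkpoint_every > 0L &&
        (epoch + 1L) %% cfg$checkpoint_every == 0L) {
      model <- assemble_model(g_ab, g_ba, d_a, d_b, hist, cfg, weights,
                              gen_cfg, disc_cfg, epoch)
      save_checkpoint(model, file.path(checkpoint_dir,
                                       sprintf("checkpoint_epoch%03d.rds", epoch + 1L)),
                      optimizers = list(gen = opt_gen, d_a = opt_da, d_b = opt_db))
    }
  }
  model <- assemble_model(g_ab, g_ba, d_a, d_b, hist, cfg, weights,
                          gen_cfg, disc_cfg, cfg$epochs - 1L)
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(model, file.path(checkpoint_dir, "checkpoint_final.rds"),
                    optimizers = list(gen = opt_gen, d_a = opt_da, d_b = opt_db))
  }
  model
}

assemble_model <- function(g_ab, g_ba, d_a, d_b, hist, cfg, weights,
                           gen_cfg, disc_cfg, epoch) {
  structure(list(g_ab = g_ab, g_ba = g_ba, d_a = d_a, d_b = d_b,
                 history = do.call(rbind, hist), cfg = cfg, weights = weights,
                 gen_cfg = gen_cfg, disc_cfg = disc_cfg, epoch = epoch),
            class = "petcycle_model")
}

# ---- checkpointing ----------------------------------------------------------

net_state <- function(net) {
  lapply(flat_layers(net), function(l) {
    s <- list(params = l$params)
    if (l$type == "bn") {
      s$running_mean <- l$running_mean
      s$running_var <- l$running_var
    }
    s
  })
}

net_restore <- function(net, state) {
  ls <- flat_layers(net)
  if (length(ls) != length(state)) stopf("checkpoint incompatible with the configured architecture")
  for (i in seq_along(ls)) {
    if (!identical(lapply(ls[[i]]$params, dim), lapply(state[[i]]$params, dim)) ||
        !identical(lapply(ls[[i]]$params, length), lapply(state[[i]]$params, length)))
      stopf("checkpoint incompatible with the configured architecture (layer %d)", i)
    ls[[i]]$params <- state[[i]]$params
    if (ls[[i]]$type == "bn") {
      ls[[i]]$running_mean <- state[[i]]$running_mean
      ls[[i]]$running_var <- state[[i]]$running_var
    }
  }
  invisible(net)
}

#' Save a trained model (and optionally optimizer state) to a checkpoint file
#'
#' @param model a [train_cycleagan()] result.
#' @param path output `.rds` path.
#' @param optimizers optional list of optimizer states to store.
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(model, path, optimizers = NULL) {
  stopifnot(inherits(model, "petcycle_model"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  opt_states <- if (!is.null(optimizers))
    lapply(optimizers, function(o) list(state = o$state, t = o$t))
  saveRDS(list(gen_cfg = model$gen_cfg, disc_cfg = model$disc_cfg,
               cfg = model$cfg, weights = model$weights, epoch = model$epoch,
               history = model$history,
               states = list(g_ab = net_state(model$g_ab),
                             g_ba = net_state(model$g_ba),
                             d_a = net_state(model$d_a),
                             d_b = net_state(model$d_b)),
               optimizers = opt_states),
          path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint `.rds` path.
#' @return a `petcycle_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("checkpoint not found: %s", path)
  ck <- readRDS(path)
  g_ab <- build_generator(ck$gen_cfg); net_restore(g_ab, ck$states$g_ab)
  g_ba <- build_generator(ck$gen_cfg); net_restore(g_ba, ck$states$g_ba)
  d_a <- build_discriminator(ck$disc_cfg); net_restore(d_a, ck$states$d_a)
  d_b <- build_discriminator(ck$disc_cfg); net_restore(d_b, ck$states$d_b)
  structure(list(g_ab = g_ab, g_ba = g_ba, d_a = d_a, d_b = d_b,
                 history = ck$history, cfg = ck$cfg, weights = ck$weights,
                 gen_cfg = ck$gen_cfg, disc_cfg = ck$disc_cfg,
                 epoch = ck$epoch), class = "petcycle_model")
}

# ---- inference --------------------------------------------------------------

#' Translate a low-quality volume slice by slice
#'
#' Each slice is normalized to \[-1, 1\], passed through the trained
#' low-to-high generator in evaluation mode (batch norm uses stored running
#' statistics) and denormalized back to the physical scale. Deterministic.
#'
#' @param model a `petcycle_model` or a checkpoint path.
#' @param slices list of [image_slice()] (e.g. from [read_volume()]).
#' @param vmin,vmax normalization bounds; default the min/max over the input
#'   volume.
#' @return list of estimated high-quality [image_slice()], same length and
#'   dimensions as the input.
#' @export
infer <- function(model, slices, vmin = NULL, vmax = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  stopifnot(inherits(model, "petcycle_model"))
  if (!length(slices)) stopf("no slices to translate")
  slices <- lapply(slices, as_image_slice)
  allpx <- range(vapply(slices, function(s) range(s$pixels), numeric(2)))
  if (is.null(vmin)) vmin <- allpx[1]
  if (is.null(vmax)) vmax <- allpx[2]
  lapply(slices, function(s) {
    xn <- normalize(s, vmin, vmax)
    yn <- generator_forward(model$g_ab, xn$pixels, mode = "eval")
    denormalize(image_slice(yn, spacing = s$spacing, label = s$label),
                vmin, vmax)
  })
}

#' Translate a NIfTI volume file
#'
#' @param model a `petcycle_model` or checkpoint path.
#' @param in_path input NIfTI volume of low-quality slices.
#' @param out_path output NIfTI path for the estimated volume.
#' @return invisibly, `out_path`.
#' @export
infer_volume <- function(model, in_path, out_path) {
  slices <- read_volume(in_path)
  write_volume(infer(model, slices), out_path)
  invisible(out_path)
}

#' Before/after image-quality evaluation on held-out pairs
#'
#' For each pair, the LQ slice is translated with the trained model (pair
#' normalized on the HQ scale, translated, denormalized) and both the raw LQ
#' and the translated slice are scored against the HQ reference.
#'
#' @param model a `petcycle_model`.
#' @param test_pairs list of physical-scale [paired_sample()]s.
#' @param cfg a [metric_config()].
#' @return list with `before` and `after` [evaluate_pairs()] reports and
#'   the translated slices (`estimates`).
#' @export
evaluate_translation <- function(model, test_pairs, cfg = metric_config()) {
  stopifnot(inherits(model, "petcycle_model"))
  ests <- lapply(test_pairs, function(p) {
    np <- normalize_pair(p)
    yn <- generator_forward(model$g_ab, np$pair$lq$pixels, mode = "eval")
    denormalize(image_slice(yn, spacing = p$lq$spacing, label = p$lq$label),
                np$vmin, np$vmax)
  })
  refs <- lapply(test_pairs, function(p) p$hq)
  lqs <- lapply(test_pairs, function(p) p$lq)
  list(before = evaluate_pairs(lqs, refs, cfg),
       after = evaluate_pairs(ests, refs, cfg),
       estimates = ests)
}
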