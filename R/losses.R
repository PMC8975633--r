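# Objective of the cycle framework:
#   L = L_adv + lambda_c * L_cyc + lambda_i * L_id + lambda_s * L_sup
# with a gradient-penalty critic adversarial term
#   L(G, D) = -E[D(real)] + E[D(fake)] + lambda_gp * E[(||grad_y D(y)|| - 1)^2],
#   y = eps * real + (1 - eps) * fake,  eps ~ U(0, 1) per sample,
# averaged over the two translation directions with the factor 1/2, and
# mean-per-pixel L1 cycle / identity / supervised terms.

#' Loss weights of the total objective
#'
#' @param lambda_c cycle-consistency weight (default 10).
#' @param lambda_i identity weight (default 0.5).
#' @param lambda_s supervised (paired L1) weight (default 0.5).
#' @param lambda_gp gradient-penalty coefficient of the critic loss
#'   (default 10).
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_c = 10, lambda_i = 0.5, lambda_s = 0.5,
                         lambda_gp = 10) {
  for (nm in c("lambda_c", "lambda_i", "lambda_s", "lambda_gp")) {
    v <- check_scalar(get(nm), nm)
    if (v < 0) stopf("'%s' must be >= 0", nm)
  }
  structure(list(lambda_c = lambda_c, lambda_i = lambda_i,
                 lambda_s = lambda_s, lambda_gp = lambda_gp),
            class = "loss_weights")
}

check_same_shape <- function(a, b, what) {
  da <- dim(a) %||% length(a); db <- dim(b) %||% length(b)
  if (!identical(da, db))
    stopf("shape mismatch in %s: %s vs %s", what,
          paste(da, collapse = "x"), paste(db, collapse = "x"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

l1_mean <- function(a, b) mean(abs(a - b))

#' Cycle-consistency loss
#'
#' Mean absolute deviation per pixel between each input and its
#' round-trip reconstruction, summed over the two directions.
#'
#' @param x_a,x_a_cycled domain-A input and its A->B->A reconstruction.
#' @param x_b,x_b_cycled domain-B input and its B->A->B reconstruction.
#' @return nonnegative scalar.
#' @export
cycle_loss <- function(x_a, x_a_cycled, x_b, x_b_cycled) {
  check_same_shape(x_a, x_a_cycled, "cycle loss (A)")
  check_same_shape(x_b, x_b_cycled, "cycle loss (B)")
  l1_mean(x_a_cycled, x_a) + l1_mean(x_b_cycled, x_b)
}

#' Identity loss
#'
#' Penalises each generator for altering inputs it should pass through:
#' mean per-pixel L1 of `G_BA(x_A) - x_A` plus `G_AB(x_B) - x_B`.
#'
#' @param x_a,gba_xa domain-A input and `G_BA(x_A)`.
#' @param x_b,gab_xb domain-B input and `G_AB(x_B)`.
#' @return nonnegative scalar.
#' @export
identity_loss <- function(x_a, gba_xa, x_b, gab_xb) {
  check_same_shape(x_a, gba_xa, "identity loss (A)")
  check_same_shape(x_b, gab_xb, "identity loss (B)")
  l1_mean(gba_xa, x_a) + l1_mean(gab_xb, x_b)
}

#' Supervised paired loss
#'
#' Pixel-aligned L1 between each translation and its paired ground truth:
#' mean per-pixel L1 of `G_AB(x_A) - x_B` plus `G_BA(x_B) - x_A`.
#'
#' @param gab_xa translation of the A batch; compared against `x_b`.
#' @param x_b paired domain-B ground truth.
#' @param gba_xb translation of the B batch; compared against `x_a`.
#' @param x_a paired domain-A ground truth.
#' @return nonnegative scalar.
#' @export
supervised_loss <- function(gab_xa, x_b, gba_xb, x_a) {
  check_same_shape(gab_xa, x_b, "supervised loss (A->B)")
  check_same_shape(gba_xb, x_a, "supervised loss (B->A)")
  l1_mean(gab_xa, x_b) + l1_mean(gba_xb, x_a)
}

#' Compose the total objective from its components
#'
#' @param components named list or vector with elements `adv`, `cyc`, `id`,
#'   `sup` (finite scalars).
#' @param weights a [loss_weights()].
#' @return an object of class `loss_breakdown` with fields `adv`, `cyc`,
#'   `id`, `sup` and `total`, where
#'   `total = adv + lambda_c*cyc + lambda_i*id + lambda_s*sup` exactly.
#' @export
total_loss <- function(components, weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  comp <- as.list(components)
  for (nm in c("adv", "cyc", "id", "sup")) {
    v <- comp[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L)
      stopf("component '%s' missing or not a scalar", nm)
    if (!is.finite(v)) stopf("loss component '%s' is not finite (%s)", nm, format(v))
  }
  total <- comp$adv + weights$lambda_c * comp$cyc +
    weights$lambda_i * comp$id + weights$lambda_s * comp$sup
  structure(list(adv = comp$adv, cyc = comp$cyc, id = comp$id,
                 sup = comp$sup, total = total, weights = weights),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total=%.6g (adv=%.6g cyc=%.6g id=%.6g sup=%.6g)\n",
              x$total, x$adv, x$cyc, x$id, x$sup))
  invisible(x)
}

# ---- critics ----------------------------------------------------------------

#' Per-sample critic scores
#'
#' Generic over critic representations: the patch discriminator (score =
#' spatial mean of its map, batch-norm statistics frozen at the batch values)
#' or an analytic critic such as [linear_critic()].
#'
#' @param d a critic.
#' @param x input batch `1 x H x W x N` (or `H x W` for a single image).
#' @return numeric vector of length N.
#' @export
critic_score <- function(d, x) UseMethod("critic_score")

#' Per-sample input gradients of a critic
#'
#' Gradient of each sample's scalar score with respect to that sample's
#' input pixels.
#'
#' @inheritParams critic_score
#' @return array shaped like `x`.
#' @export
critic_input_gradient <- function(d, x) UseMethod("critic_input_gradient")

#' Analytic linear critic
#'
#' `D(x) = <w, x> + b` per sample; used to validate the gradient penalty
#' (a unit-norm `w` has penalty exactly zero, `w = 0` gives a constant
#' critic with penalty 1).
#'
#' @param w numeric array of per-pixel weights.
#' @param b scalar offset.
#' @return an object of class `petcycle_linear_critic`.
#' @export
linear_critic <- function(w, b = 0) {
  structure(list(w = w, b = check_scalar(b, "b")),
            class = "petcycle_linear_critic")
}

as_batch4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stopf("critic input must be an array")
  if (length(d) == 2L) dim(x) <- c(1L, d, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

#' @export
critic_score.petcycle_linear_critic <- function(d, x) {
  x <- as_batch4(x)
  n <- dim(x)[4]
  m <- x; dim(m) <- c(length(x) / n, n)
  as.vector(crossprod(m, as.vector(d$w))) + d$b
}

#' @export
critic_input_gradient.petcycle_linear_critic <- function(d, x) {
  x <- as_batch4(x)
  g <- array(rep(as.vector(d$w), dim(x)[4]), dim(x))
  g
}

# Frozen-statistics forward through the patch critic: batch-norm statistics
# are computed from the incoming batch and then treated as constants, making
# the critic piecewise-affine in its input so per-sample input gradients are
# well-defined (samples do not interact through the normalisation).
critic_frozen_forward <- function(disc, x, stats = NULL) {
  tape <- vector("list", length(disc$layers))
  stats_out <- vector("list", length(disc$layers))
  for (i in seq_along(disc$layers)) {
    l <- disc$layers[[i]]
    if (l$type == "bn") {
      st <- stats[[i]]
      if (is.null(st)) {
        m <- x; dim(m) <- c(l$ch, length(x) / l$ch)
        mu <- rowMeans(m)
        v <- rowMeans((m - mu)^2)
        st <- list(mu = mu, ivar = 1 / sqrt(v + l$eps))
      }
      stats_out[[i]] <- st
      f <- bn_forward(l, x, "eval", frozen_stats = st)
    } else if (l$type %in% c("conv", "act")) {
      f <- layer_forward(l, x)
    } else stopf("unsupported critic layer type '%s'", l$type)
    tape[[i]] <- f$cache
    x <- f$y
  }
  list(score_map = x, tape = tape, stats = stats_out)
}

per_sample_mean_seed <- function(score_map) {
  d <- dim(score_map)
  array(1 / (d[1] * d[2] * d[3]), d)
}

#' @export
critic_score.petcycle_discriminator <- function(d, x) {
  x <- as_batch4(x)
  s <- critic_frozen_forward(d, x)$score_map
  n <- dim(s)[4]
  m <- s; dim(m) <- c(length(s) / n, n)
  colMeans(m)
}

#' @export
critic_input_gradient.petcycle_discriminator <- function(d, x) {
  x <- as_batch4(x)
  fw <- critic_frozen_forward(d, x)
  net_backward(d, fw$tape, per_sample_mean_seed(fw$score_map), accumulate = FALSE)
}

per_sample_norms <- function(g) {
  n <- dim(g)[4]
  m <- g; dim(m) <- c(length(g) / n, n)
  sqrt(colSums(m * m))
}

#' Gradient penalty of a critic at interpolated points
#'
#' Draws per-sample mixing weights `eps ~ U(0,1)`, forms
#' `y = eps*real + (1-eps)*fake`, and returns
#' `mean((||grad_y D(y)||_2 - 1)^2)`.
#'
#' @param d a critic ([build_discriminator()] network or [linear_critic()]).
#' @param real,fake batches of identical shape.
#' @param seed optional integer seed for the mixing weights.
#' @return list with `penalty`, the interpolates `y` and the per-sample
#'   gradient array `g`.
#' @export
gradient_penalty <- function(d, real, fake, seed = NULL) {
  real <- as_batch4(real); fake <- as_batch4(fake)
  check_same_shape(real, fake, "gradient penalty")
  n <- dim(real)[4]
  eps <- with_seed(seed, stats::runif(n))
  ef <- rep(eps, each = length(real) / n)
  dim(ef) <- dim(real)
  y <- ef * real + (1 - ef) * fake
  g <- critic_input_gradient(d, y)
  r <- per_sample_norms(g)
  list(penalty = mean((r - 1)^2), y = y, g = g, norms = r)
}

#' Adversarial loss of one translation direction
#'
#' Computes the critic objective
#' `-E[D(real)] + E[D(fake)] + lambda_gp * penalty` and the generator's
#' adversarial term `-E[D(fake)]` (values only; no parameters are updated).
#' When the two directions are summed, apply the factor 1/2.
#'
#' @param d the direction's critic.
#' @param real_batch,fake_batch real and generated batches, same shape.
#' @param weights a [loss_weights()] (supplies `lambda_gp`).
#' @param seed optional integer seed for the interpolation weights.
#' @return list with `critic_loss`, `generator_term` and `penalty`.
#' @export
adversarial_loss <- function(d, real_batch, fake_batch,
                             weights = loss_weights(), seed = NULL) {
  stopifnot(inherits(weights, "loss_weights"))
  real_batch <- as_batch4(real_batch); fake_batch <- as_batch4(fake_batch)
  check_same_shape(real_batch, fake_batch, "adversarial loss")
  s_real <- critic_score(d, real_batch)
  s_fake <- critic_score(d, fake_batch)
  gp <- gradient_penalty(d, real_batch, fake_batch, seed = seed)
  list(critic_loss = -mean(s_real) + mean(s_fake) + weights$lambda_gp * gp$penalty,
       generator_term = -mean(s_fake),
       penalty = gp$penalty)
}

# ---- penalty parameter-gradients (tangent pass) ----------------------------
#
# For the critic update the penalty's parameter gradient is computed exactly
# for the frozen-statistics (piecewise-affine) critic: with v_n the chain-rule
# coefficient 2*(r_n - 1)/(N r_n) * g_n, the scalar sum_n <v_n, g_n> equals the
# directional derivative of the summed per-sample scores along v, evaluated by
# a tangent forward pass; reversing over that pass yields d(penalty)/d(theta).
# LeakyReLU has zero second derivative almost everywhere and the frozen
# normalisation is affine, so the result is exact for the penalised function.
critic_penalty_with_grads <- function(disc, y, scale = 1) {
  fw <- critic_frozen_forward(disc, y)
  seed <- per_sample_mean_seed(fw$score_map)
  g <- net_backward(disc, fw$tape, seed, accumulate = FALSE)
  r <- per_sample_norms(g)
  penalty <- mean((r - 1)^2)
  n <- dim(y)[4]
  coef <- ifelse(r > 1e-12, 2 * (r - 1) / (r * n), 0)
  m <- g; dim(m) <- c(length(g) / n, n)
  v <- m * rep(coef * scale, each = nrow(m))
  dim(v) <- dim(y)

  # tangent forward
  tan_tape <- vector("list", length(disc$layers))
  t_cur <- v
  for (i in seq_along(disc$layers)) {
    l <- disc$layers[[i]]
    cc <- fw$tape[[i]]
    if (l$type == "conv") {
      tp <- pad_input(t_cur, l$pad, l$padmode)
      tcol <- im2col(tp, cc$ci)
      wm <- l$params$w; dim(wm) <- c(l$out_ch, l$in_ch * l$k * l$k)
      tout <- wm %*% tcol
      dim(tout) <- c(l$out_ch, cc$ci$Ho, cc$ci$Wo, cc$N)
      tan_tape[[i]] <- list(tcol = tcol)
      t_cur <- tout
    } else if (l$type == "bn") {
      tin <- t_cur
      d <- dim(t_cur)
      tm <- t_cur; dim(tm) <- c(l$ch, length(t_cur) / l$ch)
      tm <- tm * (l$params$gamma * cc$ivar)
      dim(tm) <- d
      tan_tape[[i]] <- list(tin = tin, ivar = cc$ivar)
      t_cur <- tm
    } else {            # lrelu
      t_cur <- t_cur * cc$sc
    }
  }

  # reverse over the tangent pass, accumulating into layer grads
  dt <- per_sample_mean_seed(fw$score_map)
  for (i in rev(seq_along(disc$layers))) {
    l <- disc$layers[[i]]
    cc <- fw$tape[[i]]
    if (l$type == "conv") {
      dtm <- dt; dim(dtm) <- c(l$out_ch, length(dt) / l$out_ch)
      l$grads$w <- l$grads$w +
        array(tcrossprod(dtm, tan_tape[[i]]$tcol), dim(l$params$w))
      wm <- l$params$w; dim(wm) <- c(l$out_ch, l$in_ch * l$k * l$k)
      dcol <- crossprod(wm, dtm)
      dxp <- col2im(dcol, cc$ci, cc$C, cc$Hp, cc$Wp, cc$N)
      dt <- unpad_grad(dxp, cc$pad, cc$padmode, cc$H, cc$W)
    } else if (l$type == "bn") {
      tt <- tan_tape[[i]]
      d <- dim(dt)
      dtm <- dt; dim(dtm) <- c(l$ch, length(dt) / l$ch)
      tinm <- tt$tin; dim(tinm) <- dim(dtm)
      l$grads$gamma <- l$grads$gamma + rowSums(dtm * (tt$ivar * tinm))
      dtm <- dtm * (l$params$gamma * tt$ivar)
      dim(dtm) <- d
      dt <- dtm
    } else {
      dt <- dt * cc$sc
    }
  }
  penalty
}
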