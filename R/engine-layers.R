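# Layer objects and reverse-mode differentiation.
#
# Each primitive layer is an environment holding $params and $grads (lists of
# numeric arrays) so gradient accumulation and optimizer updates mutate in
# place. A forward pass returns its intermediate values in an explicit tape,
# allowing the same network to be applied several times inside one objective
# (the cycle framework applies each generator three times per step).

new_layer_env <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  class(e) <- c(paste0("petcycle_", type), "petcycle_layer")
  e
}

# Weight init follows the image-translation convention: N(0, 0.02) kernels,
# N(1, 0.02) batch-norm scales, zero offsets. Draws from the caller's RNG.
init_array <- function(dim, sd = 0.02, mean = 0) {
  array(stats::rnorm(prod(dim), mean, sd), dim)
}

new_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L,
                     padmode = "zero", bias = TRUE) {
  e <- new_layer_env("conv")
  e$in_ch <- in_ch; e$out_ch <- out_ch; e$k <- as.integer(k)
  e$stride <- as.integer(stride); e$pad <- as.integer(pad); e$padmode <- padmode
  e$params$w <- init_array(c(out_ch, in_ch, k, k))
  if (bias) e$params$b <- numeric(out_ch)
  e
}

new_convT <- function(in_ch, out_ch, k = 3L, stride = 2L, pad = 1L, outpad = 1L) {
  e <- new_layer_env("convT")
  e$in_ch <- in_ch; e$out_ch <- out_ch; e$k <- as.integer(k)
  e$stride <- as.integer(stride); e$pad <- as.integer(pad); e$outpad <- as.integer(outpad)
  e$params$w <- init_array(c(in_ch, out_ch, k, k))
  e$params$b <- numeric(out_ch)
  e
}

new_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  e <- new_layer_env("bn")
  e$ch <- ch; e$momentum <- momentum; e$eps <- eps
  e$params$gamma <- as.numeric(init_array(ch, sd = 0.02, mean = 1))
  e$params$beta <- numeric(ch)
  e$running_mean <- numeric(ch)
  e$running_var <- rep(1, ch)
  e
}

new_act <- function(kind, slope = 0.2) {
  e <- new_layer_env("act")
  e$kind <- kind; e$slope <- slope
  e
}

new_resblock <- function(ch) {
  e <- new_layer_env("resblock")
  e$children <- list(
    conv1 = new_conv(ch, ch, 3L, 1L, 1L, padmode = "reflect"),
    bn1   = new_bn(ch),
    conv2 = new_conv(ch, ch, 3L, 1L, 1L, padmode = "reflect"),
    bn2   = new_bn(ch)
  )
  e
}

as_mat <- function(x) { dim(x) <- c(dim(x)[1], length(x) / dim(x)[1]); x }

bn_forward <- function(layer, x, mode, frozen_stats = NULL) {
  d <- dim(x)
  m <- x; dim(m) <- c(d[1], length(x) / d[1])
  if (!is.null(frozen_stats)) {
    mu <- frozen_stats$mu; ivar <- frozen_stats$ivar
  } else if (mode %in% c("train", "train_noupdate")) {
    mu <- rowMeans(m)
    xc <- m - mu
    v <- rowMeans(xc * xc)
    ivar <- 1 / sqrt(v + layer$eps)
    if (mode == "train") {
      mom <- layer$momentum
      layer$running_mean <- (1 - mom) * layer$running_mean + mom * mu
      layer$running_var <- (1 - mom) * layer$running_var + mom * v
    }
  } else {
    mu <- layer$running_mean
    ivar <- 1 / sqrt(layer$running_var + layer$eps)
  }
  xhat <- (m - mu) * ivar
  y <- layer$params$gamma * xhat + layer$params$beta
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, ivar = ivar, mu = mu, d = d,
                           train_stats = is.null(frozen_stats) &&
                             mode %in% c("train", "train_noupdate")))
}

bn_backward <- function(layer, dy, cache, accumulate = TRUE) {
  d <- cache$d
  dym <- dy; dim(dym) <- c(d[1], length(dy) / d[1])
  g <- layer$params$gamma
  if (accumulate) {
    layer$grads$gamma <- layer$grads$gamma + rowSums(dym * cache$xhat)
    layer$grads$beta <- layer$grads$beta + rowSums(dym)
  }
  dxhat <- dym * g
  if (cache$train_stats) {
    nm <- ncol(dym)
    dx <- (cache$ivar / nm) *
      (nm * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  } else {
    dx <- dxhat * cache$ivar
  }
  dim(dx) <- d
  dx
}

act_forward <- function(layer, x) {
  if (layer$kind == "relu") {
    y <- pmax(x, 0); dim(y) <- dim(x)
    return(list(y = y, cache = list(mask = x > 0)))
  }
  if (layer$kind == "lrelu") {
    sc <- layer$slope + (1 - layer$slope) * (x > 0)
    y <- x * sc
    return(list(y = y, cache = list(sc = sc)))
  }
  y <- switch(layer$kind,
    tanh = tanh(x),
    sigmoid = 1 / (1 + exp(-x)),
    stopf("unknown activation '%s'", layer$kind))
  list(y = y, cache = list(y = y))
}

act_backward <- function(layer, dy, cache) {
  switch(layer$kind,
    relu = dy * cache$mask,
    lrelu = dy * cache$sc,
    tanh = dy * (1 - cache$y^2),
    sigmoid = dy * cache$y * (1 - cache$y))
}

layer_forward <- function(layer, x, mode = "train", frozen = NULL) {
  switch(layer$type,
    conv = conv2d_forward(x, layer$params$w, layer$params$b,
                          layer$stride, layer$pad, layer$padmode),
    convT = convT2d_forward(x, layer$params$w, layer$params$b,
                            layer$stride, layer$pad, layer$outpad),
    bn = bn_forward(layer, x, mode, frozen),
    act = act_forward(layer, x),
    resblock = resblock_forward(layer, x, mode),
    cbam = cbam_forward(layer, x),
    stopf("unknown layer type '%s'", layer$type))
}

layer_backward <- function(layer, dy, cache, accumulate = TRUE) {
  switch(layer$type,
    conv = {
      r <- conv2d_backward(dy, layer$params$w, cache, accumulate)
      if (accumulate) {
        layer$grads$w <- layer$grads$w + r$dw
        if (!is.null(layer$params$b)) layer$grads$b <- layer$grads$b + r$db
      }
      r$dx
    },
    convT = {
      r <- convT2d_backward(dy, layer$params$w, cache, accumulate)
      if (accumulate) {
        layer$grads$w <- layer$grads$w + r$dw
        layer$grads$b <- layer$grads$b + r$db
      }
      r$dx
    },
    bn = bn_backward(layer, dy, cache, accumulate),
    act = act_backward(layer, dy, cache),
    resblock = resblock_backward(layer, dy, cache, accumulate),
    cbam = cbam_backward(layer, dy, cache, accumulate),
    stopf("unknown layer type '%s'", layer$type))
}

resblock_forward <- function(layer, x, mode) {
  ch <- layer$children
  f1 <- layer_forward(ch$conv1, x, mode)
  f2 <- layer_forward(ch$bn1, f1$y, mode)
  r1 <- pmax(f2$y, 0); dim(r1) <- dim(f2$y)
  f3 <- layer_forward(ch$conv2, r1, mode)
  f4 <- layer_forward(ch$bn2, f3$y, mode)
  s <- f4$y + x
  y <- pmax(s, 0); dim(y) <- dim(s)            # rectifier after the skip sum
  list(y = y, cache = list(c1 = f1$cache, b1 = f2$cache, m1 = f2$y > 0,
                           c2 = f3$cache, b2 = f4$cache, ms = s > 0))
}

resblock_backward <- function(layer, dy, cache, accumulate = TRUE) {
  ch <- layer$children
  ds <- dy * cache$ms
  d4 <- layer_backward(ch$bn2, ds, cache$b2, accumulate)
  d3 <- layer_backward(ch$conv2, d4, cache$c2, accumulate)
  d3 <- d3 * cache$m1
  d2 <- layer_backward(ch$bn1, d3, cache$b1, accumulate)
  d1 <- layer_backward(ch$conv1, d2, cache$c1, accumulate)
  d1 + ds
}

# ---- network containers -----------------------------------------------------

new_network <- function(layers, meta = list()) {
  structure(list(layers = layers, meta = meta), class = "petcycle_network")
}

net_forward <- function(net, x, mode = "train") {
  tape <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    f <- layer_forward(net$layers[[i]], x, mode)
    tape[[i]] <- f$cache
    x <- f$y
  }
  list(y = x, tape = tape)
}

net_backward <- function(net, tape, dy, accumulate = TRUE) {
  for (i in rev(seq_along(net$layers)))
    dy <- layer_backward(net$layers[[i]], dy, tape[[i]], accumulate)
  dy
}

# Flat list of primitive parameter-bearing environments (recurses into
# composite layers).
flat_layers <- function(x) {
  if (inherits(x, "petcycle_network")) return(flat_layers(x$layers))
  if (inherits(x, "petcycle_layer")) {
    out <- list(x)
    if (!is.null(x$children)) out <- c(out, flat_layers(x$children))
    return(out)
  }
  if (is.list(x)) return(do.call(c, lapply(x, flat_layers)))
  list()
}

zero_grads <- function(net) {
  for (l in flat_layers(net))
    l$grads <- lapply(l$params, function(p) { p[] <- 0; p })
  invisible(net)
}

#' Count trainable parameters of a network
#'
#' @param model a generator or discriminator built by [build_generator()] /
#'   [build_discriminator()], or any internal layer collection.
#' @return integer: the exact number of trainable scalars (convolution
#'   kernels, biases, batch-norm scales and offsets, attention weights).
#' @export
count_parameters <- function(model) {
  sum(vapply(flat_layers(model),
             function(l) sum(vapply(l$params, length, 1L)), 1L))
}

# ---- Adam -------------------------------------------------------------------

new_adam <- function(net, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$layers <- flat_layers(net)
  opt$state <- lapply(opt$layers, function(l)
    list(m = lapply(l$params, function(p) { p[] <- 0; p }),
         v = lapply(l$params, function(p) { p[] <- 0; p })))
  opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps; opt$t <- 0L
  opt
}

adam_step <- function(opt, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (i in seq_along(opt$layers)) {
    l <- opt$layers[[i]]
    st <- opt$state[[i]]
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
      st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
      mhat <- st$m[[nm]] / corr1
      vhat <- st$v[[nm]] / corr2
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + opt$eps)
    }
    opt$state[[i]] <- st
  }
  invisible(opt)
}
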