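# Convolutional block attention: sequential channel-wise then spatial-wise
# multiplicative gating of a feature map. Channel gates come from spatially
# average- and max-pooled descriptors passed through one shared bottleneck
# network; spatial gates come from channel-wise mean/max maps passed through a
# single convolution. Both are squashed by a sigmoid, so every gate lies
# strictly in (0, 1).

#' Configuration of a convolutional block attention module
#'
#' @param channels number of channels `C` of the incoming feature map.
#' @param reduction bottleneck ratio `r` of the shared channel-attention
#'   network (the descriptor is mapped `C -> C/r -> C`); default 16, the
#'   reference setting. Capped at `channels`.
#' @param spatial_kernel odd convolution size of the spatial branch
#'   (default 7, the reference setting).
#' @return an object of class `cbam_config`.
#' @export
cbam_config <- function(channels, reduction = 16L, spatial_kernel = 7L) {
  channels <- check_count(channels, "channels")
  reduction <- check_count(reduction, "reduction")
  spatial_kernel <- check_count(spatial_kernel, "spatial_kernel", min = 3L)
  if (reduction > channels)
    stopf("'reduction' (%d) must not exceed 'channels' (%d)", reduction, channels)
  if (spatial_kernel %% 2L == 0L)
    stopf("'spatial_kernel' must be odd (got %d)", spatial_kernel)
  structure(list(channels = channels, reduction = reduction,
                 spatial_kernel = spatial_kernel), class = "cbam_config")
}

new_cbam <- function(cfg) {
  e <- new_layer_env("cbam")
  C <- cfg$channels
  Cr <- max(1L, C %/% cfg$reduction)
  e$cfg <- cfg
  e$Cr <- Cr
  e$params$w1 <- init_array(c(Cr, C))
  e$params$b1 <- numeric(Cr)
  e$params$w2 <- init_array(c(C, Cr))
  e$params$b2 <- numeric(C)
  e$children <- list(
    spatial_conv = new_conv(2L, 1L, cfg$spatial_kernel, 1L,
                            (cfg$spatial_kernel - 1L) %/% 2L))
  e
}

# Spatial average/max pooling of (C,H,W,N) to per-channel descriptors (C,N).
pool_spatial <- function(x) {
  d <- dim(x); C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  xm <- x; dim(xm) <- c(C, HW, N)
  ap <- aperm(xm, c(2, 1, 3)); dim(ap) <- c(HW, C * N)
  avg <- matrix(colMeans(ap), C, N)
  imax <- max.col(t(ap), ties.method = "first")
  mx <- matrix(ap[cbind(imax, seq_len(C * N))], C, N)
  list(avg = avg, mx = mx, imax = imax, ap_dim = c(HW, C, N))
}

channel_att_forward <- function(layer, x) {
  p <- pool_spatial(x)
  w1 <- layer$params$w1; w2 <- layer$params$w2
  pre_a <- w1 %*% p$avg + layer$params$b1
  pre_m <- w1 %*% p$mx + layer$params$b1
  ha <- pmax(pre_a, 0); hm <- pmax(pre_m, 0)
  s <- (w2 %*% ha + layer$params$b2) + (w2 %*% hm + layer$params$b2)
  gate <- 1 / (1 + exp(-s))
  list(gate = gate,
       cache = list(pool = p, ha = ha, hm = hm, ma = pre_a > 0, mm = pre_m > 0,
                    gate = gate, d = dim(x)))
}

channel_att_backward <- function(layer, dgate, cache, accumulate = TRUE) {
  ds <- dgate * cache$gate * (1 - cache$gate)
  w1 <- layer$params$w1; w2 <- layer$params$w2
  dha <- crossprod(w2, ds) * cache$ma
  dhm <- crossprod(w2, ds) * cache$mm
  p <- cache$pool
  if (accumulate) {
    layer$grads$w2 <- layer$grads$w2 + tcrossprod(ds, cache$ha) + tcrossprod(ds, cache$hm)
    layer$grads$b2 <- layer$grads$b2 + 2 * rowSums(ds)
    layer$grads$w1 <- layer$grads$w1 + tcrossprod(dha, p$avg) + tcrossprod(dhm, p$mx)
    layer$grads$b1 <- layer$grads$b1 + rowSums(dha) + rowSums(dhm)
  }
  davg <- crossprod(w1, dha)                         # (C, N)
  dmx <- crossprod(w1, dhm)
  HW <- p$ap_dim[1]; C <- p$ap_dim[2]; N <- p$ap_dim[3]
  dap <- matrix(as.vector(davg) / HW, HW, C * N, byrow = TRUE)
  sel <- cbind(p$imax, seq_len(C * N))
  dap[sel] <- dap[sel] + as.vector(dmx)
  dim(dap) <- c(HW, C, N)
  dx <- aperm(dap, c(2, 1, 3))
  dim(dx) <- cache$d
  dx
}

spatial_att_forward <- function(layer, x) {
  d <- dim(x); C <- d[1]; HWN <- length(x) / C
  xm <- x; dim(xm) <- c(C, HWN)
  mean_map <- colMeans(xm)
  imax <- max.col(t(xm), ties.method = "first")
  max_map <- xm[cbind(imax, seq_len(HWN))]
  desc <- rbind(mean_map, max_map)
  dim(desc) <- c(2L, d[2], d[3], d[4])
  cv <- layer_forward(layer$children$spatial_conv, desc)
  gate <- 1 / (1 + exp(-cv$y))                       # (1, H, W, N)
  list(gate = gate,
       cache = list(conv = cv$cache, imax = imax, gate = gate, d = d))
}

spatial_att_backward <- function(layer, dgate, cache, accumulate = TRUE) {
  dpre <- dgate * cache$gate * (1 - cache$gate)
  ddesc <- layer_backward(layer$children$spatial_conv, dpre, cache$conv, accumulate)
  d <- cache$d; C <- d[1]; HWN <- length(ddesc) / 2L
  dim(ddesc) <- c(2L, HWN)
  dx <- matrix(ddesc[1L, ] / C, C, HWN, byrow = TRUE)
  sel <- cbind(cache$imax, seq_len(HWN))
  dx[sel] <- dx[sel] + ddesc[2L, ]
  dim(dx) <- d
  dx
}

expand_channel_gate <- function(gate, d) {
  # gate (C, N) -> full (C, H, W, N)
  g <- gate[, rep(seq_len(d[4]), each = d[2] * d[3]), drop = FALSE]
  dim(g) <- d
  g
}

expand_spatial_gate <- function(gate, d) {
  # gate (1, H, W, N) -> full (C, H, W, N)
  g <- rep(as.vector(gate), each = d[1])
  dim(g) <- d
  g
}

cbam_forward <- function(layer, x) {
  d <- dim(x)
  if (d[1] != layer$cfg$channels)
    stopf("feature map has %d channels but the attention block expects %d",
          d[1], layer$cfg$channels)
  ca <- channel_att_forward(layer, x)
  gc_full <- expand_channel_gate(ca$gate, d)
  x1 <- x * gc_full
  sa <- spatial_att_forward(layer, x1)
  gs_full <- expand_spatial_gate(sa$gate, d)
  y <- x1 * gs_full
  list(y = y, cache = list(ca = ca$cache, sa = sa$cache, x = x, x1 = x1,
                           gc_full = gc_full, gs_full = gs_full, d = d))
}

cbam_backward <- function(layer, dy, cache, accumulate = TRUE) {
  d <- cache$d; C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  dx1 <- dy * cache$gs_full
  dgs_arr <- dy * cache$x1
  dim(dgs_arr) <- c(C, HW * N)
  dgs <- colSums(dgs_arr)
  dim(dgs) <- c(1L, d[2], d[3], N)
  dx1 <- dx1 + spatial_att_backward(layer, dgs, cache$sa, accumulate)
  dx <- dx1 * cache$gc_full
  prod_cg <- dx1 * cache$x
  dim(prod_cg) <- c(C, HW, N)
  ap <- aperm(prod_cg, c(2, 1, 3)); dim(ap) <- c(HW, C * N)
  dgc <- matrix(colSums(ap), C, N)
  dx + channel_att_backward(layer, dgc, cache$ca, accumulate)
}

# ---- user-facing single-map interface --------------------------------------

as_batch1 <- function(f) {
  if (length(dim(f)) == 3L) { dim(f) <- c(dim(f), 1L); f }
  else if (length(dim(f)) == 4L) f
  else stopf("feature map must be a C x H x W array")
}

#' Channel attention gates of a feature map
#'
#' Spatially average- and max-pools the map to two per-channel descriptors,
#' passes both through one shared bottleneck network, sums element-wise and
#' applies a sigmoid.
#'
#' @param block a CBAM block created by [build_cbam()].
#' @param f numeric array `C x H x W` (or `C x H x W x N`).
#' @return numeric vector of length `C` (or a `C x N` matrix), all values
#'   strictly in (0, 1).
#' @export
channel_attention <- function(block, f) {
  f <- as_batch1(f)
  if (dim(f)[1] != block$cfg$channels)
    stopf("feature map has %d channels but the attention block expects %d",
          dim(f)[1], block$cfg$channels)
  g <- channel_att_forward(block, f)$gate
  if (ncol(g) == 1L) drop(g) else g
}

#' Spatial attention gates of a feature map
#'
#' Channel-wise mean and max maps are concatenated into a two-channel
#' descriptor and convolved (odd kernel, size-preserving padding), then
#' squashed by a sigmoid.
#'
#' @inheritParams channel_attention
#' @return an `H x W` matrix of gates strictly in (0, 1).
#' @export
spatial_attention <- function(block, f) {
  f <- as_batch1(f)
  g <- spatial_att_forward(block, f)$gate
  out <- g[1L, , , 1L]
  dim(out) <- dim(f)[2:3]
  out
}

#' Apply a convolutional block attention module to a feature map
#'
#' Refines `f` by multiplying with the broadcast channel gates, then the
#' spatial gates computed from the channel-refined map.
#'
#' @inheritParams channel_attention
#' @return refined feature map, same shape as `f`.
#' @export
cbam <- function(block, f) {
  f3 <- length(dim(f)) == 3L
  fb <- as_batch1(f)
  y <- cbam_forward(block, fb)$y
  if (f3) dim(y) <- dim(y)[1:3]
  y
}

#' Build a convolutional block attention module
#'
#' @param cfg a [cbam_config()].
#' @param seed optional integer seed for weight initialisation.
#' @return a CBAM block usable with [channel_attention()],
#'   [spatial_attention()] and [cbam()].
#' @export
build_cbam <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "cbam_config"))
  with_seed(seed, new_cbam(cfg))
}
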