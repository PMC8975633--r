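# Independent brute-force oracles used to validate the vectorized
# implementations, plus small fixture builders. The oracles deliberately use
# explicit loops and never share code with the implementation paths.

oracle_nrmse <- function(x, y, percent = TRUE) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    num <- num + (x[i, j] - y[i, j])^2
    den <- den + y[i, j]^2
  }
  out <- sqrt(num / den)
  if (percent) out * 100 else out
}

oracle_psnr <- function(x, y) {
  mse <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
    mse <- mse + (x[i, j] - y[i, j])^2
  mse <- mse / length(x)
  20 * log10(max(y) / sqrt(mse))
}

oracle_ssim <- function(x, y, window = 11L, sigma = 1.5,
                        k1 = 0.01, k2 = 0.03) {
  L <- max(y) - min(y)
  if (L <= 0) L <- max(abs(y), 1e-12)
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  r <- (window - 1L) / 2L
  k1d <- if (sigma > 0) exp(-((-r:r)^2) / (2 * sigma^2)) else rep(1, window)
  kk <- outer(k1d, k1d); kk <- kk / sum(kk)
  vals <- c()
  for (ci in (r + 1):(nrow(x) - r)) for (cj in (r + 1):(ncol(x) - r)) {
    wx <- x[(ci - r):(ci + r), (cj - r):(cj + r)]
    wy <- y[(ci - r):(ci + r), (cj - r):(cj + r)]
    mx <- sum(kk * wx); my <- sum(kk * wy)
    vx <- sum(kk * wx * wx) - mx^2
    vy <- sum(kk * wy * wy) - my^2
    cxy <- sum(kk * wx * wy) - mx * my
    vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  mean(vals)
}

# Channel attention recomputed with explicit loops over channels.
oracle_channel_attention <- function(block, f) {
  C <- dim(f)[1]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    avg[c] <- mean(f[c, , ])
    mx[c] <- max(f[c, , ])
  }
  mlp <- function(v) {
    h <- as.vector(block$params$w1 %*% v) + block$params$b1
    h[h < 0] <- 0
    as.vector(block$params$w2 %*% h) + block$params$b2
  }
  s <- mlp(avg) + mlp(mx)
  1 / (1 + exp(-s))
}

# Spatial attention recomputed with explicit loops over positions.
oracle_spatial_attention <- function(block, f) {
  C <- dim(f)[1]; H <- dim(f)[2]; W <- dim(f)[3]
  k <- block$cfg$spatial_kernel
  r <- (k - 1L) %/% 2L
  conv <- block$children$spatial_conv
  w <- conv$params$w       # (1, 2, k, k)
  b <- conv$params$b
  desc <- array(0, c(2, H, W))
  for (i in seq_len(H)) for (j in seq_len(W)) {
    desc[1, i, j] <- mean(f[, i, j])
    desc[2, i, j] <- max(f[, i, j])
  }
  gate <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- b[1]
    for (c in 1:2) for (ki in seq_len(k)) for (kj in seq_len(k)) {
      ii <- i + ki - 1L - r; jj <- j + kj - 1L - r
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        s <- s + w[1, c, ki, kj] * desc[c, ii, jj]
    }
    gate[i, j] <- 1 / (1 + exp(-s))
  }
  gate
}

# Spatial-size trace for a stack of (kernel, stride, pad) convolution stages.
oracle_conv_trace <- function(size, stages) {
  for (st in stages) size <- (size + 2L * st[3] - st[1]) %/% st[2] + 1L
  size
}

# L1 supervised loss with explicit loops.
oracle_supervised <- function(gab_xa, x_b, gba_xb, x_a) {
  s1 <- 0
  for (i in seq_along(gab_xa)) s1 <- s1 + abs(gab_xa[i] - x_b[i])
  s2 <- 0
  for (i in seq_along(gba_xb)) s2 <- s2 + abs(gba_xb[i] - x_a[i])
  s1 / length(gab_xa) + s2 / length(gba_xb)
}

# Force every parameter of a network (or layer) to zero.
zero_all_params <- function(net) {
  for (l in petcycle:::flat_layers(net))
    l$params <- lapply(l$params, function(p) { p[] <- 0; p })
  invisible(net)
}

# Small paired dataset for training tests (normalized members).
tiny_dataset <- function(n_pairs = 12L, grid = 32L, sensitivity = 0.15,
                         seed = 1L) {
  make_dataset(phantom_spec(grid_size = grid, seed = seed),
               degradation_spec(sensitivity = sensitivity,
                                seed = seed + 1000L),
               n_pairs, split_seed = seed + 2000L)
}

small_gen_cfg <- function(base = 8L, blocks = 2L)
  generator_config(base_channels = base, n_res_blocks = blocks)

small_disc_cfg <- function(base = 8L)
  discriminator_config(channel_ladder = base * c(1L, 2L, 4L, 8L))
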