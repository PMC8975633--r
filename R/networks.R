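# Generator and discriminator architectures of the cycle framework.
#
# Generator (single-channel in/out): 7x7 conv to `base_channels` feature maps
# (reflection padding) -> CBAM -> two 3x3 stride-2 down-sampling convolutions
# with batch norm + ReLU -> `n_res_blocks` residual blocks (two 3x3 convs with
# reflection padding and batch norm; ReLU after the first conv and after the
# skip sum) -> two 3x3 stride-2 up-sampling (transposed) convolutions with
# batch norm + ReLU -> CBAM -> 7x7 conv to one channel -> tanh.
#
# Discriminator (patch critic): C4S2-64, C4S2-128, C4S2-256, C4S1-512 (4x4
# kernels, LeakyReLU slope 0.2, batch norm from the second stage), then a 4x4
# stride-1 convolution to a one-channel raw score map (no squashing: the
# adversarial loss is a gradient-penalty critic).

#' Generator architecture configuration
#'
#' @param base_channels channels produced by the first 7x7 convolution
#'   (default 64). Down-sampling doubles this twice.
#' @param n_res_blocks number of residual blocks at the bottleneck width
#'   (default 9).
#' @param cbam a [cbam_config()] for the two attention blocks; defaults to
#'   `cbam_config(base_channels)` with reduction capped at `base_channels`.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(base_channels = 64L, n_res_blocks = 9L, cbam = NULL) {
  base_channels <- check_count(base_channels, "base_channels")
  n_res_blocks <- check_count(n_res_blocks, "n_res_blocks")
  if (is.null(cbam))
    cbam <- cbam_config(base_channels, reduction = min(16L, base_channels))
  stopifnot(inherits(cbam, "cbam_config"))
  if (cbam$channels != base_channels)
    stopf("cbam config channels (%d) must equal base_channels (%d)",
          cbam$channels, base_channels)
  structure(list(in_channels = 1L, out_channels = 1L,
                 base_channels = base_channels, n_res_blocks = n_res_blocks,
                 cbam = cbam), class = "generator_config")
}

#' Discriminator architecture configuration
#'
#' @param channel_ladder output channels of the four 4x4 convolution stages
#'   (default `c(64, 128, 256, 512)`; the first three use stride 2, the last
#'   stride 1). Must be strictly increasing.
#' @param kernel convolution kernel size (default 4).
#' @param leaky_slope negative slope of the LeakyReLU activations (default
#'   0.2), in (0, 1).
#' @return an object of class `discriminator_config`.
#' @export
discriminator_config <- function(channel_ladder = c(64L, 128L, 256L, 512L),
                                 kernel = 4L, leaky_slope = 0.2) {
  if (length(channel_ladder) != 4L || any(diff(channel_ladder) <= 0))
    stopf("'channel_ladder' must be four strictly increasing channel counts")
  kernel <- check_count(kernel, "kernel", min = 2L)
  check_scalar(leaky_slope, "leaky_slope")
  if (leaky_slope <= 0 || leaky_slope >= 1)
    stopf("'leaky_slope' must lie in (0, 1)")
  structure(list(channel_ladder = as.integer(channel_ladder), kernel = kernel,
                 leaky_slope = leaky_slope), class = "discriminator_config")
}

#' Build a translation generator
#'
#' @param cfg a [generator_config()].
#' @param seed optional integer seed for weight initialisation.
#' @return an object of class `petcycle_generator`.
#' @export
build_generator <- function(cfg = generator_config(), seed = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  b <- cfg$base_channels
  with_seed(seed, {
    layers <- list(
      new_conv(cfg$in_channels, b, 7L, 1L, 3L, padmode = "reflect"),
      new_cbam(cfg$cbam),
      new_conv(b, 2L * b, 3L, 2L, 1L), new_bn(2L * b), new_act("relu"),
      new_conv(2L * b, 4L * b, 3L, 2L, 1L), new_bn(4L * b), new_act("relu"))
    for (i in seq_len(cfg$n_res_blocks)) layers <- c(layers, list(new_resblock(4L * b)))
    layers <- c(layers, list(
      new_convT(4L * b, 2L * b), new_bn(2L * b), new_act("relu"),
      new_convT(2L * b, b), new_bn(b), new_act("relu"),
      new_cbam(cfg$cbam),
      new_conv(b, cfg$out_channels, 7L, 1L, 3L, padmode = "reflect"),
      new_act("tanh")))
    net <- new_network(layers, meta = list(cfg = cfg))
    class(net) <- c("petcycle_generator", class(net))
    net
  })
}

check_generator_input <- function(x) {
  d <- dim(x)
  if (is.null(d) || !length(d) %in% c(2L, 3L, 4L))
    stopf("generator input must be an H x W matrix or a 1 x H x W (x N) array")
  if (length(d) == 2L) { dim(x) <- c(1L, d, 1L); d <- dim(x) }
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[1] != 1L) stopf("generator input must have a single channel")
  if (d[2] %% 4L != 0L || d[3] %% 4L != 0L)
    stopf("input size %dx%d not divisible by 4 (two stride-2 stages each way)",
          d[2], d[3])
  x
}

#' Apply a generator to normalized input slices
#'
#' @param gen a generator from [build_generator()].
#' @param x an `H x W` matrix or `1 x H x W x N` array of intensities in
#'   \[-1, 1\]; `H` and `W` must be divisible by 4.
#' @param mode `"eval"` (default; batch norm uses stored running statistics)
#'   or `"train"` (batch statistics).
#' @return translated output of the same shape, values strictly in (-1, 1).
#' @export
generator_forward <- function(gen, x, mode = "eval") {
  keep <- dim(x)
  xb <- check_generator_input(x)
  y <- net_forward(gen, xb, mode)$y
  if (!is.null(keep) && length(keep) == 2L) { y <- y[1L, , , 1L]; dim(y) <- keep }
  else if (!is.null(keep) && length(keep) == 3L) dim(y) <- keep
  y
}

#' Build a patch critic (discriminator)
#'
#' @param cfg a [discriminator_config()].
#' @param seed optional integer seed for weight initialisation.
#' @return an object of class `petcycle_discriminator`.
#' @export
build_discriminator <- function(cfg = discriminator_config(), seed = NULL) {
  stopifnot(inherits(cfg, "discriminator_config"))
  ch <- cfg$channel_ladder; k <- cfg$kernel; sl <- cfg$leaky_slope
  with_seed(seed, {
    layers <- list(
      new_conv(1L, ch[1], k, 2L, 1L), new_act("lrelu", sl),
      new_conv(ch[1], ch[2], k, 2L, 1L), new_bn(ch[2]), new_act("lrelu", sl),
      new_conv(ch[2], ch[3], k, 2L, 1L), new_bn(ch[3]), new_act("lrelu", sl),
      new_conv(ch[3], ch[4], k, 1L, 1L), new_bn(ch[4]), new_act("lrelu", sl),
      new_conv(ch[4], 1L, k, 1L, 1L))
    net <- new_network(layers, meta = list(cfg = cfg))
    class(net) <- c("petcycle_discriminator", class(net))
    net
  })
}

#' Trace the spatial size of the critic's score map
#'
#' @param disc a discriminator from [build_discriminator()].
#' @param h,w input height and width.
#' @return integer vector `c(h, w)` of the output score map.
#' @export
discriminator_trace <- function(disc, h, w) {
  for (l in disc$layers) {
    if (l$type != "conv") next
    h <- (h + 2L * l$pad - l$k) %/% l$stride + 1L
    w <- (w + 2L * l$pad - l$k) %/% l$stride + 1L
    if (h < 1L || w < 1L)
      stopf("input too small for the critic's convolution stack")
  }
  c(h, w)
}

#' Apply a discriminator, returning the raw patch score map
#'
#' @param disc a discriminator from [build_discriminator()].
#' @param x an `H x W` matrix or `1 x H x W x N` array.
#' @param mode `"train"` (batch statistics, default) or `"eval"`.
#' @return `1 x h x w x N` array of raw (unsquashed) critic scores.
#' @export
discriminator_forward <- function(disc, x, mode = "train") {
  if (length(dim(x)) == 2L) dim(x) <- c(1L, dim(x), 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  discriminator_trace(disc, dim(x)[2], dim(x)[3])   # errors if too small
  net_forward(disc, x, mode)$y
}

#' Structural audit of a network
#'
#' Summarises the architecture: for generators, the number of convolutions
#' outside residual and attention blocks, attention and residual block counts,
#' first-layer kernel size and output channels, and the output squashing; for
#' discriminators, the channel trace and activation slope.
#'
#' @param net a generator or discriminator.
#' @return a named list.
#' @export
network_audit <- function(net) {
  if (inherits(net, "petcycle_generator")) {
    types <- vapply(net$layers, function(l) l$type, "")
    convs <- net$layers[types %in% c("conv", "convT")]
    first <- net$layers[[1]]
    last_act <- net$layers[[length(net$layers)]]
    list(
      n_conv_outside_blocks = length(convs),
      n_cbam = sum(types == "cbam"),
      n_res_blocks = sum(types == "resblock"),
      first_kernel = first$k,
      first_out_channels = first$out_ch,
      output_activation = last_act$kind,
      n_parameters = count_parameters(net))
  } else if (inherits(net, "petcycle_discriminator")) {
    convs <- Filter(function(l) l$type == "conv", net$layers)
    slopes <- unique(vapply(Filter(function(l) l$type == "act", net$layers),
                            function(l) l$slope, 1))
    list(
      channel_trace = c(convs[[1]]$in_ch, vapply(convs, function(l) l$out_ch, 1L)),
      strides = vapply(convs, function(l) l$stride, 1L),
      kernel = convs[[1]]$k,
      leaky_slope = slopes,
      has_bn_first_stage = net$layers[[2]]$type == "bn",
      n_parameters = count_parameters(net))
  } else stopf("not a petcycle network")
}
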