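# Vectorized convolution primitives.
#
# Feature maps are numeric arrays with dim c(C, H, W, N) (channel fastest),
# so a matrix view dim c(C, H*W*N) puts one channel per row and the im2col
# gather / col2im scatter are plain vector indexing plus rowsum(), with the
# inner products delegated to BLAS via %*%.

.petcycle_idx_cache <- new.env(parent = emptyenv())

# im2col index map for a padded input of shape (C, Hp, Wp), kernel k, stride s.
# Rows ordered (c, ki, kj) with c fastest -- matching a weight array stored as
# dim c(Cout, Cin, k, k) flattened to a (Cout, Cin*k*k) matrix.
conv_index <- function(C, Hp, Wp, k, stride) {
  key <- paste(C, Hp, Wp, k, stride, sep = "x")
  hit <- .petcycle_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  if (Ho < 1L || Wo < 1L)
    stopf("input of size %dx%d too small for kernel %d at stride %d", Hp, Wp, k, stride)
  rowbase <- rep(0:(C - 1L), times = k * k) +
    rep(rep((0:(k - 1L)) * C, each = C), times = k) +
    rep((0:(k - 1L)) * C * Hp, each = C * k)
  colbase <- rep((0:(Ho - 1L)) * stride * C, times = Wo) +
    rep((0:(Wo - 1L)) * stride * C * Hp, each = Ho)
  idx <- outer(rowbase, colbase, "+") + 1L
  storage.mode(idx) <- "integer"
  idxvec <- as.vector(idx)
  su <- sort(unique(idxvec))
  out <- list(idx = idx, idxvec = idxvec, nrow = nrow(idx), ncol = ncol(idx),
              su = su, Ho = Ho, Wo = Wo)
  .petcycle_idx_cache[[key]] <- out
  out
}

reflect_seq <- function(n, p) {
  if (p == 0L) return(seq_len(n))
  if (n < p + 1L) stopf("cannot reflect-pad size %d by %d", n, p)
  c((p + 1L):2L, 1:n, (n - 1L):(n - p))
}

# Linear source map for reflection padding of one (C, H, W) sample.
reflect_src_index <- function(C, H, W, p) {
  key <- paste("r", C, H, W, p, sep = "x")
  hit <- .petcycle_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  hs <- reflect_seq(H, p)
  ws <- reflect_seq(W, p)
  src <- outer(C * (hs - 1L), C * H * (ws - 1L), "+")      # (Hp, Wp)
  src <- rep(0:(C - 1L), times = length(src)) + rep(as.vector(src), each = C) + 1L
  storage.mode(src) <- "integer"
  .petcycle_idx_cache[[key]] <- src
  src
}

pad_input <- function(x, p, mode = "zero") {
  d <- dim(x)
  if (p == 0L) return(x)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  if (mode == "zero") {
    out <- array(0, c(C, H + 2L * p, W + 2L * p, N))
    out[, (p + 1L):(p + H), (p + 1L):(p + W), ] <- x
    out
  } else {
    src <- reflect_src_index(C, H, W, p)
    m <- x; dim(m) <- c(C * H * W, N)
    out <- m[src, , drop = FALSE]
    dim(out) <- c(C, H + 2L * p, W + 2L * p, N)
    out
  }
}

# Adjoint of pad_input: fold a padded-size gradient back to input size.
unpad_grad <- function(dxp, p, mode, H, W) {
  d <- dim(dxp)
  if (p == 0L) return(dxp)
  C <- d[1]; N <- d[4]
  if (mode == "zero") {
    dxp[, (p + 1L):(p + H), (p + 1L):(p + W), , drop = FALSE]
  } else {
    src <- reflect_src_index(C, H, W, p)
    m <- dxp; dim(m) <- c(length(src), N)
    out <- rowsum(m, src)                      # rows sorted by source index
    dim(out) <- c(C, H, W, N)
    out
  }
}

im2col <- function(xp, ci) {
  d <- dim(xp); N <- d[4]
  m <- xp; dim(m) <- c(d[1] * d[2] * d[3], N)
  col <- m[ci$idxvec, , drop = FALSE]
  dim(col) <- c(ci$nrow, ci$ncol * N)
  col
}

col2im <- function(dcol, ci, C, Hp, Wp, N) {
  dim(dcol) <- c(ci$nrow * ci$ncol, N)
  acc <- rowsum(dcol, ci$idxvec)
  out <- matrix(0, C * Hp * Wp, N)
  out[ci$su, ] <- acc
  dim(out) <- c(C, Hp, Wp, N)
  out
}

# Forward convolution. w: dim c(Cout, Cin, k, k); b: length Cout or NULL.
conv2d_forward <- function(x, w, b, stride, pad, padmode = "zero") {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  k <- dim(w)[3]
  xp <- pad_input(x, pad, padmode)
  dp <- dim(xp)
  ci <- conv_index(C, dp[2], dp[3], k, stride)
  col <- im2col(xp, ci)
  wm <- w; dim(wm) <- c(dim(w)[1], C * k * k)
  y <- wm %*% col
  if (!is.null(b)) y <- y + b
  dim(y) <- c(dim(w)[1], ci$Ho, ci$Wo, N)
  list(y = y, cache = list(col = col, ci = ci, C = C, H = H, W = W, N = N,
                           Hp = dp[2], Wp = dp[3], stride = stride,
                           pad = pad, padmode = padmode, k = k))
}

# Backward convolution: returns dx and (if wanted) dw, db.
conv2d_backward <- function(dy, w, cache, need_param_grads = TRUE) {
  cc <- cache
  Cout <- dim(w)[1]
  dym <- dy; dim(dym) <- c(Cout, length(dy) / Cout)
  wm <- w; dim(wm) <- c(Cout, cc$C * cc$k * cc$k)
  dw <- db <- NULL
  if (need_param_grads) {
    dw <- tcrossprod(dym, cc$col)
    dim(dw) <- dim(w)
    db <- rowSums(dym)
  }
  dcol <- crossprod(wm, dym)
  dxp <- col2im(dcol, cc$ci, cc$C, cc$Hp, cc$Wp, cc$N)
  dx <- unpad_grad(dxp, cc$pad, cc$padmode, cc$H, cc$W)
  list(dx = dx, dw = dw, db = db)
}

# Transposed convolution with stride 2, kernel k, pad 1, output_padding 1:
# the adjoint of conv2d(k, stride = 2, pad = 1), so spatial size exactly
# doubles. w: dim c(Cin, Cout, k, k) (Cin is the small side).
convT2d_forward <- function(x, w, b, stride = 2L, pad = 1L, outpad = 1L) {
  d <- dim(x); Cin <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  k <- dim(w)[3]; Cout <- dim(w)[2]
  Hb <- stride * (H - 1L) + k - 2L * pad + outpad
  Wb <- stride * (W - 1L) + k - 2L * pad + outpad
  Hp <- Hb + 2L * pad; Wp <- Wb + 2L * pad
  ci <- conv_index(Cout, Hp, Wp, k, stride)
  if (ci$Ho != H || ci$Wo != W)
    stopf("transposed-conv shape trace mismatch (%d vs %d)", ci$Ho, H)
  xm <- x; dim(xm) <- c(Cin, H * W * N)
  wm <- w; dim(wm) <- c(Cin, Cout * k * k)
  dcol <- crossprod(wm, xm)
  yp <- col2im(dcol, ci, Cout, Hp, Wp, N)
  y <- yp[, (pad + 1L):(pad + Hb), (pad + 1L):(pad + Wb), , drop = FALSE]
  if (!is.null(b)) {
    ym <- y; dim(ym) <- c(Cout, length(y) / Cout)
    ym <- ym + b
    dim(ym) <- c(Cout, Hb, Wb, N)
    y <- ym
  }
  list(y = y, cache = list(xm = xm, ci = ci, Cin = Cin, Cout = Cout, k = k,
                           H = H, W = W, N = N, Hb = Hb, Wb = Wb, pad = pad))
}

convT2d_backward <- function(dy, w, cache, need_param_grads = TRUE) {
  cc <- cache
  dyp <- pad_input(dy, cc$pad, "zero")
  col <- im2col(dyp, cc$ci)
  wm <- w; dim(wm) <- c(cc$Cin, cc$Cout * cc$k * cc$k)
  dx <- wm %*% col
  dim(dx) <- c(cc$Cin, cc$H, cc$W, cc$N)
  dw <- db <- NULL
  if (need_param_grads) {
    dw <- tcrossprod(cc$xm, col)
    dim(dw) <- dim(w)
    dym <- dy; dim(dym) <- c(cc$Cout, length(dy) / cc$Cout)
    db <- rowSums(dym)
  }
  list(dx = dx, dw = dw, db = db)
}

# Separable Gaussian blur of one (H, W) image, reflected borders; sigma = 0
# is the identity. Used by the phantom degradation model.
gaussian_blur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  H <- nrow(img); W <- ncol(img)
  hs <- reflect_seq(H, r)
  ws <- reflect_seq(W, r)
  ext <- img[hs, , drop = FALSE]
  tmp <- matrix(0, H, W)
  for (i in seq_along(kern)) tmp <- tmp + kern[i] * ext[i:(i + H - 1L), , drop = FALSE]
  ext <- tmp[, ws, drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(kern)) out <- out + kern[i] * ext[, i:(i + W - 1L), drop = FALSE]
  out
}
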