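# Minimal dense NN primitives (internal): batched 2-D convolution via im2col
# with exact backward passes, and SGD-with-momentum parameter updates. All
# activations are stored channel-last: (batch, height, width, channels).

# Patch gather index for im2col: matrix [out_positions x k^2] of spatial flat
# indices into the zero-padded input. Column q enumerates kernel elements
# (row-major within the kernel), rows enumerate output pixels (h fastest).
conv_patch_index <- function(h, w, k, stride, pad) {
  hp <- h + 2L * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (w + 2L * pad - k) %/% stride + 1L
  i <- rep(seq_len(ho), times = wo)             # out row, fastest
  j <- rep(seq_len(wo), each = ho)              # out col
  h0 <- (i - 1L) * stride                       # top-left in padded coords (0-based)
  w0 <- (j - 1L) * stride
  pi <- matrix(0L, ho * wo, k * k)
  q <- 0L
  for (b in seq_len(k)) {                       # kernel col (slow)
    for (a in seq_len(k)) {                     # kernel row (fast)
      q <- q + 1L
      pi[, q] <- (h0 + a) + hp * (w0 + b - 1L)
    }
  }
  list(pi = pi, ho = ho, wo = wo, hp = hp, wp = w + 2L * pad)
}

conv_pad <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1L], d[2L] + 2L * pad, d[3L] + 2L * pad, d[4L]))
  xp[, pad + seq_len(d[2L]), pad + seq_len(d[3L]), ] <- x
  xp
}

# Forward convolution. x: (B,H,W,Cin); w: (k^2*Cin) x Cout; b: Cout.
conv_forward <- function(x, w, b, k, stride = 1L, pad = 0L, idx = NULL) {
  d <- dim(x)
  B <- d[1L]; cin <- d[4L]
  if (is.null(idx)) idx <- conv_patch_index(d[2L], d[3L], k, stride, pad)
  xp <- conv_pad(x, pad)
  dim(xp) <- c(B, idx$hp * idx$wp, cin)
  xcol <- xp[, as.vector(idx$pi), , drop = FALSE]   # (B, P*k2, Cin)
  dim(xcol) <- c(B * nrow(idx$pi), k * k * cin)
  y <- xcol %*% w
  y <- y + rep(b, each = nrow(y))
  dim(y) <- c(B, idx$ho, idx$wo, ncol(w))
  list(y = y, cache = list(xcol = xcol, idx = idx, k = k, cin = cin,
                           B = B, h = d[2L], w_in = d[3L], pad = pad))
}

# Backward convolution. dy: (B,Ho,Wo,Cout). Returns gradients wrt x, w, b.
conv_backward <- function(dy, w, cache) {
  idx <- cache$idx
  k2 <- cache$k^2
  P <- nrow(idx$pi)
  dim(dy) <- c(cache$B * P, ncol(w))
  dw <- crossprod(cache$xcol, dy)
  db <- colSums(dy)
  dxcol <- dy %*% t(w)                               # (B*P, k2*Cin)
  dim(dxcol) <- c(cache$B, P, k2, cache$cin)
  dxp <- array(0, dim = c(cache$B, idx$hp * idx$wp, cache$cin))
  for (q in seq_len(k2)) {
    cols <- idx$pi[, q]
    dxp[, cols, ] <- dxp[, cols, ] + dxcol[, , q, ]
  }
  dim(dxp) <- c(cache$B, idx$hp, idx$wp, cache$cin)
  pad <- cache$pad
  dx <- dxp[, pad + seq_len(cache$h), pad + seq_len(cache$w_in), , drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

# Flat list of numeric parameters <-> momentum buffers. params/grads are
# nested lists with identical shape; update is in-place functional.
sgd_momentum_step <- function(params, grads, velocity, lr, momentum = 0.9) {
  step <- function(p, g, v) {
    if (is.list(p)) {
      out <- Map(step, p, g, v)
      return(list(p = lapply(out, `[[`, "p"), v = lapply(out, `[[`, "v")))
    }
    v <- momentum * v - lr * g
    list(p = p + v, v = v)
  }
  out <- Map(step, params, grads, velocity)
  list(params = lapply(out, `[[`, "p"), velocity = lapply(out, `[[`, "v"))
}

zero_like <- function(params) {
  if (is.list(params)) lapply(params, zero_like) else params * 0
}

count_params <- function(params) {
  if (is.list(params)) sum(vapply(params, count_params, numeric(1))) else length(params)
}
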