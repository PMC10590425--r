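#' Causal dilated temporal convolution network configuration
#'
#' The fusion module: a stack of residual layers, each applying a causal
#' dilated convolution (kernel `kernel_size`, left zero-padding) followed by
#' ReLU and a 1x1 convolution, added back to the layer input. Dilations
#' double per layer; the default (k = 2, dilations 1..256 over 9 layers)
#' yields a receptive (inception) field of exactly 512 frames.
#'
#' @param num_layers Number of residual layers L.
#' @param kernel_size Convolution kernel size k (>= 2).
#' @param dilations Integer dilation per layer; must double strictly
#'   (`2^(0:(L-1))` by default).
#' @param channels Temporal embedding width d'.
#' @param input_dim Spatial embedding dimension d mapped to d' by a 1x1 input
#'   projection.
#' @return An object of class `tcn_config`.
#' @export
tcn_config <- function(num_layers = 9L, kernel_size = 2L,
                       dilations = 2L^(seq_len(num_layers) - 1L),
                       channels = 64L, input_dim = 32L) {
  if (kernel_size < 2L) stop("kernel_size must be >= 2", call. = FALSE)
  if (length(dilations) != num_layers) {
    stop("need one dilation per layer", call. = FALSE)
  }
  if (num_layers > 1L && any(dilations[-1L] != 2L * dilations[-num_layers])) {
    stop("dilations must double strictly layer over layer", call. = FALSE)
  }
  structure(list(num_layers = as.integer(num_layers),
                 kernel_size = as.integer(kernel_size),
                 dilations = as.integer(dilations),
                 channels = as.integer(channels),
                 input_dim = as.integer(input_dim)),
            class = "tcn_config")
}

#' Receptive field of a causal TCN
#'
#' Closed form `1 + (k - 1) * sum(dilations)`: the number of consecutive
#' input positions, ending at and including `t`, that can influence the
#' output at `t`. Equals 512 for the default configuration.
#'
#' @param config A [tcn_config()].
#' @return Integer receptive-field length in frames.
#' @export
receptive_field <- function(config) {
  1L + (config$kernel_size - 1L) * sum(config$dilations)
}

#' Initialise TCN weights
#'
#' @param config A [tcn_config()].
#' @param seed Integer seed.
#' @return Named list: `in_proj` (d -> d' projection) and `layers`, each with
#'   the dilated kernel `w1` (`k x d' x d'` array, last slice = current-frame
#'   tap), 1x1 weights `w2` and biases `b1`, `b2`.
#' @export
init_tcn <- function(config = tcn_config(), seed = 1L) {
  ch <- config$channels
  k <- config$kernel_size
  withr::with_seed(seed, {
    layers <- lapply(seq_len(config$num_layers), function(l) {
      w1 <- array(stats::rnorm(k * ch * ch, sd = sqrt(2 / (k * ch))),
                  dim = c(k, ch, ch))
      # small 1x1 init keeps the residual branch a perturbation of the
      # identity at the start of training (stable through many layers)
      list(w1 = w1, b1 = numeric(ch),
           w2 = init_weight(ch, ch, scale = 0.3 * sqrt(1 / ch)), b2 = numeric(ch))
    })
    list(in_proj = list(w = init_weight(config$input_dim, ch,
                                        scale = sqrt(1 / config$input_dim)),
                        b = numeric(ch)),
         layers = layers)
  })
}

# x shifted down by s rows with zero fill (causal left padding).
shift_down <- function(x, s) {
  if (s == 0L) return(x)
  n <- nrow(x)
  keep <- seq_len(max(0L, n - s))
  rbind(matrix(0, min(s, n), ncol(x)), x[keep, , drop = FALSE])
}

# adjoint of shift_down.
shift_up <- function(x, s) {
  if (s == 0L) return(x)
  n <- nrow(x)
  drop_ <- seq.int(min(s, n) + 1L, length.out = max(0L, n - s))
  rbind(x[drop_, , drop = FALSE], matrix(0, min(s, n), ncol(x)))
}

# Causal dilated convolution: y_t = sum_j x_{t - (k - j) * dil} %*% w1[j,,] + b1.
dilated_conv <- function(d, w1, b1, dilation) {
  k <- dim(w1)[1L]
  y <- matrix(0, nrow(d), dim(w1)[3L])
  for (j in seq_len(k)) {
    y <- y + shift_down(d, (k - j) * dilation) %*% w1[j, , ]
  }
  y + rep(b1, each = nrow(d))
}

#' One causal dilated residual layer
#'
#' Computes `D + conv1x1(ReLU(causal_dilated_conv(D)))`, with left
#' zero-padding of `(k - 1) * dilation` so the output at `t` depends only on
#' inputs at positions `<= t`. All-zero weights give the identity map.
#'
#' @param d Input matrix `T x d'`.
#' @param w Layer weights: list with `w1` (`k x d' x d'`), `b1`, `w2`
#'   (`d' x d'`), `b2` (as produced by [init_tcn()]).
#' @param dilation Dilation (>= 1).
#' @return Matrix `T x d'`.
#' @export
residual_layer <- function(d, w, dilation) {
  stopifnot(dilation >= 1L)
  a <- dilated_conv(d, w$w1, w$b1, dilation)
  d + relu(a) %*% w$w2 + rep(w$b2, each = nrow(d))
}

#' Run the TCN over a spatial embedding sequence
#'
#' Projects the `T x d` spatial embeddings to `d'` channels (1x1 input
#' projection) and applies the residual layers with doubling dilations. The
#' temporal embedding `m_t` depends only on spatial embeddings within the
#' receptive field ending at `t`.
#'
#' @param spatial Numeric matrix `T x d` of spatial embeddings.
#' @param config A [tcn_config()].
#' @param weights Weights from [init_tcn()] (or trained).
#' @return Numeric matrix `T x d'` of temporal embeddings.
#' @export
tcn_forward <- function(spatial, config, weights) {
  if (nrow(spatial) == 0L) stop("empty embedding sequence", call. = FALSE)
  d <- spatial %*% weights$in_proj$w + rep(weights$in_proj$b, each = nrow(spatial))
  for (l in seq_len(config$num_layers)) {
    d <- residual_layer(d, weights$layers[[l]], config$dilations[l])
  }
  d
}

# Forward with caches for backprop.
tcn_forward_cache <- function(spatial, config, weights) {
  d <- spatial %*% weights$in_proj$w + rep(weights$in_proj$b, each = nrow(spatial))
  caches <- vector("list", config$num_layers)
  for (l in seq_len(config$num_layers)) {
    w <- weights$layers[[l]]
    a <- dilated_conv(d, w$w1, w$b1, config$dilations[l])
    r <- relu(a)
    caches[[l]] <- list(d_in = d, a = a, r = r)
    d <- d + r %*% w$w2 + rep(w$b2, each = nrow(d))
  }
  list(m = d, caches = caches, spatial = spatial)
}

# Backward pass; returns weight gradients and gradient wrt spatial input.
tcn_backward <- function(dm, config, weights, fw) {
  k <- config$kernel_size
  layer_grads <- vector("list", config$num_layers)
  dd <- dm
  for (l in rev(seq_len(config$num_layers))) {
    w <- weights$layers[[l]]
    cache <- caches_l <- fw$caches[[l]]
    dil <- config$dilations[l]
    dr <- dd %*% t(w$w2)
    dw2 <- crossprod(cache$r, dd)
    db2 <- colSums(dd)
    da <- dr * (cache$a > 0)
    dw1 <- array(0, dim = dim(w$w1))
    dd_new <- dd  # residual branch
    for (j in seq_len(k)) {
      s <- (k - j) * dil
      dw1[j, , ] <- crossprod(shift_down(cache$d_in, s), da)
      dd_new <- dd_new + shift_up(da %*% t(w$w1[j, , ]), s)
    }
    layer_grads[[l]] <- list(w1 = dw1, b1 = colSums(da), w2 = dw2, b2 = db2)
    dd <- dd_new
  }
  list(grads = list(in_proj = list(w = crossprod(fw$spatial, dd),
                                   b = colSums(dd)),
                    layers = layer_grads),
       dspatial = dd %*% t(weights$in_proj$w))
}

#' Measure the dependency span of a TCN by input perturbation
#'
#' Empirical counterpart of [receptive_field()]: perturbs single input frames
#' at increasing lag behind a fixed output position and records whether the
#' output there changes. The measured span is `1 + max influencing lag`
#' (the current frame always influences through the residual path).
#'
#' @param config A [tcn_config()].
#' @param weights TCN weights (defaults to a fresh [init_tcn()] draw).
#' @param position Output position probed (default: last frame of a sequence
#'   of length `receptive_field(config) + margin`).
#' @param n_frames Sequence length used.
#' @param lags Integer lags (>= 1) to probe; default `1..position-1`.
#' @param delta Perturbation magnitude.
#' @param seed Seed for the random input sequence (and weights if drawn).
#' @return List with `span` (measured dependency span in frames),
#'   `influencing` (logical per probed lag) and `lags`.
#' @export
measure_dependency_span <- function(config, weights = NULL, position = NULL,
                                    n_frames = NULL, lags = NULL, delta = 100,
                                    seed = 1L) {
  if (is.null(weights)) weights <- init_tcn(config, seed = sub_seed(seed, "w"))
  if (is.null(n_frames)) n_frames <- receptive_field(config) + 8L
  if (is.null(position)) position <- n_frames
  spatial <- withr::with_seed(sub_seed(seed, "x"), {
    matrix(stats::rnorm(n_frames * config$input_dim), n_frames, config$input_dim)
  })
  base <- tcn_forward(spatial, config, weights)[position, ]
  if (is.null(lags)) lags <- seq_len(position - 1L)
  probe <- function(lag, dd) {
    pert <- spatial
    pert[position - lag, ] <- pert[position - lag, ] + dd
    any(tcn_forward(pert, config, weights)[position, ] != base)
  }
  influencing <- vapply(lags, function(lag) {
    # probe both signs: a one-sided bump can be swallowed by saturated ReLUs
    probe(lag, delta) || probe(lag, -delta)
  }, logical(1))
  span <- if (any(influencing)) 1L + max(lags[influencing]) else 1L
  list(span = span, influencing = influencing, lags = lags)
}
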