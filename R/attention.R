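#' Attention head configuration
#'
#' The prediction head: the frame's spatial embedding, reduced to `d'`
#' dimensions, queries a window of the `n` most recent temporal embeddings
#' with scaled dot-product attention; a final linear 4-way classifier maps
#' the attention output to phase logits and a softmax yields `p_t`.
#'
#' @param window Attention window n (>= 1): number of most recent temporal
#'   embeddings used as keys/values, capped at `t + 1` early in a stream.
#' @param d Spatial embedding dimension.
#' @param d_prime Temporal embedding dimension.
#' @return An object of class `head_config`.
#' @export
head_config <- function(window = 30L, d = 32L, d_prime = 64L) {
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  structure(list(window = as.integer(window), d = as.integer(d),
                 d_prime = as.integer(d_prime)),
            class = "head_config")
}

#' Initialise attention head weights
#'
#' @param config A [head_config()].
#' @param seed Integer seed.
#' @return Named list: `q_red` (d x d' query reduction), `wq`, `wk`, `wv`
#'   (d' x d' projections) and `cls` (linear classifier to 4 logits).
#' @export
init_head <- function(config = head_config(), seed = 1L) {
  dp <- config$d_prime
  withr::with_seed(seed, {
    list(q_red = init_weight(config$d, dp, scale = sqrt(1 / config$d)),
         wq = init_weight(dp, dp, scale = sqrt(1 / dp)),
         wk = init_weight(dp, dp, scale = sqrt(1 / dp)),
         wv = init_weight(dp, dp, scale = sqrt(1 / dp)),
         cls = list(w = init_weight(dp, 4L, scale = 0.1 * sqrt(1 / dp)),
                    b = numeric(4L)))
  })
}

#' Reduce a spatial embedding to query dimension
#'
#' Linear map `e_t -> e_hat_t` matching the temporal embedding dimension.
#'
#' @param e Numeric d-vector (or `T x d` matrix) of spatial embeddings.
#' @param weights Head weights from [init_head()].
#' @return d'-vector (or `T x d'` matrix).
#' @export
reduce_query <- function(e, weights) {
  if (is.matrix(e)) {
    if (ncol(e) != nrow(weights$q_red)) stop("query dimension mismatch", call. = FALSE)
    e %*% weights$q_red
  } else {
    if (length(e) != nrow(weights$q_red)) stop("query dimension mismatch", call. = FALSE)
    as.vector(e %*% weights$q_red)
  }
}

#' Scaled dot-product attention over a temporal window
#'
#' Scores `(W_q e_hat) . (W_k m_j) / sqrt(d')` over the window, softmax to
#' attention weights, output `sum_j alpha_j W_v m_j`, and phase probabilities
#' from the linear classifier plus softmax.
#'
#' @param e_hat Reduced query (d'-vector).
#' @param m_window Matrix `n_t x d'` of the most recent temporal embeddings,
#'   most recent last (`n_t = min(t + 1, n)`).
#' @param weights Head weights from [init_head()].
#' @return List with `output` (d'-vector), `attention` (weights summing to
#'   1) and `p` (4-vector of phase probabilities).
#' @export
attend <- function(e_hat, m_window, weights) {
  if (is.null(dim(m_window)) || nrow(m_window) == 0L) {
    stop("empty temporal window", call. = FALSE)
  }
  dp <- ncol(m_window)
  qq <- as.vector(weights$wq %*% e_hat)
  k <- m_window %*% t(weights$wk)
  v <- m_window %*% t(weights$wv)
  scores <- as.vector(k %*% qq) / sqrt(dp)
  alpha <- softmax(scores)
  output <- as.vector(crossprod(v, alpha))
  logits <- as.vector(crossprod(weights$cls$w, output)) + weights$cls$b
  list(output = output, attention = alpha, p = softmax(logits))
}

#' Turn phase probabilities into a hard phase label
#'
#' `argmax` mode returns the most probable phase (ties broken toward the
#' lowest canonical code). `youden` mode compares each phase probability to
#' its Youden-optimal threshold: among phases with `p_k >= threshold_k` the
#' one with the largest margin `p_k - threshold_k` wins; if none passes, the
#' argmax is used.
#'
#' @param p Probability 4-vector (nonnegative, summing to 1).
#' @param mode `"argmax"` or `"youden"`.
#' @param thresholds 4-vector of per-phase thresholds (required in youden
#'   mode; see [phase_metrics()]).
#' @return Phase name (character).
#' @export
predict_phase <- function(p, mode = c("argmax", "youden"), thresholds = NULL) {
  mode <- match.arg(mode)
  if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop("p must be a probability 4-vector", call. = FALSE)
  }
  if (mode == "youden") {
    if (is.null(thresholds) || length(thresholds) != 4L) {
      stop("youden mode needs a 4-vector of thresholds", call. = FALSE)
    }
    margin <- p - thresholds
    if (any(margin >= 0)) {
      masked <- ifelse(margin >= 0, margin, -Inf)
      return(esd_phases()[which.max(masked)])
    }
  }
  esd_phases()[which.max(p)]
}

# Vectorized attention over a whole sequence with a causal window mask.
# e_mat: T x d spatial embeddings; m: T x d' temporal embeddings.
attend_sequence <- function(e_mat, m, config, weights, with_cache = FALSE) {
  n <- config$window
  tt <- nrow(m)
  dp <- ncol(m)
  ehat <- e_mat %*% weights$q_red
  qq <- ehat %*% t(weights$wq)
  k <- m %*% t(weights$wk)
  v <- m %*% t(weights$wv)
  s <- tcrossprod(qq, k) / sqrt(dp)
  row_t <- matrix(seq_len(tt), tt, tt)
  col_j <- matrix(seq_len(tt), tt, tt, byrow = TRUE)
  mask <- col_j <= row_t & col_j > row_t - n
  s[!mask] <- -Inf
  a <- softmax_rows(s)
  o <- a %*% v
  logits <- o %*% weights$cls$w + rep(weights$cls$b, each = tt)
  p <- softmax_rows(logits)
  res <- list(p = p, logits = logits)
  if (with_cache) {
    res$cache <- list(ehat = ehat, qq = qq, k = k, v = v, a = a, o = o,
                      e_mat = e_mat, m = m, dp = dp)
  }
  res
}

# Backward through attend_sequence given dlogits; returns head gradients and
# gradient wrt the temporal embeddings m.
attend_sequence_backward <- function(dlogits, weights, cache) {
  o <- cache$o
  dcls_w <- crossprod(o, dlogits)
  dcls_b <- colSums(dlogits)
  do <- dlogits %*% t(weights$cls$w)
  da <- do %*% t(cache$v)
  dv <- crossprod(cache$a, do)
  ds <- cache$a * (da - rowSums(cache$a * da))
  scale <- 1 / sqrt(cache$dp)
  dqq <- (ds %*% cache$k) * scale
  dk <- crossprod(ds, cache$qq) * scale
  dm <- dk %*% weights$wk + dv %*% weights$wv
  dwk <- crossprod(dk, cache$m)
  dwv <- crossprod(dv, cache$m)
  dehat <- dqq %*% weights$wq
  dwq <- crossprod(dqq, cache$ehat)
  dq_red <- crossprod(cache$e_mat, dehat)
  list(grads = list(q_red = dq_red, wq = dwq, wk = dwk, wv = dwv,
                    cls = list(w = dcls_w, b = dcls_b)),
       dm = dm)
}
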