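#' Spatial encoder configuration
#'
#' Configuration of the frame-wise feature extractor: a small strided
#' convolutional backbone (default) producing a `embedding_dim`-dimensional
#' embedding per frame, a two-layer projection head used only by the
#' supervised-contrastive loss, and a linear 4-way classifier used only by the
#' cross-entropy loss. Both heads are pruned away after stage-1 training.
#'
#' `contrastive_denominator` selects how the contrastive normaliser is formed:
#' `"paper_literal"` sums over different-phase samples only, `"all_others"`
#' over every non-anchor sample (the common supervised-contrastive choice).
#' The two losses differ: the literal form can be negative once positives are
#' more similar than negatives, the all-others form is nonnegative with a
#' single positive.
#'
#' @param backbone Backbone identifier; `"small-conv"` (four strided 3x3
#'   convolution blocks) is the desk-scale default.
#' @param embedding_dim Dimension d of the frame embedding.
#' @param proj_widths Two integers: hidden and output width of the projection
#'   head.
#' @param temperature Contrastive temperature tau (> 0).
#' @param contrastive_denominator `"paper_literal"` or `"all_others"`.
#' @param input_size Expected frame height/width in pixels (frames must be
#'   square multiples of 16 for the default backbone).
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(backbone = "small-conv", embedding_dim = 32L,
                           proj_widths = c(32L, 16L), temperature = 0.1,
                           contrastive_denominator = c("paper_literal", "all_others"),
                           input_size = 64L) {
  contrastive_denominator <- match.arg(contrastive_denominator)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (embedding_dim < 2L) stop("embedding_dim must be >= 2", call. = FALSE)
  stopifnot(length(proj_widths) == 2L, all(proj_widths >= 1L))
  backbone <- match.arg(backbone, c("small-conv"))
  structure(list(backbone = backbone, embedding_dim = as.integer(embedding_dim),
                 proj_widths = as.integer(proj_widths), temperature = temperature,
                 contrastive_denominator = contrastive_denominator,
                 input_size = as.integer(input_size)),
            class = "encoder_config")
}

#' Initialise a spatial encoder
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `esd_encoder` holding backbone, projection-head
#'   and classifier weights; `pruned = FALSE`.
#' @export
init_encoder <- function(config = encoder_config(), seed = 1L) {
  d <- config$embedding_dim
  channels <- c(3L, 8L, 16L, 32L, d)
  k <- 3L
  weights <- withr::with_seed(seed, {
    conv <- lapply(seq_len(4L), function(l) {
      fan_in <- k * k * channels[l]
      list(w = init_weight(fan_in, channels[l + 1L]),
           b = numeric(channels[l + 1L]))
    })
    p1 <- config$proj_widths[1L]
    p2 <- config$proj_widths[2L]
    list(conv = conv,
         proj = list(w1 = init_weight(d, p1), b1 = numeric(p1),
                     w2 = init_weight(p1, p2), b2 = numeric(p2)),
         cls = list(w = init_weight(d, 4L, scale = sqrt(1 / d)), b = numeric(4L)))
  })
  structure(list(config = config, weights = weights, pruned = FALSE,
                 loss_history = NULL),
            class = "esd_encoder")
}

#' @export
print.esd_encoder <- function(x, ...) {
  cat("<esd_encoder>", x$config$backbone, "d =", x$config$embedding_dim,
      if (x$pruned) "(pruned)" else "(with heads)",
      "-", count_params(x$weights), "parameters\n")
  invisible(x)
}

# Backbone forward. x: (B,H,W,3) doubles in [0,1]. Returns embeddings (B x d)
# and, if with_cache, everything needed for the backward pass.
backbone_forward <- function(encoder, x, with_cache = FALSE) {
  x <- x - 0.5
  caches <- vector("list", 4L)
  act <- x
  for (l in seq_len(4L)) {
    wl <- encoder$weights$conv[[l]]
    out <- conv_forward(act, wl$w, wl$b, k = 3L, stride = 2L, pad = 1L)
    pre <- out$y
    act <- if (l < 4L) relu(pre) else pre
    if (with_cache) caches[[l]] <- c(out["cache"], list(pre = pre))
  }
  d <- dim(act)
  spatial <- d[2L] * d[3L]
  dim(act) <- c(d[1L], spatial, d[4L])
  e <- apply(act, c(1L, 3L), mean)
  dim(e) <- c(d[1L], d[4L])
  if (with_cache) {
    list(e = e, caches = caches, out_dim = d)
  } else {
    list(e = e)
  }
}

backbone_backward <- function(encoder, de, fw) {
  d <- fw$out_dim
  spatial <- d[2L] * d[3L]
  # undo mean pool: spread gradient uniformly over spatial positions
  dact <- array(0, dim = c(d[1L], spatial, d[4L]))
  for (c_i in seq_len(d[4L])) {
    dact[, , c_i] <- matrix(de[, c_i] / spatial, d[1L], spatial)
  }
  dim(dact) <- d
  grads <- vector("list", 4L)
  for (l in rev(seq_len(4L))) {
    cache <- fw$caches[[l]]
    if (l < 4L) dact <- dact * (cache$pre > 0)
    bw <- conv_backward(dact, encoder$weights$conv[[l]]$w, cache$cache)
    grads[[l]] <- list(w = bw$dw, b = bw$db)
    dact <- bw$dx
  }
  grads
}

# Coerce video_stream / (T,H,W,3) / (H,W,3) input to a double array in [0,1].
frames_to_array <- function(frames) {
  if (inherits(frames, "video_stream")) frames <- frames$frames
  d <- dim(frames)
  if (length(d) == 3L) {
    dim(frames) <- c(1L, d)
    d <- dim(frames)
  }
  if (length(d) != 4L || d[4L] != 3L) {
    stop("frames must be (T,H,W,3) or (H,W,3)", call. = FALSE)
  }
  if (max(frames) > 1) frames <- frames / 255
  frames
}

#' Embed video frames into spatial feature vectors
#'
#' Runs the backbone in evaluation mode: one d-vector per frame,
#' deterministic for a given encoder. Heads (when present) are not involved,
#' so pruned and unpruned encoders produce identical embeddings.
#'
#' @param encoder An [init_encoder()] (trained or not).
#' @param frames A [video_stream()], a `(T,H,W,3)` array, or a single
#'   `(H,W,3)` frame; 8-bit values or already scaled to \[0,1\].
#' @param batch_size Frames per forward pass (memory control).
#' @return Numeric matrix `T x d` of spatial embeddings.
#' @export
embed_frames <- function(encoder, frames, batch_size = 256L) {
  x <- frames_to_array(frames)
  n <- dim(x)[1L]
  if (n == 0L) stop("no frames to embed", call. = FALSE)
  if (dim(x)[2L] %% 16L != 0L || dim(x)[3L] %% 16L != 0L) {
    stop("frame size must be a multiple of 16 for the small-conv backbone",
         call. = FALSE)
  }
  out <- matrix(0, n, encoder$config$embedding_dim)
  starts <- seq.int(1L, n, by = batch_size)
  for (s in starts) {
    e <- min(s + batch_size - 1L, n)
    out[s:e, ] <- backbone_forward(encoder, x[s:e, , , , drop = FALSE])$e
  }
  out
}

# Projection head forward: e (B x d) -> normalized z (B x p2) + cache.
projection_forward <- function(encoder, e) {
  pw <- encoder$weights$proj
  h_pre <- e %*% pw$w1 + rep(pw$b1, each = nrow(e))
  h <- relu(h_pre)
  v <- h %*% pw$w2 + rep(pw$b2, each = nrow(e))
  r <- sqrt(rowSums(v^2))
  r[r == 0] <- 1
  z <- v / r
  list(z = z, v = v, r = r, h = h, h_pre = h_pre, e = e)
}

projection_backward <- function(encoder, dz, fw) {
  pw <- encoder$weights$proj
  # through row normalization z = v / |v|
  dv <- (dz - fw$z * rowSums(fw$z * dz)) / fw$r
  dw2 <- crossprod(fw$h, dv)
  db2 <- colSums(dv)
  dh <- (dv %*% t(pw$w2)) * (fw$h_pre > 0)
  dw1 <- crossprod(fw$e, dh)
  db1 <- colSums(dh)
  de <- dh %*% t(pw$w1)
  list(grads = list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2), de = de)
}

#' Supervised contrastive loss over a batch of embeddings
#'
#' For each anchor `i` with at least one same-phase partner `A(i)` and one
#' different-phase sample `N(i)`, the loss averages
#' `-log( exp(z_i . z_n / tau) / sum_{a in D(i)} exp(z_i . z_a / tau) )` over
#' positives `n in A(i)`, and then averages over counted anchors. The
#' denominator set `D(i)` is `N(i)` under `"paper_literal"` and
#' `A(i) union N(i)` under `"all_others"`. Embedding rows are expected to be
#' unit-normalised.
#'
#' @param embeddings Numeric matrix `B x p` of (unit) embeddings.
#' @param labels Phase labels (character or 0..3 codes), length B.
#' @param tau Temperature (> 0).
#' @param denominator `"paper_literal"` or `"all_others"`.
#' @return Scalar loss.
#' @export
supcon_loss <- function(embeddings, labels, tau = 0.1,
                        denominator = c("paper_literal", "all_others")) {
  supcon_loss_grad(embeddings, labels, tau, match.arg(denominator),
                   want_grad = FALSE)$loss
}

# Loss plus gradient wrt the (normalized) embeddings; strict = error when no
# anchor is counted (exported loss), lenient = return 0 (training path).
supcon_loss_grad <- function(z, labels, tau, denominator, want_grad = TRUE,
                             strict = TRUE) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  y <- if (is.numeric(labels)) as.integer(labels) else phase_code(labels)
  B <- nrow(z)
  if (length(y) != B) stop("labels length must match embedding rows", call. = FALSE)
  same <- outer(y, y, "==")
  diag(same) <- FALSE
  diff <- outer(y, y, "!=")
  counted <- rowSums(same) > 0 & rowSums(diff) > 0
  if (!any(counted)) {
    if (strict) stop("no valid anchors: batch needs at least two phases",
                     call. = FALSE)
    return(list(loss = 0, dz = if (want_grad) z * 0))
  }
  s <- tcrossprod(z) / tau
  dmask <- if (denominator == "paper_literal") diff else (same | diff)
  sm <- s
  sm[!dmask] <- -Inf
  mrow <- apply(sm, 1L, max)
  ex <- exp(sm - mrow)
  denom <- rowSums(ex)
  log_denom <- mrow + log(denom)
  n_a <- rowSums(same)
  pos_mean <- rowSums(s * same) / pmax(n_a, 1L)
  li <- -pos_mean + log_denom
  n_counted <- sum(counted)
  loss <- sum(li[counted]) / n_counted
  if (!want_grad) return(list(loss = loss))
  p <- ex / denom                    # softmax over D(i), zero elsewhere
  ds <- matrix(0, B, B)
  cw <- which(counted)
  ds[cw, ] <- (p[cw, , drop = FALSE] -
                 same[cw, , drop = FALSE] / n_a[cw]) / n_counted
  dz <- ((ds + t(ds)) %*% z) / tau
  list(loss = loss, dz = dz)
}

#' Cross-entropy loss for 4-way phase logits
#'
#' Mean negative log-likelihood of the true phase after a softmax over the
#' four logits.
#'
#' @param logits Numeric matrix `B x 4`.
#' @param labels Phase labels (character or 0..3 codes), length B.
#' @return Scalar loss (`>= 0`).
#' @export
ce_loss <- function(logits, labels) {
  ce_loss_grad(logits, labels, want_grad = FALSE)$loss
}

ce_loss_grad <- function(logits, labels, want_grad = TRUE) {
  if (!all(is.finite(logits))) stop("logits must be finite", call. = FALSE)
  y <- if (is.numeric(labels)) as.integer(labels) else phase_code(labels)
  if (any(!y %in% 0:3)) stop("labels must code phases 0..3", call. = FALSE)
  B <- nrow(logits)
  if (length(y) != B) stop("labels length must match logits rows", call. = FALSE)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(B), y + 1L)
  loss <- -mean(log(p[idx]))
  if (!want_grad) return(list(loss = loss))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / B)
}

#' Stage-1 training of the spatial encoder
#'
#' Minimises the combined objective `L = L_con + L_ce` over frames sampled
#' uniformly from the labelled cases, by SGD with momentum 0.9 under the
#' given schedule (learning rate divided by `drop_factor` at `lr_drop_iter`).
#' Deterministic given `seed`.
#'
#' @param cases List of `esd_case` objects (each with a rendered `video` and
#'   `track`), or list of `list(video=, track=)`.
#' @param config An [encoder_config()].
#' @param schedule Stage-1 schedule, e.g. `train_schedule("desk")$stage1`.
#' @param seed Integer seed (initialisation and batch sampling).
#' @return A trained `esd_encoder` with a `loss_history` data frame
#'   (`iteration`, `loss`, `loss_con`, `loss_ce`).
#' @export
train_stage1 <- function(cases, config = encoder_config(),
                         schedule = train_schedule("desk")$stage1, seed = 1L) {
  if (length(cases) == 0L) stop("no training cases", call. = FALSE)
  videos <- lapply(cases, function(cs) frames_to_array(cs$video))
  labels <- lapply(cases, function(cs) phase_code(cs$track$labels))
  if (length(unique(unlist(labels))) < 2L) {
    stop("training data must contain at least two phases", call. = FALSE)
  }
  frame_case <- rep(seq_along(videos), vapply(videos, function(v) dim(v)[1L], 0L))
  frame_idx <- unlist(lapply(videos, function(v) seq_len(dim(v)[1L])))
  n_pool <- length(frame_case)
  encoder <- init_encoder(config, seed = sub_seed(seed, "enc-init"))
  params <- encoder$weights
  velocity <- zero_like(params)
  history <- matrix(0, schedule$iterations, 3L)
  withr::with_seed(sub_seed(seed, "stage1-batches"), {
    for (it in seq_len(schedule$iterations)) {
      lr <- schedule$lr / ifelse(it > schedule$lr_drop_iter, schedule$drop_factor, 1)
      pick <- sample.int(n_pool, schedule$batch_size, replace = n_pool < schedule$batch_size)
      x <- array(0, dim = c(length(pick), dim(videos[[1L]])[2L],
                            dim(videos[[1L]])[3L], 3L))
      yb <- integer(length(pick))
      for (b in seq_along(pick)) {
        cs <- frame_case[pick[b]]
        x[b, , , ] <- videos[[cs]][frame_idx[pick[b]], , , ]
        yb[b] <- labels[[cs]][frame_idx[pick[b]]]
      }
      encoder$weights <- params
      fw <- backbone_forward(encoder, x, with_cache = TRUE)
      pf <- projection_forward(encoder, fw$e)
      con <- supcon_loss_grad(pf$z, yb, config$temperature,
                              config$contrastive_denominator, strict = FALSE)
      logits <- fw$e %*% params$cls$w + rep(params$cls$b, each = nrow(fw$e))
      ce <- ce_loss_grad(logits, yb)
      pb <- projection_backward(encoder, con$dz, pf)
      de <- pb$de + ce$dlogits %*% t(params$cls$w)
      conv_grads <- backbone_backward(encoder, de, fw)
      grads <- list(conv = conv_grads,
                    proj = pb$grads,
                    cls = list(w = crossprod(fw$e, ce$dlogits),
                               b = colSums(ce$dlogits)))
      upd <- sgd_momentum_step(params, grads, velocity, lr, schedule$momentum)
      params <- upd$params
      velocity <- upd$velocity
      history[it, ] <- c(con$loss + ce$loss, con$loss, ce$loss)
    }
  })
  encoder$weights <- params
  encoder$loss_history <- data.frame(iteration = seq_len(schedule$iterations),
                                     loss = history[, 1L],
                                     loss_con = history[, 2L],
                                     loss_ce = history[, 3L])
  encoder
}

#' Prune the projection and classifier heads from a trained encoder
#'
#' Removes the two projection-head linear layers (and the stage-1 classifier)
#' for deployment, leaving only the backbone. Backbone weights are untouched,
#' so embeddings are identical before and after pruning.
#'
#' @param encoder An unpruned `esd_encoder`.
#' @return The encoder with heads removed and `pruned = TRUE`.
#' @export
prune_heads <- function(encoder) {
  if (isTRUE(encoder$pruned)) stop("encoder is already pruned", call. = FALSE)
  encoder$weights$proj <- NULL
  encoder$weights$cls <- NULL
  encoder$pruned <- TRUE
  encoder
}

#' Number of parameters of an encoder or weight list
#'
#' @param x An `esd_encoder` or nested list of numeric parameters.
#' @return Integer parameter count.
#' @export
n_parameters <- function(x) {
  if (inherits(x, "esd_encoder")) x <- x$weights
  count_params(x)
}
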