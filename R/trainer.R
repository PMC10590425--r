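#' Two-stage training schedule
#'
#' The `"paper"` preset is the full clinical-scale schedule: stage 1 (spatial
#' encoder) 8000 iterations, batch 128, learning rate 5e-4 divided by 10
#' after 6000 iterations; stage 2 (TCN + attention head) 4000 iterations,
#' learning rate 5e-3 divided by 10 at iterations 1500 and 2500; SGD with
#' momentum 0.9 throughout. The `"desk"` preset scales iteration counts down
#' by ~25x (stage 1: 300 iterations, batch 32; stage 2: 160 iterations) with
#' learning rates re-tuned for the small backbone, so the full pipeline runs
#' in minutes on one CPU. Stage 2 clips the global gradient norm at
#' `clip_norm` (whole-video sequences occasionally produce outlier
#' gradients).
#'
#' @param preset `"desk"` or `"paper"`.
#' @return Named list with `stage1` and `stage2` schedules.
#' @export
train_schedule <- function(preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    list(stage1 = list(iterations = 8000L, batch_size = 128L, lr = 5e-4,
                       lr_drop_iter = 6000L, drop_factor = 10, momentum = 0.9),
         stage2 = list(iterations = 4000L, lr = 5e-3,
                       lr_drop_iters = c(1500L, 2500L), drop_factor = 10,
                       momentum = 0.9, clip_norm = 5))
  } else {
    list(stage1 = list(iterations = 300L, batch_size = 32L, lr = 0.002,
                       lr_drop_iter = 225L, drop_factor = 10, momentum = 0.9),
         stage2 = list(iterations = 160L, lr = 0.005,
                       lr_drop_iters = c(60L, 100L), drop_factor = 10,
                       momentum = 0.9, clip_norm = 5))
  }
}

#' Chronological k-fold assignment
#'
#' Cases are arranged in chronological order and sampled at k equal
#' intervals: the case at chronological position `i` (0-based) goes to fold
#' `i mod k`. Fold sizes differ by at most one and every fold spans the full
#' date range — 47 cases at k = 5 give sizes 10, 10, 9, 9, 9.
#'
#' @param cases List of `esd_case` objects, or a data frame / list with a
#'   `date` per case.
#' @param k Number of folds (>= 2).
#' @return Integer vector of fold indices (1..k), aligned with the input
#'   order and named by case id when available.
#' @export
chronological_folds <- function(cases, k = 5L) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (is.data.frame(cases)) {
    dates <- as.Date(cases$date)
    ids <- cases$case_id
  } else {
    dates <- as.Date(vapply(cases, function(cs) as.character(cs$metadata$date), ""))
    ids <- vapply(cases, function(cs) cs$metadata$case_id %||% "", "")
  }
  n <- length(dates)
  if (n < k) stop("need at least k cases (", n, " < ", k, ")", call. = FALSE)
  k <- as.integer(k)
  ord <- order(dates)
  fold <- integer(n)
  fold[ord] <- (seq_len(n) - 1L) %% k + 1L
  if (!is.null(ids) && all(nzchar(ids))) names(fold) <- ids
  fold
}

#' Bundle a pruned encoder with temporal model weights
#'
#' @param encoder A pruned `esd_encoder`.
#' @param tcn_config,tcn_weights TCN configuration and weights.
#' @param head_config,head_weights Attention head configuration and weights.
#' @return An object of class `model_bundle`.
#' @export
model_bundle <- function(encoder, tcn_config, tcn_weights, head_config,
                         head_weights) {
  if (encoder$config$embedding_dim != tcn_config$input_dim) {
    stop("encoder embedding_dim (", encoder$config$embedding_dim,
         ") does not match TCN input_dim (", tcn_config$input_dim, ")",
         call. = FALSE)
  }
  if (head_config$d != encoder$config$embedding_dim) {
    stop("head query dimension does not match encoder embedding_dim", call. = FALSE)
  }
  if (head_config$d_prime != tcn_config$channels) {
    stop("head d' (", head_config$d_prime, ") does not match TCN channels (",
         tcn_config$channels, ")", call. = FALSE)
  }
  structure(list(encoder = encoder, tcn_config = tcn_config,
                 tcn_weights = tcn_weights, head_config = head_config,
                 head_weights = head_weights),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("<model_bundle> d =", x$encoder$config$embedding_dim,
      "d' =", x$tcn_config$channels,
      "receptive field =", receptive_field(x$tcn_config),
      "window =", x$head_config$window, "\n")
  invisible(x)
}

#' Stage-2 training of the temporal model
#'
#' With the pruned stage-1 encoder frozen, precomputes the spatial embeddings
#' of every training video once, then optimises the TCN and attention head
#' end-to-end: each iteration consumes all consecutive frames of one video
#' and minimises the per-frame cross-entropy of `p_t` by SGD with momentum.
#' Deterministic given `seed`; the encoder is returned bit-identical.
#'
#' @param encoder A pruned `esd_encoder` (stage-1 trained).
#' @param cases List of `esd_case` objects with videos and tracks.
#' @param tcn_config A [tcn_config()] (its `input_dim` must equal the encoder
#'   embedding dimension).
#' @param head_cfg A [head_config()].
#' @param schedule Stage-2 schedule, e.g. `train_schedule("desk")$stage2`.
#' @param seed Integer seed.
#' @return A [model_bundle()] with a `loss_history` attribute.
#' @export
train_stage2 <- function(encoder, cases, tcn_config = NULL, head_cfg = NULL,
                         schedule = train_schedule("desk")$stage2, seed = 1L) {
  if (!isTRUE(encoder$pruned)) {
    stop("stage 2 requires a pruned (frozen) encoder; call prune_heads()",
         call. = FALSE)
  }
  if (length(cases) == 0L) stop("no training cases", call. = FALSE)
  d <- encoder$config$embedding_dim
  if (is.null(tcn_config)) tcn_config <- tcn_config(input_dim = d)
  if (is.null(head_cfg)) {
    head_cfg <- head_config(d = d, d_prime = tcn_config$channels)
  }
  emb <- lapply(cases, function(cs) embed_frames(encoder, cs$video))
  lab <- lapply(cases, function(cs) phase_code(cs$track$labels))
  params <- list(tcn = init_tcn(tcn_config, seed = sub_seed(seed, "tcn")),
                 head = init_head(head_cfg, seed = sub_seed(seed, "head")))
  velocity <- zero_like(params)
  history <- numeric(schedule$iterations)
  withr::with_seed(sub_seed(seed, "stage2-batches"), {
    for (it in seq_len(schedule$iterations)) {
      lr <- schedule$lr / schedule$drop_factor^sum(it > schedule$lr_drop_iters)
      ci <- sample.int(length(cases), 1L)
      e_mat <- emb[[ci]]
      fw <- tcn_forward_cache(e_mat, tcn_config, params$tcn)
      at <- attend_sequence(e_mat, fw$m, head_cfg, params$head, with_cache = TRUE)
      ce <- ce_loss_grad(at$logits, lab[[ci]])
      ab <- attend_sequence_backward(ce$dlogits, params$head, at$cache)
      tb <- tcn_backward(ab$dm, tcn_config, params$tcn, fw)
      grads <- list(tcn = tb$grads, head = ab$grads)
      clip <- schedule$clip_norm %||% Inf
      if (is.finite(clip)) {
        gnorm <- sqrt(sum(unlist(grads, use.names = FALSE)^2))
        if (gnorm > clip) grads <- rapply(grads, function(g) g * (clip / gnorm),
                                          how = "replace")
      }
      upd <- sgd_momentum_step(params, grads, velocity, lr, schedule$momentum)
      params <- upd$params
      velocity <- upd$velocity
      history[it] <- ce$loss
    }
  })
  bundle <- model_bundle(encoder, tcn_config, params$tcn, head_cfg, params$head)
  attr(bundle, "loss_history") <- data.frame(iteration = seq_along(history),
                                             loss = history)
  bundle
}

#' Train the full two-stage model on a set of cases
#'
#' Stage 1 (contrastive + cross-entropy encoder training), head pruning, then
#' stage 2 (TCN + attention head). This is also the `train-final` path used
#' to retrain on the entire developmental dataset once hyperparameters are
#' frozen.
#'
#' @param cases List of `esd_case` objects.
#' @param enc_config An [encoder_config()].
#' @param tcn_cfg,head_cfg Temporal model configurations (defaults derived
#'   from `enc_config`).
#' @param schedule Full schedule from [train_schedule()].
#' @param seed Integer seed.
#' @return A [model_bundle()].
#' @export
train_phase_model <- function(cases, enc_config = encoder_config(),
                              tcn_cfg = NULL, head_cfg = NULL,
                              schedule = train_schedule("desk"), seed = 1L) {
  encoder <- train_stage1(cases, enc_config, schedule$stage1,
                          seed = sub_seed(seed, "s1"))
  encoder <- prune_heads(encoder)
  train_stage2(encoder, cases, tcn_cfg, head_cfg, schedule$stage2,
               seed = sub_seed(seed, "s2"))
}

#' Chronological cross-validation of the full pipeline
#'
#' Assigns cases to k chronological folds, trains the two-stage model on
#' k - 1 folds and predicts the held-out fold, rotating over folds. Emits
#' per-case prediction tracks and pooled metrics.
#'
#' @param cases List of `esd_case` objects.
#' @param k Number of folds.
#' @param enc_config,tcn_cfg,head_cfg Model configurations (see
#'   [train_phase_model()]).
#' @param schedule Full [train_schedule()].
#' @param seed Integer seed (one sub-seed per fold).
#' @return List with `folds` (assignment), `predictions` (named list of
#'   prediction tracks), `truth` (named list of annotation tracks) and
#'   `metrics` (pooled confusion matrix, accuracy/precision/recall and
#'   per-phase AUROC; see [evaluate_cases()]).
#' @export
run_cross_validation <- function(cases, k = 5L, enc_config = encoder_config(),
                                 tcn_cfg = NULL, head_cfg = NULL,
                                 schedule = train_schedule("desk"), seed = 1L) {
  folds <- chronological_folds(cases, k)
  ids <- vapply(cases, function(cs) cs$track$case_id, "")
  predictions <- stats::setNames(vector("list", length(cases)), ids)
  for (fold in seq_len(k)) {
    train_cases <- cases[folds != fold]
    test_cases <- cases[folds == fold]
    bundle <- train_phase_model(train_cases, enc_config, tcn_cfg, head_cfg,
                                schedule, seed = sub_seed(seed, paste0("fold", fold)))
    for (cs in test_cases) {
      predictions[[cs$track$case_id]] <- offline_predict(cs$video, bundle)
    }
  }
  truth <- stats::setNames(lapply(cases, `[[`, "track"), ids)
  list(folds = folds, predictions = predictions, truth = truth,
       metrics = evaluate_cases(predictions, truth))
}
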