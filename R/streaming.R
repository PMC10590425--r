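#' Per-frame phase prediction track
#'
#' @param case_id Case identifier.
#' @param fps Frame rate.
#' @param probs Numeric matrix `T x 4` of phase probabilities (rows on the
#'   simplex), columns in canonical phase order.
#' @param labels Optional character labels; defaults to the per-row argmax.
#' @param latency_ms Optional data frame of per-frame stage latencies.
#' @return An object of class `prediction_track`.
#' @export
prediction_track <- function(case_id, fps, probs, labels = NULL,
                             latency_ms = NULL) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 4L)
  colnames(probs) <- esd_phases()
  if (nrow(probs) > 0L &&
      (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-6))) {
    stop("probability rows must be nonnegative and sum to 1", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- esd_phases()[max.col(probs, ties.method = "first")]
  }
  phase_code(labels)
  structure(list(case_id = case_id, fps = fps, probs = probs,
                 labels = as.character(labels), latency_ms = latency_ms),
            class = "prediction_track")
}

#' @export
print.prediction_track <- function(x, ...) {
  cat("<prediction_track>", x$case_id, "-", nrow(x$probs), "frames @", x$fps,
      "fps\n")
  invisible(x)
}

#' @export
length.prediction_track <- function(x) nrow(x$probs)

#' Offline (batch) prediction over a whole video
#'
#' Embeds all frames, runs the full causal TCN over the entire sequence and
#' applies the attention head per frame. Because every component is causal,
#' this is the reference implementation that streaming inference must
#' reproduce frame by frame.
#'
#' @param video A [video_stream()] or `(T,H,W,3)` array.
#' @param bundle A [model_bundle()].
#' @return A [prediction_track()].
#' @export
offline_predict <- function(video, bundle) {
  case_id <- if (inherits(video, "video_stream")) video$case_id else "video"
  fps <- if (inherits(video, "video_stream")) video$fps else 1
  e_mat <- embed_frames(bundle$encoder, video)
  m <- tcn_forward(e_mat, bundle$tcn_config, bundle$tcn_weights)
  at <- attend_sequence(e_mat, m, bundle$head_config, bundle$head_weights)
  prediction_track(case_id, fps, at$p)
}

#' Initialise a streaming inference state
#'
#' Creates the bounded-memory online inference state: an empty FIFO queue
#' that will hold at most R spatial embeddings (R = the TCN receptive field,
#' 512 by default) plus a ring buffer of the last `n` temporal embeddings for
#' the attention window. Memory is independent of stream length.
#'
#' @param bundle A [model_bundle()] (dimension consistency is re-checked).
#' @return An environment of class `stream_state` with fields `t` (index of
#'   the last pushed frame, -1 when fresh), `queue` and `mbuf`.
#' @export
init_stream <- function(bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  # re-validate cross-module dimensions (a hand-edited bundle could disagree)
  bundle <- model_bundle(bundle$encoder, bundle$tcn_config, bundle$tcn_weights,
                         bundle$head_config, bundle$head_weights)
  state <- new.env(parent = emptyenv())
  state$bundle <- bundle
  state$R <- receptive_field(bundle$tcn_config)
  state$t <- -1L
  state$queue <- matrix(0, 0L, bundle$encoder$config$embedding_dim)
  state$mbuf <- matrix(0, 0L, bundle$tcn_config$channels)
  class(state) <- "stream_state"
  state
}

#' @export
print.stream_state <- function(x, ...) {
  cat("<stream_state> t =", x$t, "queue", nrow(x$queue), "/", x$R,
      "embeddings\n")
  invisible(x)
}

#' Number of spatial embeddings currently in the FIFO queue
#'
#' Always `min(t + 1, R)`.
#'
#' @param state A [init_stream()] state.
#' @return Integer queue length.
#' @export
stream_queue_length <- function(state) nrow(state$queue)

#' Push one frame through the streaming engine
#'
#' Embeds the frame, appends the embedding to the FIFO queue (evicting the
#' oldest once the queue exceeds the receptive field R), recomputes the
#' causal TCN over the queue contents to obtain the current temporal
#' embedding `m_t`, and attends over the last `min(t + 1, n)` temporal
#' embeddings to produce `p_t`. Because the queue always covers the full
#' receptive field and previously computed temporal embeddings are cached
#' for the attention window, the returned probabilities equal
#' [offline_predict()] at the same frame.
#'
#' The state is modified in place; per-stage wall-clock latencies are
#' recorded on the returned prediction (never asserted — they are hardware
#' dependent).
#'
#' @param state A [init_stream()] state (mutated).
#' @param frame A single `(H,W,3)` frame, 8-bit or \[0,1\].
#' @return List of class `frame_prediction`: `frame` (0-based index), `p`,
#'   `label` and `latency_ms` (encoder / fusion / head stages).
#' @export
push_frame <- function(state, frame) {
  bundle <- state$bundle
  t0 <- proc.time()[[3L]]
  e <- embed_frames(bundle$encoder, frame)
  t1 <- proc.time()[[3L]]
  state$queue <- rbind(state$queue, e)
  if (nrow(state$queue) > state$R) {
    state$queue <- state$queue[-1L, , drop = FALSE]
  }
  m_all <- tcn_forward(state$queue, bundle$tcn_config, bundle$tcn_weights)
  m_t <- m_all[nrow(m_all), ]
  state$mbuf <- rbind(state$mbuf, m_t)
  if (nrow(state$mbuf) > bundle$head_config$window) {
    state$mbuf <- state$mbuf[-1L, , drop = FALSE]
  }
  t2 <- proc.time()[[3L]]
  e_hat <- reduce_query(as.vector(e), bundle$head_weights)
  at <- attend(e_hat, state$mbuf, bundle$head_weights)
  t3 <- proc.time()[[3L]]
  state$t <- state$t + 1L
  structure(list(frame = state$t, p = at$p,
                 label = predict_phase(at$p),
                 latency_ms = c(encoder = (t1 - t0) * 1000,
                                fusion = (t2 - t1) * 1000,
                                head = (t3 - t2) * 1000)),
            class = "frame_prediction")
}

#' Stream a whole video through the online engine
#'
#' Convenience wrapper: pushes every frame of `video` through [push_frame()]
#' and collects the per-frame predictions into a [prediction_track()] with a
#' latency log.
#'
#' @param video A [video_stream()] or `(T,H,W,3)` array.
#' @param bundle A [model_bundle()].
#' @return A [prediction_track()] with `latency_ms` populated.
#' @export
stream_predict <- function(video, bundle) {
  x <- frames_to_array(video)
  n <- dim(x)[1L]
  state <- init_stream(bundle)
  probs <- matrix(0, n, 4L)
  lat <- matrix(0, n, 3L, dimnames = list(NULL, c("encoder", "fusion", "head")))
  for (t in seq_len(n)) {
    fp <- push_frame(state, x[t, , , ])
    probs[t, ] <- fp$p
    lat[t, ] <- fp$latency_ms
  }
  case_id <- if (inherits(video, "video_stream")) video$case_id else "video"
  fps <- if (inherits(video, "video_stream")) video$fps else 1
  prediction_track(case_id, fps, probs, latency_ms = as.data.frame(lat))
}

#' Write / read a prediction track CSV
#'
#' Columns: `frame,p_marking,p_injection,p_dissection,p_idle,label` and
#' `latency_ms` when a latency log is present (total over stages).
#'
#' @param pred A [prediction_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  df <- data.frame(frame = seq_len(nrow(pred$probs)) - 1L,
                   p_marking = pred$probs[, 1L],
                   p_injection = pred$probs[, 2L],
                   p_dissection = pred$probs[, 3L],
                   p_idle = pred$probs[, 4L],
                   label = pred$labels)
  if (!is.null(pred$latency_ms)) df$latency_ms <- rowSums(pred$latency_ms)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @param case_id,fps Metadata for the reconstructed track.
#' @return `read_predictions()`: a [prediction_track()].
#' @export
read_predictions <- function(path, case_id = NULL, fps = 1) {
  if (is.null(case_id)) case_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  probs <- as.matrix(df[, c("p_marking", "p_injection", "p_dissection", "p_idle")])
  prediction_track(case_id, fps, probs, labels = df$label)
}
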