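# Shared fixtures, memoized per test session (training fixtures are reused
# across test files to keep the suite fast).

.fixture_cache <- new.env(parent = emptyenv())

memo_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A random annotation track with geometric run lengths (not grammar-driven;
# exercises arbitrary label structure).
random_track <- function(n_frames, fps = 1, seed = 1L) {
  withr::with_seed(seed, {
    labels <- character(0)
    while (length(labels) < n_frames) {
      labels <- c(labels, rep(sample(esd_phases(), 1L), 1L + stats::rgeom(1L, 0.3)))
    }
    annotation_track("random", fps, labels[seq_len(n_frames)])
  })
}

# Small rendered cohort for training tests: 32x32 frames keep encoder work low.
tiny_cases <- function(n = 3L, duration_s = 120, size = 32L, seed = 11L) {
  memo_fixture(sprintf("cases_%d_%d_%d_%d", n, duration_s, size, seed), {
    simulate_cohort(n, seed = seed, duration_s = duration_s,
                    appearance = appearance_config(height = size, width = size))
  })
}

# Desk-preset stage-1 encoder trained once and shared.
cached_stage1_encoder <- function() {
  memo_fixture("stage1_encoder", {
    cfg <- encoder_config(input_size = 32L)
    sch <- train_schedule("desk")$stage1
    train_stage1(tiny_cases(), cfg, sch, seed = 7L)
  })
}

# Small random-weight model bundle (no training) for plumbing tests.
tiny_bundle <- function(seed = 1L, d = 8L, d_prime = 12L, num_layers = 4L,
                        window = 6L) {
  enc <- prune_heads(init_encoder(encoder_config(embedding_dim = d,
                                                 input_size = 32L),
                                  seed = seed))
  tc <- tcn_config(num_layers = num_layers, channels = d_prime, input_dim = d)
  hc <- head_config(window = window, d = d, d_prime = d_prime)
  model_bundle(enc, tc, init_tcn(tc, seed = seed + 1L),
               hc, init_head(hc, seed = seed + 2L))
}

# Explicit-loop evaluation of the attention equation, kept independent of the
# vectorized implementation.
brute_force_attend <- function(e_hat, m_window, w) {
  dp <- ncol(m_window)
  n <- nrow(m_window)
  scores <- numeric(n)
  qq <- numeric(dp)
  for (i in seq_len(dp)) qq[i] <- sum(w$wq[i, ] * e_hat)
  for (j in seq_len(n)) {
    kj <- numeric(dp)
    for (i in seq_len(dp)) kj[i] <- sum(w$wk[i, ] * m_window[j, ])
    scores[j] <- sum(qq * kj) / sqrt(dp)
  }
  alpha <- exp(scores - max(scores))
  alpha <- alpha / sum(alpha)
  out <- numeric(dp)
  for (j in seq_len(n)) {
    vj <- numeric(dp)
    for (i in seq_len(dp)) vj[i] <- sum(w$wv[i, ] * m_window[j, ])
    out <- out + alpha[j] * vj
  }
  logits <- numeric(4L)
  for (kk in seq_len(4L)) logits[kk] <- sum(w$cls$w[, kk] * out) + w$cls$b[kk]
  p <- exp(logits - max(logits))
  list(output = out, attention = alpha, p = p / sum(p))
}

# Exhaustive Youden search over every threshold cut (score >= thr positive).
brute_force_youden <- function(scores, truth) {
  truth <- as.logical(truth)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  j <- vapply(cuts, function(thr) {
    pos <- scores >= thr
    sum(pos & truth) / sum(truth) - sum(pos & !truth) / sum(!truth)
  }, numeric(1))
  best <- which.max(j)   # ties: first = highest cut
  list(threshold = cuts[best], j = j[best])
}
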