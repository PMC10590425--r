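# Shared numerical helpers (internal).

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# Row-wise softmax of a matrix; -Inf entries get weight exactly 0.
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  z <- exp(x - m)
  z / rowSums(z)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# He-scaled normal initialization for a fan_in x fan_out weight matrix.
init_weight <- function(fan_in, fan_out, scale = sqrt(2 / fan_in)) {
  matrix(stats::rnorm(fan_in * fan_out, sd = scale), fan_in, fan_out)
}

# Derive a 32-bit sub-seed from a base seed and a stream label, so that
# independent random components of one run do not share a stream.
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
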