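test_that("embedding has one row per frame and is deterministic", {
  enc <- init_encoder(encoder_config(input_size = 32), seed = 3)
  x <- withr::with_seed(1, array(runif(5 * 32 * 32 * 3), c(5, 32, 32, 3)))
  e1 <- embed_frames(enc, x)
  expect_identical(dim(e1), c(5L, 32L))
  expect_identical(e1, embed_frames(enc, x))
  expect_true(all(is.finite(e1)))
  expect_error(embed_frames(enc, array(0, c(2, 30, 30, 3))), "multiple of 16")
})

test_that("supervised contrastive loss reproduces hand-evaluated values", {
  z <- rbind(c(1, 0), c(1, 0), c(0, 1))
  y <- c("Marking", "Marking", "Injection")
  expect_equal(supcon_loss(z, y, tau = 1, "paper_literal"), -1.0)
  expect_equal(supcon_loss(z, y, tau = 1, "all_others"),
               log(1 + exp(-1)), tolerance = 1e-9)
  # large-temperature limit: single positive/negative, literal denominator -> 0
  expect_equal(supcon_loss(z, y, tau = 1e8, "paper_literal"), 0, tolerance = 1e-6)
  expect_error(supcon_loss(z, y, tau = 0), "tau")
  expect_error(supcon_loss(z, c("Idle", "Idle", "Idle"), tau = 1), "two phases")
})

test_that("supcon loss is invariant to batch permutation and orthogonal rotation", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      b <- 12L
      v <- matrix(rnorm(b * 5), b, 5)
      z <- v / sqrt(rowSums(v^2))
      y <- sample(0:3, b, replace = TRUE)
      if (length(unique(y)) < 2) next
      l0 <- supcon_loss(z, y, tau = 0.3)
      perm <- sample(b)
      expect_equal(supcon_loss(z[perm, ], y[perm], tau = 0.3), l0,
                   tolerance = 1e-12)
      q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
      expect_equal(supcon_loss(z %*% q, y, tau = 0.3), l0, tolerance = 1e-9)
    }
  })
})

test_that("the literal denominator admits negative losses; all-others does not", {
  # positives nearly identical, negative orthogonal: literal loss << 0
  z <- rbind(c(1, 0), c(1, 0), c(0, 1))
  y <- c(0, 0, 1)
  expect_lt(supcon_loss(z, y, tau = 0.05, "paper_literal"), -5)
  # one positive per anchor: all-others loss is nonnegative
  withr::with_seed(7, {
    for (rep in 1:20) {
      v <- matrix(rnorm(4 * 3), 4, 3)
      z <- v / sqrt(rowSums(v^2))
      y <- c(0, 0, 1, 1)  # exactly one positive per anchor
      expect_gte(supcon_loss(z, y, tau = 0.2, "all_others"), 0)
    }
  })
})

test_that("cross-entropy loss matches closed forms and is permutation invariant", {
  expect_equal(ce_loss(matrix(0, 6, 4), rep(0:3, length.out = 6)), log(4))
  strong <- matrix(0, 3, 4)
  strong[cbind(1:3, c(1, 3, 4))] <- 20
  expect_lt(ce_loss(strong, c(0, 2, 3)), 1e-6)
  withr::with_seed(5, {
    lg <- matrix(rnorm(20), 5, 4)
    y <- c(0, 1, 2, 3, 0)
    perm <- sample(5)
    expect_equal(ce_loss(lg[perm, ], y[perm]), ce_loss(lg, y))
  })
  expect_error(ce_loss(matrix(0, 2, 4), c(0, 5)), "0..3")
  expect_error(ce_loss(matrix(c(1, NaN), 1, 2), 0), "finite")
  expect_gt(ce_loss(matrix(rnorm(8), 2, 4), c(0, 1)), 0)
})

test_that("loss gradients agree with central finite differences", {
  withr::with_seed(31, {
    z <- matrix(rnorm(12), 4, 3)
    y <- c(0, 0, 1, 2)
    for (mode in c("paper_literal", "all_others")) {
      an <- supcon_loss_grad <- esdflow:::supcon_loss_grad(z, y, 0.5, mode)$dz
      nu <- z * 0
      for (i in seq_along(z)) {
        zp <- z; zp[i] <- zp[i] + 1e-6
        zm <- z; zm[i] <- zm[i] - 1e-6
        nu[i] <- (esdflow:::supcon_loss_grad(zp, y, 0.5, mode, want_grad = FALSE)$loss -
                  esdflow:::supcon_loss_grad(zm, y, 0.5, mode, want_grad = FALSE)$loss) / 2e-6
      }
      expect_equal(an, nu, tolerance = 1e-6)
    }
  })
})

test_that("backbone convolution gradients agree with finite differences", {
  withr::with_seed(3, {
    cfg <- encoder_config(embedding_dim = 4, proj_widths = c(4, 3),
                          input_size = 16)
    enc <- init_encoder(cfg, seed = 1)
    x <- array(runif(2 * 16 * 16 * 3), c(2, 16, 16, 3))
    r <- matrix(rnorm(8), 2, 4)
    fw <- esdflow:::backbone_forward(enc, x, with_cache = TRUE)
    grads <- esdflow:::backbone_backward(enc, r, fw)
    for (l in 1:4) {
      idx <- sample(length(enc$weights$conv[[l]]$w), 3)
      for (i in idx) {
        f <- function(val) {
          e2 <- enc
          e2$weights$conv[[l]]$w[i] <- val
          sum(esdflow:::backbone_forward(e2, x)$e * r)
        }
        w0 <- enc$weights$conv[[l]]$w[i]
        nu <- (f(w0 + 1e-6) - f(w0 - 1e-6)) / 2e-6
        expect_equal(grads[[l]]$w[i], nu, tolerance = 1e-5)
      }
    }
  })
})

test_that("desk-scale stage-1 training reduces the loss deterministically", {
  cases <- tiny_cases(2, 60, 32, seed = 21)
  cfg <- encoder_config(input_size = 32)
  sch <- list(iterations = 60L, batch_size = 16L, lr = 0.002,
              lr_drop_iter = 45L, drop_factor = 10, momentum = 0.9)
  e1 <- train_stage1(cases, cfg, sch, seed = 5)
  e2 <- train_stage1(cases, cfg, sch, seed = 5)
  h <- e1$loss_history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_identical(e1$weights, e2$weights)
  expect_error(train_stage1(list(), cfg, sch), "no training cases")
})

test_that("stage-1 embeddings separate phases well above chance", {
  enc <- cached_stage1_encoder()
  cases <- tiny_cases()
  e <- do.call(rbind, lapply(cases, function(cs) embed_frames(enc, cs$video)))
  y <- unlist(lapply(cases, function(cs) cs$track$labels), use.names = FALSE)
  present <- esd_phases()[esd_phases() %in% y]
  cent <- sapply(present, function(ph) colMeans(e[y == ph, , drop = FALSE]))
  d2 <- sapply(seq_along(present), function(k) rowSums(sweep(e, 2L, cent[, k])^2))
  acc <- mean(present[max.col(-d2)] == y)
  expect_gte(acc, 0.90)
})

test_that("pruning removes exactly the heads and leaves embeddings untouched", {
  enc <- init_encoder(encoder_config(input_size = 32), seed = 2)
  head_params <- n_parameters(enc$weights$proj) + n_parameters(enc$weights$cls)
  x <- withr::with_seed(2, array(runif(3 * 32 * 32 * 3), c(3, 32, 32, 3)))
  e_before <- embed_frames(enc, x)
  pruned <- prune_heads(enc)
  expect_identical(n_parameters(enc) - n_parameters(pruned), head_params)
  expect_identical(embed_frames(pruned, x), e_before)
  expect_true(pruned$pruned)
  expect_error(prune_heads(pruned), "already pruned")
})
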