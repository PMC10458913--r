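test_that("blockless architecture has the hand-counted parameter total", {
  cfg <- rdcnn_config(num_res_blocks = 0, num_dense_blocks = 0, filters = 63,
                      kernel = 3, head_units = 64, n_classes = 5)
  m <- build_model(cfg, beat_length = 187, seed = 1)
  # stem 1*63*3+63 = 252; head 63*64+64 = 4096; output 64*5+5 = 325
  expect_identical(as.integer(count_parameters(m)), 4673L)

  # doubling the head: +63*64 (head W) +64 (head bias) +5*64 (output W)
  m2 <- build_model(rdcnn_config(num_res_blocks = 0, num_dense_blocks = 0,
                                 head_units = 128), 187, seed = 1)
  expect_identical(as.integer(count_parameters(m2)) - 4673L,
                   63L * 64L + 64L + 5L * 64L)

  # invariant under training
  d <- clean_beat_set(3, seed = 2)
  tc <- train_config(max_epochs = 1, patience = 1, batch_size = 8,
                     validation_fraction = 0, seed = 0)
  expect_identical(count_parameters(train_model(m, d$beats, d$labels, tc)),
                   count_parameters(m))
})

test_that("softmax outputs are a probability simplex and init is seeded", {
  m <- build_model(rdcnn_config(), beat_length = 187, seed = 3)
  p <- predict(m, matrix(rnorm(4 * 187), 4, 187), type = "prob")
  expect_identical(dim(p), c(4L, 5L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)

  m2 <- build_model(rdcnn_config(), beat_length = 187, seed = 3)
  expect_identical(m$params, m2$params)
  m3 <- build_model(rdcnn_config(), beat_length = 187, seed = 4)
  expect_false(identical(m$params, m3$params))
})

test_that("zero-weight residual blocks are exact identity maps", {
  set.seed(5)
  for (rep in 1:5) {
    f <- sample(2:6, 1)
    n_layers <- sample(1:3, 1)
    L <- sample(c(16, 33, 50), 1)
    x <- matrix(rnorm(L * f), L, f)
    w <- lapply(seq_len(n_layers), function(j) {
      c_in <- f
      list(W = array(0, c(3, c_in, f)))
    })
    expect_identical(residual_block_forward(x, w), x)
  }
})

test_that("residual blocks preserve shape and realise Y = F(x) + x", {
  x <- matrix(abs(rnorm(187 * 63)), 187, 63)
  w <- list(list(W = array(rnorm(3 * 63 * 63, 0, 0.01), c(3, 63, 63))))
  out <- residual_block_forward(x, w)
  expect_identical(dim(out), dim(x))

  # identity kernel + unit batch norm: output = x + x (up to the BN epsilon)
  wid <- array(0, c(3, 63, 63))
  for (c in 1:63) wid[2, c, c] <- 1
  out2 <- residual_block_forward(x, list(list(W = wid)))
  expect_equal(out2, 2 * x, tolerance = 1e-4)
})

test_that("dense blocks grow channels by n_layers * filters", {
  # randomized configurations
  set.seed(6)
  for (rep in 1:5) {
    c_in <- sample(2:5, 1)
    f <- sample(2:5, 1)
    n_layers <- sample(1:3, 1)
    x <- matrix(rnorm(20 * c_in), 20, c_in)
    w <- lapply(seq_len(n_layers), function(j) {
      lc_in <- c_in + (j - 1L) * f
      list(W = array(rnorm(3 * lc_in * f, 0, 0.1), c(3, lc_in, f)))
    })
    out <- dense_block_forward(x, w)
    expect_identical(ncol(out), c_in + n_layers * f)
    expect_identical(nrow(out), 20L)
  }

  # all-zero weights: input channels pass through unchanged
  x <- matrix(rnorm(16 * 4), 16, 4)
  out0 <- dense_block_forward(x, list(list(W = array(0, c(3, 4, 2)))))
  expect_identical(out0[, 1:4], x)
  expect_identical(out0[, 5:6], matrix(0, 16, 2))
})

test_that("dense layer matches a brute-force convolution oracle", {
  set.seed(7)
  L <- 8; c_in <- 2; f <- 2
  x <- matrix(rnorm(L * c_in), L, c_in)
  W3 <- array(rnorm(3 * c_in * f, 0, 0.5), c(3, c_in, f))
  # brute force: same-padded conv, inference BN (mean 0, var 1), ReLU
  ref <- matrix(0, L, f)
  xp <- rbind(0, x, 0)
  for (t in 1:L) for (o in 1:f) {
    acc <- 0
    for (m in 1:3) for (c in 1:c_in) acc <- acc + W3[m, c, o] * xp[t + m - 1, c]
    ref[t, o] <- max(acc / sqrt(1 + 1e-5), 0)
  }
  out <- dense_block_forward(x, list(list(W = W3)))
  expect_equal(out[, c_in + 1:f], ref, tolerance = 1e-12)
  expect_identical(out[, 1:c_in], x)
})

test_that("analytic gradients match finite differences", {
  cfg <- rdcnn_config(num_res_blocks = 1, num_dense_blocks = 1,
                      num_res_layers = 1, num_dense_layers = 1, filters = 3,
                      kernel = 3, head_units = 4, dropout_rate = 0,
                      n_classes = 3)
  m <- build_model(cfg, beat_length = 16, seed = 42)
  set.seed(8)
  X <- matrix(rnorm(4 * 16), 4, 16)
  y <- c(0L, 1L, 2L, 0L)
  fw <- ecgbeats:::net_forward(m, X, m$params, train = TRUE, collect = TRUE)
  Y <- matrix(0, 4, 3); Y[cbind(1:4, y + 1L)] <- 1
  g <- ecgbeats:::flatten_params(
    ecgbeats:::net_backward(m, m$params, fw, (fw$probs - Y) / 4))
  flat <- ecgbeats:::flatten_params(m$params)
  loss_at <- function(fl) {
    p <- ecgbeats:::net_forward(m, X, ecgbeats:::unflatten_params(fl),
                                train = TRUE)$probs
    ecgbeats:::cross_entropy(p, y)
  }
  eps <- 1e-5
  # conv biases feeding batch norm have exactly-zero gradients (any shift is
  # absorbed by the batch mean), so compare only informative parameters
  keys <- names(g)[!grepl("l[0-9]+\\.bias$", names(g))]
  for (key in keys) {
    for (i in seq_len(min(3, length(g[[key]])))) {
      f2 <- flat
      f2[[key]][i] <- f2[[key]][i] + eps
      lp <- loss_at(f2)
      f2[[key]][i] <- f2[[key]][i] - 2 * eps
      lm <- loss_at(f2)
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - g[[key]][i]) / max(1e-6, abs(num) + abs(g[[key]][i])),
                1e-4)
    }
  }
})

test_that("training overfits a small separable beat set", {
  d <- clean_beat_set(10, seed = 0)
  m <- build_model(tiny_rdcnn(), beat_length = 187, seed = 0)
  # a larger step size than the full-scale default: 200 Adam steps must
  # suffice to memorise 50 beats
  tc <- train_config(learning_rate = 0.01, max_epochs = 50, patience = 50,
                     batch_size = 16, validation_fraction = 0, seed = 0)
  m <- train_model(m, d$beats, d$labels, tc)
  final <- m$history[nrow(m$history), ]
  expect_gte(final$train_acc, 0.95)
  expect_lte(m$history$val_loss[m$best_epoch],
             m$history$val_loss[1])
})

test_that("a zero learning rate leaves weights untouched", {
  d <- clean_beat_set(2, seed = 1)
  m <- build_model(tiny_rdcnn(), beat_length = 187, seed = 1)
  tc <- train_config(learning_rate = 0, max_epochs = 1, patience = 1,
                     batch_size = 5, validation_fraction = 0, seed = 1)
  m2 <- train_model(m, d$beats, d$labels, tc)
  flat1 <- ecgbeats:::flatten_params(m$params)
  flat2 <- ecgbeats:::flatten_params(m2$params)
  keys <- names(flat1)[!grepl("\\.(mean|var)$", names(flat1))]
  for (key in keys)
    expect_lt(max(abs(flat1[[key]] - flat2[[key]])), 1e-9)
})

test_that("early stopping halts on a validation-loss plateau", {
  d <- clean_beat_set(6, seed = 2)
  # a block-free model has no batch-norm running state, so a zero learning
  # rate manufactures an exact plateau: epoch 1 is the best epoch
  m <- build_model(rdcnn_config(num_res_blocks = 0, num_dense_blocks = 0,
                                filters = 8, head_units = 16,
                                dropout_rate = 0, n_classes = 5),
                   beat_length = 187, seed = 2)
  tc <- train_config(learning_rate = 0, max_epochs = 10, patience = 2,
                     batch_size = 10, validation_fraction = 0.2, seed = 2)
  m <- train_model(m, d$beats, d$labels, tc)
  expect_lte(nrow(m$history), 1 + 2) # best epoch + patience
  expect_identical(m$best_epoch, 1L)
})

test_that("training is reproducible under a fixed seed", {
  d <- clean_beat_set(4, seed = 3)
  tc <- train_config(max_epochs = 3, patience = 3, batch_size = 10, seed = 5)
  m1 <- train_model(build_model(tiny_rdcnn(), 187, seed = 5),
                    d$beats, d$labels, tc)
  m2 <- train_model(build_model(tiny_rdcnn(), 187, seed = 5),
                    d$beats, d$labels, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("degenerate training inputs are rejected", {
  d <- clean_beat_set(3, seed = 4)
  m <- build_model(tiny_rdcnn(), beat_length = 187, seed = 0)
  expect_error(train_model(m, d$beats, rep(0L, nrow(d$beats)),
                           train_config()),
               "degenerate")
  expect_error(train_model(m, d$beats[, 1:100], d$labels, train_config()),
               "expects")
})

test_that("extracted features are deterministic, nonnegative, right-shaped", {
  d <- clean_beat_set(2, seed = 5)
  m <- build_model(tiny_rdcnn(), beat_length = 187, seed = 6)
  f <- extract_features(m, d$beats)
  expect_identical(dim(f), c(10L, 16L))
  expect_true(all(f >= 0))
  expect_identical(f, extract_features(m, d$beats))
  # identical inputs give identical rows
  two <- rbind(d$beats[1, ], d$beats[1, ])
  f2 <- extract_features(m, two)
  expect_identical(f2[1, ], f2[2, ])
  expect_error(extract_features(m, d$beats[, 1:50]), "expects")
})

test_that("configuration invariants are enforced", {
  expect_error(rdcnn_config(kernel = 4), "odd")
  expect_error(rdcnn_config(dropout_rate = 1), "dropout_rate")
  expect_error(rdcnn_config(pool_size = 2, pool_stride = 3), "non-overlapping")
  expect_error(train_config(patience = 20, max_epochs = 10), "patience")
  expect_error(train_config(learning_rate = -1), "learning_rate")
  # pooling depth vs beat length
  deep <- rdcnn_config(num_res_blocks = 4, num_dense_blocks = 4,
                       num_res_layers = 1, num_dense_layers = 1, filters = 2)
  expect_error(build_model(deep, beat_length = 8), "below 1|too short")
})
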