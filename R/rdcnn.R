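#' Residual-dense network architecture configuration
#'
#' Describes the residual-dense 1-D convolutional network: an initial
#' convolution (63 filters of 3 taps by default), alternating residual and
#' dense blocks with optional max pooling between blocks, global average
#' pooling, a fully connected head with rectified-linear activation and
#' dropout, and a softmax output.
#'
#' @param num_res_blocks,num_dense_blocks Number of residual / dense blocks
#'   (default 2 each, interleaved residual-first).
#' @param num_res_layers,num_dense_layers Convolutional layers per residual /
#'   dense block (default 2 each).
#' @param filters Filters per convolution (default 63).
#' @param kernel Kernel taps (default 3; convolutions are one-dimensional).
#' @param head_units Width of the fully connected feature head (default 64);
#'   this is the dimension of extracted features.
#' @param dropout_rate Dropout after the head (default 0.3; 0.5 is also a
#'   documented operating point).
#' @param pool_between_blocks Max-pool between consecutive blocks
#'   (default `TRUE`).
#' @param pool_size,pool_stride Pooling window and stride (default 2/2; only
#'   non-overlapping pooling, `pool_stride == pool_size`, is supported).
#' @param n_classes Number of output classes (default 5).
#' @param dense_literal If `TRUE`, dense blocks chain layers sequentially and
#'   concatenate only the block input with the final layer output, instead of
#'   the default full dense connectivity in which each layer sees the block
#'   input and all previous layer outputs.
#' @return An object of class `rdcnn_config`.
#' @export
rdcnn_config <- function(num_res_blocks = 2, num_dense_blocks = 2,
                         num_res_layers = 2, num_dense_layers = 2,
                         filters = 63, kernel = 3, head_units = 64,
                         dropout_rate = 0.3, pool_between_blocks = TRUE,
                         pool_size = 2, pool_stride = 2, n_classes = 5,
                         dense_literal = FALSE) {
  cfg <- list(
    num_res_blocks = check_count(num_res_blocks, "num_res_blocks"),
    num_dense_blocks = check_count(num_dense_blocks, "num_dense_blocks"),
    num_res_layers = check_count(num_res_layers, "num_res_layers"),
    num_dense_layers = check_count(num_dense_layers, "num_dense_layers"),
    filters = check_count(filters, "filters", min = 1L),
    kernel = check_count(kernel, "kernel", min = 1L),
    head_units = check_count(head_units, "head_units", min = 1L),
    dropout_rate = dropout_rate,
    pool_between_blocks = isTRUE(pool_between_blocks),
    pool_size = check_count(pool_size, "pool_size", min = 2L),
    pool_stride = check_count(pool_stride, "pool_stride", min = 2L),
    n_classes = check_count(n_classes, "n_classes", min = 2L),
    dense_literal = isTRUE(dense_literal)
  )
  if (cfg$kernel %% 2L == 0L)
    stop("`kernel` must be odd (same-padded convolutions)", call. = FALSE)
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must be in [0, 1)", call. = FALSE)
  if (cfg$pool_size != cfg$pool_stride)
    stop("only non-overlapping pooling (pool_stride == pool_size) is supported",
         call. = FALSE)
  if (cfg$num_res_blocks > 0 && cfg$num_res_layers < 1)
    stop("residual blocks need at least one layer", call. = FALSE)
  if (cfg$num_dense_blocks > 0 && cfg$num_dense_layers < 1)
    stop("dense blocks need at least one layer", call. = FALSE)
  class(cfg) <- "rdcnn_config"
  cfg
}

#' Training configuration for the residual-dense network
#'
#' Defaults follow the standard operating point: Adam, learning rate 0.001,
#' batch size 64, at most 10 epochs, categorical cross-entropy loss, early
#' stopping on validation loss with patience 5.
#'
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param learning_rate Step size (>= 0; 0 leaves weights untouched).
#' @param batch_size Minibatch size (default 64; 16 is also a documented
#'   operating point).
#' @param max_epochs Epoch cap (default 10).
#' @param patience Early-stopping patience in epochs (default 5, must not
#'   exceed `max_epochs`).
#' @param validation_fraction Fraction of training rows held out (stratified)
#'   to monitor validation loss (default 0.1; 0 disables the hold-out and
#'   early stopping then monitors training loss).
#' @param seed Integer seed for shuffling, the validation split and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), learning_rate = 0.001,
                         batch_size = 64, max_epochs = 10, patience = 5,
                         validation_fraction = 0.1, seed = 0) {
  cfg <- list(
    optimizer = match.arg(optimizer),
    learning_rate = learning_rate,
    batch_size = check_count(batch_size, "batch_size", min = 1L),
    max_epochs = check_count(max_epochs, "max_epochs", min = 1L),
    patience = check_count(patience, "patience", min = 1L),
    validation_fraction = validation_fraction,
    seed = seed
  )
  if (!is.numeric(learning_rate) || learning_rate < 0)
    stop("`learning_rate` must be >= 0", call. = FALSE)
  if (cfg$patience > cfg$max_epochs)
    stop("`patience` must not exceed `max_epochs`", call. = FALSE)
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop("`validation_fraction` must be in [0, 1)", call. = FALSE)
  class(cfg) <- "train_config"
  cfg
}

#' Build an untrained residual-dense network
#'
#' Lays out the layer graph (initial convolution, alternating residual and
#' dense blocks with optional pooling, global average pooling, fully
#' connected head, dropout, softmax output) and initialises all weights with
#' a seeded variance-scaled fan-in scheme.
#'
#' @param config An [rdcnn_config()].
#' @param beat_length Input beat length in samples.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `rdcnn_model`.
#' @export
#' @examples
#' m <- build_model(rdcnn_config(num_res_blocks = 0, num_dense_blocks = 0),
#'                  beat_length = 187)
#' count_parameters(m)
build_model <- function(config = rdcnn_config(), beat_length = 187, seed = 0) {
  stopifnot(inherits(config, "rdcnn_config"))
  beat_length <- check_count(beat_length, "beat_length", min = 4L)
  kinds <- interleave_blocks(config$num_res_blocks, config$num_dense_blocks)
  blocks <- list()
  cur_c <- config$filters
  L <- beat_length
  for (i in seq_along(kinds)) {
    if (i > 1L && config$pool_between_blocks) {
      L2 <- L %/% config$pool_size
      if (L2 < 1L)
        stop(sprintf(
          "pooling reduces the temporal length below 1 (beat_length %d is too short for %d pooled blocks)",
          beat_length, length(kinds)), call. = FALSE)
      blocks[[length(blocks) + 1L]] <- list(kind = "pool")
      L <- L2
    }
    if (kinds[i] == "res") {
      blocks[[length(blocks) + 1L]] <- list(
        kind = "res", n_layers = config$num_res_layers, c_in = cur_c,
        proj = cur_c != config$filters)
      cur_c <- config$filters
    } else {
      blocks[[length(blocks) + 1L]] <- list(
        kind = "dense", n_layers = config$num_dense_layers, c_in = cur_c)
      cur_c <- cur_c + config$filters *
        (if (config$dense_literal) 1L else config$num_dense_layers)
    }
  }
  params <- with_local_seed(seed, {
    p <- list(stem = list(
      W = init_conv(config$kernel, 1L, config$filters),
      bias = numeric(config$filters)))
    bi <- 0L
    for (blk in blocks) {
      if (blk$kind == "pool") next
      bi <- bi + 1L
      bp <- list()
      c_in <- blk$c_in
      for (j in seq_len(blk$n_layers)) {
        lc_in <- if (blk$kind == "res") {
          if (j == 1L) c_in else config$filters
        } else if (config$dense_literal) {
          if (j == 1L) c_in else config$filters
        } else {
          c_in + (j - 1L) * config$filters
        }
        bp[[paste0("l", j)]] <- init_cbr(config$kernel, lc_in, config$filters)
      }
      if (blk$kind == "res" && blk$proj)
        bp$proj <- list(W = init_conv(1L, c_in, config$filters),
                        bias = numeric(config$filters))
      p[[paste0("b", bi)]] <- bp
    }
    p$head <- list(
      W = matrix(rnorm(cur_c * config$head_units, 0, sqrt(2 / cur_c)),
                 cur_c, config$head_units),
      bias = numeric(config$head_units))
    p$out <- list(
      W = matrix(rnorm(config$head_units * config$n_classes, 0,
                       sqrt(1 / config$head_units)),
                 config$head_units, config$n_classes),
      bias = numeric(config$n_classes))
    p
  })
  structure(list(config = config, beat_length = beat_length,
                 blocks = blocks, params = params,
                 feature_dim = config$head_units,
                 n_classes = config$n_classes,
                 final_channels = cur_c, final_length = L,
                 seed = seed, history = NULL, trained = FALSE),
            class = "rdcnn_model")
}

# res, dense, res, dense, ... with leftovers appended.
interleave_blocks <- function(nr, nd) {
  kinds <- character(0)
  while (nr > 0L || nd > 0L) {
    if (nr > 0L) { kinds <- c(kinds, "res"); nr <- nr - 1L }
    if (nd > 0L) { kinds <- c(kinds, "dense"); nd <- nd - 1L }
  }
  kinds
}

#' @export
print.rdcnn_model <- function(x, ...) {
  cat(sprintf("<rdcnn_model> beat_length %d, %d classes, %s\n",
              x$beat_length, x$n_classes,
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  blocks: %s\n",
              paste(vapply(x$blocks, `[[`, "", "kind"), collapse = " -> ")))
  cat(sprintf("  features: %d, parameters: %d\n",
              x$feature_dim, count_parameters(x)))
  invisible(x)
}

# Full forward pass. X is n x beat_length. Returns logits, probabilities,
# head features (post-ReLU, pre-dropout) and, when `collect = TRUE`, the
# per-layer caches needed for backprop.
net_forward <- function(model, X, params = model$params, train = FALSE,
                        collect = FALSE) {
  cfg <- model$config
  n <- nrow(X); L <- model$beat_length
  A <- matrix(as.vector(t(X)), ncol = 1L)
  stem <- conv_fwd(A, n, L, params$stem$W, params$stem$bias)
  A <- stem$out
  caches <- list(stem = if (collect) stem)
  bi <- 0L
  for (k in seq_along(model$blocks)) {
    blk <- model$blocks[[k]]
    if (blk$kind == "pool") {
      pc <- pool_fwd(A, n, L, cfg$pool_size)
      A <- pc$out; L <- pc$L2
      if (collect) caches[[paste0("pool", k)]] <- pc
      next
    }
    bi <- bi + 1L
    key <- paste0("b", bi)
    if (blk$kind == "res") {
      r <- res_block_fwd(A, n, L, params[[key]], blk$n_layers, train)
    } else {
      r <- dense_block_fwd(A, n, L, params[[key]], blk$n_layers, train,
                           literal = cfg$dense_literal)
    }
    A <- r$out
    if (collect) caches[[key]] <- r
  }
  feat0 <- gap_fwd(A, n, L)
  pre_head <- sweep(feat0 %*% params$head$W, 2L, params$head$bias, "+")
  features <- pmax(pre_head, 0)
  dropped <- features
  drop_mask <- NULL
  if (train && cfg$dropout_rate > 0) {
    drop_mask <- matrix(
      (runif(length(features)) >= cfg$dropout_rate) / (1 - cfg$dropout_rate),
      nrow(features), ncol(features))
    dropped <- features * drop_mask
  }
  logits <- sweep(dropped %*% params$out$W, 2L, params$out$bias, "+")
  list(logits = logits, probs = softmax_rows(logits), features = features,
       caches = if (collect) c(caches, list(
         feat0 = feat0, features = features, dropped = dropped,
         head_mask = pre_head > 0, drop_mask = drop_mask,
         n = n, L_final = L)))
}

# Backward pass from dlogits; returns nested grads matching `params`.
net_backward <- function(model, params, fw, dlogits) {
  cfg <- model$config
  cc <- fw$caches
  n <- cc$n; L <- cc$L_final
  grads <- list()
  grads$out <- list(W = crossprod(cc$dropped, dlogits),
                    bias = colSums(dlogits))
  dfeat <- dlogits %*% t(params$out$W)
  if (!is.null(cc$drop_mask)) dfeat <- dfeat * cc$drop_mask
  dpre <- dfeat * cc$head_mask
  grads$head <- list(W = crossprod(cc$feat0, dpre), bias = colSums(dpre))
  dfeat0 <- dpre %*% t(params$head$W)
  dA <- gap_bwd(dfeat0, n, L)
  bi <- sum(vapply(model$blocks, function(b) b$kind != "pool", TRUE))
  for (k in rev(seq_along(model$blocks))) {
    blk <- model$blocks[[k]]
    if (blk$kind == "pool") {
      pc <- cc[[paste0("pool", k)]]
      dA <- pool_bwd(dA, pc, n, pc$L_in)
      L <- pc$L_in
      next
    }
    key <- paste0("b", bi)
    if (blk$kind == "res") {
      b <- res_block_bwd(dA, cc[[key]], params[[key]], blk$n_layers, n, L)
    } else {
      b <- dense_block_bwd(dA, cc[[key]], params[[key]], blk$n_layers, n, L,
                           literal = cfg$dense_literal)
    }
    grads[[key]] <- b$grads
    dA <- b$dA
    bi <- bi - 1L
  }
  sb <- conv_bwd(dA, cc$stem, params$stem$W, n, L)
  grads$stem <- list(W = sb$dW, bias = sb$db)
  grads
}

# Copy updated batch-norm running statistics from forward caches back into
# the parameter list after a training step.
update_bn_stats <- function(params, fw, model) {
  cc <- fw$caches
  bi <- 0L
  for (k in seq_along(model$blocks)) {
    blk <- model$blocks[[k]]
    if (blk$kind == "pool") next
    bi <- bi + 1L
    key <- paste0("b", bi)
    for (j in seq_len(blk$n_layers)) {
      bn <- cc[[key]]$caches[[j]]$bn
      params[[key]][[paste0("l", j)]]$mean <- bn$new_mean
      params[[key]][[paste0("l", j)]]$var <- bn$new_var
    }
  }
  params
}

cross_entropy <- function(probs, y) {
  p <- probs[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

#' Train a residual-dense network
#'
#' Minimises categorical cross-entropy with Adam (or SGD), holding out a
#' stratified validation fraction of the training rows, and stops early when
#' the validation loss has not improved for `patience` epochs. The returned
#' model carries the weights of the best validation epoch and a per-epoch
#' history.
#'
#' @param model An [build_model()] result.
#' @param beats Training beat matrix (rows must match `model$beat_length`).
#' @param labels Integer class labels 0..(n_classes-1).
#' @param config A [train_config()].
#' @return The trained `rdcnn_model`, with `history` set to a tibble of
#'   per-epoch train/validation loss and accuracy.
#' @export
train_model <- function(model, beats, labels, config = train_config()) {
  stopifnot(inherits(model, "rdcnn_model"), inherits(config, "train_config"))
  beats <- as.matrix(beats)
  if (ncol(beats) != model$beat_length)
    stop(sprintf("beats have %d samples but the model expects %d",
                 ncol(beats), model$beat_length), call. = FALSE)
  if (nrow(beats) != length(labels))
    stop("pairing error: beats and labels differ in length", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("degenerate labels: training needs at least two classes",
         call. = FALSE)
  if (any(labels < 0L | labels >= model$n_classes))
    stop("labels outside 0..(n_classes-1)", call. = FALSE)

  if (config$validation_fraction > 0) {
    sp <- split_train_test(beats, labels,
                           train_fraction = 1 - config$validation_fraction,
                           stratified = TRUE, seed = config$seed)
    tr_x <- sp$train$beats; tr_y <- sp$train$labels
    va_x <- sp$test$beats; va_y <- sp$test$labels
  } else {
    tr_x <- beats; tr_y <- labels
    va_x <- NULL; va_y <- NULL
  }

  params <- model$params
  trainable <- flatten_params(params)
  trainable <- trainable[!grepl("\\.(mean|var)$", names(trainable))]
  state <- list(t = 0L,
                m = lapply(trainable, function(x) x * 0),
                v = lapply(trainable, function(x) x * 0))
  hist <- list()
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L

  with_local_seed(config$seed + 1L, {
    n_tr <- nrow(tr_x)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = config$batch_size)
      ep_loss <- 0; ep_correct <- 0L
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, n_tr)]
        xb <- tr_x[rows, , drop = FALSE]
        yb <- tr_y[rows]
        fw <- net_forward(model, xb, params, train = TRUE, collect = TRUE)
        nb <- length(yb)
        ep_loss <- ep_loss + cross_entropy(fw$probs, yb) * nb
        ep_correct <- ep_correct +
          sum(max.col(fw$probs, ties.method = "first") - 1L == yb)
        Y <- matrix(0, nb, model$n_classes)
        Y[cbind(seq_len(nb), yb + 1L)] <- 1
        dlogits <- (fw$probs - Y) / nb
        grads <- flatten_params(net_backward(model, params, fw, dlogits))
        flat <- flatten_params(params)
        if (config$optimizer == "adam") {
          upd <- adam_step(flat, grads, state, config$learning_rate)
          flat <- upd$theta; state <- upd$state
        } else {
          flat <- sgd_step(flat, grads, config$learning_rate)
        }
        params <- unflatten_params(flat)
        params <- update_bn_stats(params, fw, model)
      }
      train_loss <- ep_loss / n_tr
      train_acc <- ep_correct / n_tr
      if (!is.null(va_x)) {
        vfw <- net_forward(model, va_x, params, train = FALSE)
        val_loss <- cross_entropy(vfw$probs, va_y)
        val_acc <- mean(max.col(vfw$probs, ties.method = "first") - 1L == va_y)
      } else {
        val_loss <- train_loss
        val_acc <- train_acc
      }
      hist[[epoch]] <- c(epoch = epoch, train_loss = train_loss,
                         train_acc = train_acc, val_loss = val_loss,
                         val_acc = val_acc)
      if (val_loss < best$loss - 1e-12) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })

  model$params <- best$params
  model$trained <- TRUE
  model$best_epoch <- best$epoch
  model$history <- tibble::as_tibble(do.call(rbind, hist))
  model
}

#' Predict classes or probabilities for a beat matrix
#'
#' @param object A trained (or initialised) `rdcnn_model`.
#' @param beats Beat matrix with `model$beat_length` columns.
#' @param type `"class"` (default) for integer labels, `"prob"` for softmax
#'   probabilities.
#' @param ... Unused.
#' @return Integer labels or an `n x n_classes` probability matrix.
#' @export
predict.rdcnn_model <- function(object, beats, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  beats <- as.matrix(beats)
  if (ncol(beats) != object$beat_length)
    stop(sprintf("beats have %d samples but the model expects %d",
                 ncol(beats), object$beat_length), call. = FALSE)
  fw <- net_forward(object, beats, train = FALSE)
  if (type == "prob") fw$probs
  else max.col(fw$probs, ties.method = "first") - 1L
}

#' Extract learned features from the network head
#'
#' Returns the activations of the fully connected head (post-ReLU,
#' pre-dropout, pre-softmax), the representation consumed by the
#' one-versus-all SVM. Dropout is disabled, so the mapping is deterministic.
#'
#' @inheritParams predict.rdcnn_model
#' @return Numeric matrix `n x head_units`; all entries are >= 0.
#' @export
extract_features <- function(object, beats) {
  stopifnot(inherits(object, "rdcnn_model"))
  beats <- as.matrix(beats)
  if (ncol(beats) != object$beat_length)
    stop(sprintf("beats have %d samples but the model expects %d",
                 ncol(beats), object$beat_length), call. = FALSE)
  net_forward(object, beats, train = FALSE)$features
}

#' Count trainable parameters
#'
#' Total number of trainable scalars (convolution and fully connected
#' weights and biases, batch-norm scales and shifts; running statistics are
#' not trainable). A per-component breakdown is attached as the
#' `"breakdown"` attribute.
#'
#' @param model An `rdcnn_model`.
#' @return Integer count with attribute `breakdown`.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "rdcnn_model"))
  flat <- flatten_params(model$params)
  flat <- flat[!grepl("\\.(mean|var)$", names(flat))]
  sizes <- vapply(flat, length, 0L)
  structure(sum(sizes), breakdown = sizes)
}

# Coerce user-facing per-layer weights (W possibly [k, c_in, f] arrays,
# batch-norm fields optional) into the engine's parameter layout.
as_cbr_params <- function(w) {
  W <- w$W
  if (is.array(W) && length(dim(W)) == 3L) W <- conv_w_mat(W)
  f <- ncol(W)
  list(W = W,
       bias = if (is.null(w$bias)) numeric(f) else w$bias,
       gamma = if (is.null(w$gamma)) rep(1, f) else w$gamma,
       beta = if (is.null(w$beta)) numeric(f) else w$beta,
       mean = if (is.null(w$mean)) numeric(f) else w$mean,
       var = if (is.null(w$var)) rep(1, f) else w$var)
}

#' Forward pass of a single residual block
#'
#' Applies `length(weights)` convolution -> batch-normalisation -> ReLU
#' layers to a single feature map and adds the block input (the additive
#' residual connection `Y = F(x) + x`). Batch normalisation runs in
#' inference mode with the supplied running statistics (defaults: mean 0,
#' variance 1, scale 1, shift 0), so with all-zero convolution weights the
#' block is exactly the identity map.
#'
#' @param x Feature map, an `L x C` numeric matrix (time by channels).
#' @param weights List of per-layer weight lists, each with `W` (a
#'   `[kernel, c_in, filters]` array or `(kernel*c_in) x filters` matrix)
#'   and optional `bias`, `gamma`, `beta`, `mean`, `var`. An optional
#'   `proj` element (same fields, 1-tap) projects the shortcut when the
#'   input channel count differs from `filters`.
#' @return The `L x filters` output feature map.
#' @export
residual_block_forward <- function(x, weights) {
  x <- as.matrix(x)
  nm <- names(weights)
  layer_w <- if (is.null(nm)) weights else weights[nm != "proj"]
  proj_w <- if (is.null(nm)) NULL else weights[["proj"]]
  params <- list()
  for (j in seq_along(layer_w))
    params[[paste0("l", j)]] <- as_cbr_params(layer_w[[j]])
  if (!is.null(proj_w)) {
    W <- proj_w$W
    if (is.array(W) && length(dim(W)) == 3L) W <- conv_w_mat(W)
    params$proj <- list(W = W, bias = if (is.null(proj_w$bias))
      numeric(ncol(W)) else proj_w$bias)
  } else if (ncol(x) != ncol(params[[length(params)]]$W)) {
    stop("input channels differ from filters and no `proj` weights supplied",
         call. = FALSE)
  }
  r <- res_block_fwd(x, n = 1L, L = nrow(x), params, length(layer_w),
                     train = FALSE)
  r$out
}

#' Forward pass of a single dense block
#'
#' Each layer applies convolution -> batch-normalisation (inference mode) ->
#' ReLU to the channel concatenation of the block input and all previous
#' layer outputs; the block output concatenates the input with every layer
#' output, so the channel count grows to `c_in + n_layers * filters`.
#'
#' @inheritParams residual_block_forward
#' @param literal Use the sequential-chain variant (see [rdcnn_config()]).
#' @return The output feature map, `L x (c_in + n_layers * filters)` columns
#'   (or `L x (c_in + filters)` for the literal variant).
#' @export
dense_block_forward <- function(x, weights, literal = FALSE) {
  x <- as.matrix(x)
  params <- list()
  for (j in seq_along(weights))
    params[[paste0("l", j)]] <- as_cbr_params(weights[[j]])
  r <- dense_block_fwd(x, n = 1L, L = nrow(x), params, length(weights),
                       train = FALSE, literal = literal)
  r$out
}
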