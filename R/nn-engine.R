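# Internal neural-network engine for the residual-dense 1-D CNN.
#
# Feature maps are stored sample-major: a map with n beats, length L and C
# channels is a (n*L) x C matrix whose row (i-1)*L + t holds sample t of
# beat i. Convolutions are evaluated as im2col matrix products so all heavy
# lifting is BLAS.

# Gather indices for a same-padded conv: for tap m (1..k, centre at
# (k+1)/2), idx[[m]] maps each output row to the input row it reads, with
# the augmented zero row n*L + 1 standing in for out-of-range positions.
conv_gather_idx <- function(n, L, k) {
  p <- (k - 1L) %/% 2L
  t_all <- rep(seq_len(L), n)
  base <- rep((seq_len(n) - 1L) * L, each = L)
  zero_row <- n * L + 1L
  lapply(seq_len(k), function(m) {
    tm <- t_all + (m - 1L - p)
    ifelse(tm >= 1L & tm <= L, base + tm, zero_row)
  })
}

# Reshape a [kernel, c_in, filters] array into the (k*c_in) x filters matrix
# used by the im2col product (columns of the im2col matrix are ordered
# channel-fastest within tap).
conv_w_mat <- function(W3) {
  stopifnot(length(dim(W3)) == 3L)
  k <- dim(W3)[1]; C <- dim(W3)[2]; F_ <- dim(W3)[3]
  matrix(aperm(W3, c(2L, 1L, 3L)), k * C, F_)
}

conv_fwd <- function(A, n, L, W, b, idx = NULL) {
  C <- ncol(A)
  k <- nrow(W) / C
  if (is.null(idx)) idx <- conv_gather_idx(n, L, as.integer(k))
  A_aug <- rbind(A, 0)
  X2 <- do.call(cbind, lapply(idx, function(ix) A_aug[ix, , drop = FALSE]))
  out <- X2 %*% W
  out <- sweep(out, 2L, b, "+")
  list(out = out, X2 = X2, idx = idx, C = C)
}

conv_bwd <- function(dOut, cache, W, n, L) {
  dW <- crossprod(cache$X2, dOut)
  db <- colSums(dOut)
  dX2 <- dOut %*% t(W)
  C <- cache$C
  dA_aug <- matrix(0, n * L + 1L, C)
  for (m in seq_along(cache$idx)) {
    cols <- ((m - 1L) * C + 1L):(m * C)
    ix <- cache$idx[[m]]
    dA_aug[ix, ] <- dA_aug[ix, ] + dX2[, cols, drop = FALSE]
  }
  list(dA = dA_aug[seq_len(n * L), , drop = FALSE], dW = dW, db = db)
}

bn_fwd <- function(A, gamma, beta, run_mean, run_var, train, momentum = 0.9,
                   eps = 1e-5) {
  if (train) {
    mu <- colMeans(A)
    v <- colMeans(A * A) - mu^2
    v <- pmax(v, 0)
    new_mean <- momentum * run_mean + (1 - momentum) * mu
    new_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
    new_mean <- run_mean; new_var <- run_var
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(A, 2L, mu, "-"), 2L, inv_std, "*")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, xhat = xhat, inv_std = inv_std, train = train,
       new_mean = new_mean, new_var = new_var)
}

bn_bwd <- function(dOut, cache, gamma) {
  dgamma <- colSums(dOut * cache$xhat)
  dbeta <- colSums(dOut)
  dxhat <- sweep(dOut, 2L, gamma, "*")
  if (!cache$train) {
    dA <- sweep(dxhat, 2L, cache$inv_std, "*")
    return(list(dA = dA, dgamma = dgamma, dbeta = dbeta))
  }
  N <- nrow(dOut)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dA <- sweep(dxhat, 2L, s1 / N, "-") -
    sweep(cache$xhat, 2L, s2 / N, "*")
  dA <- sweep(dA, 2L, cache$inv_std, "*")
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}

# One conv -> batchnorm -> ReLU unit. `p` is its parameter sublist with
# entries W (matrix), bias, gamma, beta, mean, var.
cbr_fwd <- function(A, n, L, p, train, momentum = 0.9) {
  cv <- conv_fwd(A, n, L, p$W, p$bias)
  bn <- bn_fwd(cv$out, p$gamma, p$beta, p$mean, p$var, train, momentum)
  act <- pmax(bn$out, 0)
  list(out = act, cv = cv, bn = bn, relu_mask = bn$out > 0)
}

cbr_bwd <- function(dOut, cache, p, n, L) {
  dbn_out <- dOut * cache$relu_mask
  bnb <- bn_bwd(dbn_out, cache$bn, p$gamma)
  cvb <- conv_bwd(bnb$dA, cache$cv, p$W, n, L)
  list(dA = cvb$dA,
       grads = list(W = cvb$dW, bias = cvb$db,
                    gamma = bnb$dgamma, beta = bnb$dbeta))
}

# Residual block: n_layers conv-BN-ReLU units plus an additive shortcut;
# a 1-tap projection convolution aligns channels when c_in != filters.
res_block_fwd <- function(A, n, L, params, n_layers, train, momentum = 0.9) {
  caches <- vector("list", n_layers)
  cur <- A
  for (j in seq_len(n_layers)) {
    r <- cbr_fwd(cur, n, L, params[[paste0("l", j)]], train, momentum)
    caches[[j]] <- r
    cur <- r$out
  }
  if (!is.null(params$proj)) {
    pr <- conv_fwd(A, n, L, params$proj$W, params$proj$bias)
    shortcut <- pr$out
  } else {
    pr <- NULL
    shortcut <- A
  }
  list(out = cur + shortcut, caches = caches, proj_cache = pr)
}

res_block_bwd <- function(dOut, cache, params, n_layers, n, L) {
  grads <- list()
  d <- dOut
  for (j in rev(seq_len(n_layers))) {
    key <- paste0("l", j)
    b <- cbr_bwd(d, cache$caches[[j]], params[[key]], n, L)
    grads[[key]] <- b$grads
    d <- b$dA
  }
  if (!is.null(params$proj)) {
    pb <- conv_bwd(dOut, cache$proj_cache, params$proj$W, n, L)
    grads$proj <- list(W = pb$dW, bias = pb$db)
    dA <- d + pb$dA
  } else {
    dA <- d + dOut
  }
  list(dA = dA, grads = grads)
}

# Dense block. Full connectivity (default): layer j consumes the channel
# concatenation of the block input and every previous layer's output, and
# the block output concatenates the input with all layer outputs. The
# literal variant chains layers sequentially and concatenates the input
# with the last output only.
dense_block_fwd <- function(A, n, L, params, n_layers, train, literal = FALSE,
                            momentum = 0.9) {
  outs <- vector("list", n_layers)
  caches <- vector("list", n_layers)
  for (j in seq_len(n_layers)) {
    inp <- if (literal) {
      if (j == 1L) A else outs[[j - 1L]]
    } else {
      do.call(cbind, c(list(A), outs[seq_len(j - 1L)]))
    }
    r <- cbr_fwd(inp, n, L, params[[paste0("l", j)]], train, momentum)
    caches[[j]] <- r
    outs[[j]] <- r$out
  }
  out <- if (literal) cbind(A, outs[[n_layers]])
  else do.call(cbind, c(list(A), outs))
  list(out = out, caches = caches, outs_ncol = vapply(outs, ncol, 0L),
       c_in = ncol(A))
}

dense_block_bwd <- function(dOut, cache, params, n_layers, n, L,
                            literal = FALSE) {
  c_in <- cache$c_in
  F_ <- cache$outs_ncol
  grads <- list()
  # split the output gradient into block-input and per-layer-output slices
  douts <- vector("list", n_layers)
  if (literal) {
    for (j in seq_len(n_layers - 1L))
      douts[[j]] <- matrix(0, nrow(dOut), F_[j])
    douts[[n_layers]] <- dOut[, c_in + seq_len(F_[n_layers]), drop = FALSE]
  } else {
    off <- c_in
    for (j in seq_len(n_layers)) {
      douts[[j]] <- dOut[, off + seq_len(F_[j]), drop = FALSE]
      off <- off + F_[j]
    }
  }
  dA <- dOut[, seq_len(c_in), drop = FALSE]
  for (j in rev(seq_len(n_layers))) {
    b <- cbr_bwd(douts[[j]], cache$caches[[j]], params[[paste0("l", j)]], n, L)
    grads[[paste0("l", j)]] <- b$grads
    if (literal) {
      if (j == 1L) dA <- dA + b$dA
      else douts[[j - 1L]] <- douts[[j - 1L]] + b$dA
    } else {
      # b$dA covers concat(input, outs[1..j-1]); scatter it back
      dA <- dA + b$dA[, seq_len(c_in), drop = FALSE]
      off <- c_in
      for (jj in seq_len(j - 1L)) {
        douts[[jj]] <- douts[[jj]] +
          b$dA[, off + seq_len(F_[jj]), drop = FALSE]
        off <- off + F_[jj]
      }
    }
  }
  list(dA = dA, grads = grads)
}

# Non-overlapping max pool along the temporal axis (size == stride).
pool_fwd <- function(A, n, L, size) {
  L2 <- L %/% size
  base_out <- rep((seq_len(n) - 1L) * L, each = L2)
  u <- rep(seq_len(L2), n)
  idx <- lapply(seq_len(size), function(s) base_out + (u - 1L) * size + s)
  M <- A[idx[[1L]], , drop = FALSE]
  which_max <- matrix(1L, nrow(M), ncol(M))
  for (s in 2L:size) {
    As <- A[idx[[s]], , drop = FALSE]
    upd <- As > M
    M[upd] <- As[upd]
    which_max[upd] <- s
  }
  list(out = M, idx = idx, which_max = which_max, L2 = L2, L_in = L)
}

pool_bwd <- function(dOut, cache, n, L) {
  dA <- matrix(0, n * L, ncol(dOut))
  for (s in seq_along(cache$idx)) {
    sel <- cache$which_max == s
    tmp <- dOut * sel
    ix <- cache$idx[[s]]
    dA[ix, ] <- dA[ix, ] + tmp
  }
  dA
}

# Global average pooling: (n*L) x C -> n x C.
gap_fwd <- function(A, n, L) {
  grp <- rep(seq_len(n), each = L)
  out <- rowsum(A, grp, reorder = TRUE) / L
  dimnames(out) <- NULL
  out
}

gap_bwd <- function(dOut, n, L) {
  dOut[rep(seq_len(n), each = L), , drop = FALSE] / L
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Kaiming/He fan-in initialisation for a conv as a [k, c_in, f] array.
init_conv <- function(k, c_in, f) {
  sd <- sqrt(2 / (k * c_in))
  conv_w_mat(array(rnorm(k * c_in * f, 0, sd), dim = c(k, c_in, f)))
}

init_cbr <- function(k, c_in, f) {
  list(W = init_conv(k, c_in, f), bias = numeric(f),
       gamma = rep(1, f), beta = numeric(f),
       mean = numeric(f), var = rep(1, f))
}

adam_step <- function(theta, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    theta[[k]] <- theta[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(theta = theta, state = state)
}

sgd_step <- function(theta, grads, lr) {
  for (k in names(grads)) theta[[k]] <- theta[[k]] - lr * grads[[k]]
  theta
}

# Flatten / unflatten nested parameter lists (block -> layer -> tensor) so
# the optimiser can treat parameters uniformly.
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) out <- c(out, flatten_params(p[[nm]], key))
    else out[[key]] <- p[[nm]]
  }
  out
}

unflatten_params <- function(flat) {
  out <- list()
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    out <- assign_nested(out, parts, flat[[key]])
  }
  out
}

assign_nested <- function(lst, parts, value) {
  if (length(parts) == 1L) {
    lst[[parts]] <- value
    return(lst)
  }
  if (is.null(lst[[parts[1]]])) lst[[parts[1]]] <- list()
  lst[[parts[1]]] <- assign_nested(lst[[parts[1]]], parts[-1L], value)
  lst
}
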