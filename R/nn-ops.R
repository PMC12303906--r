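# Minimal CNN engine.
#
# Feature maps are stored in "row-major pixel" form: a (H*W*N) x C matrix
# whose row index r encodes (h, w, n) as r = h + H*(w-1) + H*W*(n-1).
# All convolutions reduce to one BLAS matmul via im2col; the index vectors
# that implement im2col / pooling / up-sampling are cached per shape.

.plq_idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .plq_idx_cache)) {
    assign(key, builder(), envir = .plq_idx_cache)
  }
  get(key, envir = .plq_idx_cache)
}

pixel_coords <- function(H, W, N) {
  list(h = rep(seq_len(H), times = W * N),
       w = rep(rep(seq_len(W), each = H), times = N),
       nb = rep(seq_len(N) - 1L, each = H * W) * (H * W))
}

im2col3 <- function(Fm, H, W, N) cpp_im2col3(Fm, H, W, N)

col2im3 <- function(dM, H, W, N, C) cpp_col2im3(dM, H, W, N, C)

conv3_fwd <- function(Fm, dims, W_arr, b) {
  M <- im2col3(Fm, dims$H, dims$W, dims$N)
  Wm <- matrix(W_arr, nrow = dim(W_arr)[1] * dim(W_arr)[2] * dim(W_arr)[3])
  Y <- M %*% Wm
  Y <- Y + rep(b, each = nrow(Y))
  list(out = Y, cache = list(M = M, W_arr = W_arr, dims = dims,
                             Cin = ncol(Fm)))
}

conv3_bwd <- function(dY, cache) {
  Wm <- matrix(cache$W_arr, nrow = 9L * cache$Cin)
  dW <- array(crossprod(cache$M, dY), dim = dim(cache$W_arr))
  db <- colSums(dY)
  dM <- dY %*% t(Wm)
  dF <- col2im3(dM, cache$dims$H, cache$dims$W, cache$dims$N, cache$Cin)
  list(dF = dF, dW = dW, db = db)
}

conv1_fwd <- function(Fm, W, b) {
  list(out = Fm %*% W + rep(b, each = nrow(Fm)),
       cache = list(Fm = Fm, W = W))
}

conv1_bwd <- function(dY, cache) {
  list(dF = dY %*% t(cache$W), dW = crossprod(cache$Fm, dY),
       db = colSums(dY))
}

# ---- batch normalisation (per channel over all pixels and batch items) ----

bn_fwd <- function(X, gamma, beta, rs, train, momentum = 0.1, eps = 1e-5) {
  n <- nrow(X)
  if (train) {
    mu <- colMeans(X)
    Xc <- X - rep(mu, each = n)
    v <- colMeans(Xc * Xc)
    rs$mean <- (1 - momentum) * rs$mean + momentum * mu
    rs$var <- (1 - momentum) * rs$var + momentum * v
  } else {
    mu <- rs$mean
    v <- rs$var
    Xc <- X - rep(mu, each = n)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- Xc * rep(inv, each = n)
  Y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(out = Y, rs = rs, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

bn_bwd <- function(dY, cache) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(cache$gamma, each = n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dX <- (dxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n)) *
    rep(cache$inv, each = n)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(X) {
  Y <- X
  Y[Y < 0] <- 0
  list(out = Y, cache = X > 0)
}

relu_bwd <- function(dY, mask) dY * mask

# ---- 2x2 max pooling, stride 2 -------------------------------------------

pool_indices <- function(H, W, N) {
  cache_get(sprintf("pool_%d_%d_%d", H, W, N), function() {
    H2 <- H %/% 2L; W2 <- W %/% 2L
    p <- pixel_coords(H2, W2, N)
    nb <- rep(seq_len(N) - 1L, each = H2 * W2) * (H * W)
    out <- vector("list", 4L)
    j <- 0L
    for (dw in 0:1) for (dh in 0:1) {
      j <- j + 1L
      out[[j]] <- (2L * p$h - 1L + dh) + (2L * p$w - 2L + dw) * H + nb
    }
    out
  })
}

pool_fwd <- function(Fm, dims) {
  idx <- pool_indices(dims$H, dims$W, dims$N)
  cur <- Fm[idx[[1]], , drop = FALSE]
  arg <- matrix(1L, nrow(cur), ncol(cur))
  for (j in 2:4) {
    g <- Fm[idx[[j]], , drop = FALSE]
    sel <- g > cur
    cur[sel] <- g[sel]
    arg[sel] <- j
  }
  list(out = cur, cache = list(arg = arg, dims = dims, C = ncol(Fm)))
}

pool_bwd <- function(dY, cache) {
  dims <- cache$dims
  idx <- pool_indices(dims$H, dims$W, dims$N)
  dF <- matrix(0, dims$H * dims$W * dims$N, cache$C)
  for (j in 1:4) {
    tmp <- dY * (cache$arg == j)
    dF[idx[[j]], ] <- dF[idx[[j]], ] + tmp
  }
  dF
}

# ---- 2x2 stride-2 transposed convolution (learned up-sampling) -----------

up_indices <- function(H, W, N) {
  # maps each input pixel to its four output positions in the 2H x 2W grid
  cache_get(sprintf("up_%d_%d_%d", H, W, N), function() {
    p <- pixel_coords(H, W, N)
    nb <- rep(seq_len(N) - 1L, each = H * W) * (4L * H * W)
    out <- vector("list", 4L)
    j <- 0L
    for (dw in 1:2) for (dh in 1:2) {
      j <- j + 1L
      out[[j]] <- (2L * p$h - 2L + dh) + (2L * p$w - 3L + dw) * (2L * H) + nb
    }
    out
  })
}

tconv_fwd <- function(Fm, dims, Wt, b) {
  Cin <- ncol(Fm); Cout <- dim(Wt)[4]
  Wtm <- matrix(aperm(Wt, c(3, 1, 2, 4)), nrow = Cin)
  Y4 <- Fm %*% Wtm
  idx <- up_indices(dims$H, dims$W, dims$N)
  out <- matrix(rep(b, each = 4L * nrow(Fm)), 4L * nrow(Fm), Cout)
  for (j in 1:4) {
    cols <- j + 4L * (seq_len(Cout) - 1L)
    out[idx[[j]], ] <- out[idx[[j]], ] + Y4[, cols, drop = FALSE]
  }
  list(out = out, cache = list(Fm = Fm, Wt = Wt, dims = dims,
                               Cin = Cin, Cout = Cout))
}

tconv_bwd <- function(dY, cache) {
  dims <- cache$dims
  idx <- up_indices(dims$H, dims$W, dims$N)
  dY4 <- matrix(0, nrow(cache$Fm), 4L * cache$Cout)
  for (j in 1:4) {
    cols <- j + 4L * (seq_len(cache$Cout) - 1L)
    dY4[, cols] <- dY[idx[[j]], , drop = FALSE]
  }
  Wtm <- matrix(aperm(cache$Wt, c(3, 1, 2, 4)), nrow = cache$Cin)
  dWtm <- crossprod(cache$Fm, dY4)
  dWt <- aperm(array(dWtm, dim = c(cache$Cin, 2, 2, cache$Cout)),
               c(2, 3, 1, 4))
  list(dF = dY4 %*% t(Wtm), dW = dWt, db = colSums(dY))
}

# ---- global average pooling and fully connected --------------------------

gap_fwd <- function(Fm, dims) {
  grp <- rep(seq_len(dims$N), each = dims$H * dims$W)
  list(out = rowsum(Fm, grp) / (dims$H * dims$W),
       cache = list(grp = grp, npix = dims$H * dims$W))
}

gap_bwd <- function(dG, cache) {
  dG[cache$grp, , drop = FALSE] / cache$npix
}

fc_fwd <- function(X, W, b) {
  list(out = X %*% W + rep(b, each = nrow(X)), cache = list(X = X, W = W))
}

fc_bwd <- function(dY, cache) {
  list(dX = dY %*% t(cache$W), dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

# ---- 1D convolution along the channel axis (ECA descriptor path) ---------

conv1d_channels <- function(D, w, b) {
  C <- ncol(D)
  ks <- length(w)
  half <- (ks - 1L) %/% 2L
  Z <- matrix(b, nrow(D), C)
  for (t in seq_len(ks)) {
    o <- t - 1L - half
    c_out <- max(1L, 1L - o):min(C, C - o)
    Z[, c_out] <- Z[, c_out] + w[t] * D[, c_out + o, drop = FALSE]
  }
  Z
}

conv1d_channels_bwd <- function(dZ, D, w) {
  C <- ncol(D)
  ks <- length(w)
  half <- (ks - 1L) %/% 2L
  dw <- numeric(ks)
  dD <- matrix(0, nrow(D), C)
  for (t in seq_len(ks)) {
    o <- t - 1L - half
    c_out <- max(1L, 1L - o):min(C, C - o)
    dw[t] <- sum(dZ[, c_out, drop = FALSE] * D[, c_out + o, drop = FALSE])
    dD[, c_out + o] <- dD[, c_out + o] + w[t] * dZ[, c_out, drop = FALSE]
  }
  list(dw = dw, db = sum(dZ), dD = dD)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- Adam ---------------------------------------------------------------

params_map <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]])) {
    out <- vector("list", length(args[[1]]))
    names(out) <- names(args[[1]])
    for (i in seq_along(out)) {
      out[[i]] <- do.call(params_map,
                          c(list(f), lapply(args, `[[`, i)))
    }
    out
  } else {
    do.call(f, args)
  }
}

adam_init <- function(params) {
  zero <- function(p) p * 0
  list(m = params_map(zero, params), v = params_map(zero, params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- params_map(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- params_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- params_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}
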