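#' Network configuration
#'
#' Hyper-parameters of the dual-branch network: a U-Net style
#' encoder-decoder segmentation trunk with a multi-layer efficient channel
#' attention (ECA) block after every encoder stage, and a diameter-regression
#' branch fed by the global average pool of the deepest (bottleneck)
#' features.
#'
#' @param input_channels input image channels (1 for grayscale B-mode).
#' @param num_classes segmentation classes (2: background, plaque).
#' @param depth number of down-sampling stages.
#' @param base_channels channels of the first encoder stage; doubled per
#'   stage.
#' @param eca_conv_layers number of stacked 1D convolutions inside each ECA
#'   block (>= 1; >= 2 gives the multi-layer variant, the default).
#' @param eca_kernel_size odd integer, or `"adaptive"` to derive the kernel
#'   from the channel count via [adaptive_kernel_size()].
#' @param use_eca logical ablation switch; `FALSE` yields a plain U-Net
#'   encoder (used by the segment-then-measure baseline).
#' @param regression_hidden_units hidden units of the regression branch.
#' @return object of class `model_config`.
#' @export
model_config <- function(input_channels = 1L, num_classes = 2L, depth = 4L,
                         base_channels = 64L, eca_conv_layers = 2L,
                         eca_kernel_size = "adaptive", use_eca = TRUE,
                         regression_hidden_units = 64L) {
  if (!identical(eca_kernel_size, "adaptive")) {
    ks <- as.integer(eca_kernel_size)
    if (ks %% 2L == 0L) stop("eca_kernel_size must be odd")
    eca_kernel_size <- ks
  }
  stopifnot(depth >= 1, base_channels >= 1, eca_conv_layers >= 1,
            num_classes >= 2, regression_hidden_units >= 1)
  structure(list(input_channels = as.integer(input_channels),
                 num_classes = as.integer(num_classes),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 eca_conv_layers = as.integer(eca_conv_layers),
                 eca_kernel_size = eca_kernel_size,
                 use_eca = isTRUE(use_eca),
                 regression_hidden_units = as.integer(regression_hidden_units),
                 regression_outputs = 2L),
            class = "model_config")
}

#' Adaptive ECA kernel size from the channel count
#'
#' `k = |log2(C)/gamma + b/gamma|` with `gamma = 2`, `b = 1`, rounded to the
#' nearest odd integer and clamped to at least 3 — the local cross-channel
#' interaction span grows logarithmically with the channel count.
#'
#' @param C positive integer channel count.
#' @return odd integer kernel size >= 3.
#' @examples
#' adaptive_kernel_size(64)  # 3
#' @export
adaptive_kernel_size <- function(C) {
  stopifnot(C >= 1)
  t <- abs(log2(C) / 2 + 1 / 2)
  k <- 2L * as.integer(round((t - 1) / 2)) + 1L
  max(3L, k)
}

eca_kernel_for <- function(cfg, C) {
  if (identical(cfg$eca_kernel_size, "adaptive")) adaptive_kernel_size(C)
  else cfg$eca_kernel_size
}

#' Multi-layer efficient channel attention
#'
#' Channel reweighting: (1) global average pooling over the spatial
#' dimensions gives one descriptor value per channel; (2) the descriptor
#' passes through `length(weights)` successive 1D convolutions along the
#' channel axis (zero-padded, single channel in and out), each but the last
#' followed by a rectifier; (3) a logistic sigmoid maps the result to
#' weights in (0, 1); (4) the input is scaled channel-wise by the weights.
#'
#' @param feature_map numeric array of dim `(H, W, C, N)` (a single image
#'   may be passed as `(H, W, C)`).
#' @param weights list with one element per 1D-convolution layer, each a
#'   list with `w` (odd-length numeric kernel) and `b` (scalar bias); see
#'   [eca_init()].
#' @return array of the same shape as `feature_map`, plus the channel
#'   weights as attribute `"channel_weights"` (an `N x C` matrix).
#' @export
eca_ml <- function(feature_map, weights) {
  x <- feature_map
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L)
  for (ly in weights)
    if (length(ly$w) %% 2L == 0L) stop("ECA kernel size must be odd")
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Fm <- matrix(aperm(x, c(1, 2, 4, 3)), nrow = H * W * N, ncol = C)
  res <- eca_fwd(Fm, list(H = H, W = W, N = N), weights)
  out <- aperm(array(res$out, dim = c(H, W, N, C)), c(1, 2, 4, 3))
  if (length(dim(feature_map)) == 3L) dim(out) <- dim(feature_map)
  attr(out, "channel_weights") <- res$cache$A
  out
}

#' Initialize ECA 1D-convolution weights
#'
#' @param layers number of stacked 1D convolutions.
#' @param kernel_size odd kernel length.
#' @param sd standard deviation of the random initialisation.
#' @return list of per-layer `list(w, b)`.
#' @export
eca_init <- function(layers, kernel_size, sd = 0.1) {
  if (kernel_size %% 2L == 0L) stop("ECA kernel size must be odd")
  lapply(seq_len(layers), function(l)
    list(w = stats::rnorm(kernel_size, 0, sd), b = 0))
}

eca_fwd <- function(Fm, dims, layers) {
  grp <- rep(seq_len(dims$N), each = dims$H * dims$W)
  npix <- dims$H * dims$W
  D <- rowsum(Fm, grp) / npix
  L <- length(layers)
  xs <- vector("list", L)   # input to each conv layer
  masks <- vector("list", L)
  x <- D
  for (l in seq_len(L)) {
    xs[[l]] <- x
    z <- conv1d_channels(x, layers[[l]]$w, layers[[l]]$b)
    if (l < L) {
      masks[[l]] <- z > 0
      z[z < 0] <- 0
    }
    x <- z
  }
  A <- sigmoid(x)
  out <- Fm * A[grp, , drop = FALSE]
  list(out = out,
       cache = list(Fm = Fm, A = A, grp = grp, npix = npix, xs = xs,
                    masks = masks))
}

eca_bwd <- function(dY, cache, layers) {
  A <- cache$A
  dFm <- dY * A[cache$grp, , drop = FALSE]
  dA <- rowsum(cache$Fm * dY, cache$grp)
  dz <- dA * A * (1 - A)
  L <- length(layers)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    g <- conv1d_channels_bwd(dz, cache$xs[[l]], layers[[l]]$w)
    grads[[l]] <- list(w = g$dw, b = g$db)
    if (l > 1L) dz <- g$dD * cache$masks[[l - 1L]]
    else dD <- g$dD
  }
  list(dF = dFm + dD[cache$grp, , drop = FALSE] / cache$npix, grads = grads)
}

# ---- construction --------------------------------------------------------

rand_conv3 <- function(Cin, Cout) {
  array(stats::rnorm(9 * Cin * Cout, 0, sqrt(2 / (9 * Cin))),
        dim = c(3, 3, Cin, Cout))
}

init_cb <- function(Cin, Cout) {
  list(W = rand_conv3(Cin, Cout), b = numeric(Cout),
       gamma = rep(1, Cout), beta = numeric(Cout))
}

init_bn_stats <- function(Cout) list(mean = numeric(Cout), var = rep(1, Cout))

stage_channels <- function(cfg) cfg$base_channels * 2^(seq_len(cfg$depth) - 1L)

#' Build the dual-branch network
#'
#' Encoder of `depth` stages (two 3x3 conv + batch norm + rectifier blocks,
#' then multi-layer ECA, then 2x max pooling; channels doubling per stage),
#' a bottleneck, a decoder mirroring the encoder with 2x2 transposed
#' convolutions and skip concatenations, a 1x1 convolution producing
#' per-pixel class scores, and a regression branch (global average pool of
#' the bottleneck, one hidden rectified layer, linear 2-output layer giving
#' long and short diameter).
#'
#' @param config a [model_config()].
#' @param seed integer seed for the weight initialisation.
#' @return object of class `plaquenet_model` holding `config`, trainable
#'   `params` and batch-norm running statistics `bn`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  with_phantom_seed(seed, 0L, {
    ch <- stage_channels(config)
    chb <- config$base_channels * 2^config$depth
    params <- list()
    bn <- list()
    enc <- list(); enc_bn <- list()
    cin <- config$input_channels
    for (i in seq_len(config$depth)) {
      st <- list(cb1 = init_cb(cin, ch[i]), cb2 = init_cb(ch[i], ch[i]))
      if (config$use_eca)
        st$eca <- eca_init(config$eca_conv_layers,
                           eca_kernel_for(config, ch[i]))
      enc[[i]] <- st
      enc_bn[[i]] <- list(cb1 = init_bn_stats(ch[i]),
                          cb2 = init_bn_stats(ch[i]))
      cin <- ch[i]
    }
    params$enc <- enc; bn$enc <- enc_bn
    params$bott <- list(cb1 = init_cb(ch[config$depth], chb),
                        cb2 = init_cb(chb, chb))
    bn$bott <- list(cb1 = init_bn_stats(chb), cb2 = init_bn_stats(chb))
    dec <- list(); dec_bn <- list()
    cur <- chb
    for (i in rev(seq_len(config$depth))) {
      dec[[i]] <- list(
        up = list(W = array(stats::rnorm(4 * cur * ch[i], 0,
                                         sqrt(2 / (4 * cur))),
                            dim = c(2, 2, cur, ch[i])),
                  b = numeric(ch[i])),
        cb1 = init_cb(2L * ch[i], ch[i]),
        cb2 = init_cb(ch[i], ch[i]))
      dec_bn[[i]] <- list(cb1 = init_bn_stats(ch[i]),
                          cb2 = init_bn_stats(ch[i]))
      cur <- ch[i]
    }
    params$dec <- dec; bn$dec <- dec_bn
    params$head <- list(W = matrix(stats::rnorm(ch[1] * config$num_classes,
                                                0, sqrt(2 / ch[1])),
                                   ch[1], config$num_classes),
                        b = numeric(config$num_classes))
    hid <- config$regression_hidden_units
    params$reg <- list(
      fc1 = list(W = matrix(stats::rnorm(chb * hid, 0, sqrt(2 / chb)),
                            chb, hid),
                 b = numeric(hid)),
      fc2 = list(W = matrix(stats::rnorm(hid * 2L, 0, sqrt(1 / hid)),
                            hid, 2L),
                 b = numeric(2L)))
    structure(list(config = config, params = params, bn = bn),
              class = "plaquenet_model")
  })
}

#' Number of trainable parameters
#' @param model a `plaquenet_model`.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  tot <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else tot <<- tot + length(x)
    invisible(NULL)
  }
  walk(model$params)
  tot
}

cb_fwd <- function(Fm, dims, p, rs, train) {
  c1 <- conv3_fwd(Fm, dims, p$W, p$b)
  b1 <- bn_fwd(c1$out, p$gamma, p$beta, rs, train)
  r1 <- relu_fwd(b1$out)
  list(out = r1$out, rs = b1$rs,
       cache = list(conv = c1$cache, bn = b1$cache, relu = r1$cache))
}

cb_bwd <- function(dY, cache) {
  dY <- relu_bwd(dY, cache$relu)
  b <- bn_bwd(dY, cache$bn)
  cv <- conv3_bwd(b$dX, cache$conv)
  list(dF = cv$dF,
       grads = list(W = cv$dW, b = cv$db, gamma = b$dgamma, dbeta = b$dbeta))
}

# Full forward pass on a batch in matrix form.
# images: (H*W*N) x 1 matrix; returns scores (H*W*N) x K, diam N x 2,
# updated bn stats, and (when train = TRUE) the caches for backward.
nn_forward <- function(params, bn, Fm, dims, cfg, train = FALSE) {
  if (dims$H %% 2^cfg$depth != 0 || dims$W %% 2^cfg$depth != 0)
    stop(sprintf("input %dx%d not divisible by 2^depth = %d",
                 dims$H, dims$W, 2^cfg$depth))
  caches <- list(enc = list(), dec = list())
  skips <- list(); skip_dims <- list()
  d <- dims
  for (i in seq_len(cfg$depth)) {
    st <- params$enc[[i]]
    c1 <- cb_fwd(Fm, d, st$cb1, bn$enc[[i]]$cb1, train)
    bn$enc[[i]]$cb1 <- c1$rs
    c2 <- cb_fwd(c1$out, d, st$cb2, bn$enc[[i]]$cb2, train)
    bn$enc[[i]]$cb2 <- c2$rs
    Fm <- c2$out
    ec <- NULL
    if (cfg$use_eca) {
      e <- eca_fwd(Fm, d, st$eca)
      Fm <- e$out
      ec <- e$cache
    }
    skips[[i]] <- Fm; skip_dims[[i]] <- d
    pl <- pool_fwd(Fm, d)
    Fm <- pl$out
    caches$enc[[i]] <- list(cb1 = c1$cache, cb2 = c2$cache, eca = ec,
                            pool = pl$cache)
    d <- list(H = d$H %/% 2L, W = d$W %/% 2L, N = d$N)
  }
  c1 <- cb_fwd(Fm, d, params$bott$cb1, bn$bott$cb1, train)
  bn$bott$cb1 <- c1$rs
  c2 <- cb_fwd(c1$out, d, params$bott$cb2, bn$bott$cb2, train)
  bn$bott$cb2 <- c2$rs
  Fb <- c2$out
  caches$bott <- list(cb1 = c1$cache, cb2 = c2$cache)
  dims_b <- d

  g <- gap_fwd(Fb, d)
  f1 <- fc_fwd(g$out, params$reg$fc1$W, params$reg$fc1$b)
  r1 <- relu_fwd(f1$out)
  f2 <- fc_fwd(r1$out, params$reg$fc2$W, params$reg$fc2$b)
  diam <- f2$out
  caches$reg <- list(gap = g$cache, fc1 = f1$cache, relu = r1$cache,
                     fc2 = f2$cache)

  Fm <- Fb
  ch <- stage_channels(cfg)
  for (i in rev(seq_len(cfg$depth))) {
    st <- params$dec[[i]]
    up <- tconv_fwd(Fm, d, st$up$W, st$up$b)
    d <- list(H = d$H * 2L, W = d$W * 2L, N = d$N)
    Fm <- cbind(skips[[i]], up$out)
    c1 <- cb_fwd(Fm, d, st$cb1, bn$dec[[i]]$cb1, train)
    bn$dec[[i]]$cb1 <- c1$rs
    c2 <- cb_fwd(c1$out, d, st$cb2, bn$dec[[i]]$cb2, train)
    bn$dec[[i]]$cb2 <- c2$rs
    Fm <- c2$out
    caches$dec[[i]] <- list(up = up$cache, cb1 = c1$cache, cb2 = c2$cache,
                            skip_channels = ch[i])
  }
  hd <- conv1_fwd(Fm, params$head$W, params$head$b)
  caches$head <- hd$cache
  caches$dims_b <- dims_b
  list(scores = hd$out, diam = diam, bn = bn,
       cache = if (train) caches else NULL)
}

# Backward pass mirroring nn_forward; returns gradients in the exact shape
# of `params`.
nn_backward <- function(params, cfg, caches, dscores, ddiam) {
  grads <- list(enc = vector("list", cfg$depth), bott = NULL,
                dec = vector("list", cfg$depth), head = NULL, reg = NULL)
  hd <- conv1_bwd(dscores, caches$head)
  grads$head <- list(W = hd$dW, b = hd$db)
  dF <- hd$dF
  dskips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {   # decoder stages, high-res first
    cc <- caches$dec[[i]]
    c2 <- cb_bwd(dF, cc$cb2)
    c1 <- cb_bwd(c2$dF, cc$cb1)
    nch <- cc$skip_channels
    dskips[[i]] <- c1$dF[, seq_len(nch), drop = FALSE]
    dup <- c1$dF[, nch + seq_len(ncol(c1$dF) - nch), drop = FALSE]
    up <- tconv_bwd(dup, cc$up)
    grads$dec[[i]] <- list(up = list(W = up$dW, b = up$db),
                           cb1 = rename_cb(c1$grads), cb2 = rename_cb(c2$grads))
    dF <- up$dF
  }
  # regression branch into the bottleneck
  f2 <- fc_bwd(ddiam, caches$reg$fc2)
  dr <- relu_bwd(f2$dX, caches$reg$relu)
  f1 <- fc_bwd(dr, caches$reg$fc1)
  dFb_reg <- gap_bwd(f1$dX, caches$reg$gap)
  grads$reg <- list(fc1 = list(W = f1$dW, b = f1$db),
                    fc2 = list(W = f2$dW, b = f2$db))
  dF <- dF + dFb_reg
  c2 <- cb_bwd(dF, caches$bott$cb2)
  c1 <- cb_bwd(c2$dF, caches$bott$cb1)
  grads$bott <- list(cb1 = rename_cb(c1$grads), cb2 = rename_cb(c2$grads))
  dF <- c1$dF
  for (i in rev(seq_len(cfg$depth))) {
    cc <- caches$enc[[i]]
    dF <- pool_bwd(dF, cc$pool)
    dF <- dF + dskips[[i]]
    st_grads <- list()
    if (cfg$use_eca) {
      e <- eca_bwd(dF, cc$eca, params$enc[[i]]$eca)
      dF <- e$dF
      st_grads$eca <- e$grads
    }
    c2 <- cb_bwd(dF, cc$cb2)
    c1 <- cb_bwd(c2$dF, cc$cb1)
    g <- list(cb1 = rename_cb(c1$grads), cb2 = rename_cb(c2$grads))
    if (cfg$use_eca) g$eca <- st_grads$eca
    grads$enc[[i]] <- g
    dF <- c1$dF
  }
  grads
}

rename_cb <- function(g) list(W = g$W, b = g$b, gamma = g$gamma, beta = g$dbeta)

batch_to_matrix <- function(images) {
  # images: list of H x W matrices -> (H*W*N) x 1 matrix plus dims
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  Fm <- matrix(unlist(images, use.names = FALSE), ncol = 1L)
  list(Fm = Fm, dims = list(H = H, W = W, N = length(images)))
}

#' Forward pass of the network
#'
#' @param model a `plaquenet_model`.
#' @param images list of H x W matrices (preprocessed intensities), or one
#'   matrix.
#' @param train logical; `TRUE` uses batch statistics (training mode).
#' @return list with `segmentation_scores` (H x W x num_classes x N array
#'   of unnormalized class scores), `diameter_predictions` (N x 2 matrix,
#'   columns long/short, network output units).
#' @export
forward <- function(model, images, train = FALSE) {
  if (is.matrix(images)) images <- list(images)
  bm <- batch_to_matrix(images)
  out <- nn_forward(model$params, model$bn, bm$Fm, bm$dims, model$config,
                    train = train)
  K <- model$config$num_classes
  sc <- aperm(array(out$scores,
                    dim = c(bm$dims$H, bm$dims$W, bm$dims$N, K)),
              c(1, 2, 4, 3))
  list(segmentation_scores = sc, diameter_predictions = out$diam)
}

#' @export
print.plaquenet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "dual-branch plaque network: depth %d, base %d channels, %s ECA (%d x 1D conv)\n",
    cfg$depth, cfg$base_channels,
    if (cfg$use_eca) "multi-layer" else "no", cfg$eca_conv_layers))
  cat(sprintf("  %d trainable parameters, %d classes + 2 diameters\n",
              n_parameters(x), cfg$num_classes))
  invisible(x)
}
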