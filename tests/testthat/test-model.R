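modify_param <- function(par, path, i, delta) {
  if (length(path) == 1) {
    par[[path[[1]]]][i] <- par[[path[[1]]]][i] + delta
    par
  } else {
    par[[path[[1]]]] <- modify_param(par[[path[[1]]]], path[-1], i, delta)
    par
  }
}

test_that("network outputs have the contracted shapes and are deterministic", {
  cfg <- model_config(depth = 4L, base_channels = 4L,
                      regression_hidden_units = 8L)
  m <- build_model(cfg, seed = 2)
  set.seed(1)
  img <- matrix(runif(64 * 64), 64, 64)
  out <- forward(m, img)
  expect_equal(dim(out$segmentation_scores), c(64, 64, 2, 1))
  expect_equal(dim(out$diameter_predictions), c(1, 2))
  expect_true(all(is.finite(out$diameter_predictions)))

  batch <- lapply(1:3, function(i) matrix(runif(64 * 64), 64, 64))
  outb <- forward(m, batch)
  expect_equal(dim(outb$segmentation_scores), c(64, 64, 2, 3))
  expect_equal(dim(outb$diameter_predictions), c(3, 2))

  expect_identical(forward(m, batch), forward(m, batch))
  expect_error(forward(m, matrix(0, 60, 60)), "divisible")
})

test_that("capacity grows with base channels and bias drives zeroed head", {
  cfg1 <- model_config(depth = 2L, base_channels = 4L)
  cfg2 <- model_config(depth = 2L, base_channels = 8L)
  expect_gt(n_parameters(build_model(cfg2, 1)),
            n_parameters(build_model(cfg1, 1)))

  # zeroing the regression output layer leaves only its bias
  m <- build_model(cfg1, seed = 3)
  m$params$reg$fc2$W[] <- 0
  m$params$reg$fc2$b <- c(1.5, -0.5)
  set.seed(2)
  out <- forward(m, lapply(1:2, function(i) matrix(runif(32 * 32), 32, 32)))
  expect_equal(out$diameter_predictions,
               matrix(c(1.5, 1.5, -0.5, -0.5), 2, 2), ignore_attr = TRUE)
})

test_that("multi-layer ECA honours its analytic contracts", {
  set.seed(3)
  x <- array(rnorm(8 * 8 * 16 * 2), c(8, 8, 16, 2))

  # zeroed convolutions: every weight is sigmoid(0) = 0.5
  w0 <- list(list(w = c(0, 0, 0), b = 0), list(w = c(0, 0, 0), b = 0))
  y <- eca_ml(x, w0)
  expect_equal(max(abs(y - 0.5 * x)), 0)

  # random weights: output shape preserved, channel weights in (0, 1)
  wr <- eca_init(2, 5)
  yr <- eca_ml(x, wr)
  expect_equal(dim(yr), dim(x))
  a <- attr(yr, "channel_weights")
  expect_true(all(a > 0 & a < 1))

  expect_error(eca_ml(x, list(list(w = c(1, 1), b = 0))), "odd")
})

test_that("single-layer ECA matches an independently coded reference", {
  set.seed(5)
  x <- array(rnorm(6 * 6 * 10 * 3), c(6, 6, 10, 3))
  w <- rnorm(3); b <- 0.3
  y <- eca_ml(x, list(list(w = w, b = b)))
  ref <- x
  for (n in 1:3) {
    d <- sapply(1:10, function(c) mean(x[, , c, n]))
    dp <- c(0, d, 0)
    z <- sapply(1:10, function(c) sum(w * dp[c:(c + 2)]) + b)
    a <- 1 / (1 + exp(-z))
    for (c in 1:10) ref[, , c, n] <- x[, , c, n] * a[c]
  }
  expect_equal(y, ref, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("adaptive kernel size follows the log2 rule and is always odd", {
  expect_equal(adaptive_kernel_size(64), 3)
  expect_equal(adaptive_kernel_size(1), 3)
  expect_equal(adaptive_kernel_size(256), 5)
  for (C in c(1, 2, 8, 16, 32, 64, 128, 512, 1024))
    expect_equal(adaptive_kernel_size(C) %% 2, 1)
})

test_that("attention is live in the graph", {
  cfg <- model_config(depth = 2L, base_channels = 4L)
  m <- build_model(cfg, seed = 7)
  m_off <- m
  m_off$config$use_eca <- FALSE  # bypass the attention blocks
  set.seed(4)
  img <- matrix(runif(32 * 32), 32, 32)
  a <- forward(m, img)
  b <- forward(m_off, img)
  expect_false(isTRUE(all.equal(a$segmentation_scores,
                                b$segmentation_scores)))
})

test_that("analytic network gradients match finite differences", {
  cfg <- model_config(depth = 2L, base_channels = 3L,
                      regression_hidden_units = 4L)
  m <- build_model(cfg, seed = 3)
  set.seed(10)
  imgs <- lapply(1:2, function(i) matrix(runif(16 * 16), 16, 16))
  labels <- rbinom(512, 1, 0.3)
  truth <- matrix(runif(4), 2, 2)
  bm <- plaquenet:::batch_to_matrix(imgs)
  lossfun <- function(params) {
    fw <- plaquenet:::nn_forward(params, m$bn, bm$Fm, bm$dims, cfg,
                                 train = TRUE)
    joint_loss(fw$scores, labels, fw$diam, truth, loss_weights(1, 1))$total
  }
  fw <- plaquenet:::nn_forward(m$params, m$bn, bm$Fm, bm$dims, cfg,
                               train = TRUE)
  lb <- joint_loss(fw$scores, labels, fw$diam, truth, loss_weights(1, 1))
  gr <- plaquenet:::nn_backward(m$params, cfg, fw$cache,
                                attr(lb, "grad_scores"),
                                attr(lb, "grad_pred"))
  expect_true(all(is.finite(unlist(gr))))
  paths <- list(list("head", "W"), list("reg", "fc1", "W"),
                list("bott", "cb1", "W"), list("enc", 1L, "cb1", "W"),
                list("enc", 2L, "eca", 2L, "w"), list("dec", 1L, "up", "W"),
                list("dec", 2L, "cb1", "gamma"))
  eps <- 1e-5
  for (path in paths) {
    g <- gr
    for (k in path) g <- g[[k]]
    i <- which.max(abs(g))  # largest-gradient coordinate: well-conditioned
    num <- (lossfun(modify_param(m$params, path, i, eps)) -
            lossfun(modify_param(m$params, path, i, -eps))) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("the model can overfit four samples", {
  cfg <- model_config(depth = 2L, base_channels = 4L,
                      regression_hidden_units = 8L)
  m <- build_model(cfg, seed = 5)
  pc <- noise_free_config(seed = 20)
  samples <- lapply(0:3, function(i) generate_sample(pc, i))
  imgs <- lapply(samples, function(s) preprocess_image(s$image))
  labels <- unlist(lapply(samples, `[[`, "mask"))
  truth <- do.call(rbind, lapply(samples, function(s)
    c(s$long_diameter_mm, s$short_diameter_mm)))
  truth <- scale(truth)[, ]  # standardized targets
  bm <- plaquenet:::batch_to_matrix(imgs)
  params <- m$params; bn <- m$bn
  opt <- plaquenet:::adam_init(params)
  total <- Inf
  for (step in 1:200) {
    fw <- plaquenet:::nn_forward(params, bn, bm$Fm, bm$dims, cfg,
                                 train = TRUE)
    bn <- fw$bn
    lb <- joint_loss(fw$scores, labels, fw$diam, truth, loss_weights(1, 1))
    total <- lb$total
    if (total < 0.05) break
    gr <- plaquenet:::nn_backward(params, cfg, fw$cache,
                                  attr(lb, "grad_scores"),
                                  attr(lb, "grad_pred"))
    st <- plaquenet:::adam_step(params, gr, opt, 0.003)
    params <- st$params; opt <- st$state
  }
  expect_lt(total, 0.1)
})
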