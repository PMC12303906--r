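test_that("cross-entropy matches its closed forms and a brute-force oracle", {
  # uniform scores over 2 classes: ln 2 per pixel
  sc <- matrix(0, 24, 2)
  expect_equal(as.numeric(segmentation_loss(sc, rep(c(0, 1), 12))), log(2))

  # near-certain correct prediction drives the loss to ~0
  y <- rep(c(0L, 1L), 8)
  sure <- cbind(ifelse(y == 0, 50, -50), ifelse(y == 1, 50, -50))
  expect_lt(as.numeric(segmentation_loss(sure, y)), 1e-6)

  # brute-force binary oracle on random 8x8 cases
  set.seed(2)
  for (i in 1:50) {
    S <- matrix(rnorm(128), 64, 2)
    y <- rbinom(64, 1, 0.5)
    p1 <- exp(S[, 2]) / (exp(S[, 1]) + exp(S[, 2]))
    oracle <- -mean(y * log(p1) + (1 - y) * log(1 - p1))
    expect_equal(as.numeric(segmentation_loss(S, y)), oracle,
                 tolerance = 1e-10)
  }
  expect_error(segmentation_loss(matrix(0, 4, 2), c(0, 1, 2, 0)), "range")
})

test_that("size loss is the mean squared error over all entries", {
  p <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(as.numeric(size_loss(p, p)), 0)
  expect_equal(as.numeric(size_loss(p + 0.5, p)), 0.25)
  set.seed(4)
  for (i in 1:20) {
    a <- matrix(rnorm(8), 4, 2); b <- matrix(rnorm(8), 4, 2)
    expect_equal(as.numeric(size_loss(a, b)), mean((a - b)^2))
  }
  expect_error(size_loss(matrix(0, 2, 2), matrix(0, 3, 2)), "mismatch")
})

test_that("joint loss is the stated weighted sum and degenerates correctly", {
  set.seed(5)
  S <- matrix(rnorm(64), 32, 2)
  y <- rbinom(32, 1, 0.4)
  pr <- matrix(rnorm(8), 4, 2); tr <- matrix(rnorm(8), 4, 2)

  jb <- joint_loss(S, y, pr, tr, loss_weights(1, 0))
  expect_equal(jb$total, jb$seg_term)

  jb2 <- joint_loss(S, y, pr, tr, loss_weights(2, 3))
  expect_equal(jb2$total, 2 * jb2$seg_term + 3 * jb2$size_term)
  # doubling alpha adds exactly one extra seg term
  jb3 <- joint_loss(S, y, pr, tr, loss_weights(4, 3))
  expect_equal(jb3$total - jb2$total, 2 * jb2$seg_term)

  # joint optimum: both heads perfect
  sure <- cbind(ifelse(y == 0, 50, -50), ifelse(y == 1, 50, -50))
  expect_lt(joint_loss(sure, y, tr, tr, loss_weights(1, 1))$total, 1e-6)

  expect_error(loss_weights(0, 0), "positive")
})

test_that("loss gradients agree with finite differences", {
  set.seed(6)
  S <- matrix(rnorm(32), 16, 2)
  y <- rbinom(16, 1, 0.5)
  pr <- matrix(rnorm(6), 3, 2); tr <- matrix(rnorm(6), 3, 2)
  w <- loss_weights(1.3, 0.7)
  jb <- joint_loss(S, y, pr, tr, w)
  gS <- attr(jb, "grad_scores"); gP <- attr(jb, "grad_pred")
  eps <- 1e-6
  for (i in sample(length(S), 6)) {
    Sp <- S; Sp[i] <- Sp[i] + eps
    Sm <- S; Sm[i] <- Sm[i] - eps
    num <- (joint_loss(Sp, y, pr, tr, w)$total -
            joint_loss(Sm, y, pr, tr, w)$total) / (2 * eps)
    expect_equal(gS[i], num, tolerance = 1e-4)
  }
  for (i in seq_along(pr)) {
    Pp <- pr; Pp[i] <- Pp[i] + eps
    Pm <- pr; Pm[i] <- Pm[i] - eps
    num <- (joint_loss(S, y, Pp, tr, w)$total -
            joint_loss(S, y, Pm, tr, w)$total) / (2 * eps)
    expect_equal(gP[i], num, tolerance = 1e-4)
  }
})

test_that("homoscedastic auto-balancing shrinks the weight of a large loss", {
  # closed form at s = 0
  w0 <- auto_balance(list(s_seg = 0, s_size = 0))
  expect_equal(w0$alpha, 1)
  expect_equal(w0$beta, 0.5)
  expect_gt(auto_balance(list(s_seg = 3, s_size = -2))$alpha, 0)

  # persistent L_size >> L_seg drives s_size up and beta down
  set.seed(8)
  S <- matrix(rnorm(32), 16, 2); y <- rbinom(16, 1, 0.5)
  big <- matrix(10, 3, 2); zero <- matrix(0, 3, 2)
  s <- list(s_seg = 0, s_size = 0)
  opt <- plaquenet:::adam_init(s)
  for (i in 1:200) {
    lb <- joint_loss(S, y, big, zero, loss_weights(mode = "auto"), s = s)
    st <- plaquenet:::adam_step(s, attr(lb, "grad_s"), opt, 0.05)
    s <- st$params; opt <- st$state
  }
  expect_gt(s$s_size, 1)
  w <- auto_balance(s)
  expect_lt(w$beta, 0.5)
  expect_gt(w$beta, 0)
})

test_that("loss breakdown identity holds across weight settings", {
  set.seed(9)
  for (i in 1:20) {
    S <- matrix(rnorm(32), 16, 2); y <- rbinom(16, 1, 0.5)
    pr <- matrix(rnorm(4), 2, 2); tr <- matrix(rnorm(4), 2, 2)
    a <- runif(1, 0, 3); b <- runif(1, 0.1, 3)
    jb <- joint_loss(S, y, pr, tr, loss_weights(a, b))
    expect_equal(jb$total,
                 jb$alpha_used * jb$seg_term + jb$beta_used * jb$size_term,
                 tolerance = 1e-12)
  }
})
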