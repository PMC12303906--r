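test_that("largest_component keeps the biggest 8-connected blob", {
  m <- matrix(0L, 16, 16)
  m[2:4, 2:4] <- 1L          # 9 px blob
  m[10:11, 10] <- 1L         # 2 px blob
  out <- largest_component(m)
  expect_equal(sum(out), 9)
  expect_equal(out[2:4, 2:4], matrix(1L, 3, 3))
  expect_identical(largest_component(matrix(0L, 4, 4)), matrix(0L, 4, 4))
  # single blob unchanged
  single <- matrix(0L, 8, 8); single[3:5, 4:6] <- 1L
  expect_identical(largest_component(single), single)
  # diagonal touching counts as connected (8-connectivity)
  diag_m <- matrix(0L, 6, 6)
  diag_m[cbind(1:4, 1:4)] <- 1L
  expect_equal(sum(largest_component(diag_m)), 4)
})

test_that("largest_component matches an independent flood-fill oracle", {
  set.seed(21)
  for (i in 1:25) {
    m <- random_blob_mask(14, 14, p = runif(1, 0.2, 0.6))
    expect_identical(largest_component(m), oracle_largest_component(m))
  }
})

test_that("diameters of canonical shapes follow the caliper conventions", {
  # filled axis-aligned ellipse, semi-axes 40 x 20 px at 0.1 mm/px
  m <- make_ellipse_mask(128, 128, 64, 64, 40, 20)
  d <- measure_diameters(m, 0.1)
  expect_lt(abs(d$long_mm - 8.0), 0.2)
  expect_lt(abs(d$short_mm - 4.0), 0.2)

  # 1 x 10 pixel row at spacing 1: centre-to-centre long, pixel-width short
  r <- matrix(0L, 5, 20); r[3, 6:15] <- 1L
  dr <- measure_diameters(r, 1)
  expect_equal(dr$long_mm, 9.0)
  expect_equal(dr$short_mm, 1.0)

  # single pixel
  p1 <- matrix(0L, 5, 5); p1[3, 3] <- 1L
  dp <- measure_diameters(p1, 0.2)
  expect_equal(dp$long_mm, 0.2)
  expect_equal(dp$short_mm, 0.2)

  expect_error(measure_diameters(matrix(0L, 4, 4), 1), "no plaque")
})

test_that("long diameter equals the exhaustive pairwise-distance maximum", {
  set.seed(33)
  for (i in 1:20) {
    m <- make_ellipse_mask(40, 40, runif(1, 15, 25), runif(1, 15, 25),
                           runif(1, 4, 12), runif(1, 2, 8),
                           runif(1, 0, pi))
    if (sum(m) == 0) next
    d <- measure_diameters(m, 0.15)
    expect_equal(d$long_mm, oracle_feret_long(m, 0.15))
  }
  for (i in 1:10) {
    m <- largest_component(random_blob_mask(20, 20, 0.5))
    if (sum(m) == 0) next
    d <- measure_diameters(m, 1)
    expect_equal(d$long_mm, oracle_feret_long(m, 1))
  }
})

test_that("diameters are invariant under flips and 90-degree rotations", {
  set.seed(44)
  m <- make_ellipse_mask(36, 36, 18, 17, 10, 5, 0.4)
  d0 <- measure_diameters(m, 0.1)
  variants <- list(m[nrow(m):1, ], m[, ncol(m):1], t(m),
                   t(m)[ncol(m):1, ])
  for (v in variants) {
    dv <- measure_diameters(v, 0.1)
    expect_equal(dv$long_mm, d0$long_mm)
    expect_equal(dv$short_mm, d0$short_mm)
  }
})

test_that("upsampling k-fold with spacing/k leaves diameters nearly unchanged", {
  # axis-aligned so the replication end-caps extend each extreme pixel by
  # exactly (k-1)/2 sub-pixels per side: the bias is bounded by 2/k pixels
  m <- make_ellipse_mask(32, 32, 16, 16, 10, 6)
  d0 <- measure_diameters(m, 0.2)
  k <- 3L
  big <- m[rep(seq_len(nrow(m)), each = k), rep(seq_len(ncol(m)), each = k)]
  dk <- measure_diameters(big, 0.2 / k)
  # 10% slack: the extreme pair of the refined boundary need not lie on
  # the original extreme axis, adding a sub-pixel diagonal component
  expect_lte(abs(dk$long_mm - d0$long_mm), 2 / k * 0.2 * 1.1)
  expect_lte(abs(dk$short_mm - d0$short_mm), 2 / k * 0.2 * 1.1)
})

test_that("min-area-rectangle alternative orders its sides consistently", {
  m <- make_ellipse_mask(48, 48, 24, 24, 14, 6, 0.7)
  d <- measure_diameters(m, 0.1, method = "min_rect")
  expect_gte(d$long_mm, d$short_mm)
  df <- measure_diameters(m, 0.1)
  # rectangle sides track the Feret pair for an ellipse
  expect_lt(abs(d$long_mm - df$long_mm), 0.5)
})
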