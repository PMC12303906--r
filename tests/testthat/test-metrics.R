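test_that("confusion counts match a per-pixel loop on random masks", {
  set.seed(1)
  for (i in 1:10) {
    p <- random_blob_mask(16, 16)
    t <- random_blob_mask(16, 16)
    cc <- confusion(p, t)$counts["class1", ]
    tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
    for (j in seq_along(p)) {
      if (p[j] == 1 && t[j] == 1) tp <- tp + 1L
      else if (p[j] == 1) fp <- fp + 1L
      else if (t[j] == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
    expect_equal(unname(cc), c(tp, fp, tn, fn))
  }
  all1 <- matrix(1L, 4, 4)
  expect_equal(unname(confusion(all1, all1)$counts["class1", ]),
               c(16, 0, 0, 0))
  cc <- confusion(1L - all1, all1)$counts["class1", ]
  expect_equal(unname(cc[c("TP", "TN")]), c(0, 0))
  expect_error(confusion(matrix(2L, 2, 2), matrix(0L, 2, 2)), "labels")
  expect_error(confusion(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shape")
})

test_that("segmentation metrics have their closed forms and identities", {
  cc <- structure(list(k = 2L, counts = rbind(
    class0 = c(TP = 5, FP = 1, TN = 3, FN = 1),
    class1 = c(TP = 3, FP = 1, TN = 5, FN = 1))),
    class = "confusion_counts")
  expect_equal(accuracy(cc), 80)
  d <- dice(structure(list(k = 2L, counts = rbind(
    class0 = c(TP = 0, FP = 0, TN = 0, FN = 0),
    class1 = c(TP = 2, FP = 1, TN = 0, FN = 1))),
    class = "confusion_counts"))
  expect_equal(d, 100 * 4 / 6)

  # enumerable 2x2 case: truth half plaque, prediction all background
  p <- matrix(0L, 2, 2); t <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  cc2 <- confusion(p, t)
  expect_equal(miou(cc2), 25)
  expect_equal(iou_excluding_background(cc2), 0)

  # perfect prediction
  cc3 <- confusion(t, t)
  expect_equal(miou(cc3), 100)
  expect_equal(dice(cc3), 100)
  expect_equal(accuracy(cc3), 100)
})

test_that("metrics agree with set-based oracles and the Dice-IoU identity", {
  set.seed(7)
  for (i in 1:200) {
    H <- sample(2:32, 1); W <- sample(2:32, 1)
    p <- random_blob_mask(H, W, runif(1, 0.1, 0.9))
    t <- random_blob_mask(H, W, runif(1, 0.1, 0.9))
    cc <- confusion(p, t)
    o <- oracle_seg(p, t)
    expect_equal(accuracy(cc), o$accuracy, tolerance = 1e-12)
    expect_equal(miou(cc), o$miou, tolerance = 1e-12)
    expect_equal(iou_excluding_background(cc), o$iou_fg, tolerance = 1e-12)
    expect_equal(dice(cc), o$dice, tolerance = 1e-12)
    I <- iou_excluding_background(cc) / 100
    expect_equal(dice(cc) / 100, 2 * I / (1 + I), tolerance = 1e-12)
    expect_gte(dice(cc), iou_excluding_background(cc))
  }
})

test_that("metrics are invariant to simultaneous spatial permutation", {
  set.seed(12)
  p <- random_blob_mask(12, 12); t <- random_blob_mask(12, 12)
  perm <- sample(144)
  p2 <- matrix(p[perm], 12, 12); t2 <- matrix(t[perm], 12, 12)
  expect_equal(seg_metrics(confusion(p, t)), seg_metrics(confusion(p2, t2)))
})

test_that("regression metrics follow the closed-form worked examples", {
  r <- regression_metrics(c(1, 2, 4), c(1, 2, 3))
  expect_equal(r$mse, 1 / 3)
  expect_equal(r$mae, 1 / 3)
  expect_equal(r$r2, 0.5)

  perfect <- regression_metrics(c(2, 4, 6), c(2, 4, 6))
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)

  null <- regression_metrics(rep(4, 3), c(2, 4, 6))
  expect_equal(null$r2, 0)

  expect_warning(z <- regression_metrics(c(1, 2), c(3, 3)), "variance")
  expect_true(is.na(z$r2))
  set.seed(3)
  for (i in 1:20) {
    truth <- rnorm(10); pred <- rnorm(10)
    r <- regression_metrics(pred, truth)
    expect_lte(r$r2, 1)
    expect_gte(r$mse, 0)
    expect_equal(r$mse, mean((pred - truth)^2))
    expect_equal(r$mae, mean(abs(pred - truth)))
  }
})
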