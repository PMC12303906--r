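test_that("training runs the requested epochs and checkpoints the best", {
  dir <- withr::local_tempdir()
  man <- tiny_manifest(16, dir, seed = 2)
  tc <- tiny_train_config(seed = 1, epochs = 3L)
  fit <- plaquenet(man, tc)
  expect_s3_class(fit, "plaquenet")
  expect_equal(nrow(fit$curves), 3)
  expect_lte(fit$best_val_loss, min(fit$curves$val_loss) + 1e-12)
  expect_lte(fit$best_val_loss, fit$curves$val_loss[3])
})

test_that("identical seeds give identical curves, different seeds differ", {
  dir <- withr::local_tempdir()
  man <- tiny_manifest(16, dir, seed = 3)
  tc <- tiny_train_config(seed = 5, epochs = 2L)
  f1 <- plaquenet(man, tc)
  f2 <- plaquenet(man, tc)
  expect_identical(f1$curves, f2$curves)
  expect_identical(f1$model$params, f2$model$params)
  f3 <- plaquenet(man, tc, repetition = 1L)
  expect_false(identical(f1$curves, f3$curves))
})

test_that("evaluation pools counts independently of image order", {
  dir <- withr::local_tempdir()
  man <- tiny_manifest(20, dir, seed = 4, ratios = c(2, 1, 2))
  tc <- tiny_train_config(seed = 2, epochs = 2L)
  fit <- plaquenet(man, tc)
  ev1 <- evaluate_model(fit, man)
  test_rows <- which(man$split == "test")
  man_perm <- man
  man_perm[test_rows, ] <- man[rev(test_rows), ]
  ev2 <- evaluate_model(fit, man_perm)
  expect_equal(ev1$seg, ev2$seg)
  expect_equal(ev1$reg_long$mse, ev2$reg_long$mse)
  # macro averaging is a different but valid aggregation
  evm <- evaluate_model(fit, man, macro = TRUE)
  expect_true(all(unlist(evm$seg) >= 0 & unlist(evm$seg) <= 100))
})

test_that("prediction returns masks, probabilities and mm diameters", {
  dir <- withr::local_tempdir()
  man <- tiny_manifest(16, dir, seed = 6)
  tc <- tiny_train_config(seed = 3, epochs = 2L)
  fit <- plaquenet(man, tc)
  te <- man[man$split == "test", ]
  pred <- predict(fit, te)
  expect_length(pred$masks, nrow(te))
  expect_true(all(vapply(pred$masks, function(m) all(m %in% 0:1),
                         logical(1))))
  expect_true(all(vapply(pred$probabilities, function(p)
    min(p) >= 0 && max(p) <= 1, logical(1))))
  expect_equal(dim(pred$diameters), c(nrow(te), 2))
  expect_true(all(is.finite(pred$diameters)))
})

test_that("a single-repetition experiment aggregates with NA deviation", {
  dir <- withr::local_tempdir()
  man <- tiny_manifest(16, dir, seed = 8)
  tc <- tiny_train_config(seed = 4, epochs = 2L)
  rep <- run_experiment(man, tc)
  expect_s3_class(rep, "run_report")
  expect_equal(nrow(rep$per_rep), 1)
  expect_true(all(is.na(rep$aggregate$sd)))
  # aggregate mean recomputable from the per-repetition table
  expect_equal(rep$aggregate$mean[rep$aggregate$metric == "dice_pct"],
               mean(rep$per_rep$dice_pct), tolerance = 1e-12)
})

test_that("checkpoints round-trip through disk", {
  dir <- withr::local_tempdir()
  man <- tiny_manifest(16, dir, seed = 9)
  tc <- tiny_train_config(seed = 6, epochs = 2L)
  fit <- plaquenet(man, tc)
  ck <- file.path(dir, "model.rds")
  save_checkpoint(fit, ck)
  expect_true(file.exists(ck))
  expect_true(file.exists(file.path(dir, "model.yaml")))
  fit2 <- load_checkpoint(ck)
  te <- man[man$split == "test", ]
  expect_identical(predict(fit, te), predict(fit2, te))
})

test_that("augmented descendants of held-out samples are refused", {
  dir <- withr::local_tempdir()
  man <- tiny_manifest(16, dir, seed = 10)
  bad <- man[man$split == "test", ][1, ]
  leak <- bad
  leak$sample_id <- paste0(bad$sample_id, "_aug01")
  leak$split <- "train"
  man$parent_id <- man$sample_id
  leak$parent_id <- bad$sample_id
  man_bad <- rbind(man, leak)
  tc <- tiny_train_config(seed = 1, epochs = 1L)
  expect_error(plaquenet(man_bad, tc), "leakage")
})

test_that("the baseline measures diameters from its predicted masks", {
  dir <- withr::local_tempdir()
  man <- tiny_manifest(24, dir, seed = 12, ratios = c(4, 1, 1))
  tc <- tiny_train_config(seed = 3, epochs = 8L)
  bl <- baseline_unet_measure(man, tc)
  expect_false(bl$fit$config$model$use_eca)
  expect_true(is.finite(bl$reg_long$mae))
  expect_gte(bl$n_excluded, 0)
  expect_true(all(unlist(bl$seg) >= 0 & unlist(bl$seg) <= 100))
})
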