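#' Training configuration
#'
#' Defaults follow the study protocol: Adam with learning rate 0.001, batch
#' size 16, up to 100 epochs with early stopping on validation total loss,
#' best-on-validation checkpointing, 10 repetitions. `input_size` must be
#' divisible by `2^depth` of the model.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximum number of epochs.
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping (`Inf` disables).
#' @param repetitions number of repeated training runs in
#'   [run_experiment()].
#' @param seed master seed; repetition `r` trains with `seed + r`.
#' @param weights a [loss_weights()].
#' @param model a [model_config()].
#' @param input_size `c(H, W)` the images are resized to before the network.
#' @param standardize_targets z-score the diameter targets on the training
#'   split (predictions are mapped back to mm).
#' @param preprocess contrast enhancement passed to [preprocess_image()].
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 16L,
                         epochs = 100L, early_stopping_patience = 15,
                         repetitions = 10L, seed = 1L,
                         weights = loss_weights(),
                         model = model_config(),
                         input_size = c(96L, 96L),
                         standardize_targets = TRUE,
                         preprocess = "clahe") {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            early_stopping_patience > 0, repetitions >= 1,
            inherits(weights, "loss_weights"), inherits(model, "model_config"),
            length(input_size) == 2)
  if (any(input_size %% 2^model$depth != 0))
    stop("input_size must be divisible by 2^depth")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 early_stopping_patience = early_stopping_patience,
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed), weights = weights, model = model,
                 input_size = as.integer(input_size),
                 standardize_targets = isTRUE(standardize_targets),
                 preprocess = preprocess),
            class = "train_config")
}

#' Smoke-scale configurations for desk-top (single CPU) experiments
#'
#' A reduced problem size used throughout the examples and the acceptance
#' workflow: 64 x 64 phantoms at 0.15 mm/px with semi-axes 1.5-3.5 mm,
#' fairly heavy 4-look speckle, and a depth-3, 8-channel network trained
#' for 12 epochs. The full-scale protocol configuration is
#' `train_config()` with its defaults.
#'
#' @param seed master seed.
#' @param looks speckle looks of the phantom generator.
#' @return `smoke_phantom_config()`: a [phantom_config()];
#'   `smoke_train_config()`: a [train_config()].
#' @export
smoke_phantom_config <- function(seed = 1L, looks = 4) {
  phantom_config(image_height_px = 64L, image_width_px = 64L,
                 pixel_spacing_mm = 0.15,
                 plaque_long_axis_range_mm = c(1.5, 3.5),
                 plaque_aspect_ratio_range = c(0.4, 0.8),
                 plaque_contrast = 0.35, background_level = 0.25,
                 speckle_looks = looks, edge_blur_sigma_px = 1,
                 shadow_probability = 0.25, seed = seed)
}

#' @rdname smoke_phantom_config
#' @export
smoke_train_config <- function(seed = 1L) {
  train_config(learning_rate = 0.001, batch_size = 16L, epochs = 12L,
               early_stopping_patience = 15, repetitions = 2L, seed = seed,
               weights = loss_weights(1, 1),
               model = model_config(depth = 3L, base_channels = 8L,
                                    eca_conv_layers = 2L),
               input_size = c(64L, 64L))
}

# ---- data loading --------------------------------------------------------

# read, preprocess and resize every row of one split; returns parallel lists
load_split <- function(manifest, split, config) {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(rows) == 0) stop("split '", split, "' is empty")
  H <- config$input_size[1]; W <- config$input_size[2]
  images <- vector("list", nrow(rows))
  masks <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    s <- read_sample(rows[i, ])
    img <- preprocess_image(s$image, method = config$preprocess)
    msk <- s$mask
    if (nrow(img) != H || ncol(img) != W) {
      img <- ebimage_resize(img, H, W, bilinear = TRUE)
      msk <- ebimage_resize(msk, H, W, bilinear = FALSE)
    }
    images[[i]] <- pmin(pmax(img, 0), 1)
    masks[[i]] <- matrix(as.integer(round(msk)), H, W)
  }
  list(images = images, masks = masks,
       diam = cbind(long = rows$long_mm, short = rows$short_mm),
       ids = rows$sample_id, rows = rows)
}

assert_no_leakage <- function(manifest) {
  if (!"parent_id" %in% names(manifest)) return(invisible(TRUE))
  aug <- manifest[manifest$sample_id != manifest$parent_id, , drop = FALSE]
  if (nrow(aug) == 0) return(invisible(TRUE))
  heldout <- manifest$sample_id[manifest$split %in% c("val", "test")]
  if (any(aug$parent_id %in% heldout))
    stop("data leakage: augmented sample descends from a val/test parent")
  invisible(TRUE)
}

batch_indices <- function(n, batch_size) {
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s) s:min(s + batch_size - 1L, n))
}

compute_loss_batch <- function(params, bn, cfg, weights, s_auto, images,
                               labels, targets, train) {
  bm <- batch_to_matrix(images)
  fw <- nn_forward(params, bn, bm$Fm, bm$dims, cfg, train = train)
  lb <- joint_loss(fw$scores, labels, fw$diam, targets, weights, s = s_auto)
  list(fw = fw, lb = lb)
}

#' Train the dual-branch network once
#'
#' One training run: Adam at the configured settings on the training split,
#' per-epoch validation total loss, best-on-validation parameter
#' checkpointing, early stopping. Fully seeded via
#' `config$seed + repetition`.
#'
#' @param manifest a split (optionally augmented) manifest.
#' @param config a [train_config()].
#' @param repetition repetition index (0-based) added to the seed.
#' @return object of class `plaquenet`: the fitted model (best-validation
#'   parameters), training curves and target scalers.
#' @export
plaquenet <- function(manifest, config = train_config(), repetition = 0L) {
  stopifnot(inherits(config, "train_config"))
  assert_no_leakage(manifest)
  tr <- load_split(manifest, "train", config)
  va <- load_split(manifest, "val", config)

  scaler <- if (config$standardize_targets) {
    mu <- colMeans(tr$diam)
    sd_ <- pmax(apply(tr$diam, 2, stats::sd), 1e-8)
    list(mean = mu, sd = sd_)
  } else list(mean = c(0, 0), sd = c(1, 1))
  std <- function(d) sweep(sweep(d, 2, scaler$mean), 2, scaler$sd, "/")
  tr_t <- std(tr$diam); va_t <- std(va$diam)

  run_seed <- config$seed + as.integer(repetition)
  model <- build_model(config$model, seed = run_seed)
  params <- model$params; bn <- model$bn
  cfg <- config$model
  opt <- adam_init(params)
  auto <- config$weights$mode == "auto"
  s_auto <- if (auto) list(s_seg = 0, s_size = 0) else NULL
  s_opt <- if (auto) adam_init(s_auto) else NULL

  n_tr <- length(tr$images)
  curves <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
  best <- list(val = Inf, params = params, bn = bn, epoch = 0L)
  stall <- 0L

  with_phantom_seed(run_seed, 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0; ep_n <- 0L
      for (bi in batch_indices(n_tr, config$batch_size)) {
        ids <- ord[bi]
        if (length(ids) < 2L) next  # batch statistics need >= 2 items
        labels <- unlist(tr$masks[ids], use.names = FALSE)
        res <- compute_loss_batch(params, bn, cfg, config$weights, s_auto,
                                  tr$images[ids], labels,
                                  tr_t[ids, , drop = FALSE], train = TRUE)
        bn <- res$fw$bn
        lb <- res$lb
        if (!is.finite(lb$total))
          stop(sprintf("training diverged at epoch %d (loss %g)", epoch,
                       lb$total))
        grads <- nn_backward(params, cfg, res$fw$cache,
                             attr(lb, "grad_scores"), attr(lb, "grad_pred"))
        stp <- adam_step(params, grads, opt, config$learning_rate)
        params <- stp$params; opt <- stp$state
        if (auto) {
          sstp <- adam_step(s_auto, attr(lb, "grad_s"), s_opt,
                            config$learning_rate)
          s_auto <- sstp$params; s_opt <- sstp$state
        }
        ep_loss <- ep_loss + lb$total * length(ids)
        ep_n <- ep_n + length(ids)
      }
      # validation total loss in inference mode
      v_loss <- 0; v_n <- 0L
      for (bi in batch_indices(length(va$images), config$batch_size)) {
        labels <- unlist(va$masks[bi], use.names = FALSE)
        res <- compute_loss_batch(params, bn, cfg, config$weights, s_auto,
                                  va$images[bi], labels,
                                  va_t[bi, , drop = FALSE], train = FALSE)
        v_loss <- v_loss + res$lb$total * length(bi)
        v_n <- v_n + length(bi)
      }
      v_loss <- v_loss / v_n
      curves <- rbind(curves,
                      data.frame(epoch = epoch, train_loss = ep_loss / ep_n,
                                 val_loss = v_loss))
      if (v_loss < best$val) {
        best <- list(val = v_loss, params = params, bn = bn, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stopping_patience) break
      }
    }
  })

  model$params <- best$params
  model$bn <- best$bn
  structure(list(model = model, config = config, curves = curves,
                 scaler = scaler, best_epoch = best$epoch,
                 best_val_loss = best$val, repetition = as.integer(repetition),
                 s_auto = s_auto),
            class = "plaquenet")
}

#' @export
print.plaquenet <- function(x, ...) {
  cat("fitted dual-branch plaque network\n")
  print(x$model)
  cat(sprintf("  trained %d epochs; best validation loss %.4f at epoch %d\n",
              nrow(x$curves), x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' @export
summary.plaquenet <- function(object, ...) {
  print(object)
  cat("\ntraining curves (last 5 epochs):\n")
  print(utils::tail(object$curves, 5), row.names = FALSE)
  invisible(object)
}

#' @export
plot.plaquenet <- function(x, ...) {
  graphics::matplot(x$curves$epoch,
                    cbind(x$curves$train_loss, x$curves$val_loss),
                    type = "l", lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "total loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Predict masks and diameters for new images
#'
#' @param object a fitted [plaquenet()] model.
#' @param newdata a manifest data.frame (rows are read, preprocessed and
#'   resized as during training) or a list of raw image matrices.
#' @param ... unused.
#' @return list with `masks` (list of H x W \{0,1\} matrices),
#'   `probabilities` (list of H x W plaque-probability matrices) and
#'   `diameters` (N x 2 matrix in mm, columns long/short).
#' @export
predict.plaquenet <- function(object, newdata, ...) {
  config <- object$config
  H <- config$input_size[1]; W <- config$input_size[2]
  if (is.data.frame(newdata)) {
    images <- lapply(seq_len(nrow(newdata)), function(i) {
      s <- read_sample(newdata[i, ])
      img <- preprocess_image(s$image, method = config$preprocess)
      if (nrow(img) != H || ncol(img) != W)
        img <- ebimage_resize(img, H, W, bilinear = TRUE)
      pmin(pmax(img, 0), 1)
    })
  } else {
    images <- if (is.matrix(newdata)) list(newdata) else newdata
  }
  masks <- vector("list", length(images))
  probs <- vector("list", length(images))
  diam <- matrix(0, length(images), 2,
                 dimnames = list(NULL, c("long", "short")))
  for (bi in batch_indices(length(images), config$batch_size)) {
    bm <- batch_to_matrix(images[bi])
    fw <- nn_forward(object$model$params, object$model$bn, bm$Fm, bm$dims,
                     config$model, train = FALSE)
    P <- softmax_rows(fw$scores)
    lab <- max.col(fw$scores) - 1L
    npx <- bm$dims$H * bm$dims$W
    for (j in seq_along(bi)) {
      rows <- (j - 1L) * npx + seq_len(npx)
      masks[[bi[j]]] <- matrix(lab[rows], bm$dims$H, bm$dims$W)
      probs[[bi[j]]] <- matrix(P[rows, 2L], bm$dims$H, bm$dims$W)
    }
    d <- fw$diam
    d <- sweep(sweep(d, 2, object$scaler$sd, "*"), 2, object$scaler$mean, "+")
    diam[bi, ] <- d
  }
  list(masks = masks, probabilities = probs, diameters = diam)
}

#' Evaluate a fitted model on one manifest split
#'
#' Runs inference, takes the per-pixel argmax as the predicted mask, pools
#' confusion counts over all pixels of all images (micro-averaging;
#' `macro = TRUE` averages per-image metrics instead) and computes the
#' segmentation panel plus per-diameter regression metrics.
#'
#' @param fit a fitted [plaquenet()] model.
#' @param manifest a split manifest.
#' @param split which split to evaluate (default `"test"`).
#' @param macro average per-image metrics instead of pooling counts.
#' @return list with `seg` ([seg_metrics()] panel), `reg_long`, `reg_short`
#'   ([regression_metrics()]) and `n` images.
#' @export
evaluate_model <- function(fit, manifest, split = "test", macro = FALSE) {
  data <- load_split(manifest, split, fit$config)
  pred <- predict(fit, data$rows)
  k <- fit$config$model$num_classes
  if (macro) {
    per <- lapply(seq_along(pred$masks), function(i)
      unlist(seg_metrics(confusion(pred$masks[[i]], data$masks[[i]], k))))
    seg <- as.list(colMeans(do.call(rbind, per)))
  } else {
    pooled <- Reduce(`+`, lapply(seq_along(pred$masks), function(i)
      confusion(pred$masks[[i]], data$masks[[i]], k)$counts))
    seg <- seg_metrics(structure(list(k = k, counts = pooled),
                                 class = "confusion_counts"))
  }
  list(seg = seg,
       reg_long = regression_metrics(pred$diameters[, 1], data$diam[, 1]),
       reg_short = regression_metrics(pred$diameters[, 2], data$diam[, 2]),
       n = length(pred$masks))
}

#' Run the repeated-training experiment
#'
#' Trains `config$repetitions` times (seeds `seed + 0 .. seed + R - 1`),
#' evaluates each best-validation model on the test split and aggregates
#' every metric as mean and standard deviation (n - 1 denominator; a single
#' repetition reports `NA` deviation).
#'
#' @param manifest a split manifest.
#' @param config a [train_config()].
#' @return object of class `run_report`: list with `per_rep` (data.frame of
#'   per-repetition metrics), `aggregate` (mean/sd per metric), `fits`
#'   (the fitted models).
#' @export
run_experiment <- function(manifest, config = train_config()) {
  reps <- config$repetitions
  fits <- vector("list", reps)
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    fit <- plaquenet(manifest, config, repetition = r - 1L)
    ev <- evaluate_model(fit, manifest)
    fits[[r]] <- fit
    rows[[r]] <- data.frame(
      repetition = r, accuracy_pct = ev$seg$accuracy_pct,
      miou_pct = ev$seg$miou_pct, iou_fg_pct = ev$seg$iou_fg_pct,
      dice_pct = ev$seg$dice_pct,
      mse_long = ev$reg_long$mse, mae_long = ev$reg_long$mae,
      r2_long = ev$reg_long$r2,
      mse_short = ev$reg_short$mse, mae_short = ev$reg_short$mae,
      r2_short = ev$reg_short$r2)
  }
  per_rep <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_rep), "repetition")
  aggregate <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_rep[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m)
      if (reps > 1) stats::sd(per_rep[[m]]) else NA_real_, numeric(1)))
  structure(list(per_rep = per_rep, aggregate = aggregate, fits = fits,
                 config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("experiment report: %d repetition(s)\n",
              nrow(x$per_rep)))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-14s %8.3f +/- %s\n", agg$metric[i], agg$mean[i],
                ifelse(is.na(agg$sd[i]), "NA", sprintf("%.3f", agg$sd[i]))))
  invisible(x)
}

#' Segment-then-measure baseline
#'
#' Trains the same trunk as a plain U-Net (attention off, size-loss weight
#' beta = 0 so the regression branch receives no gradient), predicts test
#' masks, and derives diameters by [measure_diameters()] on each predicted
#' mask — the classical pipeline against which joint regression is
#' compared. Images whose predicted mask is empty are recorded as missing
#' and excluded (their count is reported).
#'
#' @param manifest a split manifest.
#' @param config a [train_config()]; its model is rebuilt with
#'   `use_eca = FALSE` and its weights replaced by `alpha = 1, beta = 0`.
#' @param repetition repetition index added to the seed.
#' @return list with `reg_long`, `reg_short`, `seg`, `n_excluded`, `fit`.
#' @export
baseline_unet_measure <- function(manifest, config = train_config(),
                                  repetition = 0L) {
  mc <- config$model
  mc$use_eca <- FALSE
  bcfg <- config
  bcfg$model <- mc
  bcfg$weights <- loss_weights(1, 0)
  fit <- plaquenet(manifest, bcfg, repetition = repetition)
  data <- load_split(manifest, "test", bcfg)
  pred <- predict(fit, data$rows)
  H <- bcfg$input_size[1]
  est <- matrix(NA_real_, length(pred$masks), 2)
  for (i in seq_along(pred$masks)) {
    m <- pred$masks[[i]]
    if (sum(m) == 0) next
    # spacing on the resized grid
    sp <- data$rows$spacing_mm_per_px[i] * nrow(read_mask_dim(data$rows[i, ])) / H
    d <- measure_diameters(m, sp)
    est[i, ] <- c(d$long_mm, d$short_mm)
  }
  ok <- stats::complete.cases(est)
  if (!any(ok)) stop("baseline produced no nonempty predicted masks")
  k <- bcfg$model$num_classes
  pooled <- Reduce(`+`, lapply(seq_along(pred$masks), function(i)
    confusion(pred$masks[[i]], data$masks[[i]], k)$counts))
  list(reg_long = regression_metrics(est[ok, 1], data$diam[ok, 1]),
       reg_short = regression_metrics(est[ok, 2], data$diam[ok, 2]),
       seg = seg_metrics(structure(list(k = k, counts = pooled),
                                   class = "confusion_counts")),
       n_excluded = sum(!ok), fit = fit)
}

read_mask_dim <- function(row) {
  m <- png::readPNG(row$mask_path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}

#' Save / load a fitted model checkpoint
#'
#' Weights (and batch-norm statistics, target scalers) go to one RDS file;
#' the architecture and training configuration are written alongside as
#' YAML so the network is reconstructable from the checkpoint pair.
#'
#' @param fit a fitted [plaquenet()] model.
#' @param path checkpoint path (an `.rds` file; a `.yaml` sidecar is
#'   written next to it).
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: the
#'   restored `plaquenet` object.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  cfgfile <- sub("\\.rds$", ".yaml", path)
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(list(model = unclass(fit$config$model),
                          input_size = fit$config$input_size,
                          learning_rate = fit$config$learning_rate,
                          batch_size = fit$config$batch_size),
                     cfgfile)
  }
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
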