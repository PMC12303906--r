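# Shared fixtures: tiny configurations and independent brute-force oracles.

tiny_phantom_config <- function(seed = 1L, H = 48L, W = 48L, looks = 8,
                                blur = 0.5, shadow = 0) {
  phantom_config(image_height_px = H, image_width_px = W,
                 pixel_spacing_mm = 0.15,
                 plaque_long_axis_range_mm = c(1.2, 2.4),
                 plaque_aspect_ratio_range = c(0.4, 0.8),
                 plaque_contrast = 0.35, background_level = 0.25,
                 speckle_looks = looks, edge_blur_sigma_px = blur,
                 shadow_probability = shadow, seed = seed)
}

noise_free_config <- function(seed = 1L, axis = c(1.5, 3), aspect = c(0.5, 0.8)) {
  phantom_config(image_height_px = 48L, image_width_px = 48L,
                 pixel_spacing_mm = 0.15,
                 plaque_long_axis_range_mm = axis,
                 plaque_aspect_ratio_range = aspect,
                 plaque_contrast = 0.35, background_level = 0.25,
                 background_texture_amplitude = 0,
                 speckle_looks = Inf, edge_blur_sigma_px = 0,
                 shadow_probability = 0, seed = seed)
}

# small on-disk dataset + split, for pipeline/harness tests
tiny_manifest <- function(n, dir, seed = 1L, ratios = c(7, 1, 2), ...) {
  cfg <- tiny_phantom_config(seed = seed, ...)
  man <- write_dataset(generate_dataset(cfg, n), dir)
  split_manifest(man, split_spec(ratios, seed = seed))
}

tiny_train_config <- function(seed = 1L, epochs = 2L) {
  train_config(learning_rate = 0.001, batch_size = 4L, epochs = epochs,
               early_stopping_patience = 50, repetitions = 1L, seed = seed,
               weights = loss_weights(1, 1),
               model = model_config(depth = 2L, base_channels = 4L,
                                    eca_conv_layers = 2L,
                                    regression_hidden_units = 8L),
               input_size = c(48L, 48L))
}

make_ellipse_mask <- function(H, W, cy, cx, a, b, theta = 0) {
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  xr <- (xx - cx) * cos(theta) + (yy - cy) * sin(theta)
  yr <- -(xx - cx) * sin(theta) + (yy - cy) * cos(theta)
  m <- matrix(0L, H, W)
  m[(xr / a)^2 + (yr / b)^2 <= 1] <- 1L
  m
}

random_blob_mask <- function(H, W, p = 0.4) {
  m <- matrix(rbinom(H * W, 1, p), H, W)
  storage.mode(m) <- "integer"
  m
}

# set-based segmentation metric oracle (explicit pixel sets)
oracle_seg <- function(pred, truth) {
  P <- which(pred == 1); T <- which(truth == 1)
  n <- length(pred)
  tp <- length(intersect(P, T))
  fp <- length(setdiff(P, T))
  fn <- length(setdiff(T, P))
  tn <- n - tp - fp - fn
  iou_fg <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  B_p <- setdiff(seq_len(n), P); B_t <- setdiff(seq_len(n), T)
  tp0 <- length(intersect(B_p, B_t))
  u0 <- length(union(B_p, B_t))
  iou_bg <- if (u0 == 0) 1 else tp0 / u0
  dice <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  list(accuracy = 100 * (tp + tn) / n,
       miou = 100 * (iou_bg + iou_fg) / 2,
       iou_fg = 100 * iou_fg,
       dice = 100 * dice)
}

# exhaustive O(B^2) maximum pairwise boundary distance (long Feret oracle)
oracle_feret_long <- function(mask, spacing) {
  H <- nrow(mask); W <- ncol(mask)
  pts <- NULL
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (mask[r, c] != 1) next
    nb_full <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > H || cc < 1 || cc > W || mask[rr, cc] != 1)
        nb_full <- FALSE
    }
    if (!nb_full) pts <- rbind(pts, c(r, c))
  }
  if (is.null(pts) || nrow(pts) == 1) return(spacing)
  best <- 0
  for (i in seq_len(nrow(pts) - 1)) for (j in (i + 1):nrow(pts)) {
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (d > best) best <- d
  }
  max(best, 1) * spacing
}

# recursive-stack flood fill, 8-connected, independent of the package's BFS
oracle_largest_component <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  comp <- 0L
  for (start in which(mask == 1)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    stack <- start
    while (length(stack)) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[s] != 0L) next
      lab[s] <- comp
      r <- (s - 1L) %% H + 1L; c <- (s - 1L) %/% H + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
          t <- rr + (cc - 1L) * H
          if (mask[t] == 1 && lab[t] == 0L) stack <- c(stack, t)
        }
      }
    }
  }
  if (comp == 0L) return(mask * 0L)
  sizes <- tabulate(lab[lab > 0L])
  (lab == which.max(sizes)) * 1L
}
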