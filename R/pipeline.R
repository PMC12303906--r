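#' Split specification for train/validation/test partitioning
#'
#' @param ratios three positive integers, default `c(7, 1, 2)`.
#' @param seed integer seed driving the random permutation.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(ratios = c(7L, 1L, 2L), seed = 1L) {
  ratios <- as.numeric(ratios)
  if (length(ratios) != 3 || any(ratios < 0) || sum(ratios) <= 0)
    stop("ratios must be three nonnegative numbers with positive sum")
  structure(list(ratios = ratios, seed = as.integer(seed)),
            class = "split_spec")
}

#' Randomly split a manifest into train/validation/test
#'
#' Rows are permuted by the spec's seed and assigned
#' `n_train = floor(n r_tr / sum(r))`, `n_val = floor(n r_val / sum(r))`,
#' and the remainder to test. With 287 rows at 7:1:2 this yields the
#' (200, 28, 59) layout. The assignment is a partition and is deterministic
#' for a fixed seed; the returned manifest keeps the original row order.
#'
#' @param manifest manifest data.frame with all rows `unassigned`.
#' @param spec a [split_spec()].
#' @return manifest with the `split` column filled in.
#' @export
split_manifest <- function(manifest, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- nrow(manifest)
  nz <- sum(spec$ratios > 0)
  if (n < nz)
    stop(sprintf("cannot split %d rows into %d nonempty parts", n, nz))
  if (!all(manifest$split == "unassigned"))
    stop("manifest already carries split assignments")
  r <- spec$ratios / sum(spec$ratios)
  n_train <- floor(n * r[1]); n_val <- floor(n * r[2])
  n_test <- n - n_train - n_val
  perm <- with_phantom_seed(spec$seed, 0L, sample.int(n))
  lab <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  manifest$split[perm] <- lab
  manifest
}

#' Counts per split
#' @param manifest manifest data.frame.
#' @return named integer vector over train/val/test.
#' @export
split_counts <- function(manifest) {
  c(train = sum(manifest$split == "train"),
    val = sum(manifest$split == "val"),
    test = sum(manifest$split == "test"))
}

#' Normalize and contrast-enhance an intensity image
#'
#' Min-max normalizes to `[0, 1]` (a constant image maps to all zeros, no
#' division by zero), then applies contrast-limited adaptive histogram
#' equalization (CLAHE, the standard choice for ultrasound); plain global
#' histogram equalization is available via `method = "hist"` and
#' `method = "none"` skips enhancement.
#'
#' @param image numeric matrix.
#' @param method `"clahe"` (default), `"hist"` or `"none"`.
#' @return matrix of the same shape with values in `[0, 1]`.
#' @export
preprocess_image <- function(image, method = c("clahe", "hist", "none")) {
  method <- match.arg(method)
  if (length(image) == 0) stop("empty image")
  rng <- range(image)
  x <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
       else image * 0
  if (method == "none" || rng[2] == rng[1]) return(x)
  out <- if (method == "clahe") {
    nx <- max(2L, min(8L, floor(ncol(x) / 16)))
    ny <- max(2L, min(8L, floor(nrow(x) / 16)))
    as_bare_matrix(EBImage::clahe(EBImage::Image(x), nx = nx, ny = ny))
  } else {
    as_bare_matrix(EBImage::equalize(EBImage::Image(x), range = c(0, 1)))
  }
  pmin(pmax(out, 0), 1)
}

# ---- geometric warping --------------------------------------------------
# All spatial ops share one inverse-mapping sampler so image (bilinear) and
# mask (nearest-neighbour) receive the identical transform.

sample_bilinear <- function(img, ys, xs, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  get <- function(yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    v <- rep(fill, length(yy))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  v00 <- get(y0, x0); v01 <- get(y0, x0 + 1)
  v10 <- get(y0 + 1, x0); v11 <- get(y0 + 1, x0 + 1)
  v <- v00 * (1 - fy) * (1 - fx) + v01 * (1 - fy) * fx +
       v10 * fy * (1 - fx) + v11 * fy * fx
  matrix(v, H, W)
}

sample_nearest <- function(img, ys, xs, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  yy <- round(ys); xx <- round(xs)
  ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
  v <- rep(fill, length(yy))
  v[ok] <- img[cbind(yy[ok], xx[ok])]
  matrix(v, H, W)
}

# apply an inverse map (output pixel -> source coordinates) to a sample,
# re-measuring the diameters from the warped mask
warp_sample <- function(sample, ys, xs, diameters = c("remeasure", "keep")) {
  diameters <- match.arg(diameters)
  img <- sample_bilinear(sample$image, ys, xs)
  msk <- sample_nearest(sample$mask, ys, xs)
  msk <- matrix(as.integer(round(msk)), nrow(msk))
  if (sum(msk) == 0)
    stop("augmentation rejected: plaque warped out of the frame")
  out <- sample
  out$image <- pmin(pmax(img, 0), 1)
  out$mask <- msk
  if (diameters == "remeasure") {
    d <- measure_diameters(msk, sample$pixel_spacing_mm)
    out$long_diameter_mm <- d$long_mm
    out$short_diameter_mm <- d$short_mm
  }
  out
}

grid_coords <- function(H, W) {
  list(y = matrix(seq_len(H), H, W), x = matrix(seq_len(W), H, W, byrow = TRUE))
}

#' Elastic deformation of a phantom sample
#'
#' A smooth random displacement field (i.i.d. uniform noise smoothed with a
#' Gaussian of width `sigma` pixels, scaled to a maximum magnitude of order
#' `alpha` pixels) warps image and mask identically (bilinear / nearest).
#' Diameters are re-measured from the warped mask. `alpha = 0` is the
#' identity.
#'
#' @param sample a `phantom_sample`.
#' @param alpha displacement amplitude in pixels (>= 0).
#' @param sigma Gaussian smoothing width in pixels (> 0).
#' @return the deformed `phantom_sample`.
#' @export
elastic_deform <- function(sample, alpha = 30, sigma = 6) {
  if (alpha < 0 || sigma <= 0) stop("need alpha >= 0 and sigma > 0")
  if (alpha == 0) return(sample)
  H <- nrow(sample$image); W <- ncol(sample$image)
  dy <- ebimage_gblur(matrix(stats::runif(H * W, -1, 1), H, W), sigma)
  dx <- ebimage_gblur(matrix(stats::runif(H * W, -1, 1), H, W), sigma)
  # normalise the smoothed field so alpha is the max displacement in px
  mag <- max(abs(c(dy, dx)), 1e-12)
  dy <- dy / mag * alpha; dx <- dx / mag * alpha
  g <- grid_coords(H, W)
  warp_sample(sample, g$y + dy, g$x + dx)
}

#' Rotate a phantom sample about the image centre
#'
#' @param sample a `phantom_sample`.
#' @param degrees rotation angle, counter-clockwise.
#' @return rotated sample with diameters re-measured from the rotated mask.
#' @export
rotate_sample <- function(sample, degrees) {
  H <- nrow(sample$image); W <- ncol(sample$image)
  th <- degrees * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- grid_coords(H, W)
  yc <- g$y - cy; xc <- g$x - cx
  ys <- cy + cos(th) * yc - sin(th) * xc
  xs <- cx + sin(th) * yc + cos(th) * xc
  warp_sample(sample, ys, xs)
}

#' Scale a phantom sample about the image centre
#'
#' Scaling by `factor` multiplies both true diameters by `factor` (verified
#' by re-measuring the transformed mask).
#'
#' @param sample a `phantom_sample`.
#' @param factor positive scale factor.
#' @return scaled sample with diameters re-measured.
#' @export
scale_sample <- function(sample, factor) {
  if (factor <= 0) stop("scale factor must be positive")
  H <- nrow(sample$image); W <- ncol(sample$image)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- grid_coords(H, W)
  warp_sample(sample, cy + (g$y - cy) / factor, cx + (g$x - cx) / factor)
}

#' Flip a phantom sample
#'
#' Flips are involutions and leave the true diameters unchanged; diameters
#' are still re-measured from the flipped mask for uniformity.
#'
#' @param sample a `phantom_sample`.
#' @param axis `"horizontal"` (left-right) or `"vertical"` (up-down).
#' @return flipped sample.
#' @export
flip_sample <- function(sample, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  out <- sample
  if (axis == "horizontal") {
    out$image <- sample$image[, ncol(sample$image):1]
    out$mask <- sample$mask[, ncol(sample$mask):1]
  } else {
    out$image <- sample$image[nrow(sample$image):1, ]
    out$mask <- sample$mask[nrow(sample$mask):1, ]
  }
  d <- measure_diameters(out$mask, sample$pixel_spacing_mm)
  out$long_diameter_mm <- d$long_mm
  out$short_diameter_mm <- d$short_mm
  out
}

#' Augmentation plan
#'
#' @param variants_per_image augmented variants per training image
#'   (default 7, i.e. an 8-fold training set including the original).
#' @param operations subset of `c("elastic", "rotate", "scale", "flip_h",
#'   "flip_v")`; each variant draws one operation uniformly from this set.
#' @param rotate_range rotation range in degrees.
#' @param scale_range scale factor range.
#' @param elastic_alpha,elastic_sigma elastic field amplitude/width in px.
#' @param seed integer seed.
#' @return object of class `augmentation_plan`.
#' @export
augmentation_plan <- function(variants_per_image = 7L,
                              operations = c("elastic", "rotate", "scale",
                                             "flip_h", "flip_v"),
                              rotate_range = c(-15, 15),
                              scale_range = c(0.9, 1.1),
                              elastic_alpha = 30, elastic_sigma = 6,
                              seed = 1L) {
  operations <- match.arg(operations, several.ok = TRUE)
  if (variants_per_image > 0 && length(operations) == 0)
    stop("at least one operation must be enabled")
  structure(list(variants_per_image = as.integer(variants_per_image),
                 operations = operations,
                 rotate_range = rotate_range, scale_range = scale_range,
                 elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
                 seed = as.integer(seed)),
            class = "augmentation_plan")
}

apply_random_augmentation <- function(sample, plan) {
  op <- sample(plan$operations, 1L)
  switch(op,
    elastic = elastic_deform(sample, plan$elastic_alpha, plan$elastic_sigma),
    rotate = rotate_sample(sample,
                           stats::runif(1, plan$rotate_range[1],
                                        plan$rotate_range[2])),
    scale = scale_sample(sample,
                         stats::runif(1, plan$scale_range[1],
                                      plan$scale_range[2])),
    flip_h = flip_sample(sample, "horizontal"),
    flip_v = flip_sample(sample, "vertical"))
}

#' Augment the training split of a manifest
#'
#' Each training row yields the original plus `variants_per_image` augmented
#' rows; per variant one operation is drawn from the plan's set with
#' parameters from its ranges, fully seeded. Validation and test rows pass
#' through untouched, so no augmented row ever descends from a val/test
#' parent. Augmented images/masks are written as PNGs next to a new
#' manifest in `out_dir`.
#'
#' @param manifest a split manifest.
#' @param plan an [augmentation_plan()].
#' @param out_dir directory for augmented images and the new manifest.
#' @param max_retries redraws allowed when a warp expels the plaque.
#' @return the augmented manifest (with a `parent_id` column; originals
#'   carry their own id).
#' @export
augment_manifest <- function(manifest, plan, out_dir, max_retries = 5L) {
  if (plan$variants_per_image == 0) {
    manifest$parent_id <- manifest$sample_id
    return(manifest)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest$parent_id <- manifest$sample_id
  train <- manifest[manifest$split == "train", , drop = FALSE]
  new_rows <- list()
  for (i in seq_len(nrow(train))) {
    row <- train[i, ]
    s <- read_sample(row)
    for (v in seq_len(plan$variants_per_image)) {
      aug <- with_phantom_seed(plan$seed, i * 10000L + v, {
        out <- NULL
        for (try in seq_len(max_retries)) {
          out <- tryCatch(apply_random_augmentation(s, plan),
                          error = function(e) NULL)
          if (!is.null(out)) break
        }
        out
      })
      if (is.null(aug))
        stop("augmentation repeatedly expelled the plaque for ",
             row$sample_id)
      id <- sprintf("%s_aug%02d", row$sample_id, v)
      ip <- file.path(out_dir, paste0(id, "_img.png"))
      mp <- file.path(out_dir, paste0(id, "_mask.png"))
      png::writePNG(aug$image, ip)
      png::writePNG(aug$mask * 1.0, mp)
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        sample_id = id, image_path = ip, mask_path = mp,
        long_mm = aug$long_diameter_mm, short_mm = aug$short_diameter_mm,
        spacing_mm_per_px = aug$pixel_spacing_mm, split = "train",
        parent_id = row$sample_id, stringsAsFactors = FALSE)
    }
  }
  out <- rbind(manifest, do.call(rbind, new_rows))
  rownames(out) <- NULL
  write_manifest(out, out_dir)
  out
}
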