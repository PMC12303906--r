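#' Configuration for the ultrasound phantom generator
#'
#' The generator emulates the properties that make clinical carotid B-mode
#' images hard: strong multiplicative speckle, low plaque/background
#' contrast, blurred edges and occasional hypoechoic shadow bands below the
#' plaque (as cast by calcification). Each phantom contains exactly one
#' plaque rendered as a filled ellipse, so ground-truth masks and diameters
#' are exactly known.
#'
#' Default geometry (256 x 256 px at 0.1 mm/px, semi-axes 2-10 mm) is an
#' assumption: clinical image resolution and plaque size distribution are
#' not public. `plaque_long_axis_range_mm` bounds the long SEMI-axis `a`;
#' the recorded long diameter is `2 a`.
#'
#' @param image_height_px,image_width_px image size in pixels.
#' @param pixel_spacing_mm physical spacing, mm per pixel.
#' @param plaque_long_axis_range_mm `(min, max)` of the long semi-axis in mm.
#' @param plaque_aspect_ratio_range `(min, max)` of the short/long axis
#'   ratio, in (0, 1].
#' @param plaque_contrast intensity offset of the plaque over the vessel
#'   background, in (0, 1].
#' @param background_level mean background (lumen/tissue) intensity.
#' @param background_texture_amplitude amplitude of the smooth low-frequency
#'   background echo texture (0 gives a flat background).
#' @param speckle_looks number of looks `L` of the multiplicative Gamma
#'   speckle; smaller is noisier (`Inf` disables speckle).
#' @param edge_blur_sigma_px Gaussian blur of plaque edges, in pixels
#'   (0 disables).
#' @param shadow_probability probability of a hypoechoic shadow band below
#'   the plaque.
#' @param seed integer seed; together with the sample index it fully
#'   determines each sample.
#' @return An object of class `phantom_config` (validated list).
#' @export
phantom_config <- function(image_height_px = 256L,
                           image_width_px = 256L,
                           pixel_spacing_mm = 0.1,
                           plaque_long_axis_range_mm = c(2, 10),
                           plaque_aspect_ratio_range = c(0.3, 0.8),
                           plaque_contrast = 0.35,
                           background_level = 0.25,
                           background_texture_amplitude = 0.05,
                           speckle_looks = 4,
                           edge_blur_sigma_px = 1,
                           shadow_probability = 0.25,
                           seed = 1L) {
  cfg <- list(image_height_px = as.integer(image_height_px),
              image_width_px = as.integer(image_width_px),
              pixel_spacing_mm = pixel_spacing_mm,
              plaque_long_axis_range_mm = as.numeric(plaque_long_axis_range_mm),
              plaque_aspect_ratio_range = as.numeric(plaque_aspect_ratio_range),
              plaque_contrast = plaque_contrast,
              background_level = background_level,
              background_texture_amplitude = background_texture_amplitude,
              speckle_looks = speckle_looks,
              edge_blur_sigma_px = edge_blur_sigma_px,
              shadow_probability = shadow_probability,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(cfg$image_height_px > 0, cfg$image_width_px > 0,
            cfg$pixel_spacing_mm > 0,
            length(cfg$plaque_long_axis_range_mm) == 2,
            cfg$plaque_long_axis_range_mm[1] > 0,
            cfg$plaque_long_axis_range_mm[1] <= cfg$plaque_long_axis_range_mm[2],
            length(cfg$plaque_aspect_ratio_range) == 2,
            cfg$plaque_aspect_ratio_range[1] > 0,
            cfg$plaque_aspect_ratio_range[1] <= cfg$plaque_aspect_ratio_range[2],
            cfg$plaque_aspect_ratio_range[2] <= 1,
            cfg$plaque_contrast > 0, cfg$plaque_contrast <= 1,
            cfg$background_level >= 0, cfg$background_level < 1,
            cfg$background_texture_amplitude >= 0,
            cfg$speckle_looks > 0,
            cfg$edge_blur_sigma_px >= 0,
            cfg$shadow_probability >= 0, cfg$shadow_probability <= 1)
  extent_mm <- min(cfg$image_height_px, cfg$image_width_px) *
    cfg$pixel_spacing_mm
  if (2 * cfg$plaque_long_axis_range_mm[2] >= extent_mm)
    stop(sprintf(
      "long axis %.2f mm cannot fit the %.2f mm image extent",
      2 * cfg$plaque_long_axis_range_mm[2], extent_mm))
  invisible(cfg)
}

# run code under a deterministic RNG stream derived from (seed, index),
# restoring the caller's RNG state afterwards
with_phantom_seed <- function(seed, index, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  derived <- (as.double(seed) * 1000003 + as.double(index)) %% 2147483647
  set.seed(as.integer(derived))
  force(code)
}

#' Apply multiplicative Gamma speckle to an intensity image
#'
#' Coherent ultrasound speckle is modelled as i.i.d. unit-mean Gamma
#' multipliers with shape `looks` (variance `1/looks`); the product is
#' clipped to `[0, 1]`. `looks = Inf` returns the input unchanged.
#'
#' @param image numeric matrix with values in `[0, 1]`.
#' @param looks positive number of looks `L`.
#' @return matrix of the same shape, values in `[0, 1]`.
#' @export
apply_speckle <- function(image, looks) {
  if (!is.numeric(looks) || length(looks) != 1 || is.na(looks) || looks <= 0)
    stop("looks must be a positive number")
  if (is.infinite(looks)) return(image)
  s <- matrix(stats::rgamma(length(image), shape = looks, rate = looks),
              nrow = nrow(image))
  pmin(pmax(image * s, 0), 1)
}

#' Generate one synthetic plaque phantom
#'
#' Draws an ellipse centre, orientation, long semi-axis `a` (uniform over
#' the configured mm range) and aspect ratio, renders the plaque at
#' `background + contrast` over a smoothly varying vessel background, blurs
#' the edges, multiplies by Gamma speckle, and with the configured
#' probability attenuates a vertical shadow band below the plaque
#' (multiplicative factor 0.3 with a linear feather). The mask is the exact
#' set of pixel centres inside the generating ellipse; ground-truth
#' diameters are the analytic `2a` and `2b` in mm.
#'
#' @param config a [phantom_config()].
#' @param sample_index nonnegative integer; `(seed, sample_index)` fully
#'   determine the sample.
#' @return An object of class `phantom_sample`: list with `image` (H x W in
#'   `[0, 1]`), `mask` (H x W over \{0, 1\}), `long_diameter_mm`,
#'   `short_diameter_mm`, `pixel_spacing_mm`, `sample_id`.
#' @export
generate_sample <- function(config, sample_index = 0L) {
  validate_phantom_config(config)
  if (sample_index < 0) stop("sample_index must be >= 0")
  with_phantom_seed(config$seed, sample_index, {
    H <- config$image_height_px; W <- config$image_width_px
    sp <- config$pixel_spacing_mm
    a_mm <- stats::runif(1, config$plaque_long_axis_range_mm[1],
                         config$plaque_long_axis_range_mm[2])
    aspect <- stats::runif(1, config$plaque_aspect_ratio_range[1],
                           config$plaque_aspect_ratio_range[2])
    b_mm <- a_mm * aspect
    a_px <- a_mm / sp; b_px <- b_mm / sp
    if (2 * a_px >= min(H, W))
      stop(sprintf("long axis %.2f mm does not fit in the image", 2 * a_mm))
    theta <- stats::runif(1, 0, pi)
    margin <- a_px + 2
    cy <- stats::runif(1, margin, H - margin)
    cx <- stats::runif(1, margin, W - margin)

    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    xr <- (xx - cx) * cos(theta) + (yy - cy) * sin(theta)
    yr <- -(xx - cx) * sin(theta) + (yy - cy) * cos(theta)
    inside <- (xr / a_px)^2 + (yr / b_px)^2 <= 1
    mask <- matrix(0L, H, W); mask[inside] <- 1L

    bg <- config$background_level +
      background_texture(H, W, config$background_texture_amplitude)
    img <- bg
    img[inside] <- img[inside] + config$plaque_contrast
    img <- pmin(pmax(img, 0), 1)
    if (config$edge_blur_sigma_px > 0)
      img <- ebimage_gblur(img, config$edge_blur_sigma_px)
    img <- apply_speckle(img, config$speckle_looks)
    if (config$shadow_probability > 0 &&
        stats::runif(1) < config$shadow_probability)
      img <- cast_shadow(img, mask)
    img <- pmin(pmax(img, 0), 1)

    out <- list(image = img, mask = mask,
                long_diameter_mm = 2 * a_mm,
                short_diameter_mm = 2 * b_mm,
                pixel_spacing_mm = sp,
                sample_id = sprintf("phantom_%06d", as.integer(sample_index)))
    class(out) <- "phantom_sample"
    out
  })
}

# smooth low-frequency intensity variation emulating tissue echo texture
background_texture <- function(H, W, amplitude = 0.05) {
  coarse <- matrix(stats::runif(64, -1, 1), 8, 8)
  f <- ebimage_resize(coarse, H, W, bilinear = TRUE)
  amplitude * f
}

# hypoechoic band below the plaque: columns spanned by the plaque attenuated
# to factor 0.3 with a linear feather over 8 rows
cast_shadow <- function(img, mask, factor = 0.3, feather_rows = 8L) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (!length(rows) || !length(cols)) return(img)
  r0 <- max(rows) + 1L
  H <- nrow(img)
  if (r0 > H) return(img)
  depth <- seq_len(H - r0 + 1L)
  att <- pmax(factor, 1 - (1 - factor) * depth / feather_rows)
  img[r0:H, cols] <- img[r0:H, cols] * att
  img
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("phantom sample %s: %d x %d px at %.3f mm/px\n", x$sample_id,
              nrow(x$image), ncol(x$image), x$pixel_spacing_mm))
  cat(sprintf("  plaque: long %.2f mm, short %.2f mm, %d mask pixels\n",
              x$long_diameter_mm, x$short_diameter_mm, sum(x$mask)))
  invisible(x)
}

#' Generate a phantom dataset
#'
#' @param config a [phantom_config()].
#' @param n number of samples.
#' @return list of [generate_sample()] results for indices `0 .. n-1`.
#' @export
generate_dataset <- function(config, n) {
  lapply(seq_len(n) - 1L, function(i) generate_sample(config, i))
}

#' Write phantom samples and a dataset manifest to disk
#'
#' Writes one 8-bit grayscale PNG per image and per mask, plus a manifest in
#' both CSV and JSON with columns `sample_id`, `image_path`, `mask_path`,
#' `long_mm`, `short_mm`, `spacing_mm_per_px`, `split`. Masks round-trip
#' bit-exactly; images round-trip to 8-bit quantization.
#'
#' @param samples list of `phantom_sample` objects with unique ids.
#' @param directory output directory (created if missing).
#' @return the manifest as a data.frame (invisibly also written to
#'   `manifest.csv` / `manifest.json` in `directory`).
#' @export
write_dataset <- function(samples, directory) {
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample_id in samples: ", ids[duplicated(ids)][1])
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  rows <- lapply(samples, function(s) {
    ip <- file.path(directory, paste0(s$sample_id, "_img.png"))
    mp <- file.path(directory, paste0(s$sample_id, "_mask.png"))
    png::writePNG(s$image, ip)
    png::writePNG(s$mask * 1.0, mp)
    data.frame(sample_id = s$sample_id, image_path = ip, mask_path = mp,
               long_mm = s$long_diameter_mm, short_mm = s$short_diameter_mm,
               spacing_mm_per_px = s$pixel_spacing_mm, split = "unassigned",
               stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else empty_manifest()
  write_manifest(manifest, directory)
  manifest
}

empty_manifest <- function() {
  data.frame(sample_id = character(0), image_path = character(0),
             mask_path = character(0), long_mm = numeric(0),
             short_mm = numeric(0), spacing_mm_per_px = numeric(0),
             split = character(0), stringsAsFactors = FALSE)
}

#' Write a dataset manifest (CSV and JSON)
#'
#' @param manifest manifest data.frame.
#' @param directory directory receiving `manifest.csv` and `manifest.json`.
#' @return the CSV path, invisibly.
#' @export
write_manifest <- function(manifest, directory) {
  csv <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, csv, row.names = FALSE)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Read a dataset manifest written by [write_dataset()]
#'
#' @param path path to a `manifest.csv` (or a directory containing one).
#' @param check_paths verify that referenced files exist.
#' @return manifest data.frame.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "image_path", "mask_path", "long_mm", "short_mm",
              "spacing_mm_per_px", "split")
  if (!all(needed %in% names(m)))
    stop("manifest missing columns: ",
         paste(setdiff(needed, names(m)), collapse = ", "))
  if (anyDuplicated(m$sample_id)) stop("manifest has duplicate sample_ids")
  if (check_paths && nrow(m) > 0) {
    missing <- !file.exists(m$image_path) | !file.exists(m$mask_path)
    if (any(missing))
      stop("manifest references missing files, e.g. ",
           m$image_path[missing][1])
  }
  m
}

#' Read one manifest row back as a phantom sample
#'
#' @param row one-row slice of a manifest data.frame.
#' @return a `phantom_sample` with image, mask, diameters and spacing.
#' @export
read_sample <- function(row) {
  img <- png::readPNG(row$image_path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  msk <- png::readPNG(row$mask_path)
  if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
  out <- list(image = img, mask = matrix(as.integer(round(msk)), nrow(msk)),
              long_diameter_mm = row$long_mm,
              short_diameter_mm = row$short_mm,
              pixel_spacing_mm = row$spacing_mm_per_px,
              sample_id = row$sample_id)
  class(out) <- "phantom_sample"
  out
}

# EBImage wrappers keeping the rest of the package matrix-typed
as_bare_matrix <- function(x) {
  m <- EBImage::imageData(x)
  dn <- dim(m)
  attributes(m) <- NULL
  matrix(m, dn[1], dn[2])
}

ebimage_gblur <- function(m, sigma) {
  as_bare_matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

ebimage_resize <- function(m, H, W, bilinear = TRUE) {
  f <- if (bilinear) "bilinear" else "none"
  as_bare_matrix(EBImage::resize(EBImage::Image(m), w = H, h = W, filter = f))
}
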