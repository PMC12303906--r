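#' Keep only the largest 8-connected foreground component
#'
#' Predicted plaque masks can be fragmented by speckle and shadow artifacts;
#' since each image carries a single plaque, measurement retains the largest
#' 8-connected blob. An empty mask passes through empty.
#'
#' @param mask binary matrix over \{0, 1\}.
#' @return binary matrix of the same shape with only the largest component.
#' @export
largest_component <- function(mask) {
  mask <- check_binary_mask(mask)
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask * 0L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  (lab == keep) * 1L
}

check_binary_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  m <- round(mask)
  if (any(m != 0 & m != 1)) stop("mask must be binary over {0, 1}")
  storage.mode(m) <- "integer"
  m
}

# 8-connected component labelling by frontier BFS; returns an integer matrix
# with 0 for background and 1..n component labels.
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  todo <- which(mask == 1)
  if (length(todo) == 0L) return(lab)
  visited <- !mask
  offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  off_idx <- offs[, "dr"] + H * offs[, "dc"]
  comp <- 0L
  for (s in todo) {
    if (visited[s]) next
    comp <- comp + 1L
    frontier <- s
    visited[s] <- TRUE
    lab[s] <- comp
    while (length(frontier)) {
      # expand each neighbour offset over the whole frontier at once;
      # row bound check prevents column wrap-around in linear indexing
      r <- ((frontier - 1L) %% H) + 1L
      cand_all <- as.vector(outer(frontier, off_idx, `+`))
      rr <- rep(r, times = length(off_idx)) +
        rep(offs[, "dr"], each = length(frontier))
      ok <- rr >= 1L & rr <= H & cand_all >= 1L & cand_all <= H * W
      cand <- unique(cand_all[ok])
      cand <- cand[!visited[cand]]
      visited[cand] <- TRUE
      lab[cand] <- comp
      frontier <- cand
    }
  }
  lab
}

# boundary pixels: foreground with at least one background/out-of-frame
# 4- or 8-neighbour; returns an n x 2 matrix of (row, col) centres
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  inner <- pad[2:(H + 1L), 2:(W + 1L)] == 1L
  full <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    full <- full & (pad[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc] == 1L)
  }
  which(inner & !full, arr.ind = TRUE)
}

#' Measure plaque long and short diameters from a binary mask
#'
#' The long diameter is the maximum Feret diameter: the largest
#' centre-to-centre Euclidean distance between boundary pixels of the
#' largest 8-connected component (computed exactly via the convex hull of the
#' boundary pixel centres). The short diameter is the extent of the
#' component measured perpendicular to the long-diameter axis. Both use the
#' pixel-centre convention with a one-pixel floor, so a single-pixel
#' component measures `spacing` in both directions and a 1 x 10 row of
#' pixels measures 9 x 1 pixel spacings. `method = "min_rect"` instead
#' reports the side lengths of the minimum-area enclosing rectangle of the
#' boundary centres.
#'
#' @param mask binary matrix over \{0, 1\} with at least one foreground pixel.
#' @param spacing_mm_per_px physical pixel spacing in mm per pixel.
#' @param method `"feret"` (default) or `"min_rect"`.
#' @return An object of class `diameter_pair`: list with `long_mm` and
#'   `short_mm`, `long_mm >= short_mm > 0`.
#' @examples
#' m <- matrix(0L, 32, 32); m[10:20, 14:17] <- 1L
#' measure_diameters(m, 0.1)
#' @export
measure_diameters <- function(mask, spacing_mm_per_px,
                              method = c("feret", "min_rect")) {
  method <- match.arg(method)
  if (spacing_mm_per_px <= 0) stop("spacing must be positive")
  mask <- check_binary_mask(mask)
  mask <- largest_component(mask)
  if (sum(mask) == 0) stop("no plaque found: mask has no foreground pixels")
  bp <- boundary_pixels(mask)
  if (nrow(bp) == 1L) {
    out <- list(long_mm = spacing_mm_per_px, short_mm = spacing_mm_per_px)
    class(out) <- "diameter_pair"
    return(out)
  }
  pts <- cbind(x = bp[, "col"], y = bp[, "row"])
  hull <- hull_points(pts)
  if (method == "feret") {
    dm <- as.matrix(stats::dist(hull))
    ij <- which(dm == max(dm), arr.ind = TRUE)[1L, ]
    d_long <- dm[ij[1L], ij[2L]]
    dirv <- hull[ij[2L], ] - hull[ij[1L], ]
    nv <- sqrt(sum(dirv^2))
    if (nv == 0) { # all points coincide
      d_long <- 0; perp_ext <- 0
    } else {
      perp <- c(-dirv[2L], dirv[1L]) / nv
      proj <- pts %*% perp
      perp_ext <- max(proj) - min(proj)
    }
    long_px <- max(d_long, 1)
    short_px <- max(perp_ext, 1)
  } else {
    rect <- min_area_rect(hull)
    long_px <- max(rect[1L], 1)
    short_px <- max(rect[2L], 1)
  }
  if (short_px > long_px) { tmp <- long_px; long_px <- short_px; short_px <- tmp }
  out <- list(long_mm = long_px * spacing_mm_per_px,
              short_mm = short_px * spacing_mm_per_px)
  class(out) <- "diameter_pair"
  out
}

#' @export
print.diameter_pair <- function(x, ...) {
  cat(sprintf("plaque diameters: long %.3f mm, short %.3f mm\n",
              x$long_mm, x$short_mm))
  invisible(x)
}

hull_points <- function(pts) {
  if (nrow(pts) <= 2L) return(pts)
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  pts[h, , drop = FALSE]
}

# minimum-area enclosing rectangle over hull edge directions; returns
# c(longer side, shorter side) in pixels (centre-to-centre extents)
min_area_rect <- function(hull) {
  n <- nrow(hull)
  if (n <= 1L) return(c(0, 0))
  best <- NULL; best_area <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len
    v <- c(-u[2L], u[1L])
    pu <- hull %*% u
    pv <- hull %*% v
    w <- max(pu) - min(pu)
    h <- max(pv) - min(pv)
    if (w * h < best_area) { best_area <- w * h; best <- c(w, h) }
  }
  if (is.null(best)) { # degenerate: collinear points
    dm <- as.matrix(stats::dist(hull))
    best <- c(max(dm), 0)
  }
  c(max(best), min(best))
}
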