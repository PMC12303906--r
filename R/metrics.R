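#' Pixel confusion counts between a predicted and a true mask
#'
#' Counts true/false positives/negatives treating the plaque class (label 1)
#' as the positive class. For `k > 2` classes, per-class one-vs-rest counts
#' are returned so that mean IoU over all classes can be formed.
#'
#' @param pred integer/numeric matrix of predicted labels in `[0, k)`.
#' @param truth integer/numeric matrix of true labels, same shape as `pred`.
#' @param k number of classes (default 2: background, plaque).
#' @return An object of class `confusion_counts`: a list with `k` and a
#'   `k x 4` matrix `counts` with columns `TP`, `FP`, `TN`, `FN` (one row per
#'   class, row `i` treating class `i - 1` as positive).
#' @examples
#' p <- matrix(c(1, 1, 0, 0), 2)
#' t <- matrix(c(1, 0, 0, 1), 2)
#' confusion(p, t)
#' @export
confusion <- function(pred, truth, k = 2L) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must have identical shape")
  pv <- as.integer(round(as.vector(pred)))
  tv <- as.integer(round(as.vector(truth)))
  if (any(pv < 0L | pv >= k) || any(tv < 0L | tv >= k))
    stop("labels must lie in [0, k)")
  counts <- matrix(0L, nrow = k, ncol = 4L,
                   dimnames = list(paste0("class", seq_len(k) - 1L),
                                   c("TP", "FP", "TN", "FN")))
  n <- length(pv)
  for (cls in seq_len(k) - 1L) {
    tp <- sum(pv == cls & tv == cls)
    fp <- sum(pv == cls & tv != cls)
    fn <- sum(pv != cls & tv == cls)
    counts[cls + 1L, ] <- c(tp, fp, n - tp - fp - fn, fn)
  }
  structure(list(k = k, counts = counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Pixel confusion counts (", x$k, " classes)\n", sep = "")
  print(x$counts)
  invisible(x)
}

as_counts_matrix <- function(counts) {
  if (inherits(counts, "confusion_counts")) counts$counts
  else if (is.matrix(counts)) counts
  else matrix(as.numeric(counts[c("TP", "FP", "TN", "FN")]), nrow = 1,
              dimnames = list(NULL, c("TP", "FP", "TN", "FN")))
}

#' Pixel accuracy in percent
#'
#' `100 * (TP + TN) / (TP + TN + FP + FN)`, using the positive-class
#' (plaque) row of the confusion counts.
#'
#' @param counts a `confusion_counts` object (or a named TP/FP/TN/FN vector).
#' @return accuracy in percent.
#' @export
accuracy <- function(counts) {
  m <- as_counts_matrix(counts)
  row <- if (nrow(m) >= 2) m[2L, ] else m[1L, ]
  tot <- sum(row)
  if (tot <= 0) stop("empty confusion counts")
  100 * (row[["TP"]] + row[["TN"]]) / tot
}

iou_per_class <- function(counts) {
  m <- as_counts_matrix(counts)
  apply(m, 1L, function(r) {
    denom <- r[["TP"]] + r[["FP"]] + r[["FN"]]
    # class absent from both masks: vacuous perfect agreement
    if (denom == 0) 1 else r[["TP"]] / denom
  })
}

#' Mean intersection-over-union in percent
#'
#' Averages per-class IoU `TP_i / (TP_i + FP_i + FN_i)` over all classes,
#' background included. A class absent from both masks contributes IoU 1
#' (vacuous agreement).
#'
#' @inheritParams accuracy
#' @return mean IoU in percent.
#' @export
miou <- function(counts) 100 * mean(iou_per_class(counts))

#' Background-excluded IoU in percent
#'
#' Averages per-class IoU over the non-background classes only (labels > 0);
#' for the binary plaque task this is the plaque-class IoU.
#'
#' @inheritParams accuracy
#' @return background-excluded IoU in percent.
#' @export
iou_excluding_background <- function(counts) {
  iou <- iou_per_class(counts)
  if (length(iou) < 2) stop("need at least 2 classes to exclude background")
  100 * mean(iou[-1L])
}

#' Dice similarity coefficient in percent
#'
#' `100 * 2 TP / (2 TP + FP + FN)` for the plaque class. Two empty masks
#' give 100 (vacuous agreement).
#'
#' @inheritParams accuracy
#' @return Dice coefficient in percent.
#' @export
dice <- function(counts) {
  m <- as_counts_matrix(counts)
  row <- if (nrow(m) >= 2) m[2L, ] else m[1L, ]
  denom <- 2 * row[["TP"]] + row[["FP"]] + row[["FN"]]
  if (denom == 0) 100 else 100 * 2 * row[["TP"]] / denom
}

#' Full segmentation metric panel
#'
#' @inheritParams accuracy
#' @return list with `accuracy_pct`, `miou_pct`, `iou_fg_pct`, `dice_pct`.
#' @export
seg_metrics <- function(counts) {
  list(accuracy_pct = accuracy(counts),
       miou_pct = miou(counts),
       iou_fg_pct = iou_excluding_background(counts),
       dice_pct = dice(counts))
}

#' Regression error metrics for diameter prediction
#'
#' Mean squared error, mean absolute error and the coefficient of
#' determination \eqn{R^2 = 1 - \sum (y_i - \hat y_i)^2 / \sum (y_i - \bar
#' y)^2}. With zero variance in `truth`, `r2` is undefined and returned as
#' `NA` with a warning.
#'
#' @param pred numeric vector of predicted values (mm).
#' @param truth numeric vector of true values (mm), same length.
#' @return list with `mse` (mm^2), `mae` (mm) and `r2`.
#' @examples
#' regression_metrics(c(1, 2, 4), c(1, 2, 3))  # mse 1/3, mae 1/3, r2 0.5
#' @export
regression_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  err <- pred - truth
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero variance in truth: r2 undefined")
    NA_real_
  } else 1 - sum(err^2) / ss_tot
  list(mse = mean(err^2), mae = mean(abs(err)), r2 = r2)
}
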