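#' Loss weights for the joint objective
#'
#' The joint loss is `alpha * L_seg + beta * L_size` with `L_seg` the mean
#' per-pixel cross-entropy and `L_size` the mean squared diameter error.
#' `mode = "auto"` replaces the fixed weights with homoscedastic-uncertainty
#' weighting driven by two learnable log-variances (see [auto_balance()]).
#'
#' @param alpha nonnegative segmentation weight.
#' @param beta nonnegative size weight.
#' @param mode `"fixed"` or `"auto"`.
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 1, beta = 1, mode = c("fixed", "auto")) {
  mode <- match.arg(mode)
  if (alpha < 0 || beta < 0) stop("weights must be nonnegative")
  if (alpha + beta <= 0) stop("alpha + beta must be positive")
  structure(list(alpha = alpha, beta = beta, mode = mode),
            class = "loss_weights")
}

softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' Mean per-pixel cross-entropy segmentation loss
#'
#' Softmax over the class scores followed by the mean (not sum) of
#' `-log p_true` over all pixels of the batch, so the loss is invariant to
#' batch and image size.
#'
#' @param scores numeric matrix `(n_pixels x num_classes)` of unnormalized
#'   class scores, or the `segmentation_scores` array from [forward()].
#' @param labels integer vector/array of true labels in `[0, num_classes)`.
#' @return nonnegative scalar; attribute `"grad"` holds the gradient with
#'   respect to `scores` (matrix form).
#' @export
segmentation_loss <- function(scores, labels) {
  S <- scores_as_matrix(scores)
  y <- as.integer(round(as.vector(labels)))
  if (length(y) != nrow(S)) stop("labels do not match scores")
  K <- ncol(S)
  if (any(y < 0L | y >= K)) stop("label out of range [0, num_classes)")
  P <- softmax_rows(S)
  n <- nrow(S)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  G <- P
  G[idx] <- G[idx] - 1
  attr(loss, "grad") <- G / n
  loss
}

scores_as_matrix <- function(scores) {
  if (is.matrix(scores)) return(scores)
  d <- dim(scores)
  if (length(d) == 4L) {
    # (H, W, K, N) array -> (H*W*N) x K
    matrix(aperm(scores, c(1, 2, 4, 3)), ncol = d[3])
  } else stop("scores must be a matrix or a 4D array")
}

#' Mean squared error of the diameter predictions
#'
#' Mean over all `2 x batch` entries of the squared long/short diameter
#' error.
#'
#' @param pred `N x 2` matrix of predicted diameters.
#' @param truth `N x 2` matrix of true diameters.
#' @return nonnegative scalar with gradient attribute `"grad"`.
#' @export
size_loss <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("pred/truth shape mismatch")
  err <- pred - truth
  loss <- mean(err^2)
  attr(loss, "grad") <- 2 * err / length(err)
  loss
}

#' Weighted joint loss
#'
#' `total = alpha * L_seg + beta * L_size` (fixed mode). In auto mode the
#' total is the homoscedastic-uncertainty objective
#' `exp(-s_seg) L_seg + s_seg + exp(-s_size) L_size / 2 + s_size / 2` and
#' the reported effective weights are `alpha = exp(-s_seg)`,
#' `beta = exp(-s_size) / 2`.
#'
#' @param scores,labels as in [segmentation_loss()].
#' @param pred,truth as in [size_loss()].
#' @param weights a [loss_weights()].
#' @param s auto-mode state `list(s_seg, s_size)` (learnable log-variances).
#' @return object of class `loss_breakdown`: list with `total`, `seg_term`,
#'   `size_term`, `alpha_used`, `beta_used` and gradient attributes
#'   `grad_scores`, `grad_pred` (and `grad_s` in auto mode).
#' @export
joint_loss <- function(scores, labels, pred, truth, weights = loss_weights(),
                       s = NULL) {
  stopifnot(inherits(weights, "loss_weights"))
  lseg <- segmentation_loss(scores, labels)
  lsize <- size_loss(pred, truth)
  if (weights$mode == "auto") {
    if (is.null(s)) s <- list(s_seg = 0, s_size = 0)
    a <- exp(-s$s_seg)
    b <- exp(-s$s_size) / 2
    total <- a * as.numeric(lseg) + s$s_seg +
      b * as.numeric(lsize) + s$s_size / 2
    grad_s <- list(s_seg = -a * as.numeric(lseg) + 1,
                   s_size = -b * as.numeric(lsize) + 1 / 2)
  } else {
    a <- weights$alpha; b <- weights$beta
    total <- a * as.numeric(lseg) + b * as.numeric(lsize)
    grad_s <- NULL
  }
  out <- list(total = total, seg_term = as.numeric(lseg),
              size_term = as.numeric(lsize), alpha_used = a, beta_used = b)
  attr(out, "grad_scores") <- a * attr(lseg, "grad")
  attr(out, "grad_pred") <- b * attr(lsize, "grad")
  attr(out, "grad_s") <- grad_s
  class(out) <- "loss_breakdown"
  out
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("joint loss %.6f = %.3f x seg %.6f + %.3f x size %.6f\n",
              x$total, x$alpha_used, x$seg_term, x$beta_used, x$size_term))
  invisible(x)
}

#' Effective loss weights under homoscedastic-uncertainty balancing
#'
#' Given learnable log-variances `s_seg`, `s_size`, the task weights are
#' `alpha = exp(-s_seg)` and `beta = exp(-s_size)/2`; a task whose loss
#' stays persistently large drives its log-variance up and its weight down.
#'
#' @param s list with `s_seg` and `s_size`.
#' @return a [loss_weights()] in fixed mode with the current effective
#'   weights.
#' @export
auto_balance <- function(s) {
  loss_weights(alpha = exp(-s$s_seg), beta = exp(-s$s_size) / 2)
}
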