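# Training objectives: softmax cross-entropy and the multi-label focal
# loss (MFL).
#
# The MFL casts each sequence position's single-token target as a
# multi-label problem over all n vocabulary classes: every logit o_i is
# squashed independently by a sigmoid, the per-class label probability is
#   p_i = sigma(o_i)       if y_i = 1
#   p_i = 1 - sigma(o_i)   otherwise,
# and the position loss is the class average of the focal-modulated binary
# loss  -alpha_i (1 - p_i)^gamma log(p_i).  With gamma = 0 and alpha_i = 1
# this reduces exactly to the mean per-class binary cross-entropy; gamma >
# 0 down-weights classes the model already predicts well, countering the
# long-tailed token frequency distribution.

MFL_EPS <- 1e-12

#' Per-class label probability under the sigmoid multi-label cast
#'
#' @param o numeric vector/matrix of logits.
#' @param y 0/1 ground-truth indicators, same shape as `o`.
#' @return `sigma(o)` where `y = 1`, `1 - sigma(o)` elsewhere, clamped away
#'   from 0 and 1 for numerical safety.
#' @examples
#' label_probability(0, 1)   # 0.5
#' label_probability(0, 0)   # 0.5
#' @export
label_probability <- function(o, y) {
  stopifnot(all(y %in% c(0, 1)), length(o) == length(y))
  s <- stats::plogis(o)
  p <- ifelse(y == 1, s, 1 - s)
  pmin(pmax(p, MFL_EPS), 1 - MFL_EPS)
}

# Shared core: loss value and d(loss)/d(logits) for the MFL.
# o: positions x classes; y: same-shape one-hot; alpha: per-class vector;
# keep: logical per position.
mfl_core <- function(o, y, alpha, gamma, keep) {
  n_pos <- sum(keep)
  if (n_pos == 0L) stop("all positions are masked out")
  n_cls <- ncol(o)
  A <- matrix(alpha, nrow(o), n_cls, byrow = TRUE)
  p <- label_probability(o, y)
  per <- -A * (1 - p)^gamma * log(p)
  loss <- sum(per[keep, , drop = FALSE]) / (n_cls * n_pos)
  sign <- ifelse(y == 1, -1, 1)
  grad <- sign * A * ((1 - p)^(gamma + 1) - gamma * (1 - p)^gamma * p * log(p))
  grad[!keep, ] <- 0
  grad <- grad / (n_cls * n_pos)
  list(loss = loss, grad = grad)
}

ce_core <- function(o, y, keep) {
  n_pos <- sum(keep)
  if (n_pos == 0L) stop("all positions are masked out")
  m <- apply(o, 1L, max)
  e <- exp(o - m)
  q <- e / rowSums(e)
  lse <- m + log(rowSums(e))
  true_logit <- rowSums(o * y)
  per <- lse - true_logit
  loss <- sum(per[keep]) / n_pos
  grad <- (q - y) / n_pos
  grad[!keep, ] <- 0
  list(loss = loss, grad = grad)
}

as_onehot <- function(y, n_cls) {
  if (is.matrix(y)) return(y)
  oh <- matrix(0, length(y), n_cls)
  oh[cbind(seq_along(y), y)] <- 1
  oh
}

check_loss_inputs <- function(o, y, keep) {
  stopifnot(is.matrix(o), is.matrix(y), all(dim(o) == dim(y)),
            all(y %in% c(0, 1)))
  rs <- rowSums(y)
  if (any(rs[keep] != 1))
    stop("each unmasked position must have exactly one positive class")
}

#' Multi-label focal loss
#'
#' Average over classes of the focal-modulated per-class binary loss, then
#' average over unmasked positions:
#' `MFL = (1/n) sum_i -alpha_i (1 - p_i)^gamma log(p_i)`.
#' With `gamma = 0` and `alpha = 1` this equals the mean per-class binary
#' cross-entropy.
#'
#' @param o logits matrix (positions x classes); a vector is treated as one
#'   position.
#' @param y one-hot matrix of the same shape (or integer class ids).
#' @param alpha per-class weighting factors (scalar or length-classes
#'   vector), all >= 0.
#' @param gamma focusing parameter, >= 0.
#' @param mask logical per-position vector; positions with `FALSE` (pads)
#'   are excluded from the average.  Default keeps all.
#' @return Scalar loss (>= 0).
#' @examples
#' mfl(matrix(0, 1, 2), matrix(c(1, 0), 1), alpha = 1, gamma = 0) # log(2)
#' @export
mfl <- function(o, y, alpha = 0.25, gamma = 2, mask = NULL) {
  if (!is.matrix(o)) o <- matrix(o, nrow = 1L)
  if (!is.matrix(y) && length(y) == length(o) && all(y %in% c(0, 1)))
    y <- matrix(y, nrow = nrow(o))
  y <- as_onehot(y, ncol(o))
  keep <- if (is.null(mask)) rep(TRUE, nrow(o)) else as.logical(mask)
  stopifnot(gamma >= 0, all(alpha >= 0))
  check_loss_inputs(o, y, keep)
  mfl_core(o, y, rep(alpha, length.out = ncol(o)), gamma, keep)$loss
}

#' Softmax cross-entropy loss
#'
#' Standard cross-entropy `-log softmax(o)[true class]` averaged over
#' unmasked positions.
#'
#' @inheritParams mfl
#' @return Scalar loss (>= 0).
#' @examples
#' ce(matrix(0, 1, 79), 1L)   # log(79)
#' @export
ce <- function(o, y, mask = NULL) {
  if (!is.matrix(o)) o <- matrix(o, nrow = 1L)
  if (!is.matrix(y) && length(y) == length(o) && all(y %in% c(0, 1)))
    y <- matrix(y, nrow = nrow(o))
  y <- as_onehot(y, ncol(o))
  keep <- if (is.null(mask)) rep(TRUE, nrow(o)) else as.logical(mask)
  check_loss_inputs(o, y, keep)
  ce_core(o, y, keep)$loss
}

# Fused autograd ops sharing the cores above (see autograd.R).
ag_mfl_loss <- function(logits, target_ids, alpha, gamma, keep = NULL) {
  o <- ag_val(logits)
  y <- as_onehot(target_ids, ncol(o))
  if (is.null(keep)) keep <- rep(TRUE, nrow(o))
  res <- mfl_core(o, y, rep(alpha, length.out = ncol(o)), gamma, keep)
  op(matrix(res$loss, 1L, 1L), list(logits), function(n)
    ag_accum(n$parents[[1]], n$g[1] * res$grad))
}

ag_ce_loss <- function(logits, target_ids, keep = NULL) {
  o <- ag_val(logits)
  y <- as_onehot(target_ids, ncol(o))
  if (is.null(keep)) keep <- rep(TRUE, nrow(o))
  res <- ce_core(o, y, keep)
  op(matrix(res$loss, 1L, 1L), list(logits), function(n)
    ag_accum(n$parents[[1]], n$g[1] * res$grad))
}
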