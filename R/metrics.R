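# Evaluation metrics. Implemented from their standard definitions so the
# test suite can cross-check them against independent reference
# implementations.

#' Root mean squared error
#' @param pred,truth numeric vectors
#' @return non-negative scalar
#' @export
rmse <- function(pred, truth) sqrt(mean((pred - truth)^2))

#' Pearson correlation coefficient
#' @param pred,truth numeric vectors
#' @return value in `[-1, 1]`
#' @export
pcc <- function(pred, truth) stats::cor(pred, truth)

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` around the mean of the observed values.
#' @param pred,truth numeric vectors
#' @return scalar (can be negative for poor fits)
#' @export
rsq <- function(pred, truth) {
  1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
}

#' Area under the receiver operating characteristic curve
#'
#' Computed as the normalised Mann-Whitney U statistic, with the standard
#' half-credit for tied scores.
#' @param scores numeric prediction scores
#' @param labels binary labels (1 = positive)
#' @return AUC in `[0, 1]`, or `NA` with a warning for a single-class input
#' @export
aucScore <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) {
    warning("AUC undefined: single-class label set", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation (average precision): the sum over ranked
#' positives of precision at each recall increment.
#' @param scores numeric prediction scores
#' @param labels binary labels (1 = positive)
#' @return AUPR in `[0, 1]`, or `NA` with a warning for a single-class input
#' @export
auprScore <- function(scores, labels) {
  nPos <- sum(labels == 1)
  if (nPos == 0 || nPos == length(labels)) {
    warning("AUPR undefined: single-class label set", call. = FALSE)
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab == 1)
  precision <- tp / seq_along(lab)
  sum(precision[lab == 1]) / nPos
}

#' Huber loss
#'
#' Quadratic within `delta` of zero error and linear beyond, so the gradient
#' magnitude never exceeds `delta`. The batch loss is the mean over
#' instances.
#'
#' @param pred predicted values
#' @param truth observed values
#' @param delta scale parameter delta > 0 (default 1)
#' @param reduce return the batch mean (default) or per-instance losses
#' @return scalar loss (or vector when `reduce = FALSE`)
#' @export
huberLoss <- function(pred, truth, delta = 1, reduce = TRUE) {
  stopIfNot(delta > 0, "delta must be positive")
  e <- pred - truth
  l <- ifelse(abs(e) <= delta, 0.5 * e^2, delta * abs(e) - 0.5 * delta^2)
  if (reduce) mean(l) else l
}

#' Gradient of the Huber loss with respect to the prediction
#' @inheritParams huberLoss
#' @return per-instance gradient vector (not averaged)
#' @export
huberGrad <- function(pred, truth, delta = 1) {
  e <- pred - truth
  ifelse(abs(e) <= delta, e, delta * sign(e))
}
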