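#' Loss configuration
#'
#' @param lambda_weight Non-negative weight of the F1/FPR term in the combined
#'   CCE-F1 loss (default 2).
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(lambda_weight = 2) {
  if (lambda_weight < 0) stop("lambda_weight must be >= 0")
  structure(list(lambda_weight = lambda_weight,
                 exon_class_indices = .EXON_CLASSES),
            class = "loss_config")
}

.PROB_FLOOR <- 1e-12

.as_labels <- function(y) {
  y <- as.integer(y)
  if (length(y) && (min(y) < 1L || max(y) > 15L)) stop("labels out of range")
  y
}

#' Categorical cross-entropy over a label sequence
#'
#' Position-mean negative log predicted probability of the true label, with
#' probabilities floored at 1e-12.
#'
#' @param y_true Integer label vector (or [label_seq()]).
#' @param y_hat T x 15 predicted probability matrix (rows on the simplex).
#' @return Scalar loss.
#' @export
categorical_cross_entropy <- function(y_true, y_hat) {
  y <- .as_labels(y_true)
  p <- y_hat[cbind(seq_along(y), y)]
  -mean(log(pmax(p, .PROB_FLOOR)))
}

.cce_grad <- function(y, y_hat) {
  g <- matrix(0, nrow(y_hat), 15)
  p <- y_hat[cbind(seq_along(y), y)]
  live <- p > .PROB_FLOOR
  g[cbind(seq_along(y), y)] <- ifelse(live, -1 / (length(y) * pmax(p, .PROB_FLOOR)), 0)
  g
}

#' Soft (differentiable) per-class F1 estimates
#'
#' Soft counts over positions: `TP_i = sum_j y_hat[j,i] * [y_j = i]`,
#' predicted mass `P_i = sum_j y_hat[j,i]`, actual count `A_i`, and
#' `F1_i = 2 TP_i / (P_i + A_i)` with 0/0 mapped to 0.
#'
#' @inheritParams categorical_cross_entropy
#' @param classes State indices to evaluate (default: the 11 exon classes).
#' @return Named numeric vector of soft F1 values per class.
#' @export
soft_f1_scores <- function(y_true, y_hat, classes = .EXON_CLASSES) {
  y <- .as_labels(y_true)
  vapply(classes, function(i) {
    tp <- sum(y_hat[y == i, i])
    denom <- sum(y_hat[, i]) + sum(y == i)
    if (denom == 0) 0 else 2 * tp / denom
  }, numeric(1)) |> setNames(.STATES[classes])
}

#' Soft F1 loss over exon classes
#'
#' `sum over exon classes present in y_true of (1 - F1_i)`; exon classes
#' absent from the labels contribute nothing (their false-positive mass is
#' handled by the FPR fallback of [cce_f1_loss()] on exon-free sequences).
#'
#' @inheritParams categorical_cross_entropy
#' @param config A [loss_config()].
#' @return Scalar loss (>= 0).
#' @export
f1_loss <- function(y_true, y_hat, config = loss_config()) {
  y <- .as_labels(y_true)
  present <- intersect(config$exon_class_indices, unique(y))
  if (length(present) == 0L) return(0)
  sum(1 - soft_f1_scores(y, y_hat, present))
}

.f1_grad <- function(y, y_hat, config) {
  g <- matrix(0, nrow(y_hat), 15)
  present <- intersect(config$exon_class_indices, unique(y))
  for (i in present) {
    ind <- as.numeric(y == i)
    tp <- sum(y_hat[, i] * ind)
    denom <- sum(y_hat[, i]) + sum(ind)
    if (denom == 0) next
    # d(1 - F1_i)/d y_hat[j, i] = -(2*ind_j*denom - 2*tp) / denom^2
    g[, i] <- g[, i] - (2 * ind * denom - 2 * tp) / denom^2
  }
  g
}

#' Estimated exon false-positive rate
#'
#' Mean over positions of the total predicted exon-class probability mass;
#' the training fallback for sequences without any exon label.
#'
#' @inheritParams categorical_cross_entropy
#' @param exon_class_indices Indices of the exon classes.
#' @return Scalar in `[0, 1]`.
#' @export
estimated_fpr <- function(y_hat, exon_class_indices = .EXON_CLASSES) {
  sum(y_hat[, exon_class_indices]) / nrow(y_hat)
}

.fpr_grad <- function(y_hat, exon_class_indices) {
  g <- matrix(0, nrow(y_hat), 15)
  g[, exon_class_indices] <- 1 / nrow(y_hat)
  g
}

#' Combined CCE-F1 training loss
#'
#' Per sequence: `CCE + lambda * F1-loss` when the labels contain at least one
#' exon class, and `CCE + lambda * FPR` on exon-free sequences. Batch loss is
#' the mean of per-sequence losses.
#'
#' @inheritParams f1_loss
#' @return Scalar loss.
#' @seealso [cce_f1_batch()] for the batched mean.
#' @export
cce_f1_loss <- function(y_true, y_hat, config = loss_config()) {
  y <- .as_labels(y_true)
  cce <- categorical_cross_entropy(y, y_hat)
  has_exon <- any(y %in% config$exon_class_indices)
  extra <- if (has_exon) f1_loss(y, y_hat, config) else
    estimated_fpr(y_hat, config$exon_class_indices)
  cce + config$lambda_weight * extra
}

#' Gradient of the CCE-F1 loss with respect to the predictions
#'
#' @inheritParams cce_f1_loss
#' @return T x 15 gradient matrix.
#' @export
cce_f1_grad <- function(y_true, y_hat, config = loss_config()) {
  y <- .as_labels(y_true)
  g <- .cce_grad(y, y_hat)
  has_exon <- any(y %in% config$exon_class_indices)
  extra <- if (has_exon) .f1_grad(y, y_hat, config) else
    .fpr_grad(y_hat, config$exon_class_indices)
  g + config$lambda_weight * extra
}

#' Mean CCE-F1 loss over a batch of sequences
#'
#' @param y_list List of label vectors.
#' @param y_hat_list List of matching prediction matrices.
#' @param config A [loss_config()].
#' @return Scalar batch loss (mean of per-sequence losses).
#' @export
cce_f1_batch <- function(y_list, y_hat_list, config = loss_config()) {
  stopifnot(length(y_list) == length(y_hat_list))
  mean(mapply(cce_f1_loss, y_list, y_hat_list,
              MoreArgs = list(config = config)))
}
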