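#' Dice coefficient between two binary masks
#'
#' `DC = 2|A ∩ P| / (|A| + |P|)`, the overlap statistic used both for
#' evaluation and, inside the training loss, in its differentiable soft
#' form. When both masks are empty there is nothing to find and nothing
#' found, which counts as perfect agreement (`DC = 1`).
#'
#' @param a,p Binary 0/1 matrices of equal shape.
#' @return A number in \[0, 1\].
#' @export
dice_coefficient <- function(a, p) {
  assert_mask(a, "a"); assert_mask(p, "p")
  assert_same_shape(a, p, "dice_coefficient masks")
  sa <- sum(a); sp <- sum(p)
  if (sa + sp == 0) return(1)
  2 * sum(a * p) / (sa + sp)
}

#' Soft (differentiable) Dice between a mask and a probability map
#'
#' `(2 * sum(a * p) + eps) / (sum(a) + sum(p) + eps)` with additive
#' smoothing `eps` (default 1) in numerator and denominator. The smoothing
#' keeps the ratio defined — and equal to 1 — when both inputs are empty,
#' and makes the statistic differentiable in `p` everywhere. With `eps = 0`
#' and a binary `p` it reduces to [dice_coefficient()].
#'
#' @param a Binary 0/1 matrix.
#' @param p Numeric matrix of per-pixel probabilities in \[0, 1\].
#' @param eps Smoothing constant, default 1.
#' @return A number in \[0, 1\].
#' @export
soft_dice <- function(a, p, eps = 1) {
  assert_mask(a, "a")
  if (!is.matrix(p)) stop_contract("p must be a matrix")
  assert_same_shape(a, p, "soft_dice inputs")
  if (min(p) < 0 || max(p) > 1) stop_contract("probabilities must lie in [0, 1]")
  sa <- sum(a); sp <- sum(p)
  if (eps == 0 && sa + sp == 0) return(1)
  (2 * sum(a * p) + eps) / (sa + sp + eps)
}

# Cross-class soft Dice: smoothing in the denominator only, so that a
# prediction strictly disjoint from the other class's annotation yields
# exactly 0 and contributes zero cross-suppression loss.
cross_soft_dice <- function(a, p, eps = 1) {
  sa <- sum(a); sp <- sum(p)
  2 * sum(a * p) / (sa + sp + eps)
}

#' Customized Dice-logarithmic multilabel loss
#'
#' The training loss of the two-head network:
#' \deqn{L = -w_1 \log DC(A_s, P_s) - w_2 \log DC(A_v, P_v)
#'           - w_3 \log(1 - DC(A_s, P_v)) - w_4 \log(1 - DC(A_v, P_s))}
#' The two matching terms reward overlap of each head with its own
#' annotation; the two cross terms penalize overlap of a head with the
#' *other* class's annotation, preventing the soma output from absorbing
#' vessel structure and vice versa — the mechanism by which the loss copes
#' with the class imbalance between frequent somata and sparse vessels
#' without extra class-weight hyperparameters.
#'
#' Matching DCs are computed by [soft_dice()] (smoothing `eps`); cross DCs
#' use denominator-only smoothing so that strictly disjoint classes
#' contribute exactly zero. Every DC is clamped to `[tau, 1 - tau]` before
#' the natural logarithm, so the loss is always finite; the gradient is
#' zero where the clamp is active.
#'
#' @param anno_soma,anno_vessel Binary annotation masks.
#' @param pred_soma,pred_vessel Probability maps in \[0, 1\], same shape.
#' @param term_weights Numeric length-4 vector weighting the terms in the
#'   order soma-match, vessel-match, soma-into-vessel cross,
#'   vessel-into-soma cross. Default all 1. Per-instance boosting weights
#'   enter training through this hook.
#' @param eps Soft-Dice smoothing, default 1.
#' @param tau Clamp applied to each DC before the log, default 1e-7.
#' @return A list of class `loss_breakdown` with elements `total` and
#'   `terms` (named length-4 vector); `total == sum(terms)`.
#' @export
dice_log_loss <- function(anno_soma, anno_vessel, pred_soma, pred_vessel,
                          term_weights = c(1, 1, 1, 1), eps = 1, tau = 1e-7) {
  maps <- list(pred_soma, pred_vessel)
  if (!all(vapply(maps, function(m) all(is.finite(m)), TRUE))) {
    stop_contract("predictions must be finite")
  }
  assert_same_shape(anno_soma, pred_soma, "loss inputs")
  assert_same_shape(anno_vessel, pred_vessel, "loss inputs")
  clamp <- function(x) min(max(x, tau), 1 - tau)
  dc_ss <- clamp(soft_dice(anno_soma, pred_soma, eps))
  dc_vv <- clamp(soft_dice(anno_vessel, pred_vessel, eps))
  dc_sv <- clamp(cross_soft_dice(anno_soma, pred_vessel, eps))
  dc_vs <- clamp(cross_soft_dice(anno_vessel, pred_soma, eps))
  terms <- c(soma_match = -term_weights[1L] * log(dc_ss),
             vessel_match = -term_weights[2L] * log(dc_vv),
             soma_cross = -term_weights[3L] * log(1 - dc_sv),
             vessel_cross = -term_weights[4L] * log(1 - dc_vs))
  structure(list(total = sum(terms), terms = terms), class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss_breakdown> total = %.6f\n", x$total))
  print(round(x$terms, 6))
  invisible(x)
}

#' Mean Dice coefficient over a set of instances
#'
#' Arithmetic mean of the per-instance hard DC between each instance's
#' annotation mask for `class` and the corresponding prediction binarized
#' at `threshold`.
#'
#' @param instances List of [annotated_instance()] objects.
#' @param predictions List (same order) of per-class probability maps or
#'   binary masks; each element a named list with one matrix per class.
#' @param class `"soma"` or `"vessel"`.
#' @param threshold Binarization threshold for probability maps, default 0.5.
#' @return Mean DC, a number in \[0, 1\].
#' @export
mean_dice <- function(instances, predictions, class, threshold = 0.5) {
  if (length(instances) == 0L) stop_contract("mean_dice needs a nonempty set")
  if (length(instances) != length(predictions)) {
    stop_contract("instances and predictions differ in length")
  }
  mean(vapply(seq_along(instances), function(i) {
    p <- predictions[[i]][[class]]
    pb <- matrix(as.integer(p >= threshold), nrow(p), ncol(p))
    dice_coefficient(instances[[i]]$masks[[class]], pb)
  }, 0))
}

#' Linear trend of performance across boosting iterations
#'
#' Ordinary-least-squares slope of mean DC against the iteration index
#' `1..T` — the "linear coefficient" summarizing whether boosting iterations
#' improve (positive slope) or degrade (negative) segmentation performance.
#'
#' @param mean_dcs Numeric vector of mean DCs, one per iteration.
#' @return The OLS slope.
#' @export
trend_slope <- function(mean_dcs) {
  if (length(mean_dcs) < 2L) stop_contract("trend_slope needs at least 2 iterations")
  iteration <- seq_along(mean_dcs)
  unname(coef(lm(mean_dcs ~ iteration))[2L])
}
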