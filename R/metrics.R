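#' V-measure of a clustering against ground-truth labels
#'
#' Harmonic mean (weight 1) of homogeneity and completeness computed from
#' the conditional entropies of the truth/prediction contingency table.
#' Invariant to label permutation: any bijective relabeling of the truth
#' scores 1.
#'
#' @param true_labels,pred_labels equal-length label vectors (any atomic
#'   type).
#' @return score in `[0, 1]`.
#' @export
v_measure <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels)) {
    stop("label vectors have different lengths")
  }
  n <- length(true_labels)
  if (n < 1L) stop("empty label vectors")
  tab <- table(true_labels, pred_labels)
  p <- tab / n
  pc <- rowSums(p)
  pk <- colSums(p)
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  H_C <- -sum(xlogx(pc))
  H_K <- -sum(xlogx(pk))
  # H(C|K) = -sum_ck p_ck log(p_ck / p_k)
  H_CgK <- -sum(xlogx(p)) + sum(xlogx(pk))
  H_KgC <- -sum(xlogx(p)) + sum(xlogx(pc))
  h <- if (H_C == 0) 1 else 1 - H_CgK / H_C
  co <- if (H_K == 0) 1 else 1 - H_KgC / H_K
  if (h + co == 0) 0 else 2 * h * co / (h + co)
}

#' Genotype reconstruction accuracy, sensitivity and specificity
#'
#' Compares the predicted binary genotype matrix Z to the true matrix
#' Z-star entry by entry, after dropping doublet rows from both. Accuracy
#' is the fraction of correct entries; sensitivity the fraction of true
#' 1-entries called 1; specificity the fraction of true 0-entries called 0.
#' A rate whose reference class is empty is reported as `NA`.
#'
#' @param Z predicted N x M binary matrix.
#' @param Z_star true N x M binary matrix.
#' @param doublet_indices row indices excluded before comparison.
#' @return named vector `c(accuracy, sensitivity, specificity)`.
#' @export
genotype_metrics <- function(Z, Z_star, doublet_indices = integer(0)) {
  if (!all(dim(Z) == dim(Z_star))) stop("Z and Z_star have different shapes")
  if (length(doublet_indices)) {
    Z <- Z[-doublet_indices, , drop = FALSE]
    Z_star <- Z_star[-doublet_indices, , drop = FALSE]
  }
  ones <- Z_star == 1
  zeros <- Z_star == 0
  acc <- mean(Z == Z_star)
  sens <- if (any(ones)) mean(Z[ones] == 1) else NA_real_
  spec <- if (any(zeros)) mean(Z[zeros] == 0) else NA_real_
  c(accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Evaluate a fit against simulated ground truth
#'
#' Computes the clustering V-measure and the genotype reconstruction
#' metrics, with doublet cells excluded from all of them.
#'
#' @param fit a `clonemix_fit`.
#' @param truth a `sim_truth` from [simulate_dataset()].
#' @return one-row data.frame with `v_measure`, `accuracy`, `sensitivity`,
#'   `specificity` and `n_cells_evaluated`.
#' @export
evaluate_fit <- function(fit, truth) {
  stopifnot(inherits(fit, "clonemix_fit"), inherits(truth, "sim_truth"))
  dbl <- truth$doublet_indices
  keep <- setdiff(seq_along(truth$cell_clone), dbl)
  gm <- genotype_metrics(fit$Z, truth$Z_star, dbl)
  data.frame(
    v_measure = v_measure(truth$cell_clone[keep], fit$assignments[keep]),
    accuracy = gm[["accuracy"]],
    sensitivity = gm[["sensitivity"]],
    specificity = gm[["specificity"]],
    n_cells_evaluated = length(keep)
  )
}
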