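#' Empirical per-locus mismatch probabilities
#'
#' Probability that two cells drawn from clusters whose true states at a
#' locus are s and t show *different* observed states there (missing counts
#' as its own state), as a function of the converged error rates and the
#' missing fraction of the input matrix. Both-missing entries count as
#' equal, which is why the missing contribution is `2*eta*(1-eta)` rather
#' than including an `eta^2` term.
#'
#' @param alpha_star,beta_star converged false-positive / false-negative
#'   rates.
#' @param eta fraction of missing entries in the observed matrix.
#' @return named vector `c(p00, p01, p10, p11)`; `p10 == p01`.
#' @export
mismatch_probs <- function(alpha_star, beta_star, eta) {
  stopifnot(alpha_star >= 0, alpha_star <= 1,
            beta_star >= 0, beta_star <= 1, eta >= 0, eta <= 1)
  obs2 <- (1 - eta)^2
  miss <- 2 * eta * (1 - eta)
  p00 <- 2 * alpha_star * (1 - alpha_star) * obs2 + miss
  p01 <- ((1 - alpha_star) * (1 - beta_star) + alpha_star * beta_star) * obs2 + miss
  p11 <- 2 * beta_star * (1 - beta_star) * obs2 + miss
  c(p00 = p00, p01 = p01, p10 = p01, p11 = p11)
}

#' Expected inter-cluster distance between two subclone genotypes
#'
#' Expected number of loci at which two cells drawn from the two clusters
#' show different observed states, given the clusters' inferred genotypes
#' and the mismatch probabilities.
#'
#' @param c_i,c_k binary genotype vectors of equal length.
#' @param probs output of [mismatch_probs()].
#' @return expected locus-mismatch count (not a proportion).
#' @export
expected_distance <- function(c_i, c_k, probs) {
  if (length(c_i) != length(c_k)) stop("genotypes have different lengths")
  n00 <- sum((1 - c_i) * (1 - c_k))
  n01 <- sum((1 - c_i) * c_k)
  n10 <- sum(c_i * (1 - c_k))
  n11 <- sum(c_i * c_k)
  unname(probs["p00"] * n00 + probs["p01"] * n01 +
           probs["p10"] * n10 + probs["p11"] * n11)
}

# N x N matrix of pairwise observed mismatch counts between cells,
# treating missing as a third state equal only to itself.
.pairwise_mismatch <- function(values) {
  M <- ncol(values)
  I0 <- matrix(0, nrow(values), M)
  I0[which(values == 0L)] <- 1
  I1 <- matrix(0, nrow(values), M)
  I1[which(values == 1L)] <- 1
  Im <- matrix(0, nrow(values), M)
  Im[which(is.na(values))] <- 1
  M - (tcrossprod(I0) + tcrossprod(I1) + tcrossprod(Im))
}

#' Mean observed distance between the cells of two clusters
#'
#' Mean, over all cross pairs, of the number of loci where the two cells'
#' observed ternary states differ (missing equals missing only).
#'
#' @param gtm a `genotype_matrix`.
#' @param cells_i,cells_k disjoint, non-empty cell index sets.
#' @export
observed_mean_distance <- function(gtm, cells_i, cells_k) {
  if (!length(cells_i) || !length(cells_k)) stop("empty cell set")
  if (length(intersect(cells_i, cells_k))) stop("cell sets must be disjoint")
  mm <- .pairwise_mismatch(gtm$values[c(cells_i, cells_k), , drop = FALSE])
  ni <- length(cells_i)
  mean(mm[seq_len(ni), ni + seq_along(cells_k)])
}

#' Inter-cluster pair score
#'
#' `exp(-(d - d_hat)^2)`: close agreement between the expected and observed
#' mean inter-cluster distances scores near 1, disagreement decays as a
#' Gaussian.
#'
#' @param d expected inter-cluster distance.
#' @param d_hat observed mean inter-cluster distance.
#' @export
pair_score <- function(d, d_hat) {
  exp(-(d - d_hat)^2)
}

#' Inter-cluster-variance score of a fitted model
#'
#' Mean pair score over all unordered pairs of non-empty predicted
#' clusters. A homogeneous model (one cluster, or one non-empty cluster
#' after dropping empty ones) scores 0 by convention so that any separable
#' structure can beat it.
#'
#' @param gtm a `genotype_matrix`.
#' @param fit a `clonemix_fit`.
#' @param mismatch optional precomputed N x N observed mismatch matrix
#'   (re-used across K by [select_k()]).
#' @param detail if `TRUE`, attach the pair matrices as attribute `"table"`.
#' @param rates optional length-2 vector `c(alpha, beta)` overriding the
#'   fit's own error-rate estimates in the mismatch probabilities;
#'   [select_k()] scores every candidate model with the rates of the most
#'   refined fit so that the probabilities describe measurement noise
#'   rather than model lack-of-fit.
#' @return scalar score `s_K` in `[0, 1]`.
#' @export
model_score <- function(gtm, fit, mismatch = NULL, detail = FALSE,
                        rates = NULL) {
  stopifnot(inherits(fit, "clonemix_fit"))
  K <- fit$params$K
  sizes <- tabulate(fit$assignments, K)
  keep <- which(sizes > 0L)
  if (length(keep) < K) {
    message(sprintf("model_score: dropping %d empty predicted cluster(s)",
                    K - length(keep)))
  }
  if (length(keep) < 2L) return(0)
  C <- fit$params$C[keep, , drop = FALSE]
  if (is.null(rates)) rates <- c(fit$params$alpha, fit$params$beta)
  probs <- mismatch_probs(rates[1L], rates[2L], gtm$eta)
  if (is.null(mismatch)) mismatch <- .pairwise_mismatch(gtm$values)
  Kk <- length(keep)
  A <- matrix(0, nrow(gtm$values), Kk)
  A[cbind(seq_len(nrow(A)), match(fit$assignments, keep))] <- 1
  cross_sum <- crossprod(A, mismatch %*% A)
  n <- sizes[keep]
  d_hat <- cross_sum / tcrossprod(n)
  d_exp <- matrix(0, Kk, Kk)
  for (i in seq_len(Kk - 1L)) {
    for (k in (i + 1L):Kk) {
      d_exp[i, k] <- d_exp[k, i] <- expected_distance(C[i, ], C[k, ], probs)
    }
  }
  s <- pair_score(d_exp, d_hat)
  s_K <- mean(s[upper.tri(s)])
  if (detail) {
    attr(s_K, "table") <- list(d_expected = d_exp, d_observed = d_hat,
                               s = s, clusters = keep)
  }
  s_K
}

# Robust selection score used by select_k to compare models across K.
#
# Same ingredients as model_score (expected vs observed inter-cluster
# distances under the empirical mismatch probabilities), hardened in three
# ways that matter when comparing models of different complexity:
#   * each pair's expected/observed gap is standardized by the sampling
#     error of the observed mean distance (Hajek projection), so pairs of
#     small clusters are not out-scored merely because their observed mean
#     distance is noisier;
#   * each cluster also contributes a within-cluster self-consistency gap
#     (the expected-distance formula applied with i = k): a cluster that
#     secretly merges several
#     subclones shows inflated within-cluster observed distances that
#     cannot cancel, unlike cross-cluster gaps whose signed per-locus
#     errors do;
#   * the pair score is exp of minus the mean of the three standardized
#     squared gaps, still in (0, 1] and averaged over unordered pairs.
# A 0.02-locus floor on every standard error absorbs the sub-locus
# residuals that the clamped error rates leave on noise-free data.
.selection_score <- function(gtm, fit, mismatch, rates) {
  K <- fit$params$K
  sizes <- tabulate(fit$assignments, K)
  keep <- which(sizes > 0L)
  if (length(keep) < 2L) return(0)
  C <- fit$params$C[keep, , drop = FALSE]
  probs <- mismatch_probs(rates[1L], rates[2L], gtm$eta)
  Kk <- length(keep)
  cells <- split(seq_len(nrow(gtm$values)),
                 factor(fit$assignments, levels = keep))
  z_within <- numeric(Kk)
  for (i in seq_len(Kk)) {
    ci <- cells[[i]]
    n <- length(ci)
    if (n < 2L) next
    sub <- mismatch[ci, ci, drop = FALSE]
    d_hat <- sum(sub) / (n * (n - 1))
    d <- expected_distance(C[i, ], C[i, ], probs)
    se <- 2 * stats::sd(rowSums(sub) / (n - 1)) / sqrt(n) + 0.02
    z_within[i] <- (d - d_hat) / se
  }
  s <- matrix(1, Kk, Kk)
  for (i in seq_len(Kk - 1L)) {
    for (k in (i + 1L):Kk) {
      ci <- cells[[i]]
      ck <- cells[[k]]
      sub <- mismatch[ci, ck, drop = FALSE]
      d_hat <- mean(sub)
      d <- expected_distance(C[i, ], C[k, ], probs)
      va <- if (length(ci) > 1L) stats::var(rowMeans(sub)) / length(ci) else 0
      vb <- if (length(ck) > 1L) stats::var(colMeans(sub)) / length(ck) else 0
      z <- (d - d_hat) / (sqrt(va + vb) + 0.02)
      s[i, k] <- s[k, i] <-
        exp(-(z^2 + z_within[i]^2 + z_within[k]^2) / 3)
    }
  }
  mean(s[upper.tri(s)])
}

# Drop mixture components that no cell is assigned to. The partition, the
# per-cell predictions and (up to renormalization of the weights) the
# likelihood are unchanged; only the reported number of subclones shrinks.
.prune_empty_clusters <- function(fit) {
  K <- fit$params$K
  sizes <- tabulate(fit$assignments, K)
  keep <- which(sizes > 0L)
  if (length(keep) == K) return(fit)
  gamma <- fit$gamma[, keep, drop = FALSE]
  fit$gamma <- gamma / rowSums(gamma)
  pi <- fit$params$pi[keep]
  fit$params <- mixture_params(fit$params$C[keep, , drop = FALSE],
                               pi / sum(pi),
                               fit$params$alpha, fit$params$beta)
  fit$assignments <- match(fit$assignments, keep)
  fit$Z <- fit$params$C[fit$assignments, , drop = FALSE]
  fit
}

#' Select the number of subclones
#'
#' Fits the mixture for K = 1, 2, 3, ... (each with the full restart / grid
#' protocol of [fit_em()], seeded deterministically from `(seed, K)`) and
#' scores each fit by inter-cluster-variance: how well the observed mean
#' inter-cluster distances agree with the distances expected from the
#' inferred genotypes under the empirical mismatch probabilities. The
#' search stops once the best score seen has not strictly improved for
#' `kappa` consecutive K values or K reaches `k_max`.
#'
#' For comparing models across K the selector hardens the plain pair score
#' of [model_score()] in two ways (see the methods vignette): gaps between
#' expected and observed distances are standardized by their sampling
#' error, with within-cluster self-consistency gaps included so that
#' under-split models cannot hide merged subclones, and all candidates are
#' re-scored with the error-rate estimates of the highest-likelihood fit,
#' because an under-split model absorbs subclonal structure into its own
#' inflated error-rate estimates and would otherwise self-calibrate. The
#' fit with the maximum anchored score is returned, ties going to the
#' smallest K. Components with no assigned cells are dropped from the
#' returned fit, so the reported K counts populated subclones only.
#'
#' @param gtm a `genotype_matrix`.
#' @param config an [em_config()].
#' @param kappa patience: consecutive non-improving K values before
#'   stopping (default 10).
#' @param k_max upper bound on K (default `min(N, 50)`).
#' @param seed optional integer master seed.
#' @param verbose print the per-K score trace.
#' @return the best `clonemix_fit`, with `score` set and a `k_trace`
#'   data.frame (K, log_likelihood, score) attached.
#' @export
select_k <- function(gtm, config = em_config(), kappa = 10L, k_max = NULL,
                     seed = NULL, verbose = FALSE) {
  stopifnot(inherits(gtm, "genotype_matrix"), kappa >= 1L)
  N <- nrow(gtm$values)
  if (is.null(k_max)) k_max <- min(N, 50L)
  k_max <- min(k_max, N)
  mismatch <- .pairwise_mismatch(gtm$values)
  child_seed <- function(K) {
    if (is.null(seed)) NULL else (as.integer(seed) + 7919L * K) %% 2147483647L
  }
  fits <- list()
  best_score <- -Inf
  stale <- 0L
  for (K in seq_len(k_max)) {
    fit <- fit_em(gtm, K, config, seed = child_seed(K))
    s <- if (K == 1L) 0 else {
      .selection_score(gtm, fit, mismatch,
                       c(fit$params$alpha, fit$params$beta))
    }
    fits[[K]] <- fit
    if (verbose) {
      message(sprintf("K = %d: logL = %.2f, s = %.6f", K,
                      fit$log_likelihood, s))
    }
    if (s > best_score + 1e-12) {
      best_score <- s
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    if (stale >= kappa) break
  }
  # anchor the mismatch probabilities at the most refined fit's rates and
  # re-score all candidates on that common footing
  logls <- vapply(fits, function(f) f$log_likelihood, numeric(1))
  ref <- fits[[which.max(logls)]]$params
  final_scores <- vapply(seq_along(fits), function(K) {
    if (K == 1L) 0 else .selection_score(gtm, fits[[K]], mismatch,
                                         c(ref$alpha, ref$beta))
  }, numeric(1))
  # parsimony rule on the plateau: scores rise steeply while clusters are
  # still merged and then fluctuate around a plateau of calibrated models;
  # take the smallest K that reaches 75% of the plateau maximum rather
  # than the argmax, which would pick plateau noise
  best_K <- which(final_scores >= 0.75 * max(final_scores))[1L]
  best_fit <- fits[[best_K]]
  best_fit$score <- final_scores[best_K]
  best_fit <- .prune_empty_clusters(best_fit)
  best_fit$k_trace <- data.frame(
    K = seq_along(fits),
    log_likelihood = logls,
    score = final_scores,
    s_K = vapply(seq_along(fits), function(K) {
      suppressMessages(model_score(gtm, fits[[K]], mismatch = mismatch))
    }, numeric(1)))
  best_fit
}
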