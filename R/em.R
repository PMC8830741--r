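# rate clamp keeping log() finite
.RATE_MIN <- 1e-6
.clamp_rate <- function(x) min(max(x, .RATE_MIN), 1 - .RATE_MIN)

# Indicator masks of the observed matrix: D1[i,j]=1 iff D_ij==1 observed,
# D0[i,j]=1 iff D_ij==0 observed; missing entries are 0 in both so they
# contribute factor 1 to the per-cell likelihood product.
.gtm_masks <- function(values) {
  N <- nrow(values)
  M <- ncol(values)
  D1 <- matrix(0, N, M)
  D1[which(values == 1L)] <- 1
  D0 <- matrix(0, N, M)
  D0[which(values == 0L)] <- 1
  list(D1 = D1, D0 = D0, r1 = rowSums(D1), r0 = rowSums(D0))
}

# N x K matrix of log p(D_i | C_k); tC is t(C)
.loglik_matrix <- function(masks, tC, alpha, beta) {
  S1 <- masks$D1 %*% tC
  S0 <- masks$D0 %*% tC
  S1 * log(1 - beta) + (masks$r1 - S1) * log(alpha) +
    S0 * log(beta) + (masks$r0 - S0) * log(1 - alpha)
}

# log-sum-exp E-step: responsibilities and total log-likelihood
.posterior <- function(L, pi) {
  K <- length(pi)
  A <- L + matrix(log(pi), nrow(L), K, byrow = TRUE)
  m <- A[, 1L]
  if (K > 1L) for (k in 2:K) m <- pmax(m, A[, k])
  W <- exp(A - m)
  s <- rowSums(W)
  list(gamma = W / s, loglik = sum(m + log(s)))
}

#' Log-probability of a single observed genotype entry
#'
#' The error model of the mixture: an observed 1 at a truly unmutated locus
#' is a false positive (rate `alpha`), an observed 0 at a mutated locus is a
#' false negative / allele dropout (rate `beta`). Missing observations carry
#' no information and return 0 (log of 1).
#'
#' @param d observed state: 0, 1 or `NA`; vectorized.
#' @param c true cluster state: 0 or 1; recycled against `d`.
#' @param alpha false-positive rate in (0, 1).
#' @param beta false-negative rate in (0, 1).
#' @return log p(d | c), elementwise.
#' @export
entry_log_prob <- function(d, c, alpha, beta) {
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1)
  cc <- rep_len(c, length(d))
  out <- numeric(length(d))
  obs <- !is.na(d)
  out[obs] <- ifelse(cc[obs] == 1,
                     ifelse(d[obs] == 1, log(1 - beta), log(beta)),
                     ifelse(d[obs] == 1, log(alpha), log(1 - alpha)))
  out
}

#' Log-likelihood of one cell's observed row under one cluster genotype
#'
#' Sum of [entry_log_prob()] over the observed loci; an all-missing row
#' scores 0.
#'
#' @param d_row length-M ternary observation (0/1/`NA`).
#' @param c_row length-M binary cluster genotype.
#' @inheritParams entry_log_prob
#' @export
cell_log_likelihood <- function(d_row, c_row, alpha, beta) {
  if (length(d_row) != length(c_row)) {
    stop("observed row and cluster genotype have different lengths")
  }
  sum(entry_log_prob(d_row, c_row, alpha, beta))
}

#' Parameters of the binary mixture model
#'
#' @param C K x M binary matrix of cluster (subclone) genotypes.
#' @param pi length-K mixture weights summing to 1.
#' @param alpha,beta false-positive and false-negative rates; clamped to
#'   `[1e-6, 1 - 1e-6]`.
#' @return an object of class `mixture_params`.
#' @export
mixture_params <- function(C, pi, alpha, beta) {
  C <- as.matrix(C)
  if (!all(C %in% c(0, 1))) stop("cluster genotypes must be binary")
  K <- nrow(C)
  if (length(pi) != K) stop("pi length must equal nrow(C)")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-10) {
    stop("mixture weights must be non-negative and sum to 1")
  }
  structure(list(C = C, pi = as.numeric(pi),
                 alpha = .clamp_rate(alpha), beta = .clamp_rate(beta),
                 K = K),
            class = "mixture_params")
}

#' Total observed-data log-likelihood of the mixture
#'
#' Computes `sum_i log sum_k pi_k p(D_i | C_k)` with log-sum-exp
#' stabilization.
#'
#' @param gtm a `genotype_matrix`.
#' @param params a `mixture_params`.
#' @export
total_log_likelihood <- function(gtm, params) {
  masks <- .gtm_masks(gtm$values)
  L <- .loglik_matrix(masks, t(params$C), params$alpha, params$beta)
  .posterior(L, params$pi)$loglik
}

#' E-step: posterior cluster responsibilities
#'
#' Returns the N x K matrix of posterior probabilities that cell i belongs
#' to cluster k under the current parameters; rows sum to 1.
#'
#' @inheritParams total_log_likelihood
#' @export
e_step <- function(gtm, params) {
  masks <- .gtm_masks(gtm$values)
  L <- .loglik_matrix(masks, t(params$C), params$alpha, params$beta)
  .posterior(L, params$pi)$gamma
}

#' M-step update of the cluster genotype matrix
#'
#' For each cluster/locus pair, picks the state maximizing the
#' responsibility-weighted expected log-likelihood over the cells whose
#' entry at that locus is observed. An exact tie is resolved to 0
#' (no mutation).
#'
#' @param gtm a `genotype_matrix`.
#' @param gamma N x K responsibility matrix (rows sum to 1).
#' @inheritParams entry_log_prob
#' @return K x M binary matrix.
#' @export
update_genotypes <- function(gtm, gamma, alpha, beta) {
  masks <- .gtm_masks(gtm$values)
  G1 <- crossprod(gamma, masks$D1)
  G0 <- crossprod(gamma, masks$D0)
  obj1 <- G1 * log(1 - beta) + G0 * log(beta)
  obj0 <- G1 * log(alpha) + G0 * log(1 - alpha)
  (obj1 > obj0) * 1
}

#' M-step update of the mixture weights
#'
#' @param gamma N x K responsibility matrix.
#' @return length-K weight vector summing to 1.
#' @export
update_pi <- function(gamma) {
  colMeans(gamma)
}

#' M-step update of the false-negative rate
#'
#' Responsibility-weighted fraction of observed 0-calls among entries whose
#' cluster genotype is 1. Missing entries are excluded from both sums. If no
#' cluster carries a mutation over observed data, the previous value is
#' retained with a warning.
#'
#' @inheritParams update_genotypes
#' @param C K x M binary cluster genotype matrix.
#' @param prev value returned when the denominator is zero.
#' @export
update_beta <- function(gtm, gamma, C, prev = NA_real_) {
  masks <- .gtm_masks(gtm$values)
  G1 <- crossprod(gamma, masks$D1)
  G0 <- crossprod(gamma, masks$D0)
  den <- sum(C * (G0 + G1))
  if (den <= 0) {
    warning("no observed entries under mutated cluster genotypes; beta not updated")
    return(prev)
  }
  .clamp_rate(sum(C * G0) / den)
}

#' M-step update of the false-positive rate
#'
#' Mirror image of [update_beta()]: responsibility-weighted fraction of
#' observed 1-calls among entries whose cluster genotype is 0.
#'
#' @inheritParams update_beta
#' @export
update_alpha <- function(gtm, gamma, C, prev = NA_real_) {
  masks <- .gtm_masks(gtm$values)
  G1 <- crossprod(gamma, masks$D1)
  G0 <- crossprod(gamma, masks$D0)
  den <- sum((1 - C) * (G0 + G1))
  if (den <= 0) {
    warning("no observed entries under unmutated cluster genotypes; alpha not updated")
    return(prev)
  }
  .clamp_rate(sum((1 - C) * G1) / den)
}

#' Initialize mixture parameters
#'
#' Uniform mixture weights, user-supplied starting error rates, and cluster
#' genotypes drawn as K distinct cell rows sampled without replacement from
#' the observed matrix (missing entries replaced by 0).
#'
#' @param gtm a `genotype_matrix`.
#' @param K number of clusters, `1 <= K <= N`.
#' @param beta0 starting false-negative rate.
#' @param alpha0 starting false-positive rate (default 0.01).
#' @param seed optional integer seed for the row sampling.
#' @return a `mixture_params`.
#' @export
init_params <- function(gtm, K, beta0 = 0.2, alpha0 = 0.01, seed = NULL) {
  N <- nrow(gtm$values)
  if (K < 1L || K > N) stop(sprintf("K must be between 1 and N = %d", N))
  if (!is.null(seed)) set.seed(seed)
  rows <- sample.int(N, K)
  C <- gtm$values[rows, , drop = FALSE]
  C[is.na(C)] <- 0L
  mixture_params(C, rep(1 / K, K), alpha0, beta0)
}

#' EM fitting configuration
#'
#' @param beta_grid starting values for the false-negative rate explored by
#'   grid search.
#' @param alpha0 starting false-positive rate.
#' @param fixed_alpha,fixed_beta if non-`NULL`, the rate is held at this
#'   value and never updated.
#' @param n_restarts number of random genotype initializations per
#'   (K, beta0) pair.
#' @param max_iter maximum EM iterations per run.
#' @param tol absolute log-likelihood change declaring convergence.
#' @export
em_config <- function(beta_grid = c(0.1, 0.2, 0.3, 0.4, 0.5), alpha0 = 0.01,
                      fixed_alpha = NULL, fixed_beta = NULL,
                      n_restarts = 10L, max_iter = 300L, tol = 1e-6) {
  stopifnot(all(beta_grid > 0 & beta_grid < 1), n_restarts >= 1L,
            max_iter >= 1L, tol > 0)
  structure(list(beta_grid = beta_grid, alpha0 = alpha0,
                 fixed_alpha = fixed_alpha, fixed_beta = fixed_beta,
                 n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "em_config")
}

# One EM run from a fixed initialization. Returns params, gamma,
# log-likelihood trace and the iterations where an empty cluster was
# re-seeded (monotonicity is suspended there).
.em_run <- function(masks, N, M, C, alpha, beta, config) {
  K <- nrow(C)
  pi <- rep(1 / K, K)
  free_alpha <- is.null(config$fixed_alpha)
  free_beta <- is.null(config$fixed_beta)
  ll_prev <- -Inf
  ll_trace <- numeric(0)
  reseed_iters <- integer(0)
  gamma <- NULL
  for (it in seq_len(config$max_iter)) {
    L <- .loglik_matrix(masks, t(C), alpha, beta)
    post <- .posterior(L, pi)
    gamma <- post$gamma
    ll_trace[it] <- post$loglik
    if (abs(post$loglik - ll_prev) < config$tol) break
    ll_prev <- post$loglik
    # M-step, coordinate order: C, beta, alpha, pi
    G1 <- crossprod(gamma, masks$D1)
    G0 <- crossprod(gamma, masks$D0)
    obj1 <- G1 * log(1 - beta) + G0 * log(beta)
    obj0 <- G1 * log(alpha) + G0 * log(1 - alpha)
    C <- (obj1 > obj0) * 1
    if (free_beta) {
      den <- sum(C * (G0 + G1))
      if (den > 0) beta <- .clamp_rate(sum(C * G0) / den)
    }
    if (free_alpha) {
      den <- sum((1 - C) * (G0 + G1))
      if (den > 0) alpha <- .clamp_rate(sum((1 - C) * G1) / den)
    }
    pi <- colMeans(gamma)
    # re-seed clusters whose weight collapsed
    dead <- which(pi < 1 / (10 * N))
    if (length(dead)) {
      for (k in dead) {
        row <- masks$D1[sample.int(N, 1L), ]
        C[k, ] <- row
      }
      pi[dead] <- 1 / N
      pi <- pi / sum(pi)
      reseed_iters <- c(reseed_iters, it)
    }
  }
  # final E-step so that gamma/loglik are consistent with returned params
  L <- .loglik_matrix(masks, t(C), alpha, beta)
  post <- .posterior(L, pi)
  list(C = C, pi = pi, alpha = alpha, beta = beta,
       gamma = post$gamma, loglik = post$loglik,
       n_iter = length(ll_trace), ll_trace = ll_trace,
       reseed_iters = reseed_iters)
}

#' Fit the binary mixture model for a fixed number of clusters
#'
#' Runs EM from `n_restarts` random genotype initializations for every
#' starting false-negative rate in the grid and keeps the run with the
#' highest final log-likelihood (ties broken by earliest run). User-fixed
#' error rates are honored by skipping their updates.
#'
#' @param gtm a `genotype_matrix`.
#' @param K number of clusters.
#' @param config an [em_config()].
#' @param seed optional integer seed; all randomness (initial genotype rows,
#'   empty-cluster re-seeds) flows from it.
#' @return an object of class `clonemix_fit` with elements `params`
#'   (`mixture_params`), `gamma` (N x K responsibilities), `assignments`
#'   (argmax posterior, 1-based), `Z` (N x M predicted genotypes),
#'   `log_likelihood`, `n_iter`, `ll_trace`, `reseed_iters`, `score`
#'   (filled by [select_k()]/[model_score()]), and the cell/locus ids.
#' @export
fit_em <- function(gtm, K, config = em_config(), seed = NULL) {
  stopifnot(inherits(gtm, "genotype_matrix"), K >= 1L)
  N <- nrow(gtm$values)
  M <- ncol(gtm$values)
  if (K > N) stop(sprintf("K must be between 1 and N = %d", N))
  if (!is.null(seed)) set.seed(seed)
  masks <- .gtm_masks(gtm$values)
  alpha0 <- if (is.null(config$fixed_alpha)) config$alpha0 else config$fixed_alpha
  grid <- if (is.null(config$fixed_beta)) config$beta_grid else config$fixed_beta
  best <- NULL
  for (beta0 in grid) {
    for (r in seq_len(config$n_restarts)) {
      rows <- sample.int(N, K)
      C0 <- masks$D1[rows, , drop = FALSE]  # missing entries already 0
      run <- .em_run(masks, N, M, C0, .clamp_rate(alpha0),
                     .clamp_rate(beta0), config)
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
  }
  assignments <- max.col(best$gamma, ties.method = "first")
  structure(
    list(params = mixture_params(best$C, best$pi, best$alpha, best$beta),
         gamma = best$gamma,
         assignments = assignments,
         Z = best$C[assignments, , drop = FALSE],
         log_likelihood = best$loglik,
         n_iter = best$n_iter,
         ll_trace = best$ll_trace,
         reseed_iters = best$reseed_iters,
         score = NULL,
         cell_ids = gtm$cell_ids,
         locus_ids = gtm$locus_ids),
    class = "clonemix_fit"
  )
}

#' @export
print.clonemix_fit <- function(x, ...) {
  cat(sprintf(
    "clonemix_fit: K = %d, alpha = %.4f, beta = %.4f, logL = %.2f%s\n",
    x$params$K, x$params$alpha, x$params$beta, x$log_likelihood,
    if (is.null(x$score)) "" else sprintf(", s_K = %.4f", x$score)))
  invisible(x)
}
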