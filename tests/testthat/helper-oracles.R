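# Independent brute-force oracles used to cross-check the vectorized
# implementation on small instances. These deliberately use naive loops /
# formulas structured differently from the package code.

# Eq-by-entry mixture log-likelihood via an explicit double loop
naive_total_loglik <- function(values, C, pi, alpha, beta) {
  total <- 0
  for (i in seq_len(nrow(values))) {
    comp <- numeric(length(pi))
    for (k in seq_along(pi)) {
      lp <- 0
      for (j in seq_len(ncol(values))) {
        d <- values[i, j]
        if (is.na(d)) next
        p <- if (C[k, j] == 1) {
          if (d == 1) 1 - beta else beta
        } else {
          if (d == 1) alpha else 1 - alpha
        }
        lp <- lp + log(p)
      }
      comp[k] <- pi[k] * exp(lp)
    }
    total <- total + log(sum(comp))
  }
  total
}

# V-measure recomputed directly from joint label frequencies
naive_v_measure <- function(truth, pred) {
  n <- length(truth)
  joint <- table(truth, pred) / n
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  hc <- ent(rowSums(joint))
  hk <- ent(colSums(joint))
  h_c_given_k <- 0
  for (k in seq_len(ncol(joint))) {
    pk <- sum(joint[, k])
    if (pk > 0) {
      cond <- joint[, k] / pk
      h_c_given_k <- h_c_given_k + pk * ent(cond)
    }
  }
  h_k_given_c <- 0
  for (cc in seq_len(nrow(joint))) {
    pc <- sum(joint[cc, ])
    if (pc > 0) {
      cond <- joint[cc, ] / pc
      h_k_given_c <- h_k_given_c + pc * ent(cond)
    }
  }
  h <- if (hc == 0) 1 else 1 - h_c_given_k / hc
  co <- if (hk == 0) 1 else 1 - h_k_given_c / hk
  if (h + co == 0) 0 else 2 * h * co / (h + co)
}

# ternary mismatch count between two rows; NA equals NA only
naive_row_mismatch <- function(a, b) {
  same <- (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  sum(!same)
}

# random point on the probability simplex
random_simplex <- function(K) {
  x <- rexp(K)
  x / sum(x)
}

# random small observed matrix (0/1/NA)
random_gtm <- function(N, M, p_missing = 0.15, p_one = 0.4) {
  vals <- matrix(sample(c(0L, 1L), N * M, replace = TRUE,
                        prob = c(1 - p_one, p_one)), N, M)
  vals[matrix(runif(N * M) < p_missing, N, M)] <- NA_integer_
  genotype_matrix(vals)
}

# Global maximum of the mixture log-likelihood over all binary cluster
# genotype matrices (fixed alpha/beta, mixture weights optimized per
# candidate by a vectorized weight-EM). Feasible for K <= 2, M <= 5.
exhaustive_best_loglik <- function(gtm, K, alpha, beta) {
  values <- gtm$values
  M <- ncol(values)
  rows <- as.matrix(expand.grid(rep(list(0:1), M)))
  # per-cell log-likelihood under every candidate genotype row
  D1 <- (!is.na(values) & values == 1L) * 1
  D0 <- (!is.na(values) & values == 0L) * 1
  Lrow <- D1 %*% t(rows) * log(1 - beta) +
    D1 %*% t(1 - rows) * log(alpha) +
    D0 %*% t(rows) * log(beta) +
    D0 %*% t(1 - rows) * log(1 - alpha)
  if (K == 1L) return(max(colSums(Lrow)))
  stopifnot(K == 2L)
  pr <- which(upper.tri(diag(nrow(rows)), diag = TRUE), arr.ind = TRUE)
  EA <- exp(Lrow[, pr[, 1L], drop = FALSE])
  EB <- exp(Lrow[, pr[, 2L], drop = FALSE])
  p <- rep(0.5, nrow(pr))
  for (it in 1:2000) {
    mixA <- sweep(EA, 2L, p, `*`)
    mix <- mixA + sweep(EB, 2L, 1 - p, `*`)
    p_new <- colMeans(mixA / mix)
    if (max(abs(p_new - p)) < 1e-13) {
      p <- p_new
      break
    }
    p <- p_new
  }
  mix <- sweep(EA, 2L, p, `*`) + sweep(EB, 2L, 1 - p, `*`)
  max(colSums(log(mix)))
}

# all spanning trees of the complete graph on n labelled nodes,
# enumerated through Pruefer sequences; returns minimum total weight
min_spanning_weight_exhaustive <- function(D) {
  n <- nrow(D)
  if (n == 2L) return(D[1L, 2L])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    pruefer <- seqs[r, ]
    degree <- rep(1L, n)
    for (v in pruefer) degree[v] <- degree[v] + 1L
    w <- 0
    avail <- pruefer
    for (v in avail) {
      leaf <- which(degree == 1L)[1L]
      w <- w + D[leaf, v]
      degree[leaf] <- degree[leaf] - 1L
      degree[v] <- degree[v] - 1L
    }
    left <- which(degree == 1L)
    w <- w + D[left[1L], left[2L]]
    best <- min(best, w)
  }
  best
}
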