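test_that("entry_log_prob implements the error model and skips missing entries", {
  a <- 0.01
  b <- 0.2
  expect_equal(entry_log_prob(1, 0, a, b), log(a))
  expect_equal(entry_log_prob(0, 1, a, b), log(b))
  expect_equal(entry_log_prob(1, 1, a, b), log(1 - b))
  expect_equal(entry_log_prob(0, 0, a, b), log(1 - a))
  expect_equal(entry_log_prob(NA, 1, a, b), 0)
  expect_equal(entry_log_prob(NA, 0, 0.3, 0.4), 0)
})

test_that("cell_log_likelihood sums per-locus terms over observed loci", {
  expect_equal(cell_log_likelihood(c(1, 0), c(1, 1), 0.01, 0.2),
               log(0.8) + log(0.2))
  expect_equal(cell_log_likelihood(c(NA, NA), c(1, 0), 0.01, 0.2), 0)
  # perfect match, vanishing error rates -> log-likelihood approaches 0
  expect_equal(cell_log_likelihood(c(1, 1), c(1, 1), 1e-12, 1e-12), 0,
               tolerance = 1e-10)
  expect_error(cell_log_likelihood(c(1, 0, 1), c(1, 1), 0.01, 0.2),
               "lengths")
})

test_that("total_log_likelihood matches the naive double-loop oracle", {
  set.seed(42)
  for (rep in 1:10) {
    N <- sample(2:6, 1)
    M <- sample(2:5, 1)
    K <- sample(1:3, 1)
    g <- random_gtm(N, M)
    C <- matrix(sample(0:1, K * M, replace = TRUE), K, M)
    pi <- random_simplex(K)
    params <- mixture_params(C, pi, 0.05, 0.25)
    expect_equal(total_log_likelihood(g, params),
                 naive_total_loglik(g$values, C, pi, 0.05, 0.25),
                 tolerance = 1e-10)
  }
})

test_that("total_log_likelihood is invariant to splitting a component in two", {
  set.seed(1)
  g <- random_gtm(5, 4)
  C <- matrix(sample(0:1, 8, replace = TRUE), 2, 4)
  p1 <- mixture_params(C, c(0.6, 0.4), 0.02, 0.3)
  p2 <- mixture_params(C[c(1, 1, 2), ], c(0.3, 0.3, 0.4), 0.02, 0.3)
  expect_equal(total_log_likelihood(g, p1), total_log_likelihood(g, p2),
               tolerance = 1e-10)
  # K = 1 reduces to the sum of per-cell log-likelihoods
  pk1 <- mixture_params(C[1, , drop = FALSE], 1, 0.02, 0.3)
  expect_equal(total_log_likelihood(g, pk1),
               sum(apply(g$values, 1, cell_log_likelihood, C[1, ], 0.02, 0.3)))
})

test_that("e_step produces normalized posteriors matching direct arithmetic", {
  g <- genotype_matrix(matrix(c(1L, 0L, 1L, 1L), 2, 2))
  # identical components: posterior equals the prior for every cell
  p_same <- mixture_params(rbind(c(1, 0), c(1, 0)), c(0.3, 0.7), 0.1, 0.2)
  gam <- e_step(g, p_same)
  expect_equal(gam, matrix(c(0.3, 0.3, 0.7, 0.7), 2, 2))

  p1 <- mixture_params(matrix(c(1, 0), 1, 2), 1, 0.1, 0.2)
  expect_equal(e_step(g, p1), matrix(1, 2, 1))

  # hand-computed two-cell, two-cluster instance
  C <- rbind(c(1, 1), c(0, 0))
  pm <- mixture_params(C, c(0.5, 0.5), 0.1, 0.2)
  gam <- e_step(g, pm)
  num <- function(d, crow) exp(cell_log_likelihood(d, crow, 0.1, 0.2))
  for (i in 1:2) {
    w <- c(0.5 * num(g$values[i, ], C[1, ]), 0.5 * num(g$values[i, ], C[2, ]))
    expect_equal(gam[i, ], w / sum(w), tolerance = 1e-12)
  }
  expect_equal(rowSums(gam), c(1, 1), tolerance = 1e-12)
})

test_that("update_genotypes maximizes the weighted objective with ties to 0", {
  # unanimous evidence: all cells observed 1 -> genotype 1
  g <- genotype_matrix(matrix(1L, 4, 2))
  gam <- matrix(1, 4, 1)
  expect_equal(update_genotypes(g, gam, 0.01, 0.2), matrix(1, 1, 2))
  # fully missing column gives an exact tie -> 0
  g2 <- genotype_matrix(matrix(c(1L, 1L, NA, NA), 2, 2))
  expect_equal(update_genotypes(g2, matrix(1, 2, 1), 0.01, 0.2),
               matrix(c(1, 0), 1, 2))
  # soft responsibilities: compare against exhaustive evaluation of both states
  set.seed(5)
  g3 <- random_gtm(4, 3)
  gam3 <- matrix(runif(8), 4, 2)
  gam3 <- gam3 / rowSums(gam3)
  C <- update_genotypes(g3, gam3, 0.05, 0.3)
  for (k in 1:2) {
    for (j in 1:3) {
      obj <- sapply(c(0, 1), function(s) {
        sum(gam3[, k] * entry_log_prob(g3$values[, j], s, 0.05, 0.3))
      })
      expect_equal(C[k, j], if (obj[2] > obj[1]) 1 else 0)
    }
  }
})

test_that("update_pi averages responsibilities", {
  gam <- matrix(0, 4, 2)
  gam[cbind(1:4, c(1, 1, 1, 2))] <- 1
  expect_equal(update_pi(gam), c(0.75, 0.25))
  expect_equal(update_pi(matrix(0.5, 6, 2)), c(0.5, 0.5))
  set.seed(2)
  g <- matrix(runif(12), 4, 3)
  g <- g / rowSums(g)
  expect_equal(sum(update_pi(g)), 1)
})

test_that("update_beta and update_alpha are counting estimators over observed entries", {
  # 10 observed entries under an all-ones genotype, 3 of them zero -> 0.3
  vals <- matrix(c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, NA, NA), 3, 4)
  g <- genotype_matrix(vals)
  gam <- matrix(1, 3, 1)
  C1 <- matrix(1, 1, 4)
  expect_equal(update_beta(g, gam, C1), 0.3)
  # noise-free data hits the clamp floor
  gperf <- genotype_matrix(matrix(1L, 2, 3))
  expect_equal(update_beta(gperf, matrix(1, 2, 1), matrix(1, 1, 3)), 1e-6)
  # degenerate denominator keeps the previous value and warns
  expect_warning(
    out <- update_beta(g, gam, matrix(0, 1, 4), prev = 0.17),
    "not updated")
  expect_equal(out, 0.17)

  # alpha: 1 one among 20 observed entries under all-zero genotypes -> 0.05
  vals2 <- matrix(0L, 4, 5)
  vals2[2, 3] <- 1L
  g2 <- genotype_matrix(vals2)
  expect_equal(update_alpha(g2, matrix(1, 4, 1), matrix(0, 1, 5)), 0.05)
  expect_warning(
    outa <- update_alpha(g2, matrix(1, 4, 1), matrix(1, 1, 5), prev = 0.02),
    "not updated")
  expect_equal(outa, 0.02)
})

test_that("init_params follows the initialization scheme", {
  set.seed(9)
  g <- random_gtm(10, 6)
  p <- init_params(g, 4, beta0 = 0.3, seed = 11)
  expect_equal(p$pi, rep(0.25, 4))
  expect_equal(p$alpha, 0.01)
  expect_equal(p$beta, 0.3)
  expect_false(anyNA(p$C))
  p2 <- init_params(g, 4, beta0 = 0.3, seed = 11)
  expect_identical(p$C, p2$C)
  expect_error(init_params(g, 11), "between 1 and N")
})

test_that("fit_em recovers well-separated clusters from clean data", {
  set.seed(21)
  truth <- simulate_dataset(sim_config(45, 12, 3, alpha = 0, beta = 0,
                                       eta = 0, rho = 0, seed = 21))
  fit <- fit_em(truth$D, 3, em_config(n_restarts = 4, beta_grid = 0.2),
                seed = 5)
  expect_equal(v_measure(truth$cell_clone, fit$assignments), 1)
  expect_equal(fit$Z, truth$Z_star, ignore_attr = TRUE)
})

test_that("log-likelihood is monotone within EM runs", {
  set.seed(33)
  for (s in 1:4) {
    truth <- simulate_dataset(sim_config(40, 10, 3, seed = 33 + s))
    fit <- fit_em(truth$D, 3, em_config(n_restarts = 2, beta_grid = c(0.2, 0.4)),
                  seed = s)
    ok <- diff(fit$ll_trace) >= -1e-8
    # iterations right after an empty-cluster re-seed may dip
    ok[fit$reseed_iters[fit$reseed_iters < length(fit$ll_trace)]] <- TRUE
    expect_true(all(ok))
  }
})

test_that("likelihood and predictions are invariant to cluster relabeling", {
  set.seed(8)
  g <- random_gtm(12, 5)
  fit <- fit_em(g, 3, em_config(n_restarts = 3, beta_grid = 0.2), seed = 2)
  perm <- c(3, 1, 2)
  permuted <- mixture_params(fit$params$C[perm, ], fit$params$pi[perm],
                             fit$params$alpha, fit$params$beta)
  expect_equal(total_log_likelihood(g, permuted), fit$log_likelihood,
               tolerance = 1e-9)
  gam <- e_step(g, permuted)
  Z_perm <- permuted$C[max.col(gam, ties.method = "first"), ]
  expect_equal(Z_perm, fit$Z, ignore_attr = TRUE)
})

test_that("fixed error rates are honored", {
  set.seed(14)
  truth <- simulate_dataset(sim_config(30, 8, 2, seed = 14))
  fit <- fit_em(truth$D, 2,
                em_config(fixed_alpha = 0.01, fixed_beta = 0.2,
                          n_restarts = 2),
                seed = 1)
  expect_equal(fit$params$alpha, 0.01)
  expect_equal(fit$params$beta, 0.2)
})

test_that("fit_em attains the exhaustively enumerated optimum on a tiny instance", {
  set.seed(50)
  g <- random_gtm(6, 4)
  fit <- fit_em(g, 2, em_config(fixed_alpha = 0.1, fixed_beta = 0.2,
                                n_restarts = 10, tol = 1e-10, max_iter = 500),
                seed = 3)
  best <- exhaustive_best_loglik(g, 2L, 0.1, 0.2)
  expect_equal(fit$log_likelihood, best, tolerance = 1e-6)
})

test_that("error rates and clustering are recovered on simulated data", {
  # moderately sized design: 200 cells, 100 loci, 5 subclones, no doublets
  cfg <- em_config()
  hits_beta <- 0
  hits_v <- 0
  for (s in 1:10) {
    truth <- simulate_dataset(sim_config(200, 100, 5, alpha = 0.01,
                                         beta = 0.2, eta = 0.2, rho = 0,
                                         seed = 600 + s))
    fit <- fit_em(truth$D, 5, cfg, seed = s)
    keep <- seq_len(200)
    if (abs(fit$params$beta - 0.2) <= 0.05) hits_beta <- hits_beta + 1
    if (v_measure(truth$cell_clone, fit$assignments) >= 0.95) hits_v <- hits_v + 1
  }
  expect_gte(hits_beta, 9)
  expect_gte(hits_v, 9)
})
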