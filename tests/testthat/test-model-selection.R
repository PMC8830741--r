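test_that("mismatch_probs matches direct substitution and boundary identities", {
  # noiseless, complete data: equal true states never differ, unequal always do
  expect_equal(mismatch_probs(0, 0, 0),
               c(p00 = 0, p01 = 1, p10 = 1, p11 = 0))
  # fully missing data: the (1 - eta) factors vanish
  expect_equal(mismatch_probs(0.3, 0.4, 1),
               c(p00 = 0, p01 = 0, p10 = 0, p11 = 0))
  # generic values against an independently written substitution
  a <- 0.01
  b <- 0.2
  e <- 0.2
  p <- mismatch_probs(a, b, e)
  both_obs <- (1 - e)^2
  one_miss <- 2 * e * (1 - e)
  expect_equal(p[["p00"]], (a * (1 - a) + (1 - a) * a) * both_obs + one_miss)
  expect_equal(p[["p11"]], (b * (1 - b) + (1 - b) * b) * both_obs + one_miss)
  expect_equal(p[["p01"]],
               ((1 - a) * (1 - b) + a * b) * both_obs + one_miss)
  expect_equal(p[["p10"]], p[["p01"]])
})

test_that("distinct true states mismatch at least as often as equal ones", {
  set.seed(77)
  for (rep in 1:20) {
    a <- runif(1, 0, 0.49)
    b <- runif(1, 0, 0.49)
    e <- runif(1, 0, 1)
    p <- mismatch_probs(a, b, e)
    expect_gte(p[["p01"]], p[["p00"]])
    expect_gte(p[["p01"]], p[["p11"]])
  }
})

test_that("expected_distance counts state pairs correctly", {
  p <- mismatch_probs(0.05, 0.3, 0.1)
  expect_equal(expected_distance(rep(0, 7), rep(0, 7), p), 7 * p[["p00"]])
  expect_equal(expected_distance(c(0, 1), c(1, 1), p),
               p[["p10"]] + p[["p11"]])
  set.seed(4)
  ci <- sample(0:1, 10, replace = TRUE)
  ck <- sample(0:1, 10, replace = TRUE)
  loop <- sum(sapply(1:10, function(j) {
    p[[sprintf("p%d%d", ci[j], ck[j])]]
  }))
  expect_equal(expected_distance(ci, ck, p), loop)
  expect_error(expected_distance(c(0, 1), c(1, 1, 0), p), "lengths")
})

test_that("observed_mean_distance uses the ternary missing-state convention", {
  g <- genotype_matrix(rbind(c(1L, NA), c(1L, NA), c(1L, 0L)))
  expect_equal(observed_mean_distance(g, 1, 2), 0)
  expect_equal(observed_mean_distance(g, 1, 3), 1)
  set.seed(12)
  g2 <- random_gtm(5, 8)
  ci <- 1:3
  ck <- 4:5
  brute <- mean(outer(ci, ck, Vectorize(function(a, b) {
    naive_row_mismatch(g2$values[a, ], g2$values[b, ])
  })))
  expect_equal(observed_mean_distance(g2, ci, ck), brute)
  expect_error(observed_mean_distance(g2, integer(0), 1:2), "empty")
  expect_error(observed_mean_distance(g2, 1:3, 3:4), "disjoint")
})

test_that("pair_score is a unit-peak Gaussian in the distance gap", {
  expect_equal(pair_score(12.3, 12.3), 1)
  expect_equal(pair_score(5, 4), exp(-1))
  expect_equal(pair_score(0, 10), exp(-100))
})

test_that("model_score averages pair scores and handles degenerate fits", {
  set.seed(31)
  truth <- simulate_dataset(sim_config(60, 20, 3, rho = 0, seed = 31))
  g <- truth$D
  fit <- fit_em(g, 3, em_config(n_restarts = 3, beta_grid = 0.2), seed = 2)
  s <- model_score(g, fit, detail = TRUE)
  tab <- attr(s, "table")
  expect_equal(tab$s, t(tab$s))
  direct <- mean(c(tab$s[1, 2], tab$s[1, 3], tab$s[2, 3]))
  expect_equal(as.numeric(s), direct)
  # K = 2: the score is the single pair score
  fit2 <- fit_em(g, 2, em_config(n_restarts = 3, beta_grid = 0.2), seed = 2)
  s2 <- model_score(g, fit2, detail = TRUE)
  expect_equal(as.numeric(s2), attr(s2, "table")$s[1, 2])
  # K = 1 scores 0 by convention
  fit1 <- fit_em(g, 1, em_config(n_restarts = 1, beta_grid = 0.2), seed = 1)
  expect_equal(model_score(g, fit1), 0)
  # pair scores are probabilities-like
  expect_true(all(tab$s >= 0 & tab$s <= 1))
})

test_that("noise-free, perfectly recovered structure scores s_K = 1", {
  set.seed(19)
  truth <- simulate_dataset(sim_config(40, 12, 3, alpha = 0, beta = 0,
                                       eta = 0, rho = 0, seed = 19))
  fit <- fit_em(truth$D, 3, em_config(n_restarts = 4, beta_grid = 0.2),
                seed = 7)
  # with alpha*, beta* at the clamp floor and eta = 0, the expected distance
  # reduces to the Hamming distance between cluster genotypes
  s <- model_score(truth$D, fit, detail = TRUE)
  tab <- attr(s, "table")
  expect_equal(as.numeric(s), 1, tolerance = 1e-3)
  H <- as.matrix(dist(fit$params$C, method = "manhattan"))
  expect_equal(tab$d_expected, H, tolerance = 1e-2, ignore_attr = TRUE)
  expect_equal(tab$d_observed, H, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("select_k keeps a homogeneous model for homogeneous data", {
  # identical cells, no noise: no K >= 2 produces two populated clusters
  vals <- matrix(rep(c(1L, 0L, 1L, 0L, 0L, 1L), each = 30), nrow = 30)
  g <- genotype_matrix(vals)
  fit <- select_k(g, em_config(n_restarts = 2, beta_grid = 0.2), kappa = 3,
                  seed = 1)
  expect_equal(fit$params$K, 1L)
})

test_that("select_k recovers the number of well separated subclones", {
  set.seed(87)
  truth <- simulate_dataset(sim_config(60, 18, 3, alpha = 0, beta = 0,
                                       eta = 0, rho = 0, seed = 87))
  fit <- select_k(truth$D, em_config(n_restarts = 4, beta_grid = 0.2),
                  kappa = 4, seed = 6)
  expect_equal(fit$params$K, 3L)
  expect_equal(evaluate_fit(fit, truth)$v_measure, 1)
  expect_equal(fit$k_trace$K, seq_len(nrow(fit$k_trace)))
})
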