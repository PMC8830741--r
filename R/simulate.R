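#' Simulation configuration
#'
#' Bundles the controlling factors of a simulated single-cell SNV dataset:
#' numbers of cells, mutations and subclones, the three noise rates and the
#' doublet rate.
#'
#' @param N number of cells.
#' @param M number of mutations (loci).
#' @param K number of subclones (non-root tree nodes).
#' @param alpha false-positive rate applied to observed entries.
#' @param beta false-negative rate (allele dropout) applied to observed
#'   entries.
#' @param eta missing rate: probability an entry is unobserved.
#' @param rho doublet rate: fraction of cells merged with another cell's
#'   genotype.
#' @param seed integer seed making the dataset reproducible.
#' @param assign_root if `TRUE`, cells may also occupy the mutation-free
#'   root (normal-cell simulation); default `FALSE`.
#' @export
sim_config <- function(N, M, K, alpha = 0.01, beta = 0.2, eta = 0.2,
                       rho = 0.1, seed = NULL, assign_root = FALSE) {
  stopifnot(N >= 1L, M >= 1L, K >= 1L,
            alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            eta >= 0, eta <= 1, rho >= 0, rho <= 1)
  if (K > M) warning("more subclones than mutations: some subclones may share genotypes")
  structure(list(N = as.integer(N), M = as.integer(M), K = as.integer(K),
                 alpha = alpha, beta = beta, eta = eta, rho = rho,
                 seed = seed, assign_root = isTRUE(assign_root)),
            class = "sim_config")
}

#' Preset simulation designs
#'
#' Factories for the seven benchmark designs: D1/D2 are 500 x 200 matrices
#' with 10 subclones sweeping the false-negative rate (D1) or missing rate
#' (D2); D3 is 1000 x 500 with beta = 0.8; D4 sweeps K in 1000 x 500
#' matrices; D5 sweeps N at M = 200, K = 15; D6 is the small 200 x 50,
#' K = 5 design; D7 draws alpha ~ U(0.01, 0.1) and beta ~ U(0.05, 0.4) on
#' 100 x 100, K = 5 matrices for error-rate estimation experiments.
#' Unswept factors keep the defaults (alpha 0.01, beta 0.2, eta 0.2,
#' rho 0.1).
#'
#' @param name one of `"D1" ... "D7"`.
#' @param seed integer seed (also drives the D7 rate draw).
#' @param beta,eta,K,N value of the swept factor where the design sweeps
#'   one.
#' @return a [sim_config()].
#' @export
sim_preset <- function(name, seed = NULL, beta = NULL, eta = NULL,
                       K = NULL, N = NULL) {
  pick <- function(x, default) if (is.null(x)) default else x
  switch(
    name,
    D1 = sim_config(500L, 200L, 10L, beta = pick(beta, 0.2), seed = seed),
    D2 = sim_config(500L, 200L, 10L, eta = pick(eta, 0.2), seed = seed),
    D3 = sim_config(1000L, 500L, 10L, beta = 0.8, seed = seed),
    D4 = sim_config(1000L, 500L, pick(K, 20L), beta = 0.3, seed = seed),
    D5 = sim_config(pick(N, 500L), 200L, 15L, beta = 0.3, seed = seed),
    D6 = sim_config(200L, 50L, 5L, seed = seed),
    D7 = {
      if (!is.null(seed)) set.seed(seed)
      sim_config(100L, 100L, 5L,
                 alpha = stats::runif(1, 0.01, 0.1),
                 beta = stats::runif(1, 0.05, 0.4),
                 seed = seed)
    },
    stop(sprintf("unknown preset '%s' (expected D1..D7)", name))
  )
}

#' Sample a random subclonal tree
#'
#' The tree starts with the root and its first child; each further subclone
#' attaches to a uniformly chosen existing non-root node. Uses the current
#' RNG state.
#'
#' @param K number of subclones.
#' @return integer parent vector of length K; `parent[1] == 0` (the root),
#'   and `parent[k] < k` for all k.
#' @export
sample_tree <- function(K) {
  stopifnot(K >= 1L)
  parent <- integer(K)
  parent[1L] <- 0L
  if (K >= 2L) {
    for (k in 2:K) parent[k] <- sample.int(k - 1L, 1L)
  }
  parent
}

#' Assign mutations to tree edges
#'
#' Each mutation is independently placed on one of the K edges (the edge
#' above each non-root node) with uniform probability, honoring the
#' infinite sites model: each mutation occurs on exactly one edge.
#'
#' @param parent parent vector from [sample_tree()].
#' @param M number of mutations.
#' @return list of length K; element k holds the mutation indices on the
#'   edge above node k.
#' @export
assign_mutations <- function(parent, M) {
  K <- length(parent)
  edge_of <- sample.int(K, M, replace = TRUE)
  lapply(seq_len(K), function(k) which(edge_of == k))
}

#' Assign cells to subclones with size-proportional probability
#'
#' Preferential attachment: every eligible subclone starts with pseudo-size
#' 1 and each cell joins a subclone with probability proportional to its
#' current size, yielding right-skewed (differently sized) subclones. Any
#' subclone left empty afterwards receives one cell reassigned from a
#' subclone with at least two, so that every truth label is populated.
#'
#' @param K number of subclones.
#' @param N number of cells.
#' @param assign_root if `TRUE` the mutation-free root (label 0) is also
#'   eligible.
#' @return integer vector of length N with values in `1..K` (or `0..K`
#'   when `assign_root`).
#' @export
assign_cells <- function(K, N, assign_root = FALSE) {
  labels <- if (assign_root) 0:K else seq_len(K)
  if (N < length(labels)) {
    stop(sprintf("need at least %d cells to populate every subclone", length(labels)))
  }
  sizes <- rep(1, length(labels))
  clone <- integer(N)
  for (i in seq_len(N)) {
    pick <- sample.int(length(labels), 1L, prob = sizes)
    clone[i] <- labels[pick]
    sizes[pick] <- sizes[pick] + 1
  }
  counts <- table(factor(clone, levels = labels))
  for (l in which(counts == 0L)) {
    donor_cells <- which(clone %in% labels[counts >= 2L])
    take <- donor_cells[sample.int(length(donor_cells), 1L)]
    counts[as.character(clone[take])] <- counts[as.character(clone[take])] - 1L
    clone[take] <- labels[l]
    counts[l] <- 1L
  }
  clone
}

#' True genotypes from the clonal tree
#'
#' A cell carries exactly the mutations on the edges of the path from the
#' root to its subclone.
#'
#' @param parent parent vector.
#' @param edge_mutations list from [assign_mutations()].
#' @param cell_clone subclone label per cell (0 = root).
#' @param M number of mutations.
#' @return N x M binary matrix.
#' @export
true_genotypes <- function(parent, edge_mutations, cell_clone, M) {
  K <- length(parent)
  nodeC <- matrix(0L, K + 1L, M)  # row 1 = root
  for (k in seq_len(K)) {
    nodeC[k + 1L, ] <- nodeC[parent[k] + 1L, ]
    nodeC[k + 1L, edge_mutations[[k]]] <- 1L
  }
  nodeC[cell_clone + 1L, , drop = FALSE]
}

#' Inject doublets into a true genotype matrix
#'
#' `round(rho * N)` distinct cells are chosen uniformly; each one's genotype
#' row is replaced by the elementwise OR of its own row and the row of a
#' uniformly chosen different cell (noise is applied afterwards by
#' [add_noise()]).
#'
#' @param Z_star N x M binary true genotype matrix.
#' @param rho doublet rate.
#' @return list with `Z` (modified matrix) and `doublet_indices`.
#' @export
inject_doublets <- function(Z_star, rho) {
  N <- nrow(Z_star)
  nd <- round(rho * N)
  if (nd == 0L) return(list(Z = Z_star, doublet_indices = integer(0)))
  idx <- sort(sample.int(N, nd))
  Z <- Z_star
  for (i in idx) {
    partner <- sample.int(N - 1L, 1L)
    if (partner >= i) partner <- partner + 1L
    Z[i, ] <- pmax(Z_star[i, ], Z_star[partner, ])
  }
  list(Z = Z, doublet_indices = idx)
}

#' Apply observation noise to a binary genotype matrix
#'
#' Independently per entry: with probability `eta` the entry becomes
#' missing (`NA`); otherwise a 0 flips to 1 with probability `alpha` and a
#' 1 flips to 0 with probability `beta`.
#'
#' @param Z binary matrix.
#' @param alpha,beta,eta noise rates.
#' @return integer matrix with entries 0/1/`NA`.
#' @export
add_noise <- function(Z, alpha, beta, eta) {
  N <- nrow(Z)
  M <- ncol(Z)
  D <- Z
  u_miss <- matrix(stats::runif(N * M), N, M)
  u_flip <- matrix(stats::runif(N * M), N, M)
  flip <- (Z == 1L & u_flip < beta) | (Z == 0L & u_flip < alpha)
  D[flip] <- 1L - Z[flip]
  D[u_miss < eta] <- NA_integer_
  storage.mode(D) <- "integer"
  D
}

#' Simulate a ground-truthed noisy genotype matrix
#'
#' Composes the generative steps in order: random subclonal tree, uniform
#' mutation placement on edges (infinite sites), size-proportional cell
#' assignment, path-derived true genotypes, doublet OR-merging, and
#' entrywise FP/FN/missing noise. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()] or [sim_preset()].
#' @return an object of class `sim_truth`: `config`, `parent`,
#'   `edge_mutations`, `cell_clone`, `Z_star` (pure tree-derived true
#'   genotypes), `doublet_indices`, and `D` (the observed
#'   `genotype_matrix`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  parent <- sample_tree(config$K)
  edge_mutations <- assign_mutations(parent, config$M)
  cell_clone <- assign_cells(config$K, config$N,
                             assign_root = config$assign_root)
  Z_star <- true_genotypes(parent, edge_mutations, cell_clone, config$M)
  dbl <- inject_doublets(Z_star, config$rho)
  D_vals <- add_noise(dbl$Z, config$alpha, config$beta, config$eta)
  structure(
    list(config = config,
         parent = parent,
         edge_mutations = edge_mutations,
         cell_clone = cell_clone,
         Z_star = Z_star,
         doublet_indices = dbl$doublet_indices,
         D = genotype_matrix(D_vals)),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "sim_truth: %d cells x %d loci, K = %d, alpha = %.3f, beta = %.3f, eta = %.3f, %d doublets\n",
    x$config$N, x$config$M, x$config$K, x$config$alpha, x$config$beta,
    x$config$eta, length(x$doublet_indices)))
  invisible(x)
}
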