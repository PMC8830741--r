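#' Build the subclone lineage tree as a minimum spanning tree
#'
#' Constructs the complete graph over the inferred subclone genotypes
#' (optionally plus a mutation-free root) with Hamming-distance edge
#' weights, and extracts a minimum spanning tree with Prim's algorithm and
#' deterministic lexicographic tie-breaking. With the root included, the
#' tree is rooted there for display and export.
#'
#' @param C K x M binary subclone genotype matrix.
#' @param include_root add an all-zero (diploid/normal) root node
#'   (default `TRUE`).
#' @return an object of class `lineage_tree`: `genotypes` (node x M),
#'   `labels`, `edges` (data.frame from/to/weight), and `parent` (parent
#'   index per node, 0 for the tree root).
#' @export
build_mst <- function(C, include_root = TRUE) {
  C <- as.matrix(C)
  if (!all(C %in% c(0, 1))) stop("subclone genotypes must be binary")
  K <- nrow(C)
  G <- if (include_root) rbind(0, C) else C
  labels <- if (include_root) {
    c("root", paste0("subclone_", seq_len(K)))
  } else {
    paste0("subclone_", seq_len(K))
  }
  n <- nrow(G)
  # pairwise Hamming distances
  ones <- G %*% t(G)
  r <- rowSums(G)
  D <- outer(r, r, "+") - 2 * ones
  in_tree <- rep(FALSE, n)
  in_tree[1L] <- TRUE
  best_w <- D[1L, ]
  best_from <- rep(1L, n)
  parent <- integer(n)
  edges <- NULL
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_w[cand])]  # first index wins ties
    parent[v] <- best_from[v]
    edges <- rbind(edges, data.frame(from = best_from[v], to = v,
                                     weight = best_w[v]))
    in_tree[v] <- TRUE
    upd <- !in_tree & D[v, ] < best_w  # strict <: earlier attachment kept
    best_w[upd] <- D[v, upd]
    best_from[upd] <- v
  }
  structure(list(genotypes = G, labels = labels,
                 edges = if (is.null(edges)) {
                   data.frame(from = integer(0), to = integer(0),
                              weight = numeric(0))
                 } else edges,
                 parent = parent),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("lineage_tree: %d nodes, total MST weight %g\n",
              length(x$labels), sum(x$edges$weight)))
  for (i in seq_len(nrow(x$edges))) {
    cat(sprintf("  %s -> %s (d = %g)\n", x$labels[x$edges$from[i]],
                x$labels[x$edges$to[i]], x$edges$weight[i]))
  }
  invisible(x)
}

#' Export a lineage tree in Newick format
#'
#' Branch lengths are the MST edge weights (genotype distances); optional
#' subclone sizes are appended to the node labels.
#'
#' @param tree a `lineage_tree`.
#' @param sizes optional integer vector of cells per node (same order as
#'   `tree$labels`).
#' @return single-element character vector (Newick string with trailing
#'   semicolon).
#' @export
lineage_newick <- function(tree, sizes = NULL) {
  stopifnot(inherits(tree, "lineage_tree"))
  lab <- tree$labels
  if (!is.null(sizes)) lab <- sprintf("%s_n%d", lab, as.integer(sizes))
  children <- split(seq_along(tree$parent), tree$parent)
  wt <- numeric(length(tree$parent))
  wt[tree$edges$to] <- tree$edges$weight
  rec <- function(v) {
    kids <- children[[as.character(v)]]
    node <- if (is.null(kids)) {
      lab[v]
    } else {
      sprintf("(%s)%s", paste(vapply(kids, rec, character(1)),
                              collapse = ","), lab[v])
    }
    if (tree$parent[v] == 0L) node else sprintf("%s:%g", node, wt[v])
  }
  root <- which(tree$parent == 0L)[1L]
  paste0(rec(root), ";")
}
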