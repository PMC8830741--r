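#' Run the full clustering pipeline on a genotype matrix file
#'
#' Reads the observed matrix, runs model selection (or a fixed-K fit),
#' and writes all artifacts: assignments, subclone genotypes, predicted
#' genotype matrix, summary, per-K score trace and the MST lineage tree
#' (edge list and Newick).
#'
#' @param input path to a delimited genotype matrix file, or a
#'   `genotype_matrix`.
#' @param out_dir output directory (created if absent).
#' @param k if given, fit exactly this number of clusters and skip
#'   selection.
#' @param kappa selection patience (default 10).
#' @param k_max upper bound on K during selection.
#' @param config an [em_config()]; `fixed_alpha` / `fixed_beta` there pin
#'   the error rates.
#' @param seed integer master seed.
#' @param missing_code,delimiter,has_header,cells_as_rows passed to
#'   [read_gtm()] when `input` is a path.
#' @param verbose log the per-K score trace.
#' @return the final `clonemix_fit`, invisibly.
#' @export
run_cluster <- function(input, out_dir, k = NULL, kappa = 10L, k_max = NULL,
                        config = em_config(), seed = NULL,
                        missing_code = 3L, delimiter = NULL,
                        has_header = FALSE, cells_as_rows = TRUE,
                        verbose = FALSE) {
  gtm <- if (inherits(input, "genotype_matrix")) {
    input
  } else {
    read_gtm(input, missing_code = missing_code, delimiter = delimiter,
             has_header = has_header, cells_as_rows = cells_as_rows)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(k)) {
    fit <- select_k(gtm, config = config, kappa = kappa, k_max = k_max,
                    seed = seed, verbose = verbose)
    utils::write.table(fit$k_trace, file.path(out_dir, "score_trace.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    fit <- fit_em(gtm, k, config = config, seed = seed)
    fit$score <- model_score(gtm, fit)
  }
  write_results(fit, file.path(out_dir, "clonemix"))
  sizes <- tabulate(fit$assignments, fit$params$K)
  tree <- build_mst(fit$params$C, include_root = TRUE)
  utils::write.table(
    data.frame(from = tree$labels[tree$edges$from],
               to = tree$labels[tree$edges$to],
               weight = tree$edges$weight),
    file.path(out_dir, "lineage_mst.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(lineage_newick(tree, sizes = c(0L, sizes)),
             file.path(out_dir, "lineage_mst.nwk"))
  invisible(fit)
}

#' Simulate a dataset and write every artifact
#'
#' Writes the observed matrix `D`, the true genotype matrix, the true cell
#' labels, the doublet indices, and the simulated tree as a parent-vector
#' TSV and in Newick form.
#'
#' @param config a [sim_config()] or [sim_preset()].
#' @param out_prefix path prefix for the output files.
#' @return the `sim_truth`, invisibly.
#' @export
run_simulate <- function(config, out_prefix) {
  truth <- simulate_dataset(config)
  write_gtm(truth$D, paste0(out_prefix, "_D.tsv"))
  write_gtm(truth$Z_star, paste0(out_prefix, "_Zstar.tsv"))
  utils::write.table(
    data.frame(cell_id = truth$D$cell_ids, clone = truth$cell_clone),
    paste0(out_prefix, "_labels.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  writeLines(as.character(truth$doublet_indices),
             paste0(out_prefix, "_doublets.txt"))
  utils::write.table(
    data.frame(node = seq_along(truth$parent), parent = truth$parent),
    paste0(out_prefix, "_tree.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  node_geno <- true_genotypes(truth$parent, truth$edge_mutations,
                              seq_along(truth$parent), truth$config$M)
  tree <- structure(
    list(genotypes = rbind(0L, node_geno),
         labels = c("root", paste0("subclone_", seq_along(truth$parent))),
         edges = data.frame(from = truth$parent + 1L,
                            to = seq_along(truth$parent) + 1L,
                            weight = lengths(truth$edge_mutations)),
         parent = c(0L, truth$parent + 1L)),
    class = "lineage_tree")
  writeLines(lineage_newick(tree), paste0(out_prefix, "_tree.nwk"))
  invisible(truth)
}

#' Evaluate predictions against simulator truth files
#'
#' @param pred_assign path to an assignment table (as written by
#'   [write_results()]).
#' @param pred_z path to the predicted genotype matrix.
#' @param true_labels path to the true label table (from
#'   [run_simulate()]).
#' @param true_z path to the true genotype matrix.
#' @param doublets optional path to the doublet index list.
#' @param out optional path for the report TSV.
#' @return one-row data.frame (see [evaluate_fit()] for columns).
#' @export
run_evaluate <- function(pred_assign, pred_z, true_labels, true_z,
                         doublets = NULL, out = NULL) {
  asg <- utils::read.delim(pred_assign)
  lab <- utils::read.delim(true_labels)
  Z <- read_gtm(pred_z)$values
  Zs <- read_gtm(true_z)$values
  if (nrow(asg) != nrow(lab) || !all(dim(Z) == dim(Zs))) {
    stop("prediction and truth files have mismatched shapes")
  }
  dbl <- integer(0)
  if (!is.null(doublets)) {
    txt <- readLines(doublets, warn = FALSE)
    dbl <- as.integer(txt[nzchar(txt)])
  }
  keep <- setdiff(seq_len(nrow(asg)), dbl)
  gm <- genotype_metrics(Z, Zs, dbl)
  report <- data.frame(
    v_measure = v_measure(lab$clone[keep], asg$cluster[keep]),
    accuracy = gm[["accuracy"]],
    sensitivity = gm[["sensitivity"]],
    specificity = gm[["specificity"]],
    n_cells_evaluated = length(keep)
  )
  if (!is.null(out)) {
    utils::write.table(report, out, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  report
}
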