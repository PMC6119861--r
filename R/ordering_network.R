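#' Conserved temporal-precedence network
#'
#' For every ordered gene pair (A, B), counts the datasets where both genes
#' have a peak time and A's earliest peak strictly precedes B's; an edge
#' A -> B is emitted when that support reaches the quorum (seven of eight
#' datasets in the reference analysis). Ties support neither direction, and
#' a dataset contributes to a pair only when both peak times are present.
#'
#' @param tp_matrix numeric genes x datasets matrix of earliest peak times
#'   (minutes), `NA` where a gene has no peak (see [peak_time_matrix()]).
#' @param quorum minimum number of supporting datasets
#'   (`quorum <= ncol(tp_matrix)`).
#' @return an object of class `OrderingNetwork`: `edges` (data frame
#'   `from`, `to`, `support`), `genes`, `quorum`, `n_datasets`.
#' @export
conserved_orderings <- function(tp_matrix, quorum = 7) {
  tp_matrix <- as.matrix(tp_matrix)
  stopifnot(nrow(tp_matrix) >= 2, quorum >= 1, quorum <= ncol(tp_matrix))
  genes <- rownames(tp_matrix) %||% paste0("g", seq_len(nrow(tp_matrix)))
  supp <- pair_support_cpp(tp_matrix)
  hit <- which(supp >= quorum, arr.ind = TRUE)
  edges <- data.frame(from = genes[hit[, 1]], to = genes[hit[, 2]],
                      support = supp[hit], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, genes = genes, quorum = quorum,
                 n_datasets = ncol(tp_matrix)),
            class = "OrderingNetwork")
}

#' @export
print.OrderingNetwork <- function(x, ...) {
  cat(sprintf("OrderingNetwork: %d genes, %d conserved edges (quorum %d/%d)\n",
              length(x$genes), nrow(x$edges), x$quorum, x$n_datasets))
  invisible(x)
}

#' Permutation null for the conserved-edge count
#'
#' Each permutation independently shuffles the peak times within every
#' dataset column across the genes present there (missing entries stay
#' missing in place), recounts the conserved edges, and accumulates how many
#' permutations reach at least the observed count. The empirical p-value
#' counts the observed dataset as one more at least as extreme as itself,
#' `p = (exceed + 1) / (n_perm + 1)`, so `p` is always in `(0, 1]`; the
#' plain proportion `exceed / n_perm` is available with
#' `include_observed = FALSE`.
#'
#' @inheritParams conserved_orderings
#' @param n_perm number of permutations (at least 1000 for scaled-down
#'   runs; 1e6 for a full-scale analysis).
#' @param seed integer seed.
#' @param include_observed count the observed dataset in the proportion
#'   (default TRUE).
#' @return an object of class `PermutationResult`: `observed`, `n_perm`,
#'   `exceed`, `p`, `seed`, `include_observed`.
#' @export
permutation_null <- function(tp_matrix, quorum = 7, n_perm = 10000, seed = 1,
                             include_observed = TRUE) {
  tp_matrix <- as.matrix(tp_matrix)
  stopifnot(n_perm >= 1)
  observed <- nrow(conserved_orderings(tp_matrix, quorum)$edges)
  counts <- perm_edge_counts_cpp(tp_matrix, as.integer(quorum),
                                 as.integer(n_perm), as.integer(seed))
  exceed <- sum(counts >= observed)
  p <- if (include_observed) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  structure(list(observed = observed, n_perm = as.integer(n_perm),
                 exceed = as.integer(exceed), p = p, seed = seed,
                 include_observed = include_observed,
                 null_mean = mean(counts)),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf("PermutationResult: observed %d edges; %d/%d permutations >= observed; p = %.3g\n",
              x$observed, x$exceed, x$n_perm, x$p))
  invisible(x)
}

#' Roots, sinks and counts of an ordering network
#'
#' Roots are nodes with no incoming edge (first to activate), sinks nodes
#' with no outgoing edge (last to activate); in an empty network every node
#' is both.
#'
#' @param net a [conserved_orderings()] object.
#' @return list with `roots`, `sinks`, `n_nodes`, `n_edges`,
#'   `n_connected` (nodes incident to at least one edge).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "OrderingNetwork"))
  has_in <- net$genes %in% net$edges$to
  has_out <- net$genes %in% net$edges$from
  list(roots = net$genes[!has_in], sinks = net$genes[!has_out],
       n_nodes = length(net$genes), n_edges = nrow(net$edges),
       n_connected = sum(has_in | has_out))
}

#' Write network edges as TSV
#'
#' @param net a [conserved_orderings()] object.
#' @param path output path.
#' @export
write_edges <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
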