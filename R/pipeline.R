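#' Median replicate noise of a set of bundles
#'
#' Median across all non-degenerate series of the pooled replicate sd on the
#' normalized scale; the default calibration noise, so the complexity
#' offsets are computed at a noise level matching the data.
#'
#' @param bundles list of [dataset_bundle()] objects.
#' @return scalar sd (normalized units).
#' @export
median_replicate_noise <- function(bundles) {
  sds <- unlist(lapply(bundles, function(b)
    vapply(b$timecourses, function(tc) {
      s <- normalize_series(tc)
      if (s$degenerate) NA_real_ else estimate_noise_sd(s)
    }, 0)))
  stats::median(sds, na.rm = TRUE)
}

#' Classify several datasets end to end
#'
#' Filters each bundle by TPM, calibrates the complexity offsets once (at
#' the median replicate noise of the filtered data, on the first dataset's
#' sampling grid unless `calibration_times` is given), classifies every TSS
#' of every dataset, and returns the combined records plus the offsets.
#'
#' @param bundles list of [dataset_bundle()] objects.
#' @param n_per_model calibration datasets per model comparison.
#' @param n_live,margin,seed,slow_factor,n_steps see [classify_dataset()]
#'   and [calibrate_offsets()].
#' @param coding_min,noncoding_min TPM thresholds (see [filter_by_tpm()]).
#' @param offsets optional pre-computed [calibrate_offsets()] object
#'   (skips calibration).
#' @param noise calibration noise; default the median replicate noise.
#' @param calibration_times sampling grid for the calibration series.
#' @return list with `classifications` (combined data frame), `offsets`,
#'   and per-stage `counts`.
#' @export
run_classification <- function(bundles, n_per_model = 1000, n_live = 200,
                               margin = 1, seed = 1, slow_factor = 10,
                               coding_min = 10, noncoding_min = 2,
                               offsets = NULL, noise = NULL,
                               calibration_times = NULL, n_steps = 30L) {
  filtered <- lapply(bundles, filter_by_tpm, coding_min = coding_min,
                     noncoding_min = noncoding_min)
  n_in <- sum(vapply(bundles, length, 0L))
  n_kept <- sum(vapply(filtered, length, 0L))
  if (is.null(offsets)) {
    noise <- noise %||% median_replicate_noise(filtered)
    calibration_times <- calibration_times %||% filtered[[1]]$timecourses[[1]]$times
    offsets <- calibrate_offsets(calibration_times, noise,
                                 n_per_model = n_per_model, n_live = n_live,
                                 seed = derive_seed(seed, "calibration"),
                                 slow_factor = slow_factor, n_steps = n_steps)
  }
  cls <- lapply(filtered, classify_dataset, offsets = offsets, margin = margin,
                n_live = n_live, seed = seed, slow_factor = slow_factor,
                n_steps = n_steps)
  combined <- do.call(rbind, cls)
  rownames(combined) <- NULL
  list(classifications = combined, offsets = offsets,
       counts = c(tss_input = n_in, tss_filtered = n_kept,
                  table(factor(combined$model,
                               levels = c("linear", "decay", "dip", "peak",
                                          "unclassified")))))
}

#' Meta-analysis of classifications across datasets
#'
#' Builds the gene-level peak table, the robust and permissive shared sets,
#' the shared-set IEG enrichment rows and the per-dataset per-class
#' enrichments.
#'
#' @param classifications combined classification records (data frame with
#'   `dataset_id`) or a list of per-dataset data frames.
#' @param ieg_labels known-IEG gene ids.
#' @param robust_min,permissive_min dataset quorums defining the robust and
#'   permissive shared sets.
#' @return list with `table`, `robust`, `permissive`, `shared_enrichment`,
#'   `class_enrichment`.
#' @export
run_meta <- function(classifications, ieg_labels, robust_min = 7,
                     permissive_min = 4) {
  table <- build_gene_peak_table(classifications)
  nd <- length(table$datasets)
  ks <- 2:nd
  list(table = table,
       robust = shared_set(table, min(robust_min, nd)),
       permissive = shared_set(table, min(permissive_min, nd)),
       shared_enrichment = enrichment_by_shared(table, classifications,
                                                ieg_labels, ks = ks),
       class_enrichment = per_dataset_class_enrichment(classifications,
                                                       ieg_labels))
}

#' Conserved-ordering network stage
#'
#' Restricts the peak-time matrix to the candidate genes (the robust set in
#' the reference analysis), builds the conserved-precedence network and
#' assesses its edge count against the within-dataset permutation null.
#'
#' @param table a [build_gene_peak_table()] object.
#' @param genes candidate gene roster.
#' @param quorum minimum supporting datasets per edge.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `tp_matrix`, `network`, `permutation`, `summary`.
#' @export
run_network <- function(table, genes, quorum = 7, n_perm = 10000, seed = 1) {
  m <- peak_time_matrix(table, genes)
  net <- conserved_orderings(m, quorum)
  perm <- permutation_null(m, quorum, n_perm = n_perm,
                           seed = derive_seed(seed, "permutation"))
  list(tp_matrix = m, network = net, permutation = perm,
       summary = network_summary(net))
}

#' Run the whole pipeline on a set of bundles
#'
#' Classification, meta-analysis and ordering network in sequence, with a
#' run manifest of per-stage counts.
#'
#' @inheritParams run_classification
#' @param ieg_labels known-IEG gene ids; defaults to the labels carried by
#'   the first bundle.
#' @param robust_min,permissive_min,quorum,n_perm see [run_meta()] and
#'   [run_network()].
#' @return list with `classification`, `meta`, `network`, `manifest`.
#' @export
run_pipeline <- function(bundles, ieg_labels = NULL, n_per_model = 1000,
                         n_live = 200, margin = 1, seed = 1,
                         robust_min = 7, permissive_min = 4, quorum = 7,
                         n_perm = 10000, ...) {
  ieg_labels <- ieg_labels %||% bundles[[1]]$ieg_labels
  cl <- run_classification(bundles, n_per_model = n_per_model,
                           n_live = n_live, margin = margin, seed = seed, ...)
  meta <- run_meta(cl$classifications, ieg_labels,
                   robust_min = robust_min, permissive_min = permissive_min)
  net <- if (length(meta$robust) >= 2)
    run_network(meta$table, meta$robust, quorum = quorum,
                n_perm = n_perm, seed = seed)
  else NULL
  manifest <- list(
    seed = seed, n_datasets = length(bundles),
    counts = as.list(cl$counts),
    offsets = as.list(cl$offsets$offsets),
    calibration = list(noise = cl$offsets$noise,
                       n_per_model = cl$offsets$n_per_model),
    robust_set_size = length(meta$robust),
    permissive_set_size = length(meta$permissive),
    n_edges = if (is.null(net)) NA_integer_ else nrow(net$network$edges),
    permutation_p = if (is.null(net)) NA_real_ else net$permutation$p)
  list(classification = cl, meta = meta, network = net, manifest = manifest)
}

#' Write pipeline results and a checksummed manifest
#'
#' Classifications, gene peak table, shared sets, enrichment tables, network
#' edges and permutation summary as TSV/JSON, plus `manifest.json` listing
#' every output file with its md5 checksum.
#'
#' @param results a [run_pipeline()] result.
#' @param dir output directory.
#' @return path of the manifest, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    wr(results$classification$classifications, "classifications.tsv"),
    wr(results$meta$table$cells, "gene_peak_table.tsv"),
    wr(results$meta$shared_enrichment, "shared_enrichment.tsv"),
    wr(results$meta$class_enrichment, "class_enrichment.tsv"))
  op <- file.path(dir, "offsets.json")
  write_offsets(results$classification$offsets, op)
  paths <- c(paths, op)
  if (!is.null(results$network)) {
    paths <- c(paths, wr(results$network$network$edges, "edges.tsv"))
    pp <- file.path(dir, "permutation.json")
    perm <- results$network$permutation
    jsonlite::write_json(unclass(perm), pp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, pp)
  }
  manifest <- results$manifest
  manifest$files <- lapply(stats::setNames(paths, basename(paths)),
                           function(p) unname(tools::md5sum(p)))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Load a pipeline configuration from YAML
#'
#' Thresholds, quorums, margins, sampler settings and seeds can be kept in a
#' YAML file; values omitted there fall back to the package defaults.
#'
#' @param path YAML file path (optional).
#' @param overrides named list overriding file values.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  defaults <- list(coding_min = 10, noncoding_min = 2, margin = 1,
                   n_live = 200, n_per_model = 1000, robust_min = 7,
                   permissive_min = 4, quorum = 7, n_perm = 10000,
                   slow_factor = 10, seed = 1)
  cfg <- defaults
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    cfg[names(y)] <- y
  }
  cfg[names(overrides)] <- overrides
  cfg
}
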