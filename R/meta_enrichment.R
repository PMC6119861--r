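#' Aggregate per-dataset classifications into a gene-level peak table
#'
#' For every gene and dataset the table records whether any of the gene's
#' TSSs was classified to the peak model, how many were, and the earliest
#' peak time (smallest posterior-mean `t_p`) among them. Genes absent from a
#' dataset (e.g. below the TPM threshold there) count as not peaking in it.
#'
#' @param classifications either a list of per-dataset [classify_dataset()]
#'   data frames or one combined data frame with a `dataset_id` column;
#'   at least two datasets are required.
#' @return an object of class `GenePeakTable`: `genes` (gene_id, biotype,
#'   `n_datasets_peak`), `cells` (long data frame gene x dataset:
#'   `peak`, `n_peak_tss`, `earliest_tp`), `datasets`.
#' @export
build_gene_peak_table <- function(classifications) {
  df <- if (is.data.frame(classifications)) classifications
        else do.call(rbind, classifications)
  stopifnot(all(c("dataset_id", "tss_id", "gene_id", "model") %in% names(df)))
  datasets <- unique(df$dataset_id)
  if (length(datasets) < 2)
    stop("gene-level aggregation requires at least two datasets")
  genes <- unique(df[, c("gene_id", "biotype")])
  genes <- genes[!duplicated(genes$gene_id), ]
  peaks <- df[df$model == "peak", , drop = FALSE]
  cells <- expand.grid(gene_id = genes$gene_id, dataset_id = datasets,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(peaks$gene_id, peaks$dataset_id, sep = "\r")
  n_peak <- table(key)
  cell_key <- paste(cells$gene_id, cells$dataset_id, sep = "\r")
  cells$n_peak_tss <- as.integer(n_peak[cell_key])
  cells$n_peak_tss[is.na(cells$n_peak_tss)] <- 0L
  cells$peak <- cells$n_peak_tss > 0L
  tp_min <- tapply(peaks$tp_mean, paste(peaks$gene_id, peaks$dataset_id,
                                        sep = "\r"), min)
  cells$earliest_tp <- as.numeric(tp_min[cell_key])
  cells$earliest_tp[!cells$peak] <- NA_real_
  shared <- tapply(cells$peak, cells$gene_id, sum)
  genes$n_datasets_peak <- as.integer(shared[genes$gene_id])
  rownames(genes) <- NULL
  structure(list(genes = genes, cells = cells, datasets = datasets),
            class = "GenePeakTable")
}

#' @export
print.GenePeakTable <- function(x, ...) {
  cat(sprintf("GenePeakTable: %d genes x %d datasets; %d genes peak somewhere\n",
              nrow(x$genes), length(x$datasets), sum(x$genes$n_datasets_peak > 0)))
  invisible(x)
}

#' Genes whose promoters peak in at least `min_datasets` datasets
#'
#' With eight datasets, `min_datasets = 7` yields the robust candidate-IEG
#' set and `min_datasets = 4` the permissive set.
#'
#' @param table a [build_gene_peak_table()] object.
#' @param min_datasets required number of datasets with a peak
#'   (`1 <= min_datasets <= number of datasets`).
#' @return character vector of gene ids.
#' @export
shared_set <- function(table, min_datasets) {
  stopifnot(inherits(table, "GenePeakTable"),
            min_datasets >= 1, min_datasets <= length(table$datasets))
  table$genes$gene_id[table$genes$n_datasets_peak >= min_datasets]
}

#' Gene x dataset matrix of earliest peak times
#'
#' @param table a [build_gene_peak_table()] object.
#' @param genes optional gene subset (rows), e.g. a [shared_set()].
#' @return numeric matrix (genes x datasets) of earliest `t_p` in minutes,
#'   `NA` where a gene has no peak-classified TSS in a dataset.
#' @export
peak_time_matrix <- function(table, genes = NULL) {
  stopifnot(inherits(table, "GenePeakTable"))
  genes <- genes %||% table$genes$gene_id
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(table$datasets),
              dimnames = list(genes, table$datasets))
  cells <- table$cells[table$cells$gene_id %in% genes & table$cells$peak, ]
  m[cbind(match(cells$gene_id, genes), match(cells$dataset_id, table$datasets))] <-
    cells$earliest_tp
  m
}

#' Known-IEG enrichment of a TSS group (Fisher's exact test)
#'
#' Builds the 2x2 table `[a = group IEG TSSs, b = group non-IEG TSSs;
#' c = outside IEG TSSs, d = outside non-IEG TSSs]` and reports the sample
#' odds ratio `(a d) / (b c)` together with the two-sided Fisher's exact
#' p-value. A zero cell triggers a 0.5 continuity correction for the odds
#' ratio (flagged in the output); the p-value remains exact.
#'
#' @param group_tss_total,group_tss_ieg TSS counts in the group.
#' @param all_tss_total,all_tss_ieg TSS counts over all tested TSSs.
#' @return one-row data frame with the cells, `odds_ratio`, `p_value` and a
#'   `continuity` flag.
#' @export
ieg_enrichment <- function(group_tss_total, group_tss_ieg,
                           all_tss_total, all_tss_ieg) {
  a <- group_tss_ieg
  b <- group_tss_total - a
  c <- all_tss_ieg - a
  d <- all_tss_total - group_tss_total - c
  if (min(a, b, c, d) < 0 || group_tss_ieg > group_tss_total ||
      all_tss_ieg > all_tss_total || group_tss_total > all_tss_total)
    stop("inconsistent contingency counts")
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  continuity <- any(tab == 0)
  orr <- if (continuity) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
         else (a * d) / (b * c)
  p <- stats::fisher.test(tab)$p.value
  data.frame(group_total = group_tss_total, group_ieg = a,
             outside_total = all_tss_total - group_tss_total, outside_ieg = c,
             odds_ratio = orr, p_value = p, continuity = continuity)
}

#' IEG enrichment of shared-peak gene groups
#'
#' For each minimum number of shared datasets `k`, the group holds all
#' peak-classified TSS records (across datasets) of genes peaking in at
#' least `k` datasets, compared against the peak-classified TSS records of
#' the remaining tested genes.
#'
#' @param table a [build_gene_peak_table()] object.
#' @param classifications the classification records used to build `table`
#'   (list or combined data frame).
#' @param ieg_labels character vector of known-IEG gene ids.
#' @param ks integer vector of `min_datasets` group definitions.
#' @return data frame, one row per `k`, with gene and TSS counts, sample OR
#'   and Fisher p.
#' @export
enrichment_by_shared <- function(table, classifications, ieg_labels,
                                 ks = 2:8) {
  df <- if (is.data.frame(classifications)) classifications
        else do.call(rbind, classifications)
  peaks <- df[df$model == "peak", , drop = FALSE]
  all_total <- nrow(peaks)
  all_ieg <- sum(peaks$gene_id %in% ieg_labels)
  out <- lapply(ks, function(k) {
    genes <- shared_set(table, k)
    grp <- peaks[peaks$gene_id %in% genes, , drop = FALSE]
    enr <- ieg_enrichment(nrow(grp), sum(grp$gene_id %in% ieg_labels),
                          all_total, all_ieg)
    cbind(data.frame(min_datasets = k, n_genes = length(genes),
                     n_ieg_genes = sum(genes %in% ieg_labels)), enr)
  })
  do.call(rbind, out)
}

#' Published shared-peak enrichment counts
#'
#' TSS and gene counts per shared-dataset group from the eight-dataset CAGE
#' time-course meta-analysis this package's methods mirror, with the
#' odds ratios and Fisher p-values as printed there. Used to validate
#' [ieg_enrichment()]: every printed OR reproduces from the counts alone.
#'
#' @return data frame with one row per shared-dataset group.
#' @export
reference_shared_enrichment <- function() {
  utils::read.delim(system.file("extdata", "shared_peak_enrichment.tsv",
                                package = "promkin"),
                    stringsAsFactors = FALSE)
}

#' Per-dataset, per-class IEG enrichment
#'
#' For each dataset and model class, compares the class's TSSs against all
#' other classified TSSs of that dataset in a 2x2 IEG/non-IEG table.
#'
#' @inheritParams enrichment_by_shared
#' @param classifications list or combined data frame of classification
#'   records.
#' @return data frame with one row per dataset x class.
#' @export
per_dataset_class_enrichment <- function(classifications, ieg_labels) {
  df <- if (is.data.frame(classifications)) classifications
        else do.call(rbind, classifications)
  df <- df[df$model != "unclassified", , drop = FALSE]
  out <- list()
  for (ds in unique(df$dataset_id)) {
    sub <- df[df$dataset_id == ds, ]
    tot <- nrow(sub)
    tot_ieg <- sum(sub$gene_id %in% ieg_labels)
    for (cl in c("linear", "decay", "dip", "peak")) {
      grp <- sub[sub$model == cl, ]
      if (!nrow(grp)) next
      enr <- ieg_enrichment(nrow(grp), sum(grp$gene_id %in% ieg_labels),
                            tot, tot_ieg)
      out[[length(out) + 1L]] <-
        cbind(data.frame(dataset_id = ds, class = cl), enr)
    }
  }
  do.call(rbind, out)
}
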