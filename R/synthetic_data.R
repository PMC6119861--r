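#' Generate one calibration series from a model's priors
#'
#' Reproduces the calibration scheme used for the complexity offsets:
#' parameter values are drawn at random from the model's prior ranges to
#' generate one noise-free replicate, and two further replicates are formed
#' by adding and subtracting the same fixed noise value at every time point.
#'
#' Real series enter classification normalized so that their median
#' trajectory spans exactly 10 units; `min_range` restricts the prior draws
#' to comparably plausible trajectories (rejection sampling on the span of
#' the noise-free curve over the sampling grid), which is how the priors are
#' "restricted to plausible values" for calibration purposes.
#'
#' @param spec a [model_spec()].
#' @param noise noise offset on the normalized scale (`>= 0`).
#' @param seed integer seed for the parameter draw.
#' @param times sampling times (minutes).
#' @param params optional explicit parameter vector (skips the prior draw).
#' @param min_range minimum span (max minus min, normalized units) the clean
#'   trajectory must reach over the sampling grid; 0 disables the
#'   constraint.
#' @return a `NormalizedSeries` with three replicates and identity anchors;
#'   the generating parameters are attached as `attr(x, "params")`.
#' @export
generate_calibration_series <- function(spec, noise, seed, times,
                                        params = NULL, min_range = 0) {
  stopifnot(inherits(spec, "ModelSpec"), noise >= 0)
  if (is.null(params)) {
    params <- with_seed(seed, {
      for (attempt in 1:20000) {
        p <- stats::runif(length(spec$par_names), spec$lower, spec$upper)
        curve <- eval_model_cpp(spec$code, p, as.numeric(times))
        if (max(curve) - min(curve) >= min_range) break
        p <- NULL
      }
      if (is.null(p))
        stop(sprintf("could not draw a '%s' trajectory with span >= %g",
                     spec$name, min_range))
      p
    })
  }
  params <- check_params(spec, params)
  clean <- eval_model(spec, params, times)
  values <- rbind(clean, clean + noise, clean - noise)
  out <- normalized_series(values, times,
                           tss_id = sprintf("calib_%s_%d", spec$name, seed),
                           dataset_id = "calibration")
  attr(out, "params") <- stats::setNames(params, spec$par_names)
  out
}

default_time_grids <- function(n_datasets) {
  grids <- list(
    c(0, 15, 30, 45, 60, 80, 100, 120, 160, 200, 240, 300),
    c(0, 15, 30, 45, 60, 90, 120, 150, 180, 240, 300, 360),
    c(0, 10, 20, 30, 45, 60, 90, 120, 180, 240, 300),
    c(0, 15, 30, 45, 60, 75, 90, 120, 150, 200, 250, 300),
    c(0, 20, 40, 60, 80, 100, 140, 180, 220, 260, 300, 400),
    c(0, 15, 30, 60, 90, 120, 180, 240, 300),
    c(0, 10, 25, 40, 55, 70, 85, 100, 130, 160, 200, 240, 300),
    c(0, 15, 30, 45, 60, 80, 100, 120, 160, 200, 240, 300, 360))
  rep(grids, length.out = n_datasets)
}

#' Configuration of the synthetic multi-dataset cohort generator
#'
#' Defaults emulate the structure the analysis assumes: eight datasets with
#' irregular, densely early sampling grids within 0--400 min; three
#' replicates per time point; a class mixture dominated by peaks; a planted
#' set of known-IEG labels enriched among peak-class genes; and a planted
#' roster of genes with a strict common peak-time ordering (rank r peaks at
#' `ordering_start + ordering_gap * (r - 1)` minutes, jittered per dataset).
#'
#' @param n_datasets number of virtual datasets.
#' @param times list of per-dataset sampling grids (minutes).
#' @param n_genes_coding,n_genes_noncoding genes per biotype.
#' @param tss_lambda Poisson rate of extra TSSs per gene (each gene has
#'   `1 + rpois(tss_lambda)` TSSs).
#' @param class_mix named fractions (summing to 1) of
#'   linear/decay/dip/peak/flat gene classes; `flat` genes are constant
#'   (unclassifiable) controls.
#' @param peak_share_prob probability that a non-roster peak-class gene
#'   actually peaks in any given dataset (peaking elsewhere reverts to
#'   linear), creating the observed cross-dataset sharing structure.
#' @param ieg_fraction overall fraction of genes labelled known IEG.
#' @param ieg_peak_enrichment odds multiplier for IEG labels among
#'   peak-class genes.
#' @param ordering_n_genes,ordering_start,ordering_gap,ordering_jitter_sd
#'   planted conserved-ordering roster: size, base time of rank 1, spacing
#'   between ranks and per-dataset jitter sd (minutes).
#' @param noise_sd i.i.d. Gaussian replicate noise sd on the normalized
#'   0--10 scale.
#' @param seed master seed.
#' @return a `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_datasets = 8, times = NULL,
                             n_genes_coding = 260, n_genes_noncoding = 40,
                             tss_lambda = 0.7,
                             class_mix = c(linear = 0.2, decay = 0.15,
                                           dip = 0.1, peak = 0.4, flat = 0.15),
                             peak_share_prob = 0.6,
                             ieg_fraction = 0.1, ieg_peak_enrichment = 5,
                             ordering_n_genes = 20, ordering_start = 30,
                             ordering_gap = 20, ordering_jitter_sd = 5,
                             noise_sd = 0.3, seed = 1) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8, noise_sd > 0,
            all(sort(names(class_mix)) ==
                  sort(c("linear", "decay", "dip", "peak", "flat"))),
            ordering_n_genes <= n_genes_coding)
  times <- times %||% default_time_grids(n_datasets)
  stopifnot(length(times) == n_datasets,
            all(vapply(times, function(t) t[1] == 0 && all(diff(t) > 0), TRUE)))
  structure(list(n_datasets = n_datasets, times = times,
                 n_genes_coding = n_genes_coding,
                 n_genes_noncoding = n_genes_noncoding,
                 tss_lambda = tss_lambda, class_mix = class_mix,
                 peak_share_prob = peak_share_prob,
                 ieg_fraction = ieg_fraction,
                 ieg_peak_enrichment = ieg_peak_enrichment,
                 ordering_n_genes = ordering_n_genes,
                 ordering_start = ordering_start,
                 ordering_gap = ordering_gap,
                 ordering_jitter_sd = ordering_jitter_sd,
                 noise_sd = noise_sd, seed = seed),
            class = "SyntheticConfig")
}

draw_class_params <- function(class, tp = NULL, t_max = 300) {
  switch(class,
    linear = {
      a <- stats::runif(1, 0, 5)
      b <- stats::runif(1, -a / t_max, (10 - a) / t_max)
      c(intercept = a, slope = b)
    },
    decay = c(base = stats::runif(1, 0, 3), amp = stats::runif(1, 3, 9),
              k = stats::runif(1, 0.005, 0.1)),
    dip = {
      base <- stats::runif(1, 6, 10)
      c(base = base, depth = stats::runif(1, 2, min(8, base)),
        k = stats::runif(1, 0.01, 0.2), ratio = stats::runif(1, 0.1, 0.6))
    },
    peak = {
      td <- min(max(0.3 * tp + stats::runif(1, -5, 5), 0), 0.8 * t_max)
      ts <- max(tp - td, 1)
      td <- tp - ts # keep td + ts == tp exactly
      c(p1 = stats::runif(1, 0, 2), p2 = stats::runif(1, 2, 9),
        td = td, ts = ts,
        r_rise = stats::runif(1, 0.03, 0.3),
        r_fall = stats::runif(1, 0.005, 0.08))
    },
    flat = c(level = stats::runif(1, 2, 8)))
}

eval_class_curve <- function(class, params, times, t_max) {
  if (class == "flat") return(rep(params[["level"]], length(times)))
  spec <- model_spec(if (class == "peak") "peak" else class, t_max)
  # planted peak times may exceed the prior box of a single window; evaluate
  # directly rather than through the prior check
  eval_model_cpp(spec$code, unname(params), as.numeric(times))
}

#' Generate a ground-truth-labelled multi-dataset synthetic cohort
#'
#' Emits one `DatasetBundle` per virtual dataset on the TPM scale (each TSS
#' is mapped from the normalized scale through randomized anchors chosen so
#' coding TSSs exceed the 10 TPM filter and non-coding ones the 2 TPM
#' filter), together with the complete ground truth: per-TSS generating
#' class and peak time per dataset, per-gene IEG flag and planted ordering
#' rank. Deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `SyntheticCohort`: `bundles` (list of
#'   [dataset_bundle()]), `truth` (list with `genes` and `records` data
#'   frames), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n_genes <- config$n_genes_coding + config$n_genes_noncoding
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(n_genes)),
    biotype = rep(c("coding", "noncoding"),
                  c(config$n_genes_coding, config$n_genes_noncoding)),
    stringsAsFactors = FALSE)
  genes$class_base <- sample(names(config$class_mix), n_genes, replace = TRUE,
                             prob = config$class_mix)
  genes$order_rank <- NA_integer_
  if (config$ordering_n_genes > 0) {
    roster <- seq_len(config$ordering_n_genes) # first coding genes
    genes$class_base[roster] <- "peak"
    genes$order_rank[roster] <- seq_along(roster)
  }
  # IEG labels enriched among peak-class genes by the configured factor
  n_peak <- sum(genes$class_base == "peak")
  p0 <- config$ieg_fraction * n_genes /
    ((n_genes - n_peak) + config$ieg_peak_enrichment * n_peak)
  p1 <- min(0.95, config$ieg_peak_enrichment * p0)
  genes$ieg <- ifelse(genes$class_base == "peak",
                      stats::runif(n_genes) < p1, stats::runif(n_genes) < p0)
  genes$n_tss <- 1L + stats::rpois(n_genes, config$tss_lambda)
  genes$base_tp <- stats::runif(n_genes, 25, 250)

  bundles <- vector("list", config$n_datasets)
  records <- list()
  for (d in seq_len(config$n_datasets)) {
    dataset_id <- sprintf("DS%02d", d)
    times <- config$times[[d]]
    t_max <- max(times)
    tcs <- list()
    for (g in seq_len(n_genes)) {
      rank <- genes$order_rank[g]
      cls <- genes$class_base[g]
      if (cls == "peak" && is.na(rank) &&
          stats::runif(1) > config$peak_share_prob)
        cls <- "linear"
      tp_gene <- if (cls != "peak") NA_real_
        else if (!is.na(rank))
          max(config$ordering_start + config$ordering_gap * (rank - 1) +
                stats::rnorm(1, 0, config$ordering_jitter_sd), 10)
        else min(max(genes$base_tp[g] + stats::rnorm(1, 0, 15), 10), 1.5 * t_max)
      for (k in seq_len(genes$n_tss[g])) {
        tss_id <- sprintf("%s_p%d", genes$gene_id[g], k)
        tp_tss <- if (is.na(tp_gene)) NA_real_
                  else if (k == 1) tp_gene else tp_gene + abs(stats::rnorm(1, 0, 3))
        params <- draw_class_params(cls, tp = tp_tss, t_max = t_max)
        clean <- eval_class_curve(cls, params, times, t_max)
        y <- matrix(rep(clean, each = 3), nrow = 3) +
          stats::rnorm(3 * length(times), 0, config$noise_sd)
        # map to TPM with anchors clearing the biotype's filter threshold
        coding <- genes$biotype[g] == "coding"
        tpm_min <- if (coding) stats::runif(1, 0, 3) else stats::runif(1, 0, 1)
        tpm_max <- if (coding) stats::runif(1, 15, 100) else stats::runif(1, 4, 30)
        rng <- max(clean) - min(clean)
        tpm <- if (rng > 0)
          pmax(tpm_min + (y - min(clean)) * (tpm_max - tpm_min) / rng, 0)
        else # flat controls sit at a constant level above the filter
          pmax(tpm_max + (y - clean[1]) * tpm_max / 20, 0)
        tcs[[tss_id]] <- time_course(tss_id, genes$gene_id[g],
                                     genes$biotype[g], dataset_id, times, tpm)
        records[[length(records) + 1L]] <- data.frame(
          dataset_id = dataset_id, tss_id = tss_id,
          gene_id = genes$gene_id[g], biotype = genes$biotype[g],
          class = cls, tp_true = tp_tss, max_tpm = max(tpm),
          stringsAsFactors = FALSE)
      }
    }
    bundles[[d]] <- dataset_bundle(dataset_id, tcs,
                                   ieg_labels = genes$gene_id[genes$ieg])
  }
  names(bundles) <- vapply(bundles, `[[`, "", "dataset_id")
  structure(list(bundles = bundles,
                 truth = list(genes = genes,
                              records = do.call(rbind, records)),
                 config = config),
            class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d datasets, %d genes, %d TSS records\n",
              length(x$bundles), nrow(x$truth$genes), nrow(x$truth$records)))
  invisible(x)
}

#' Ground-truth peak-time matrix of a synthetic cohort
#'
#' Earliest true peak time per gene and dataset (the planted analogue of
#' [peak_time_matrix()]), `NA` where the gene has no peaking TSS.
#'
#' @param cohort a [generate_cohort()] object.
#' @param genes optional gene subset (defaults to the planted ordering
#'   roster).
#' @return numeric genes x datasets matrix.
#' @export
truth_peak_time_matrix <- function(cohort, genes = NULL) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  tr <- cohort$truth
  genes <- genes %||% tr$genes$gene_id[!is.na(tr$genes$order_rank)]
  datasets <- names(cohort$bundles)
  rec <- tr$records[tr$records$class == "peak" & tr$records$gene_id %in% genes, ]
  m <- matrix(NA_real_, length(genes), length(datasets),
              dimnames = list(genes, datasets))
  if (nrow(rec)) {
    agg <- stats::aggregate(tp_true ~ gene_id + dataset_id, rec, min)
    m[cbind(match(agg$gene_id, genes), match(agg$dataset_id, datasets))] <-
      agg$tp_true
  }
  m
}

#' Write a synthetic cohort to disk
#'
#' Emits one expression TSV per dataset, the planted IEG label list, the
#' ground-truth tables, and the generation parameters as JSON.
#'
#' @param cohort a [generate_cohort()] object.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (b in cohort$bundles) {
    p <- file.path(dir, sprintf("expression_%s.tsv", b$dataset_id))
    write_expression_table(b, p)
    paths[b$dataset_id] <- p
  }
  p <- file.path(dir, "ieg_labels.txt")
  writeLines(cohort$bundles[[1]]$ieg_labels, p)
  paths["ieg_labels"] <- p
  p <- file.path(dir, "truth_genes.tsv")
  utils::write.table(cohort$truth$genes, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth_genes"] <- p
  p <- file.path(dir, "truth_records.tsv")
  utils::write.table(cohort$truth$records, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth_records"] <- p
  p <- file.path(dir, "config.json")
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, p, auto_unbox = TRUE, digits = NA)
  paths["config"] <- p
  invisible(paths)
}
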