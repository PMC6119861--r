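#' Calibrate complexity offsets for the model decision
#'
#' A model fitted to data it generated itself enjoys a systematic log Z
#' elevation that differs between models (through their prior volumes and
#' flexibility), biasing the decision toward the more complex signatures.
#' To measure it, each calibration iteration draws, for every model,
#' parameter values at random from that model's prior ranges to generate one
#' noise-free replicate plus two replicates offset by plus and minus the
#' same noise value (the noise value is shared by all models within an
#' iteration), and fits each model to its own series. The advantage of each
#' complex model (decay, dip, both peak variants) is its own-series log Z
#' minus the linear model's own-series log Z in the same iteration --
#' pairing that cancels the common noise-dependent part of log Z, so the
#' advantage is stable across the range of linear log Z values. The offset
#' subtracted at decision time is mean + 2 sd of this advantage over
#' `n_per_model` iterations; raw log Z values are never mutated.
#'
#' @param times sampling-time vector (minutes) the calibration series are
#'   generated on.
#' @param noise noise offset on the normalized scale added/subtracted to the
#'   clean replicate (typically the median pooled replicate sd of the data
#'   being classified); may be a vector, recycled over iterations.
#' @param n_per_model number of calibration datasets fitted per model
#'   (1000 in a full run; at least 100 for scaled-down runs).
#' @param n_live,n_steps nested-sampling settings (see
#'   [nested_sampling_logZ()]).
#' @param seed run-level seed; per-fit seeds are derived with
#'   [derive_seed()].
#' @param slow_factor rate scaling of the slow peak variant.
#' @param t_max last time used to build the priors (defaults to
#'   `max(times)`).
#' @param min_range optional span constraint on the calibration draws (see
#'   [generate_calibration_series()]); the default 0 keeps the draws
#'   unconstrained, exactly "at random from the prior ranges".
#' @return an object of class `CalibrationOffsets`: `offsets` (named vector
#'   for decay, dip, peak_fast, peak_slow; linear is 0 by definition),
#'   `table` (per-iteration own-series log Z draws), and the calibration
#'   provenance (`noise`, `n_per_model`, `n_live`, `seed`, `n_failed`).
#' @export
calibrate_offsets <- function(times, noise, n_per_model = 1000,
                              n_live = 200, seed = 1, slow_factor = 10,
                              n_steps = 30L, t_max = max(times),
                              min_range = 0) {
  stopifnot(n_per_model >= 10, all(noise >= 0))
  specs <- kinetic_model_set(t_max, slow_factor)
  noise <- rep_len(noise, n_per_model)
  rows <- vector("list", n_per_model)
  n_failed <- 0L
  for (i in seq_len(n_per_model)) {
    logZ <- vapply(names(specs), function(m) {
      series <- generate_calibration_series(
        specs[[m]], noise[i],
        seed = derive_seed(seed, "calibration-series", i, m), times = times,
        min_range = min_range)
      fit <- nested_sampling_logZ(specs[[m]], series,
                                  estimate_noise_sd(series), n_live = n_live,
                                  seed = derive_seed(seed, "calibration-fit", i, m),
                                  n_steps = n_steps)
      if (!fit$converged) NA_real_ else fit$logZ
    }, 0)
    if (anyNA(logZ)) {
      n_failed <- n_failed + 1L
      next
    }
    rows[[i]] <- c(iteration = i, logZ)
  }
  tab <- as.data.frame(do.call(rbind, rows[!vapply(rows, is.null, TRUE)]))
  if (nrow(tab) < 2)
    stop("calibration failed: fewer than two successful iterations")
  complex <- c("decay", "dip", "peak_fast", "peak_slow")
  offsets <- vapply(complex, function(m) {
    adv <- tab[[m]] - tab$linear
    mean(adv) + 2 * stats::sd(adv)
  }, 0)
  structure(list(offsets = offsets, table = tab, noise = unique(noise),
                 n_per_model = n_per_model, n_live = n_live, seed = seed,
                 n_failed = n_failed, slow_factor = slow_factor,
                 times = times),
            class = "CalibrationOffsets")
}

#' @export
print.CalibrationOffsets <- function(x, ...) {
  cat(sprintf("CalibrationOffsets (n = %d, noise = %.3g, %d failed):\n",
              x$n_per_model, x$noise, x$n_failed))
  print(round(x$offsets, 3))
  invisible(x)
}

#' Persist / restore calibration offsets as JSON
#'
#' @param offsets a [calibrate_offsets()] object.
#' @param path JSON file path.
#' @return `path` / the restored `CalibrationOffsets`.
#' @export
write_offsets <- function(offsets, path) {
  stopifnot(inherits(offsets, "CalibrationOffsets"))
  jsonlite::write_json(
    list(offsets = as.list(offsets$offsets), noise = offsets$noise,
         n_per_model = offsets$n_per_model, n_live = offsets$n_live,
         seed = offsets$seed, n_failed = offsets$n_failed,
         slow_factor = offsets$slow_factor, times = offsets$times,
         table = offsets$table),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_offsets
#' @param path JSON file written by [write_offsets()].
#' @export
read_offsets <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(offsets = unlist(x$offsets), table = as.data.frame(x$table),
                 noise = x$noise, n_per_model = x$n_per_model,
                 n_live = x$n_live, seed = x$seed, n_failed = x$n_failed,
                 slow_factor = x$slow_factor, times = x$times),
            class = "CalibrationOffsets")
}

#' Classify one TSS from its per-model fits
#'
#' The two peak variants are first collapsed to the better
#' (higher offset-corrected log Z) one; the winner among linear, decay, dip
#' and peak is the model whose corrected log Z exceeds the runner-up's by at
#' least `margin` natural-log units, otherwise the TSS is unclassified.
#' Missing or unconverged fits make the TSS unclassified with a reason.
#'
#' @param fits named list of [nested_sampling_logZ()] fits with elements
#'   `linear`, `decay`, `dip`, `peak_fast`, `peak_slow`.
#' @param offsets a [calibrate_offsets()] object (or a named numeric vector
#'   of offsets for decay, dip, peak_fast, peak_slow).
#' @param margin decision margin in natural-log units (default 1, a Bayes
#'   factor of about e).
#' @return one-row data frame: `model` (or `"unclassified"`), `variant`,
#'   corrected log Z per candidate, achieved margin, `tp_mean`, `tp_sd`
#'   (peak winners only) and `reason` for unclassified records.
#' @export
classify_tss <- function(fits, offsets, margin = 1) {
  off <- if (inherits(offsets, "CalibrationOffsets")) offsets$offsets else offsets
  need <- c("linear", "decay", "dip", "peak_fast", "peak_slow")
  missing_fit <- vapply(need, function(m)
    is.null(fits[[m]]) || !isTRUE(fits[[m]]$converged), TRUE)
  unclass_row <- function(reason) {
    data.frame(model = "unclassified", variant = NA_character_,
               logZ_linear = NA_real_, logZ_decay = NA_real_,
               logZ_dip = NA_real_, logZ_peak = NA_real_,
               decision_margin = NA_real_, tp_mean = NA_real_,
               tp_sd = NA_real_, reason = reason, stringsAsFactors = FALSE)
  }
  if (any(missing_fit))
    return(unclass_row(paste("missing or unconverged fit:",
                             paste(need[missing_fit], collapse = ", "))))
  corrected <- c(linear = fits$linear$logZ,
                 decay = fits$decay$logZ - off[["decay"]],
                 dip = fits$dip$logZ - off[["dip"]],
                 peak_fast = fits$peak_fast$logZ - off[["peak_fast"]],
                 peak_slow = fits$peak_slow$logZ - off[["peak_slow"]])
  peak_variant <- if (corrected[["peak_fast"]] >= corrected[["peak_slow"]])
    "peak_fast" else "peak_slow"
  cand <- c(linear = corrected[["linear"]], decay = corrected[["decay"]],
            dip = corrected[["dip"]], peak = corrected[[peak_variant]])
  ord <- order(cand, decreasing = TRUE)
  achieved <- cand[ord[1]] - cand[ord[2]]
  winner <- names(cand)[ord[1]]
  is_peak <- winner == "peak"
  peak_fit <- fits[[peak_variant]]
  if (achieved < margin)
    return(transform(unclass_row("margin not met"),
                     logZ_linear = cand[["linear"]], logZ_decay = cand[["decay"]],
                     logZ_dip = cand[["dip"]], logZ_peak = cand[["peak"]],
                     decision_margin = achieved))
  data.frame(model = winner,
             variant = if (is_peak) sub("peak_", "", peak_variant) else NA_character_,
             logZ_linear = cand[["linear"]], logZ_decay = cand[["decay"]],
             logZ_dip = cand[["dip"]], logZ_peak = cand[["peak"]],
             decision_margin = achieved,
             tp_mean = if (is_peak) peak_fit$tp_mean else NA_real_,
             tp_sd = if (is_peak) peak_fit$tp_sd else NA_real_,
             reason = NA_character_, stringsAsFactors = FALSE)
}

fit_all_models <- function(series, specs, noise_sd, n_live, seed, n_steps = 30L) {
  stats::setNames(lapply(names(specs), function(m)
    nested_sampling_logZ(specs[[m]], series, noise_sd, n_live = n_live,
                         seed = derive_seed(seed, series$dataset_id,
                                            series$tss_id, m),
                         n_steps = n_steps)),
    names(specs))
}

#' Classify every TSS in a dataset bundle
#'
#' Normalizes each time course (constant median trajectories are flagged
#' unclassifiable), estimates its replicate noise, fits all models by nested
#' sampling and applies the offset-corrected decision. Peak winners carry
#' posterior `t_p` (minutes) and the log2 fold change on the original TPM
#' scale, `log2((p1 + p2) / max(p1, fc_floor))`, computed from the posterior
#' parameter means mapped back through the normalization anchors.
#'
#' @param bundle a TPM-filtered [dataset_bundle()].
#' @param offsets a [calibrate_offsets()] object.
#' @param margin decision margin in natural-log units.
#' @param n_live,n_steps nested-sampling settings.
#' @param seed run-level seed; per-series/model seeds are derived from it.
#' @param fc_floor TPM floor for the fold-change baseline.
#' @param slow_factor rate scaling of the slow peak variant.
#' @return data frame with one row per TSS: identities, winning `model`,
#'   corrected log Z values, `tp_mean`, `tp_sd`, `log2_fc`, `reason`.
#' @export
classify_dataset <- function(bundle, offsets, margin = 1, n_live = 200,
                             seed = 1, fc_floor = 0.5, slow_factor = 10,
                             n_steps = 30L) {
  stopifnot(inherits(bundle, "DatasetBundle"))
  if (!length(bundle$timecourses)) {
    out <- classify_tss(list(), offsets, margin)[0, ]
    return(cbind(data.frame(dataset_id = character(), tss_id = character(),
                            gene_id = character(), biotype = character(),
                            stringsAsFactors = FALSE),
                 out, data.frame(log2_fc = numeric())))
  }
  t_max <- max(bundle$timecourses[[1]]$times)
  specs <- kinetic_model_set(t_max, slow_factor)
  rows <- lapply(bundle$timecourses, function(tc) {
    series <- normalize_series(tc)
    id <- data.frame(dataset_id = tc$dataset_id, tss_id = tc$tss_id,
                     gene_id = tc$gene_id, biotype = tc$biotype,
                     stringsAsFactors = FALSE)
    if (series$degenerate) {
      rec <- classify_tss(list(), offsets, margin)
      rec$reason <- "degenerate: constant median trajectory"
      return(cbind(id, rec, data.frame(log2_fc = NA_real_)))
    }
    sd_fit <- estimate_noise_sd(series)
    fits <- fit_all_models(series, specs, sd_fit, n_live, seed,
                           n_steps = n_steps)
    rec <- classify_tss(fits, offsets, margin)
    log2_fc <- NA_real_
    if (identical(rec$model, "peak")) {
      variant <- paste0("peak_", rec$variant)
      post <- fits[[variant]]$post
      p1n <- post$mean[post$parameter == "p1"]
      p2n <- post$mean[post$parameter == "p2"]
      p1 <- max(denormalize(p1n, series), 0)
      peak_tpm <- max(denormalize(p1n + p2n, series), 0)
      log2_fc <- fold_change(p1, max(peak_tpm - p1, 0), floor = fc_floor)
    }
    cbind(id, rec, data.frame(log2_fc = log2_fc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
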