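#' Kinetic signature specification
#'
#' Defines one of the four kinetic signatures (plus an internal constant
#' model used to validate the evidence computation) together with its
#' parameter names and uniform prior ranges on the normalized 0--10
#' expression scale. Priors follow the package defaults: baselines and
#' amplitudes live on the normalized scale, delays and durations are bounded
#' by the span of the sampling window, and rate constants span
#' `[1e-3, 1]` per minute (scaled down by `slow_factor` for the slow peak
#' variant, which models transcripts peaking later in time).
#'
#' @param name one of `"linear"`, `"decay"`, `"dip"`, `"peak"`, `"const"`.
#' @param t_max last sampling time (minutes); bounds the delay/duration
#'   priors.
#' @param variant `"fast"` or `"slow"`; only meaningful for the peak model.
#' @param slow_factor factor by which the slow peak variant's rate priors are
#'   scaled down (default 10).
#' @return an object of class `ModelSpec` with fields `name`, `variant`,
#'   `code` (internal integer), `par_names`, `lower`, `upper`.
#' @export
model_spec <- function(name, t_max, variant = "fast", slow_factor = 10) {
  name <- match.arg(name, c("linear", "decay", "dip", "peak", "const"))
  variant <- match.arg(variant, c("fast", "slow"))
  stopifnot(t_max > 0, slow_factor >= 1)
  rate_lo <- 1e-3; rate_hi <- 1
  if (name == "peak" && variant == "slow") {
    rate_lo <- rate_lo / slow_factor
    rate_hi <- rate_hi / slow_factor
  }
  def <- switch(name,
    const = list(code = 0L, par = "level", lo = 0, hi = 10),
    linear = list(code = 1L, par = c("intercept", "slope"),
                  lo = c(0, -10 / t_max), hi = c(10, 10 / t_max)),
    decay = list(code = 2L, par = c("base", "amp", "k"),
                 lo = c(0, 0.1, rate_lo), hi = c(10, 10, rate_hi)),
    dip = list(code = 3L, par = c("base", "depth", "k", "ratio"),
               lo = c(0, 0.1, rate_lo, 0.05), hi = c(10, 10, rate_hi, 0.95)),
    peak = list(code = 4L, par = c("p1", "p2", "td", "ts", "r_rise", "r_fall"),
                lo = c(0, 0.1, 0, 1, rate_lo, rate_lo),
                hi = c(10, 10, 0.8 * t_max, t_max, rate_hi, rate_hi)))
  structure(list(name = name, variant = if (name == "peak") variant else "none",
                 code = def$code,
                 par_names = def$par,
                 lower = stats::setNames(def$lo, def$par),
                 upper = stats::setNames(def$hi, def$par),
                 t_max = t_max),
            class = "ModelSpec")
}

#' The model set fitted to every series
#'
#' Linear, decay, dip, and both rate variants of the delayed peak model; the
#' two peak variants are collapsed to the better one at decision time.
#'
#' @inheritParams model_spec
#' @return named list of [model_spec()] objects.
#' @export
kinetic_model_set <- function(t_max, slow_factor = 10) {
  list(linear = model_spec("linear", t_max),
       decay = model_spec("decay", t_max),
       dip = model_spec("dip", t_max),
       peak_fast = model_spec("peak", t_max, "fast", slow_factor),
       peak_slow = model_spec("peak", t_max, "slow", slow_factor))
}

check_params <- function(spec, params) {
  params <- as.numeric(params)
  if (length(params) != length(spec$par_names))
    stop(sprintf("model '%s' expects %d parameters (%s)", spec$name,
                 length(spec$par_names), paste(spec$par_names, collapse = ", ")))
  out <- params < spec$lower - 1e-12 | params > spec$upper + 1e-12
  if (any(out))
    stop(sprintf("parameter(s) outside the prior range for model '%s': %s",
                 spec$name, paste(spec$par_names[out], collapse = ", ")))
  params
}

#' Evaluate a kinetic signature at given times
#'
#' The delayed peak model returns `p1` for `t <= td`, rises monotonically in
#' exponential fashion on `(td, t_p]` reaching exactly `p1 + p2` at
#' `t_p = td + ts`, and decays exponentially back toward `p1` afterwards.
#' The dip model falls to a minimum of `base - depth` and recovers; decay is
#' monotone non-increasing toward its asymptote; linear is affine in `t`.
#'
#' @param spec a [model_spec()].
#' @param params numeric parameter vector in `spec$par_names` order, within
#'   the prior ranges.
#' @param times numeric vector of times (minutes, `>= 0`).
#' @return numeric vector of normalized expression values.
#' @export
eval_model <- function(spec, params, times) {
  stopifnot(inherits(spec, "ModelSpec"), all(times >= 0))
  params <- check_params(spec, params)
  eval_model_cpp(spec$code, params, as.numeric(times))
}

#' Peak time of the delayed peak model
#'
#' @param params named vector or list with elements `td` and `ts`.
#' @return `td + ts`, minutes.
#' @export
peak_time <- function(params) {
  p <- as.list(params)
  stopifnot(!is.null(p$td), !is.null(p$ts), p$td >= 0, p$ts > 0)
  as.numeric(p$td) + as.numeric(p$ts)
}

#' Log2 fold change of a peak on the original TPM scale
#'
#' `log2((p1 + p2) / max(p1, floor))`, with `p1`, `p2` already mapped back
#' to the original TPM scale; the floor guards against vanishing baselines.
#'
#' @param p1 baseline expression at time zero (TPM).
#' @param p2 increase in expression at the time of peaking (TPM).
#' @param floor strictly positive baseline floor (TPM).
#' @return log2 fold change.
#' @export
fold_change <- function(p1, p2, floor = 0.5) {
  stopifnot(floor > 0, p1 >= 0, p2 >= 0)
  log2((p1 + p2) / max(p1, floor))
}

#' Normalize a time course to the 0--10 scale
#'
#' Computes the per-time median trajectory across replicates and applies to
#' all replicates the affine map sending the median trajectory's minimum to
#' 0 and its maximum to 10. The anchors are stored so reported magnitudes
#' can be mapped back to TPM with [denormalize()].
#'
#' @param tc a [time_course()].
#' @return an object of class `NormalizedSeries` with fields `values`
#'   (replicates x times matrix), `times`, `anchor_min`, `anchor_max`,
#'   `degenerate` (TRUE when the median trajectory is constant, in which case
#'   the series is unclassifiable and `values` is unscaled), and the identity
#'   fields of the input.
#' @export
normalize_series <- function(tc) {
  stopifnot(inherits(tc, "TimeCourse"))
  med <- col_medians(tc$expr)
  lo <- min(med); hi <- max(med)
  degenerate <- (hi - lo) <= 0
  values <- if (degenerate) tc$expr else (tc$expr - lo) * 10 / (hi - lo)
  structure(list(tss_id = tc$tss_id, gene_id = tc$gene_id,
                 biotype = tc$biotype, dataset_id = tc$dataset_id,
                 times = tc$times, values = values,
                 anchor_min = lo, anchor_max = hi,
                 degenerate = degenerate),
            class = "NormalizedSeries")
}

#' Map normalized values back to the original TPM scale
#'
#' @param x numeric values on the normalized 0--10 scale.
#' @param series the [normalize_series()] object holding the anchors.
#' @return values on the original TPM scale.
#' @export
denormalize <- function(x, series) {
  stopifnot(inherits(series, "NormalizedSeries"))
  series$anchor_min + x * (series$anchor_max - series$anchor_min) / 10
}

# Bare normalized series constructor used by the synthetic generator: values
# are already on the normalized scale, anchors default to the identity map.
normalized_series <- function(values, times, tss_id = "synthetic",
                              gene_id = "synthetic", biotype = "coding",
                              dataset_id = "synthetic",
                              anchor_min = 0, anchor_max = 10) {
  structure(list(tss_id = tss_id, gene_id = gene_id, biotype = biotype,
                 dataset_id = dataset_id, times = as.numeric(times),
                 values = as.matrix(values),
                 anchor_min = anchor_min, anchor_max = anchor_max,
                 degenerate = FALSE),
            class = "NormalizedSeries")
}
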