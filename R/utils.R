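#' Derive a reproducible sub-seed from a run seed and string labels
#'
#' All randomness in a run flows from one run-level seed; per-series and
#' per-model seeds are derived by hashing the identifying labels (FNV-1a over
#' the concatenated labels, folded with the run seed). The result is a
#' positive 31-bit integer, safe to hand to any seeded routine.
#'
#' @param seed run-level integer seed.
#' @param ... character/numeric labels identifying the unit of work
#'   (e.g. dataset id, TSS id, model name).
#' @return a single integer in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "\r")
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  h <- (h + as.numeric(seed) * 2654435761) %% (2^31 - 1)
  as.integer(h) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

col_medians <- function(m) apply(m, 2, stats::median)

`%||%` <- function(a, b) if (is.null(a)) b else a
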