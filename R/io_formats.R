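#' Construct a replicated expression time course for one TSS
#'
#' A `TimeCourse` holds the TPM values of one CAGE-defined TSS over an
#' ordered set of sampling times, with one row per replicate. Time zero is
#' the unstimulated state.
#'
#' @param tss_id,gene_id,dataset_id identifier strings.
#' @param biotype `"coding"` or `"noncoding"`.
#' @param times numeric vector of sampling times in minutes, strictly
#'   increasing, all `>= 0`.
#' @param expr numeric matrix of TPM values, one row per replicate (at least
#'   2, typically 3), one column per time; all values finite and `>= 0`.
#' @return an object of class `TimeCourse`.
#' @export
time_course <- function(tss_id, gene_id, biotype, dataset_id, times, expr) {
  biotype <- match.arg(biotype, c("coding", "noncoding"))
  times <- as.numeric(times)
  expr <- as.matrix(expr)
  if (any(diff(times) <= 0) || any(times < 0))
    stop("`times` must be strictly increasing and non-negative")
  if (ncol(expr) != length(times))
    stop("`expr` must have one column per sampling time")
  if (nrow(expr) < 2)
    stop("at least two replicates are required")
  if (anyNA(expr) || any(!is.finite(expr)))
    stop(sprintf("TSS '%s': missing or non-finite expression values", tss_id))
  if (any(expr < 0))
    stop(sprintf("TSS '%s': negative TPM values are not allowed", tss_id))
  structure(
    list(tss_id = as.character(tss_id), gene_id = as.character(gene_id),
         biotype = biotype, dataset_id = as.character(dataset_id),
         times = times, expr = expr),
    class = "TimeCourse")
}

#' Bundle the time courses of one dataset
#'
#' @param dataset_id identifier string.
#' @param timecourses list of [time_course()] objects sharing one
#'   sampling-time vector; `tss_id` must be unique within the bundle.
#' @param ieg_labels character vector of gene ids flagged as known immediate
#'   early genes.
#' @return an object of class `DatasetBundle`.
#' @export
dataset_bundle <- function(dataset_id, timecourses, ieg_labels = character()) {
  ids <- vapply(timecourses, `[[`, "", "tss_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate tss_id in dataset '%s': %s", dataset_id,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(timecourses)) {
    t0 <- timecourses[[1]]$times
    same <- vapply(timecourses, function(tc) identical(tc$times, t0), TRUE)
    if (!all(same))
      stop("all time courses in a bundle must share the sampling-time vector")
  }
  names(timecourses) <- ids
  structure(list(dataset_id = as.character(dataset_id),
                 timecourses = timecourses,
                 ieg_labels = unique(as.character(ieg_labels))),
            class = "DatasetBundle")
}

#' @export
length.DatasetBundle <- function(x) length(x$timecourses)

#' @export
print.DatasetBundle <- function(x, ...) {
  cat(sprintf("DatasetBundle '%s': %d TSSs, %d sampling times, %d IEG labels\n",
              x$dataset_id, length(x$timecourses),
              if (length(x$timecourses)) length(x$timecourses[[1]]$times) else 0L,
              length(x$ieg_labels)))
  invisible(x)
}

parse_time_rep_header <- function(cols) {
  m <- regmatches(cols, regexec("^t([0-9]+\\.?[0-9]*)_r([0-9]+)$", cols))
  bad <- cols[vapply(m, length, 0L) != 3L]
  if (length(bad))
    stop(sprintf("malformed expression column name(s): %s (expected t<minutes>_r<replicate>)",
                 paste(bad, collapse = ", ")))
  data.frame(col = cols,
             time = vapply(m, function(x) as.numeric(x[2]), 0),
             rep = vapply(m, function(x) as.integer(x[3]), 0L),
             stringsAsFactors = FALSE)
}

#' Read a tab-separated expression table as a dataset bundle
#'
#' The dialect is a TSV with header columns `tss_id`, `gene_id`, `biotype`
#' and one column per time-by-replicate measurement named `t<minutes>_r<k>`
#' (e.g. `t0_r1`, `t45_r3`). Times are parsed from the header and sorted
#' ascending; every time must carry the same set of replicates.
#'
#' @param path path to the TSV file.
#' @param dataset_id identifier to stamp on the bundle.
#' @return a [dataset_bundle()].
#' @export
read_expression_table <- function(path, dataset_id) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("tss_id", "gene_id", "biotype")
  if (!all(need %in% names(df)))
    stop(sprintf("expression table must contain columns: %s",
                 paste(need, collapse = ", ")))
  meta <- parse_time_rep_header(setdiff(names(df), need))
  meta <- meta[order(meta$time, meta$rep), ]
  times <- sort(unique(meta$time))
  reps <- sort(unique(meta$rep))
  full <- expand.grid(rep = reps, time = times)
  want <- sprintf("t%s_r%d", format(full$time, trim = TRUE, scientific = FALSE),
                  full$rep)
  if (!setequal(meta$col, unique(want)) || nrow(meta) != length(times) * length(reps))
    stop("every sampling time must carry the same replicate columns")
  tcs <- lapply(seq_len(nrow(df)), function(i) {
    expr <- matrix(NA_real_, nrow = length(reps), ncol = length(times))
    for (ri in seq_along(reps)) for (ti in seq_along(times)) {
      cn <- meta$col[meta$time == times[ti] & meta$rep == reps[ri]]
      v <- df[[cn]][i]
      if (is.na(v) || !is.numeric(v))
        stop(sprintf("row '%s', column '%s': missing or non-numeric value",
                     df$tss_id[i], cn))
      if (v < 0)
        stop(sprintf("row '%s', column '%s': negative TPM (%g)",
                     df$tss_id[i], cn, v))
      expr[ri, ti] <- v
    }
    time_course(df$tss_id[i], df$gene_id[i], df$biotype[i], dataset_id,
                times, expr)
  })
  dataset_bundle(dataset_id, tcs)
}

#' Write a dataset bundle as a tab-separated expression table
#'
#' Values are serialized at full double precision so that
#' `read_expression_table(write_expression_table(b))` is an identity on
#' values and identifiers.
#'
#' @param bundle a [dataset_bundle()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(bundle, path) {
  tcs <- bundle$timecourses
  if (!length(tcs)) stop("cannot write an empty bundle")
  times <- tcs[[1]]$times
  nrep <- nrow(tcs[[1]]$expr)
  cols <- as.vector(t(outer(seq_along(times), seq_len(nrep), function(ti, ri)
    sprintf("t%s_r%d", format(times[ti], trim = TRUE, scientific = FALSE), ri))))
  rows <- vapply(tcs, function(tc) {
    vals <- as.vector(tc$expr) # column-major: replicates within time
    paste(c(tc$tss_id, tc$gene_id, tc$biotype,
            sprintf("%.17g", vals)), collapse = "\t")
  }, "")
  header <- paste(c("tss_id", "gene_id", "biotype", cols), collapse = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Filter a bundle by biotype-specific TPM thresholds
#'
#' A TSS is retained iff its maximum TPM across all replicates and times
#' strictly exceeds the threshold for its biotype (more than 10 TPM for
#' protein-coding TSSs, more than 2 TPM for non-coding ones, by default).
#'
#' @param bundle a [dataset_bundle()].
#' @param coding_min,noncoding_min strictly positive TPM thresholds.
#' @return the filtered bundle.
#' @export
filter_by_tpm <- function(bundle, coding_min = 10, noncoding_min = 2) {
  stopifnot(coding_min > 0, noncoding_min > 0)
  keep <- vapply(bundle$timecourses, function(tc) {
    thr <- if (tc$biotype == "coding") coding_min else noncoding_min
    max(tc$expr) > thr
  }, TRUE)
  dataset_bundle(bundle$dataset_id, bundle$timecourses[keep], bundle$ieg_labels)
}

#' Load a gene label list (one id per line)
#'
#' Lines starting with `#` (and inline `#` comments) are ignored; ids are
#' deduplicated with case preserved.
#'
#' @param path path to the text file.
#' @return character vector of unique gene ids (empty, with a warning, if the
#'   file holds none).
#' @export
load_gene_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  ids <- unique(lines[nzchar(lines)])
  if (!length(ids)) warning(sprintf("no gene ids found in '%s'", path))
  ids
}
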