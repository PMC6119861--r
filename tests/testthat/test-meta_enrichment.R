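# Minimal classification-record stubs: only the columns the meta stage uses.
fake_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(dataset_id = r[[1]], tss_id = r[[2]], gene_id = r[[3]],
               biotype = r[[4]] %||% "coding", model = r[[5]],
               tp_mean = if (length(r) > 5) r[[6]] else NA_real_,
               stringsAsFactors = FALSE)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("gene peak tables aggregate indicators, counts and earliest t_p", {
  recs <- fake_records(
    list("D1", "t1", "gA", "coding", "peak", 35),
    list("D1", "t2", "gA", "coding", "peak", 60),
    list("D2", "t1", "gA", "coding", "peak", 50),
    list("D1", "t3", "gB", "coding", "linear"),
    list("D2", "t3", "gB", "coding", "peak", 120))
  tab <- build_gene_peak_table(recs)
  expect_equal(sort(tab$genes$gene_id), c("gA", "gB"))
  gA <- tab$genes[tab$genes$gene_id == "gA", ]
  expect_equal(gA$n_datasets_peak, 2L)
  cellA1 <- tab$cells[tab$cells$gene_id == "gA" & tab$cells$dataset_id == "D1", ]
  expect_equal(cellA1$n_peak_tss, 2L)
  expect_equal(cellA1$earliest_tp, 35) # min rule over the gene's TSSs
  cellB1 <- tab$cells[tab$cells$gene_id == "gB" & tab$cells$dataset_id == "D1", ]
  expect_false(cellB1$peak)
  expect_true(is.na(cellB1$earliest_tp))

  m <- peak_time_matrix(tab)
  expect_equal(m["gA", "D1"], 35)
  expect_true(is.na(m["gB", "D1"]))

  expect_error(build_gene_peak_table(recs[recs$dataset_id == "D1", ]),
               "at least two datasets")
})

test_that("shared sets respect the quorum and nest monotonically", {
  set.seed(23)
  datasets <- paste0("D", 1:8)
  recs <- do.call(rbind, lapply(1:40, function(g) {
    in_ds <- sample(datasets, sample(0:8, 1))
    if (!length(in_ds)) in_ds <- character()
    out_ds <- setdiff(datasets, in_ds)
    rbind(
      if (length(in_ds))
        data.frame(dataset_id = in_ds, tss_id = sprintf("g%02d_p1", g),
                   gene_id = sprintf("g%02d", g), biotype = "coding",
                   model = "peak", tp_mean = runif(length(in_ds), 10, 250)),
      if (length(out_ds))
        data.frame(dataset_id = out_ds,
                   tss_id = sprintf("g%02d_p1", g),
                   gene_id = sprintf("g%02d", g), biotype = "coding",
                   model = "linear", tp_mean = NA_real_))
  }))
  tab <- build_gene_peak_table(recs)
  truth <- tapply(recs$model == "peak", recs$gene_id, sum)
  expect_equal(tab$genes$n_datasets_peak[match(names(truth), tab$genes$gene_id)],
               unname(as.integer(truth)))
  sizes <- vapply(1:8, function(k) length(shared_set(tab, k)), 0L)
  expect_true(all(diff(sizes) <= 0))
  for (k in 1:7)
    expect_true(all(shared_set(tab, k + 1) %in% shared_set(tab, k)))
  expect_setequal(shared_set(tab, 1),
                  tab$genes$gene_id[tab$genes$n_datasets_peak >= 1])
})

test_that("Fisher enrichment reproduces closed cases and the enumeration oracle", {
  # equal proportions inside and outside -> OR 1, p 1
  r <- ieg_enrichment(100, 10, 1000, 100)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)

  # small table vs exhaustive hypergeometric tail enumeration
  r2 <- ieg_enrichment(10, 3, 100, 8)   # a=3 b=7 c=5 d=85
  expect_equal(r2$odds_ratio, (3 * 85) / (7 * 5))
  expect_equal(r2$p_value, fisher_p_enum(3, 7, 5, 85), tolerance = 1e-10)

  # zero cell engages the continuity note
  r3 <- ieg_enrichment(5, 5, 50, 10)
  expect_true(r3$continuity)
  expect_true(is.finite(r3$odds_ratio))

  expect_error(ieg_enrichment(10, 11, 100, 20), "inconsistent")
})

test_that("per-dataset class enrichment recovers a planted enrichment", {
  set.seed(41)
  n <- 400
  ieg <- paste0("g", sample(n, 60))
  recs <- do.call(rbind, lapply(1:n, function(g) {
    gene <- paste0("g", g)
    is_ieg <- gene %in% ieg
    # IEGs peak with 5x the odds of non-IEGs
    p_peak <- if (is_ieg) 0.625 else 0.25
    data.frame(dataset_id = "D1", tss_id = paste0(gene, "_p1"), gene_id = gene,
               biotype = "coding",
               model = if (runif(1) < p_peak) "peak" else "linear",
               tp_mean = NA_real_, stringsAsFactors = FALSE)
  }))
  enr <- per_dataset_class_enrichment(recs, ieg)
  peak_row <- enr[enr$class == "peak", ]
  # odds ratio of 5 planted: (0.625/0.375)/(0.25/0.75) = 5
  expect_gt(peak_row$odds_ratio, 2)
  expect_lt(peak_row$p_value, 0.01)
  lin_row <- enr[enr$class == "linear", ]
  expect_lt(lin_row$odds_ratio, 1)
})

test_that("the published enrichment counts reproduce their printed ORs", {
  ref <- reference_shared_enrichment()
  all_row <- ref[ref$shared_datasets == "1-8", ]
  for (i in which(!is.na(ref$odds_ratio))) {
    r <- ieg_enrichment(ref$n_tss[i], ref$n_ieg_tss[i],
                        all_row$n_tss, all_row$n_ieg_tss)
    expect_equal(r$odds_ratio, ref$odds_ratio[i], tolerance = 0.1 / ref$odds_ratio[i])
  }
})
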