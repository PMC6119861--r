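test_that("calibration series follow the plus/minus offset scheme", {
  spec <- model_spec("decay", t_max = 300)
  s0 <- generate_calibration_series(spec, 0, seed = 3, times = grid12)
  expect_equal(s0$values[1, ], s0$values[2, ])
  expect_equal(s0$values[1, ], s0$values[3, ])

  s <- generate_calibration_series(spec, 0.4, seed = 3, times = grid12)
  spread <- apply(s$values, 2, function(col) max(col) - min(col))
  expect_equal(spread, rep(0.8, length(grid12)))
  # replicate 1 is the exact trajectory of the attached parameters
  expect_equal(s$values[1, ],
               eval_model(spec, attr(s, "params"), grid12))

  # the span constraint is honored
  s8 <- generate_calibration_series(spec, 0.2, seed = 5, times = grid12,
                                    min_range = 8)
  expect_gte(max(s8$values[1, ]) - min(s8$values[1, ]), 8)

  # determinism
  a <- generate_calibration_series(spec, 0.2, seed = 11, times = grid12)
  b <- generate_calibration_series(spec, 0.2, seed = 11, times = grid12)
  expect_identical(a$values, b$values)
})

test_that("cohort generation is deterministic and self-consistent", {
  cfg <- synthetic_config(n_datasets = 3, n_genes_coding = 30,
                          n_genes_noncoding = 6, ordering_n_genes = 5,
                          ordering_jitter_sd = 0, noise_sd = 0.2, seed = 99)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(co1, d1)
  write_cohort(co2, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)

  # truth and emitted tables agree: recomputed max TPM matches bookkeeping
  rec <- co1$truth$records
  for (i in sample(nrow(rec), 20)) {
    tc <- co1$bundles[[rec$dataset_id[i]]]$timecourses[[rec$tss_id[i]]]
    expect_equal(max(tc$expr), rec$max_tpm[i])
  }

  # with zero jitter the planted ranks are reproduced in every dataset
  m <- truth_peak_time_matrix(co1)
  expect_equal(nrow(m), 5)
  for (d in seq_len(ncol(m)))
    expect_equal(order(m[, d]), 1:5)

  # round-trip through the TSV dialect preserves the tables
  b <- co1$bundles[[1]]
  rt <- read_expression_table(file.path(d1, sprintf("expression_%s.tsv",
                                                    b$dataset_id)),
                              b$dataset_id)
  expect_identical(names(rt$timecourses), names(b$timecourses))
  id <- sample(names(b$timecourses), 1)
  expect_identical(unname(rt$timecourses[[id]]$expr),
                   unname(b$timecourses[[id]]$expr))
})

test_that("class mixture fractions converge to the configuration", {
  cfg <- synthetic_config(n_datasets = 2, n_genes_coding = 400,
                          n_genes_noncoding = 100, ordering_n_genes = 0,
                          seed = 5)
  co <- generate_cohort(cfg)
  frac <- table(co$truth$genes$class_base) / 500
  for (cl in names(cfg$class_mix)) {
    tol <- 3 * sqrt(cfg$class_mix[[cl]] * (1 - cfg$class_mix[[cl]]) / 500)
    expect_lt(abs(frac[[cl]] - cfg$class_mix[[cl]]), tol + 1e-9)
  }

  # planted IEG labels are enriched among peak-class genes
  g <- co$truth$genes
  peak_rate <- mean(g$ieg[g$class_base == "peak"])
  other_rate <- mean(g$ieg[g$class_base != "peak"])
  expect_gt(peak_rate, other_rate)
})

test_that("planted cohort survives TPM filtering and downstream aggregation", {
  cfg <- synthetic_config(n_datasets = 4, n_genes_coding = 25,
                          n_genes_noncoding = 5, ordering_n_genes = 6,
                          ordering_jitter_sd = 2, seed = 31)
  co <- generate_cohort(cfg)
  # every planted trajectory was anchored above its biotype threshold
  for (b in co$bundles)
    expect_equal(length(filter_by_tpm(b)), length(b))

  # ground-truth-based records feed the meta stage coherently
  rec <- co$truth$records
  rec$model <- rec$class
  rec$tp_mean <- rec$tp_true
  tab <- build_gene_peak_table(rec)
  roster <- co$truth$genes$gene_id[!is.na(co$truth$genes$order_rank)]
  expect_true(all(roster %in% shared_set(tab, 4)))
  m <- peak_time_matrix(tab, roster)
  expect_equal(unname(m), unname(truth_peak_time_matrix(co)))
})
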