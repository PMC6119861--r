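fake_fit <- function(logZ, model = "x", tp_mean = 50, tp_sd = 5) {
  structure(list(model = model, variant = "none", logZ = logZ,
                 logZ_err = 0.1, converged = TRUE,
                 post = data.frame(parameter = "p", mean = 1, sd = 0.1),
                 tp_mean = tp_mean, tp_sd = tp_sd),
            class = "ModelFit")
}
zero_off <- c(decay = 0, dip = 0, peak_fast = 0, peak_slow = 0)

test_that("the decision rule picks clear winners and respects the margin", {
  fits <- list(linear = fake_fit(-10), decay = fake_fit(-12),
               dip = fake_fit(-15), peak_fast = fake_fit(-3, tp_mean = 42),
               peak_slow = fake_fit(-9))
  rec <- classify_tss(fits, zero_off, margin = 1)
  expect_equal(rec$model, "peak")
  expect_equal(rec$variant, "fast")
  expect_equal(rec$tp_mean, 42)
  expect_equal(rec$decision_margin, 7)

  # margin not met -> unclassified, corrected values still reported
  fits2 <- list(linear = fake_fit(-5.0), decay = fake_fit(-30),
                dip = fake_fit(-30), peak_fast = fake_fit(-4.6),
                peak_slow = fake_fit(-30))
  rec2 <- classify_tss(fits2, zero_off, margin = 1)
  expect_equal(rec2$model, "unclassified")
  expect_equal(rec2$reason, "margin not met")
  expect_true(is.na(rec2$tp_mean))
  expect_equal(rec2$logZ_peak, -4.6)

  # offsets are applied to the complex models only, at decision time
  off <- c(decay = 2, dip = 3, peak_fast = 8, peak_slow = 4)
  rec3 <- classify_tss(fits, off, margin = 1)
  expect_equal(rec3$logZ_linear, -10)
  expect_equal(rec3$logZ_decay, -14)
  # slow peak variant (-9 - 4 = -13) beats fast (-3 - 8 = -11)? no: -11 > -13
  expect_equal(rec3$logZ_peak, -11)

  # a missing or unconverged fit yields an explained unclassified record
  bad <- fits
  bad$dip$converged <- FALSE
  rec4 <- classify_tss(bad, zero_off, margin = 1)
  expect_equal(rec4$model, "unclassified")
  expect_match(rec4$reason, "dip")
})

test_that("calibration offsets are seeded, reproducible and resampling-stable", {
  times <- grid12
  o1 <- calibrate_offsets(times, 0.3, n_per_model = 12, n_live = 60, seed = 7)
  o2 <- calibrate_offsets(times, 0.3, n_per_model = 12, n_live = 60, seed = 7)
  expect_identical(o1$offsets, o2$offsets)
  expect_identical(o1$table, o2$table)
  expect_true(all(is.finite(o1$offsets)))

  # offsets are recomputable from the stored calibration table
  adv <- o1$table$peak_fast - o1$table$linear
  expect_equal(o1$offsets[["peak_fast"]], mean(adv) + 2 * sd(adv))

  # JSON round trip preserves offsets and provenance
  p <- withr::local_tempfile(fileext = ".json")
  write_offsets(o1, p)
  o3 <- read_offsets(p)
  expect_equal(o3$offsets, o1$offsets)
  expect_equal(o3$n_per_model, o1$n_per_model)
})

test_that("classification is invariant to replicate and TSS ordering", {
  times <- grid12
  spec <- model_spec("peak", t_max = 300)
  s <- generate_calibration_series(
    spec, 0.3, seed = 2, times = times,
    params = c(p1 = 0.5, p2 = 8, td = 15, ts = 45, r_rise = 0.1,
               r_fall = 0.03))
  tpm <- 2 + 4 * s$values # to the TPM scale, max > 10
  tc1 <- time_course("t1", "g1", "coding", "DS", times, tpm)
  tc1_shuffled <- time_course("t1", "g1", "coding", "DS", times,
                              tpm[c(3, 1, 2), ])
  off <- structure(list(offsets = c(decay = 2, dip = 2, peak_fast = 5,
                                    peak_slow = 3)),
                   class = "CalibrationOffsets")
  b1 <- dataset_bundle("DS", list(tc1))
  b2 <- dataset_bundle("DS", list(tc1_shuffled))
  r1 <- classify_dataset(b1, off, n_live = 80, seed = 5)
  r2 <- classify_dataset(b2, off, n_live = 80, seed = 5)
  expect_equal(r1$model, "peak")
  expect_equal(r2$model, r1$model)
  expect_equal(r2$tp_mean, r1$tp_mean, tolerance = 0.2)

  # a degenerate (constant) series is unclassifiable with a reason
  flat <- time_course("t2", "g2", "coding", "DS", times,
                      matrix(20, 3, length(times)))
  rf <- classify_dataset(dataset_bundle("DS", list(flat)), off, n_live = 80)
  expect_equal(rf$model, "unclassified")
  expect_match(rf$reason, "degenerate")

  # empty bundles classify to an empty record set
  empty <- dataset_bundle("DS", list())
  expect_equal(nrow(classify_dataset(empty, off)), 0)
})

test_that("clear synthetic signals recover their generating model", {
  times <- grid12
  specs <- kinetic_model_set(300)
  off <- calibrate_offsets(times, 0.25, n_per_model = 15, n_live = 80,
                           seed = 3)
  cases <- list(
    decay = c(base = 0.5, amp = 9, k = 0.03),
    dip = c(base = 9, depth = 8, k = 0.08, ratio = 0.3),
    peak_fast = c(p1 = 0.5, p2 = 9, td = 20, ts = 40, r_rise = 0.08,
                  r_fall = 0.02),
    linear = c(intercept = 0.2, slope = 0.03))
  for (m in names(cases)) {
    s <- generate_calibration_series(specs[[m]], 0.25, seed = 4,
                                     times = times, params = cases[[m]])
    fits <- promkin:::fit_all_models(s, specs, estimate_noise_sd(s),
                                     n_live = 100, seed = 9)
    rec <- classify_tss(fits, off, margin = 1)
    expect_equal(rec$model, sub("_fast", "", m), label = m)
  }
})
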