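# The 30-item feature set: interval arithmetic, cardiac axis, recovery of
# programmed generator parameters, and invariances.

test_that("beat intervals follow the index arithmetic and telescoping identity", {
  ann <- beat_annotations(q = c(100, 1100), r = c(140, 1140),
                          s = c(180, 1180))
  iv <- beat_intervals(ann, 1000)
  expect_equal(iv$rr, c(1000, NA))
  expect_equal(iv$qr, c(40, 40))
  expect_equal(iv$rs, c(40, 40))
  expect_equal(iv$qs, c(80, 80))
  # telescoping on an uneven synthetic delineation
  e <- quick_record(duration = 8, fs = 500)
  iv2 <- beat_intervals(e$annotations, 500)
  expect_equal(iv2$qs, iv2$qr + iv2$rs)
  expect_true(all(iv2$rr > 0, na.rm = TRUE))
  expect_error(beat_intervals(beat_annotations(integer(0), integer(0),
                                               integer(0)), 500), "beat")
})

test_that("uniform R spacing gives the exact RR mean", {
  ann <- beat_annotations(q = c(90, 1090, 2090), r = c(100, 1100, 2100),
                          s = c(110, 1110, 2110))
  expect_equal(beat_intervals(ann, 1000)$rr[1:2], c(1000, 1000))
})

test_that("cardiac axis follows the frontal-plane convention", {
  expect_equal(cardiac_axis(1, 0), 0)
  expect_equal(cardiac_axis(0, 1), 90)
  expect_equal(cardiac_axis(1, 1), 45)
  expect_equal(cardiac_axis(-1, 0), 180)
  expect_equal(cardiac_axis(0, -1), -90)
  expect_error(cardiac_axis(0, 0), "undefined")
})

test_that("feature vector has the canonical 30 entries in order", {
  e <- quick_record(duration = 8, fs = 500)
  fv <- extract_features(e$record, e$annotations)
  expect_length(fv, 30)
  expect_identical(names(fv), feature_names())
  expect_equal(which(names(fv) == "axis_mean"), 5L)
  expect_equal(which(names(fv) == "axis_var"), 13L)
  expect_true(all(fv[grepl("_var$", names(fv))] >= 0))
})

test_that("zero-dispersion records yield exactly zero variance features", {
  e <- quick_record(duration = 10, fs = 1000, hr = 60, seed = 3,
                    params = list(rr_mean_ms = 1000, rr_cv = 0,
                                  stage_jitter_sd = 0, amp_jitter_sd = 0,
                                  qs_jitter_sd_ms = 0, frac_jitter = 0,
                                  axis_jitter_sd = 0))
  fv <- extract_features(e$record, e$annotations)
  expect_equal(unname(fv["di_rr_mean"]), 1000)
  vars <- fv[grepl("_var$", names(fv)) | names(fv) == "axis_var"]
  expect_true(all(vars == 0))
})

test_that("programmed axis angles are recovered within 5 degrees", {
  for (ax in c(-30, 0, 45, 90)) {
    e <- quick_record(duration = 15, fs = 500, seed = 17,
                      params = list(axis_deg = ax))
    fv <- extract_features(e$record, e$annotations)
    expect_lt(abs(fv[["axis_mean"]] - ax), 5)
  }
})

test_that("scaling both leads leaves ratios and axis unchanged and scales amplitudes", {
  e <- quick_record(duration = 8, fs = 500, seed = 19)
  fv <- extract_features(e$record, e$annotations)
  scaled <- e$record
  scaled$samples <- scaled$samples * 3
  fs <- extract_features(scaled, e$annotations)
  for (nm in c("di_rq_ratio_mean", "di_rs_ratio_mean", "axis_mean",
               "avf_rq_ratio_mean")) {
    expect_equal(fs[[nm]], fv[[nm]], tolerance = 1e-10)
  }
  expect_equal(fs[["di_r_amp_mean"]], 3 * fv[["di_r_amp_mean"]],
               tolerance = 1e-10)
})

test_that("extracted mean RR correlates above 0.99 with the programmed value over 50 subjects", {
  sp <- cohort_spec(n_ms = 25, n_control = 25, stages = "basal",
                    duration = 60, sample_rate = 250,
                    effects = null_effects(), seed = 23)
  co <- generate_cohort(sp)
  feats <- cohort_features(co, use_truth = TRUE)
  prog <- co$truth$rr_mean_ms[match(feats$subject_id, co$truth$subject_id)]
  expect_gt(cor(feats$di_rr_mean, prog), 0.99)
})

test_that("feature extraction validates its inputs", {
  e <- quick_record(duration = 4, fs = 250)
  one <- beat_annotations(q = 10, r = 20, s = 30)
  expect_error(extract_features(e$record, one), "2 valid beats")
  noavf <- e$record
  noavf$samples <- noavf$samples[1, , drop = FALSE]
  noavf$lead_names <- "I"
  expect_error(extract_features(noavf, e$annotations), "aVF")
})

test_that("abs_ratios flag flips ratio signs only", {
  e <- quick_record(duration = 8, fs = 500)
  signed <- extract_features(e$record, e$annotations)
  absd <- extract_features(e$record, e$annotations, abs_ratios = TRUE)
  expect_lt(signed[["di_rq_ratio_mean"]], 0)   # Q is a trough
  expect_gt(absd[["di_rq_ratio_mean"]], 0)
  expect_equal(absd[["di_rr_mean"]], signed[["di_rr_mean"]])
})
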