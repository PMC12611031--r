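# Synthetic ECG cohort generator: determinism, beat placement, axis
# projection, SNR contracts and programmed group effects.

test_that("identical spec and seed give bit-identical records and cohorts", {
  spec <- cohort_spec(duration = 6, sample_rate = 250, seed = 11)
  a <- generate_record(spec, "S01", "control", "basal")
  b <- generate_record(spec, "S01", "control", "basal")
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$annotations, b$annotations)

  small <- cohort_spec(n_ms = 2, n_control = 2, stages = c("basal", "60min"),
                       duration = 5, sample_rate = 250, seed = 3)
  c1 <- generate_cohort(small)
  c2 <- generate_cohort(small)
  expect_identical(lapply(c1$records, function(e) e$record$samples),
                   lapply(c2$records, function(e) e$record$samples))
  expect_identical(c1$truth, c2$truth)
  # generation order does not matter: a single record regenerated alone
  # matches its in-cohort twin
  solo <- generate_record(small, "MS02", "ms", "60min")
  twin <- Filter(function(e) e$record$subject_id == "MS02" &&
                   e$record$stage == "60min", c1$records)[[1]]
  expect_identical(solo$record$samples, twin$record$samples)
})

test_that("beat count follows the programmed heart rate", {
  e <- quick_record(duration = 10, fs = 500, hr = 60, seed = 1,
                    params = list(rr_mean_ms = 1000))
  expect_gte(n_beats(e$annotations), 9)
  expect_lte(n_beats(e$annotations), 11)
})

test_that("axis projection: 0 degrees puts the QRS on lead I only", {
  e <- quick_record(params = list(axis_deg = 0, axis_jitter_sd = 0))
  expect_lt(max(abs(ecg_lead(e$record, "aVF"))), 1e-12)
  expect_gt(max(ecg_lead(e$record, "I")), 0.5)
  # and 90 degrees the other way around
  e90 <- quick_record(params = list(axis_deg = 90, axis_jitter_sd = 0))
  expect_lt(max(abs(ecg_lead(e90$record, "I"))), 1e-12)
  expect_gt(max(ecg_lead(e90$record, "aVF")), 0.5)
})

test_that("annotations mark true extrema: r_idx is the lead-I maximum within +-50 ms", {
  e <- quick_record(duration = 8, fs = 500)
  x <- ecg_lead(e$record, "I")
  half <- round(0.05 * 500)
  for (r in e$annotations$r) {
    lo <- max(1, r - half); hi <- min(length(x), r + half)
    expect_equal(which.max(x[lo:hi]) + lo - 1L, r)
  }
})

test_that("additive noise hits the requested SNR within 0.1 dB", {
  e <- quick_record(duration = 8, fs = 500)
  for (snr in c(60, 24, 12)) {
    nz <- add_noise(e$record, snr, "gaussian", seed = 5)
    expect_false(identical(nz$samples, e$record$samples))
    got <- measure_snr(e$record, nz)
    expect_true(all(abs(got - snr) <= 0.1))
  }
  for (kind in c("baseline_wander", "em_artifact")) {
    nz <- add_noise(e$record, 24, kind, seed = 5)
    expect_true(all(abs(measure_snr(e$record, nz) - 24) <= 0.1))
  }
  # determinism and degenerate inputs
  n1 <- add_noise(e$record, 24, "gaussian", seed = 9)
  n2 <- add_noise(e$record, 24, "gaussian", seed = 9)
  expect_identical(n1$samples, n2$samples)
  expect_error(add_noise(e$record, Inf, "gaussian"), "finite")
  zero <- e$record; zero$samples[] <- 0
  expect_error(add_noise(zero, 24, "gaussian"), "all-zero")
})

test_that("baseline wander and EM artifact live in their frequency bands", {
  e <- quick_record(duration = 8, fs = 500)
  spec_power <- function(noise, fs, lo, hi) {
    sp <- Mod(stats::fft(noise))^2
    f <- (seq_along(noise) - 1) / length(noise) * fs
    band <- f >= lo & f <= hi & f <= fs / 2
    sum(sp[band]) / sum(sp[f <= fs / 2])
  }
  bw <- add_noise(e$record, 24, "baseline_wander", seed = 2)
  nbw <- bw$samples[1, ] - e$record$samples[1, ]
  expect_gt(spec_power(nbw, 500, 0, 1.5), 0.95)
  em <- add_noise(e$record, 24, "em_artifact", seed = 2)
  nem <- em$samples[1, ] - e$record$samples[1, ]
  expect_gt(spec_power(nem, 500, 25, 160), 0.95)
})

test_that("default cohort has 25 subjects x 5 stages and carries labels", {
  spec <- cohort_spec(duration = 4, sample_rate = 250, seed = 1)
  co <- generate_cohort(spec)
  expect_length(co$records, 125)
  expect_equal(nrow(co$truth), 125)
  expect_equal(sum(co$truth$group == "ms"), 75)
  expect_setequal(unique(co$truth$stage), OGTT_STAGES)
})

test_that("invalid labels and specs are rejected", {
  spec <- cohort_spec(duration = 4, sample_rate = 250)
  expect_error(generate_record(spec, "S1", "healthy", "basal"), "group")
  expect_error(generate_record(spec, "S1", "control", "15min"), "stage")
  expect_error(cohort_spec(n_ms = 0, n_control = 1), "n_ms")
  expect_error(group_effects(rr_cv_scale = 0))
})

test_that("raising rr_cv_scale strictly raises the extracted RR variance", {
  rrvar <- vapply(c(1, 2, 4), function(scl) {
    sp <- cohort_spec(n_ms = 10, n_control = 2, stages = "basal",
                      duration = 30, sample_rate = 250,
                      effects = group_effects(axis_shift = 0,
                                              rr_cv_scale = scl,
                                              qrs_width_scale = 1,
                                              amplitude_scale = 1),
                      seed = 7)
    f <- cohort_features(generate_cohort(sp), use_truth = TRUE)
    mean(f$di_rr_var[f$group == "ms"])
  }, numeric(1))
  expect_true(all(diff(rrvar) > 0))
})

test_that("twelve-lead mode produces axis-consistent limb leads", {
  sp <- cohort_spec(duration = 5, sample_rate = 250, twelve_lead = TRUE,
                    seed = 2)
  e <- generate_record(sp, "S01", "control", "basal",
                       params = list(axis_deg = 30, axis_jitter_sd = 0))
  expect_setequal(e$record$lead_names,
                  c("I", "II", "III", "aVR", "aVL", "aVF",
                    paste0("V", 1:6)))
  r <- e$annotations$r[3]
  # R amplitude across limb leads follows cos(axis - lead angle)
  amps <- c(ecg_lead(e$record, "I")[r], ecg_lead(e$record, "II")[r],
            ecg_lead(e$record, "aVF")[r])
  expect_equal(unname(amps / amps[1]),
               cos((30 - c(0, 60, 90)) * pi / 180) / cos(30 * pi / 180),
               tolerance = 1e-6)
})
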