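# Seeded synthetic multi-lead ECG cohort generator with beat-level ground
# truth. Beats are template-based (sums of Gaussian deflections) so the true
# Q/R/S sample positions are known exactly; the frontal-plane projection of a
# common source waveform onto leads I and aVF encodes the programmed cardiac
# axis (lead I gain = cos(axis), aVF gain = sin(axis)).

#' Programmed group-level effects for the synthetic cohort
#'
#' Multiplicative/additive contrasts applied to every metabolic-syndrome
#' subject relative to the control distribution. These are the knobs that
#' make the two groups separable; neutral values (`axis_shift = 0`, all
#' scales `1`) yield statistically indistinguishable groups.
#'
#' @param axis_shift Degrees added to the MS-group mean frontal-plane
#'   axis. The default is a leftward (negative) deviation, the direction
#'   associated with left-ventricular hypertrophy.
#' @param rr_cv_scale Factor (> 0) on the MS-group RR-interval coefficient
#'   of variation.
#' @param qrs_width_scale Factor (> 0) on the MS-group Q-R and R-S offsets.
#' @param amplitude_scale Factor (> 0) on the MS-group R amplitude.
#' @return An object of class `group_effects`.
#' @export
group_effects <- function(axis_shift = -30, rr_cv_scale = 1.8,
                          qrs_width_scale = 1.15, amplitude_scale = 1.25) {
  stopifnot(is.finite(axis_shift),
            rr_cv_scale > 0, qrs_width_scale > 0, amplitude_scale > 0)
  structure(list(axis_shift = axis_shift, rr_cv_scale = rr_cv_scale,
                 qrs_width_scale = qrs_width_scale,
                 amplitude_scale = amplitude_scale),
            class = "group_effects")
}

#' Neutral group effects (null cohort)
#'
#' Convenience constructor for a cohort with no group separation, used for
#' type-I-error calibration of the statistical screen.
#' @export
null_effects <- function() {
  group_effects(axis_shift = 0, rr_cv_scale = 1, qrs_width_scale = 1,
                amplitude_scale = 1)
}

#' Specification of a synthetic ECG cohort
#'
#' Defaults mirror the study design the generator emulates: 15 metabolic
#' syndrome and 10 control subjects, five OGTT stages, 1 kHz sampling.
#' Record duration defaults to 60 s, which gives roughly 70 beats per
#' record -- enough for stable interval statistics at desk scale.
#'
#' @param n_ms,n_control Subject counts per group (`n_ms + n_control >= 2`).
#' @param stages Subset of [OGTT_STAGES] to record per subject.
#' @param duration Record duration in seconds (> 0).
#' @param sample_rate Samples per second.
#' @param base_heart_rate Control-group mean heart rate, beats/minute.
#' @param effects A [group_effects()] object.
#' @param seed Integer master seed; everything downstream is deterministic
#'   in it.
#' @param p_wave,t_wave Include low-amplitude P/T deflections (default on,
#'   so the Q/S search must discriminate them).
#' @param twelve_lead Also synthesize the remaining limb leads and six
#'   pseudo-precordial leads (axis-consistent projections with small
#'   independent noise); only leads I and aVF carry ground-truth structure.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ms = 15, n_control = 10, stages = OGTT_STAGES,
                        duration = 60, sample_rate = 1000,
                        base_heart_rate = 70, effects = group_effects(),
                        seed = 1, p_wave = TRUE, t_wave = TRUE,
                        twelve_lead = FALSE) {
  stopifnot(n_ms >= 0, n_control >= 0, n_ms + n_control >= 2,
            duration > 0, sample_rate > 0, base_heart_rate > 0,
            inherits(effects, "group_effects"),
            is.numeric(seed), length(seed) == 1L)
  if (!all(stages %in% OGTT_STAGES) || length(stages) < 1) {
    stop("`stages` must be a non-empty subset of OGTT_STAGES")
  }
  structure(list(n_ms = as.integer(n_ms), n_control = as.integer(n_control),
                 stages = stages, duration = duration,
                 sample_rate = sample_rate,
                 base_heart_rate = base_heart_rate, effects = effects,
                 seed = as.integer(seed), p_wave = isTRUE(p_wave),
                 t_wave = isTRUE(t_wave), twelve_lead = isTRUE(twelve_lead)),
            class = "cohort_spec")
}

# Deterministic 31-bit stream seed from the master seed and string tags, so
# every (subject, stage) record draws from its own reproducible stream
# regardless of generation order.
.mix_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (tok in unlist(list(...))) {
    for (code in utf8ToInt(as.character(tok))) {
      h <- (h * 31 + code) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

.rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

# Per-subject physiological parameters; constant across that subject's
# stages. Group effects are applied here.
.subject_params <- function(spec, subject_id, group) {
  .with_seed(.mix_seed(spec$seed, "subject", subject_id), {
    p <- list(
      axis_deg  = stats::rnorm(1, 40, 10),
      rr_mean_ms = 60000 / spec$base_heart_rate * exp(stats::rnorm(1, 0, 0.08)),
      rr_cv     = 0.05 * exp(stats::rnorm(1, 0, 0.2)),
      r_amp_mv  = .rtrunc_norm(1, 1.0, 0.1, lo = 0.5),
      qr_ms     = .rtrunc_norm(1, 40, 3, lo = 25),
      rs_ms     = .rtrunc_norm(1, 40, 3, lo = 25),
      q_frac    = .rtrunc_norm(1, 0.15, 0.02, lo = 0.05, hi = 0.30),
      s_frac    = .rtrunc_norm(1, 0.20, 0.03, lo = 0.08, hi = 0.35),
      stage_jitter_sd = 0.005,     # per-record heart-rate jitter
      amp_jitter_sd = 0.02,        # per-beat overall amplitude jitter
      qs_jitter_sd_ms = 2,         # per-beat Q/S timing jitter
      frac_jitter = 0.05,          # per-beat relative Q/S depth jitter
      axis_jitter_sd = 3           # per-beat (respiratory) axis jitter, deg
    )
    if (group == "ms") {
      ef <- spec$effects
      p$axis_deg <- p$axis_deg + ef$axis_shift
      p$rr_cv    <- p$rr_cv * ef$rr_cv_scale
      p$qr_ms    <- p$qr_ms * ef$qrs_width_scale
      p$rs_ms    <- p$rs_ms * ef$qrs_width_scale
      p$r_amp_mv <- p$r_amp_mv * ef$amplitude_scale
    }
    p
  })
}

# Single-beat source waveform: Gaussian Q/R/S deflections plus optional P/T
# waves, sampled at `fs`. Returns the kernel and the numerically located
# extremum offsets (1-based, relative to kernel start) used as ground truth.
.beat_kernel <- function(fs, params, p_wave = TRUE, t_wave = TRUE) {
  pre_ms <- 420; post_ms <- 500
  t_ms <- seq(-pre_ms, post_ms, by = 1000 / fs)
  g <- function(amp, center, sigma) amp * exp(-0.5 * ((t_ms - center) / sigma)^2)
  k <- g(params$r_amp_mv, 0, 12) +
    g(-params$q_frac * params$r_amp_mv, -params$qr_ms, 8) +
    g(-params$s_frac * params$r_amp_mv,  params$rs_ms, 8)
  if (p_wave) k <- k + g(0.12, -180, 25)
  if (t_wave) k <- k + g(0.28 * params$r_amp_mv, 280, 45)
  r_off <- which.max(k)
  win <- round(0.1 * fs)                       # +-100 ms extremum search
  lo <- max(1, r_off - win)
  q_off <- lo - 1 + which.min(k[lo:(r_off - 1)])
  hi <- min(length(k), r_off + win)
  s_off <- r_off + which.min(k[(r_off + 1):hi])
  list(k = k, r_off = as.integer(r_off), q_off = as.integer(q_off),
       s_off = as.integer(s_off))
}

# Frontal-plane lead angles (degrees) for the six limb leads.
.LIMB_ANGLES <- c(I = 0, II = 60, III = 120, aVR = -150, aVL = -30, aVF = 90)

#' Generate one synthetic ECG record with ground-truth annotations
#'
#' Builds a record for one (subject, stage) cell of a [cohort_spec()]:
#' beats from a parameterized Q/R/S template are placed at RR intervals
#' drawn from a log-normal distribution with the subject's programmed
#' mean and coefficient of variation, then projected onto the requested
#' leads through the subject's frontal-plane axis. Annotation indices mark
#' the true template extremum positions.
#'
#' @param spec A [cohort_spec()].
#' @param subject_id Subject identifier.
#' @param group `"control"` or `"ms"`.
#' @param stage One of `spec$stages`.
#' @param params Optional named list overriding drawn subject parameters
#'   (`axis_deg`, `rr_mean_ms`, `rr_cv`, `r_amp_mv`, `qr_ms`, `rs_ms`,
#'   `q_frac`, `s_frac`, `amp_jitter_sd`); useful for programmed-value
#'   recovery tests (`rr_cv = 0, amp_jitter_sd = 0` gives a
#'   zero-dispersion record with identical, equally spaced beats).
#' @return A list with elements `record` ([ecg_record()]), `annotations`
#'   ([beat_annotations()], shared by all leads) and `params` (the subject
#'   parameters actually used).
#' @export
generate_record <- function(spec, subject_id, group, stage, params = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!group %in% c("control", "ms")) stop("invalid group label: ", group)
  if (!stage %in% OGTT_STAGES) stop("invalid stage label: ", stage)
  p <- .subject_params(spec, subject_id, group)
  if (!is.null(params)) {
    unknown <- setdiff(names(params), names(p))
    if (length(unknown)) stop("unknown parameter override(s): ",
                              paste(unknown, collapse = ", "))
    p[names(params)] <- params
  }
  fs <- spec$sample_rate
  n_samp <- round(spec$duration * fs)
  # mild stage-dependent heart-rate modulation (glucose response)
  stage_mult <- c(basal = 1, "30min" = 0.955, "60min" = 0.965,
                  "90min" = 0.98, "120min" = 0.99)[[stage]]
  .with_seed(.mix_seed(spec$seed, "record", subject_id, stage), {
    rr_stage <- p$rr_mean_ms * stage_mult *
      exp(stats::rnorm(1, 0, p$stage_jitter_sd))
    # beat-to-beat morphology variability: a small bank of kernel variants
    # with jittered Q/S timing and depth, each with exact extremum offsets
    n_var <- if (p$qs_jitter_sd_ms == 0 && p$frac_jitter == 0) 1L else 8L
    kerns <- lapply(seq_len(n_var), function(v) {
      pv <- p
      if (n_var > 1) {
        pv$qr_ms <- .rtrunc_norm(1, p$qr_ms, p$qs_jitter_sd_ms, lo = 20)
        pv$rs_ms <- .rtrunc_norm(1, p$rs_ms, p$qs_jitter_sd_ms, lo = 20)
        pv$q_frac <- p$q_frac * exp(stats::rnorm(1, 0, p$frac_jitter))
        pv$s_frac <- p$s_frac * exp(stats::rnorm(1, 0, p$frac_jitter))
      }
      .beat_kernel(fs, pv, spec$p_wave, spec$t_wave)
    })
    lk <- length(kerns[[1]]$k)
    max_beats <- ceiling(spec$duration * 1000 / rr_stage * 1.5) + 2
    if (p$rr_cv > 0) {
      sdlog <- sqrt(log(1 + p$rr_cv^2))
      mulog <- log(rr_stage) - sdlog^2 / 2
      rr_ms <- stats::rlnorm(max_beats, mulog, sdlog)
    } else {
      rr_ms <- rep(rr_stage, max_beats)
    }
    rr_samp <- round(rr_ms * fs / 1000)
    amp_jit <- stats::rnorm(max_beats, 1, p$amp_jitter_sd)
    variant <- sample.int(n_var, max_beats, replace = TRUE)
    theta_b <- (p$axis_deg +
                  stats::rnorm(max_beats, 0, p$axis_jitter_sd)) * pi / 180
    starts <- round(0.05 * fs) + 1 + c(0, cumsum(rr_samp))
    keep <- starts + lk - 1 <= n_samp
    starts <- starts[keep]
    nb <- length(starts)
    source_sig <- numeric(n_samp)           # unit-gain source (precordials)
    lead_I <- numeric(n_samp)
    lead_F <- numeric(n_samp)
    for (j in seq_len(nb)) {
      idx <- starts[j]:(starts[j] + lk - 1)
      beat <- amp_jit[j] * kerns[[variant[j]]]$k
      source_sig[idx] <- source_sig[idx] + beat
      lead_I[idx] <- lead_I[idx] + cos(theta_b[j]) * beat
      lead_F[idx] <- lead_F[idx] + sin(theta_b[j]) * beat
    }
    if (spec$twelve_lead) {
      leads <- names(.LIMB_ANGLES)
      samples <- matrix(0, nrow = 6, ncol = n_samp)
      for (j in seq_len(nb)) {
        idx <- starts[j]:(starts[j] + lk - 1)
        beat <- amp_jit[j] * kerns[[variant[j]]]$k
        gains <- cos(theta_b[j] - .LIMB_ANGLES * pi / 180)
        samples[, idx] <- samples[, idx] + outer(gains, beat)
      }
      prec_gain <- c(V1 = -0.3, V2 = 0.2, V3 = 0.6, V4 = 1.1, V5 = 1.0,
                     V6 = 0.8)
      prec <- outer(prec_gain, source_sig) +
        matrix(stats::rnorm(6 * n_samp, 0, 0.01), nrow = 6)
      samples <- rbind(samples, prec)
      leads <- c(leads, names(prec_gain))
    } else {
      leads <- c("I", "aVF")
      samples <- rbind(lead_I, lead_F)
    }
    rec <- ecg_record(samples, fs, leads, subject_id = subject_id,
                      group = group, stage = stage)
    q_off <- vapply(kerns, `[[`, 0L, "q_off")[variant[seq_len(nb)]]
    r_off <- vapply(kerns, `[[`, 0L, "r_off")[variant[seq_len(nb)]]
    s_off <- vapply(kerns, `[[`, 0L, "s_off")[variant[seq_len(nb)]]
    ann <- beat_annotations(q = starts + q_off - 1L,
                            r = starts + r_off - 1L,
                            s = starts + s_off - 1L)
    list(record = rec, annotations = ann, params = p)
  })
}

#' Add calibrated noise to an ECG record
#'
#' The noise component is scaled per lead so that the realized
#' signal-to-noise ratio `10*log10(P_signal/P_noise)` equals `snr_db`
#' exactly (the scaling uses the empirical power of the generated noise).
#'
#' @param record An [ecg_record()].
#' @param snr_db Target SNR in decibels (finite).
#' @param kind `"gaussian"` (white), `"baseline_wander"` (band-limited
#'   below 1 Hz) or `"em_artifact"` (30--150 Hz bursts).
#' @param seed Integer seed for the noise stream.
#' @return A new [ecg_record()] with noise added.
#' @export
add_noise <- function(record, snr_db,
                      kind = c("gaussian", "baseline_wander", "em_artifact"),
                      seed = 1) {
  stopifnot(inherits(record, "ecg_record"))
  kind <- match.arg(kind)
  if (!is.finite(snr_db)) stop("`snr_db` must be finite")
  x <- record$samples
  if (!all(is.finite(x))) stop("record contains non-finite samples")
  if (all(x == 0)) stop("all-zero signal: SNR is undefined")
  fs <- record$sample_rate
  n <- ncol(x)
  nyq <- fs / 2
  .with_seed(.mix_seed(seed, "noise", kind, record$subject_id, record$stage), {
    for (i in seq_len(nrow(x))) {
      p_sig <- mean(x[i, ]^2)
      if (p_sig == 0) next                     # silent lead: nothing to scale to
      nz <- stats::rnorm(n)
      if (kind == "baseline_wander") {
        bf <- signal::butter(2, min(1, 0.99 * nyq) / nyq, type = "low")
        nz <- signal::filtfilt(bf, nz)
      } else if (kind == "em_artifact") {
        band <- c(min(30, 0.5 * nyq), min(150, 0.95 * nyq)) / nyq
        bf <- signal::butter(3, band, type = "pass")
        nz <- signal::filtfilt(bf, nz)
        # burst envelope: ~0.5 bursts/s, 200 ms Gaussian bumps
        n_burst <- max(1, round(0.5 * n / fs))
        centers <- sort(stats::runif(n_burst, 1, n))
        env <- rep(0.05, n)
        tt <- seq_len(n)
        for (cb in centers) env <- env + exp(-0.5 * ((tt - cb) / (0.1 * fs))^2)
        nz <- nz * env
      }
      p_nz <- mean(nz^2)
      if (p_nz == 0) next
      target <- p_sig / 10^(snr_db / 10)
      x[i, ] <- x[i, ] + nz * sqrt(target / p_nz)
    }
  })
  out <- record
  out$samples <- x
  out
}

#' Measure the realized per-lead SNR between a clean and a noisy record
#'
#' @param clean,noisy Two [ecg_record()]s of identical shape.
#' @return Named numeric vector of SNRs in dB, one per lead (`Inf` for
#'   leads with no added noise).
#' @export
measure_snr <- function(clean, noisy) {
  stopifnot(identical(dim(clean$samples), dim(noisy$samples)))
  vapply(seq_len(nrow(clean$samples)), function(i) {
    p_sig <- mean(clean$samples[i, ]^2)
    p_nz <- mean((noisy$samples[i, ] - clean$samples[i, ])^2)
    if (p_nz == 0) return(Inf)
    10 * log10(p_sig / p_nz)
  }, numeric(1)) |> stats::setNames(clean$lead_names)
}

#' Generate a full synthetic cohort
#'
#' One record per subject per stage, with group effects applied to the
#' metabolic-syndrome subjects and per-record ground truth retained.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `ecg_cohort`: a list with `records` (list of
#'   `generate_record()` results), `truth` (data frame of programmed
#'   per-subject parameters) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- c(sprintf("MS%02d", seq_len(spec$n_ms)),
           sprintf("CT%02d", seq_len(spec$n_control)))
  groups <- rep(c("ms", "control"), c(spec$n_ms, spec$n_control))
  records <- list()
  truth <- list()
  for (i in seq_along(ids)) {
    for (stage in spec$stages) {
      entry <- generate_record(spec, ids[i], groups[i], stage)
      records[[length(records) + 1L]] <- entry
      truth[[length(truth) + 1L]] <- data.frame(
        subject_id = ids[i], group = groups[i], stage = stage,
        axis_deg = entry$params$axis_deg,
        rr_mean_ms = entry$params$rr_mean_ms,
        rr_cv = entry$params$rr_cv,
        r_amp_mv = entry$params$r_amp_mv)
    }
  }
  structure(list(records = records, truth = do.call(rbind, truth),
                 spec = spec),
            class = "ecg_cohort")
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cat(sprintf("<ecg_cohort> %d record(s): %d MS + %d control subject(s) x %d stage(s), %g s @ %g Hz\n",
              length(x$records), x$spec$n_ms, x$spec$n_control,
              length(x$spec$stages), x$spec$duration, x$spec$sample_rate))
  invisible(x)
}

#' Write a cohort to disk (CSV records + CSV annotations)
#'
#' Creates `records/<subject>_<stage>.csv` and
#' `annotations/<subject>_<stage>.csv` under `dir`.
#'
#' @param cohort An `ecg_cohort`.
#' @param dir Output directory (created if missing).
#' @param format `"csv"` or `"wfdb"` for the signal files (annotations are
#'   always CSV).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  rec_dir <- file.path(dir, "records")
  ann_dir <- file.path(dir, "annotations")
  dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(ann_dir, recursive = TRUE, showWarnings = FALSE)
  for (entry in cohort$records) {
    stem <- paste0(entry$record$subject_id, "_", entry$record$stage)
    if (format == "csv") {
      write_record_csv(entry$record, file.path(rec_dir, paste0(stem, ".csv")))
    } else {
      write_wfdb(entry$record, stem, rec_dir)
    }
    write_annotations_csv(entry$annotations,
                          file.path(ann_dir, paste0(stem, ".csv")))
  }
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
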