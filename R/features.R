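# The 30-item hand-crafted feature set: per-lead interval and amplitude
# statistics on leads I (DI) and aVF, plus the frontal-plane cardiac axis
# computed jointly from both leads.

#' Names of the 30 ECG features, in canonical order
#'
#' First the 16 lead-I entries (interval means, axis mean, ratio means,
#' R-amplitude mean, then the matching variances with the axis variance in
#' the same slot), then the 14 lead-aVF entries (the axis appears only
#' once, it is a two-lead composite).
#'
#' @return Character vector of length 30.
#' @export
feature_names <- function() {
  c("di_rr_mean", "di_rs_mean", "di_qs_mean", "di_qr_mean",
    "axis_mean",
    "di_rq_ratio_mean", "di_rs_ratio_mean", "di_r_amp_mean",
    "di_rr_var", "di_rs_var", "di_qs_var", "di_qr_var",
    "axis_var",
    "di_rq_ratio_var", "di_rs_ratio_var", "di_r_amp_var",
    "avf_rr_mean", "avf_rs_mean", "avf_qs_mean", "avf_qr_mean",
    "avf_rq_ratio_mean", "avf_rs_ratio_mean", "avf_r_amp_mean",
    "avf_rr_var", "avf_rs_var", "avf_qs_var", "avf_qr_var",
    "avf_rq_ratio_var", "avf_rs_ratio_var", "avf_r_amp_var")
}

#' Per-beat interval table from beat annotations
#'
#' Intervals in milliseconds: `rr[i] = (r[i+1] - r[i]) / fs * 1000` (the
#' last beat has no successor, so its RR is `NA`), `rs = s - r`,
#' `qs = s - q`, `qr = r - q`. The telescoping identity `qs = qr + rs`
#' holds beat-wise. Beats with failed Q/S delineation yield `NA` in the
#' affected columns.
#'
#' @param ann A [beat_annotations()] object with at least one beat (two
#'   for RR intervals).
#' @param sample_rate Samples per second.
#' @return Data frame with columns `rr`, `rs`, `qs`, `qr` (ms), one row
#'   per beat.
#' @export
beat_intervals <- function(ann, sample_rate) {
  stopifnot(inherits(ann, "beat_annotations"))
  n <- n_beats(ann)
  if (n < 1) stop("no beats: cannot compute intervals")
  ms <- 1000 / sample_rate
  rr <- if (n >= 2) c(diff(ann$r), NA_real_) * ms else {
    stop("need at least 2 beats for RR intervals")
  }
  data.frame(rr = rr,
             rs = (ann$s - ann$r) * ms,
             qs = (ann$s - ann$q) * ms,
             qr = (ann$r - ann$q) * ms)
}

#' Frontal-plane cardiac axis from net QRS amplitudes on leads I and aVF
#'
#' The clinical two-orthogonal-lead estimate: lead I points at 0 degrees,
#' aVF at +90 degrees, so the axis is `atan2(net_aVF, net_I)` in degrees,
#' in (-180, 180]. Vectorized over beats.
#'
#' @param net_amp_I,net_amp_aVF Net QRS amplitudes (mV) on the two leads.
#' @return Axis angle(s) in degrees.
#' @export
cardiac_axis <- function(net_amp_I, net_amp_aVF) {
  if (any(net_amp_I == 0 & net_amp_aVF == 0)) {
    stop("cardiac axis undefined: both net amplitudes are zero")
  }
  deg <- atan2(net_amp_aVF, net_amp_I) * 180 / pi
  deg[deg <= -180] <- deg[deg <= -180] + 360
  deg
}

# sample variance (n-1 divisor) that returns exact 0 for a single value
.svar <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(if (length(x) == 1) 0 else NA_real_)
  stats::var(x)
}

.smean <- function(x) mean(x, na.rm = TRUE)

# per-lead per-beat signed amplitudes at annotated indices, baseline
# corrected by the record's per-lead median (filterless amplitude fidelity)
.beat_amplitudes <- function(x, ann) {
  base <- stats::median(x)
  list(q = ifelse(is.na(ann$q), NA_real_, x[ann$q] - base),
       r = x[ann$r] - base,
       s = ifelse(is.na(ann$s), NA_real_, x[ann$s] - base))
}

#' Extract the 30-item feature vector from one record
#'
#' Computes, per lead (I then aVF): mean and variance of the RR, RS, QS
#' and QR intervals (ms, ms^2); mean and variance of the signed R/Q and
#' R/S amplitude ratios; mean and variance of the R amplitude (mV); plus
#' mean and variance of the per-beat frontal-plane cardiac axis (degrees),
#' computed jointly from both leads. The per-beat net QRS amplitude of a
#' lead is the signed sum of its baseline-corrected Q, R and S amplitudes.
#'
#' Beats with failed Q/S delineation are excluded from the statistics that
#' need them; beats whose |Q| or |S| amplitude is below `ratio_guard`
#' times that beat's |R| are additionally excluded from the ratio
#' features (near-zero denominators).
#'
#' @param record An [ecg_record()] containing leads `"I"` and `"aVF"`.
#' @param ann_I,ann_aVF [beat_annotations()] for the two leads (commonly
#'   identical when R peaks were detected once and reused).
#' @param abs_ratios Use absolute instead of signed amplitudes in the R/Q
#'   and R/S ratios.
#' @param ratio_guard Relative amplitude threshold for the ratio guard.
#' @return Named numeric vector of length 30, ordered as
#'   [feature_names()].
#' @export
extract_features <- function(record, ann_I, ann_aVF = ann_I,
                             abs_ratios = FALSE, ratio_guard = 0.01) {
  for (ld in c("I", "aVF")) {
    if (!ld %in% record$lead_names) stop("record lacks required lead ", ld)
  }
  if (n_beats(ann_I) < 2 || n_beats(ann_aVF) < 2) {
    stop("need at least 2 valid beats per lead")
  }
  fs <- record$sample_rate

  lead_stats <- function(lead, ann) {
    x <- ecg_lead(record, lead)
    iv <- beat_intervals(ann, fs)
    amp <- .beat_amplitudes(x, ann)
    ok <- !is.na(amp$q) & !is.na(amp$s)
    guard <- ok & abs(amp$q) >= ratio_guard * abs(amp$r) &
      abs(amp$s) >= ratio_guard * abs(amp$r)
    num <- if (abs_ratios) abs(amp$r) else amp$r
    qden <- if (abs_ratios) abs(amp$q) else amp$q
    sden <- if (abs_ratios) abs(amp$s) else amp$s
    rq <- ifelse(guard, num / qden, NA_real_)
    rs <- ifelse(guard, num / sden, NA_real_)
    list(
      means = c(.smean(iv$rr), .smean(iv$rs), .smean(iv$qs), .smean(iv$qr),
                .smean(rq), .smean(rs), .smean(amp$r)),
      vars = c(.svar(iv$rr), .svar(iv$rs), .svar(iv$qs), .svar(iv$qr),
               .svar(rq), .svar(rs), .svar(amp$r)),
      amp = amp)
    }

  st_I <- lead_stats("I", ann_I)
  st_F <- lead_stats("aVF", ann_aVF)

  # per-beat axis: the net QRS vector samples both leads at the same
  # instants, so both amplitude readings use lead I's beat annotations
  # (the lead whose delineation anchors the pipeline); this keeps the
  # axis defined even when the other lead is electrically silent
  axis <- .per_beat_axis(record, ann_I, st_I$amp)

  out <- c(st_I$means[1:4], .smean(axis), st_I$means[5:7],
           st_I$vars[1:4], .svar(axis), st_I$vars[5:7],
           st_F$means[1:4], st_F$means[5:7],
           st_F$vars[1:4], st_F$vars[5:7])
  names(out) <- feature_names()
  if (all(is.na(out))) stop("no valid beats: feature extraction failed")
  out
}

# Net QRS amplitude per beat on both leads at lead I's annotation
# instants, then atan2 axis.
.per_beat_axis <- function(record, ann_I, amp_I) {
  keep <- which(!is.na(amp_I$q) & !is.na(amp_I$s))
  if (!length(keep)) return(NA_real_)
  xf <- ecg_lead(record, "aVF")
  base_f <- stats::median(xf)
  net_I <- amp_I$q[keep] + amp_I$r[keep] + amp_I$s[keep]
  net_F <- (xf[ann_I$q[keep]] - base_f) + (xf[ann_I$r[keep]] - base_f) +
    (xf[ann_I$s[keep]] - base_f)
  both_zero <- net_I == 0 & net_F == 0
  if (all(both_zero)) return(NA_real_)
  cardiac_axis(net_I[!both_zero], net_F[!both_zero])
}

#' Feature table for a whole cohort
#'
#' Runs delineation (or reuses the generator's ground-truth annotations)
#' on every record and assembles one feature row per (subject, stage).
#' R peaks are detected on lead I and reused for aVF -- the axis features
#' need beat-aligned annotations and lead I always carries an upright R
#' projection for physiological axes.
#'
#' @param cohort An `ecg_cohort` from [generate_cohort()].
#' @param use_truth Use ground-truth annotations instead of running the
#'   detector (isolates feature-level behavior from detection).
#' @param config [detector_config()] used when `use_truth = FALSE`.
#' @param quiet Suppress per-record progress messages.
#' @return Data frame: `subject_id`, `group`, `stage`, then the 30
#'   feature columns of [feature_names()].
#' @export
cohort_features <- function(cohort, use_truth = FALSE,
                            config = detector_config(), quiet = TRUE) {
  stopifnot(inherits(cohort, "ecg_cohort"))
  rows <- lapply(cohort$records, function(entry) {
    rec <- entry$record
    if (use_truth) {
      ann_I <- ann_F <- entry$annotations
    } else {
      ann_I <- delineate(rec, "I", config)
      ann_F <- delineate(rec, "aVF", config, r_peaks = ann_I$r,
                         auto_invert = TRUE)
    }
    if (!quiet) message("features: ", rec$subject_id, " ", rec$stage,
                        " (", n_beats(ann_I), " beats)")
    fv <- tryCatch(extract_features(rec, ann_I, ann_F),
                   error = function(e) stats::setNames(
                     rep(NA_real_, 30), feature_names()))
    cbind(data.frame(subject_id = rec$subject_id, group = rec$group,
                     stage = rec$stage), as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}

#' Write a cohort feature table as CSV
#'
#' @param features Data frame from [cohort_features()].
#' @param path Output path.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
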