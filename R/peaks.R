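# QRS delineation: Pan-Tompkins R-peak detection, derivative-inversion
# S-trough search, and Q detection by re-running the S search on the
# time-flipped (sample-reversed) signal.

#' Detector configuration
#'
#' Parameters of the Pan-Tompkins stages and the Q/S search. Defaults are
#' the classic values: 5--15 Hz band-pass, 150 ms moving-window
#' integration, 200 ms refractory period. `qs_search_window` bounds the
#' distance from the R peak within which a Q or S trough is accepted
#' (120 ms covers the upper range of normal QRS duration with margin).
#'
#' @param bandpass_low,bandpass_high Band-pass corner frequencies, Hz.
#' @param integration_window Moving-window integration length, ms.
#' @param refractory Minimum spacing between detected R peaks, ms.
#' @param qs_search_window Maximum |Q - R| and |S - R| distance, ms.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(bandpass_low = 5, bandpass_high = 15,
                            integration_window = 150, refractory = 200,
                            qs_search_window = 120) {
  stopifnot(bandpass_low > 0, bandpass_high > bandpass_low,
            integration_window > 0, refractory > 0, qs_search_window > 0)
  structure(list(bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 integration_window = integration_window,
                 refractory = refractory,
                 qs_search_window = qs_search_window),
            class = "detector_config")
}

# centered moving average; edges zero-filled so peak positions stay aligned
.mwi <- function(x, w) {
  y <- stats::filter(x, rep(1 / w, w), sides = 2)
  y[is.na(y)] <- 0
  as.numeric(y)
}

# indices of strict local maxima
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Band-pass filter (zero-phase Butterworth), five-point derivative,
#' squaring, centered moving-window integration, then adaptive dual
#' thresholds with search-back on the integrated signal. Each accepted
#' detection is finally snapped to the local maximum of the raw signal
#' within +-50 ms, so the returned indices point at true R-wave apices.
#'
#' The detector assumes an upright (positive) R wave in the supplied lead;
#' invert the lead beforehand if its projection is negative.
#'
#' @param x Single-lead amplitude vector (mV).
#' @param sample_rate Samples per second.
#' @param config A [detector_config()].
#' @return Strictly increasing integer vector of R-peak sample indices
#'   (1-based); empty for a constant signal.
#' @export
detect_r_peaks <- function(x, sample_rate, config = detector_config()) {
  fs <- sample_rate
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  if (length(x) < 2 * fs) {
    stop("signal shorter than 2 s: not enough data for filter warm-up")
  }
  if (max(x) == min(x)) return(integer(0))
  nyq <- fs / 2
  hi <- min(config$bandpass_high, 0.95 * nyq)
  bf <- signal::butter(3, c(config$bandpass_low, hi) / nyq, type = "pass")
  bp <- signal::filtfilt(bf, x)
  dv <- stats::filter(bp, c(1, 2, 0, -2, -1) / 8, sides = 2)
  dv[is.na(dv)] <- 0
  integ <- .mwi(as.numeric(dv)^2, max(3L, round(config$integration_window / 1000 * fs)))

  cand <- .local_maxima(integ)
  if (!length(cand)) return(integer(0))
  refr <- round(config$refractory / 1000 * fs)
  warm <- min(length(integ), round(2 * fs))
  spki <- max(integ[seq_len(warm)])
  npki <- mean(integ[seq_len(warm)]) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)
  qrs <- integer(0)
  rr_hist <- numeric(0)
  last <- -Inf
  for (p in cand) {
    if (p - last < refr) next
    if (integ[p] >= thr1) {
      # search-back first: a missed beat between `last` and `p`
      avg_rr <- if (length(rr_hist)) mean(utils::tail(rr_hist, 8)) else NA
      if (!is.na(avg_rr) && is.finite(last) && (p - last) > 1.66 * avg_rr) {
        mid <- cand[cand > last + refr & cand < p - refr]
        mid <- mid[integ[mid] >= 0.5 * thr1]
        if (length(mid)) {
          b <- mid[which.max(integ[mid])]
          if (length(qrs)) rr_hist <- c(rr_hist, b - last)
          qrs <- c(qrs, b)
          last <- b
        }
      }
      if (length(qrs)) rr_hist <- c(rr_hist, p - last)
      qrs <- c(qrs, p)
      last <- p
      spki <- 0.125 * integ[p] + 0.875 * spki
    } else {
      npki <- 0.125 * integ[p] + 0.875 * npki
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  if (!length(qrs)) return(integer(0))
  # two-step snap: first to the band-passed QRS apex within +-75 ms
  # (robust to shoulder maxima of the integrated signal), then to the
  # raw-signal apex within +-50 ms
  half75 <- round(0.075 * fs)
  half <- round(0.05 * fs)
  r <- vapply(qrs, function(p) {
    lo <- max(1L, p - half75); hi2 <- min(length(x), p + half75)
    p <- lo - 1L + which.max(bp[lo:hi2])
    lo <- max(1L, p - half); hi2 <- min(length(x), p + half)
    as.integer(lo - 1L + which.max(x[lo:hi2]))
  }, integer(1))
  r <- sort(unique(r))
  # enforce refractory after snapping: keep the taller of close pairs
  if (length(r) > 1) {
    keep <- rep(TRUE, length(r))
    i <- 1L
    for (j in 2:length(r)) {
      if (r[j] - r[i] < refr) {
        if (x[r[j]] > x[r[i]]) { keep[i] <- FALSE; i <- j } else keep[j] <- FALSE
      } else i <- j
    }
    r <- r[keep]
  }
  as.integer(r)
}

#' Time-flip (sample-order reversal) of a signal
#'
#' Mirrors the signal in time: `output[n] = input[N + 1 - n]` for a signal
#' of length `N`. Applying it twice returns the original signal. This is
#' the trick that lets the S-trough detector find Q troughs: on the
#' flipped signal a Q wave looks like an S wave.
#'
#' @param x Non-empty numeric vector.
#' @return The reversed vector, same length.
#' @export
time_flip <- function(x) {
  if (!length(x)) stop("cannot time-flip an empty signal")
  rev(x)
}

# local minima as sign inversions of the first-difference sequence:
# index m is a trough when x[m-1] > x[m] and x[m] <= x[m+1]
.local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  which(d[1:(n - 2)] < 0 & d[2:(n - 1)] >= 0) + 1L
}

#' Locate S troughs after each R peak
#'
#' For every R peak, finds the nearest local minimum of the signal (a sign
#' inversion of the first difference) after the peak and within
#' `qs_search_window` ms. Beats with no such inversion in the window --
#' e.g. a monotone tail at the record end -- are marked failed with `NA`
#' rather than raising an error.
#'
#' @param x Single-lead amplitude vector.
#' @param r_peaks Integer vector of R-peak indices (1-based, increasing).
#' @param sample_rate Samples per second.
#' @param config A [detector_config()].
#' @return Integer vector, one S index (or `NA`) per R peak.
#' @export
locate_s_peaks <- function(x, r_peaks, sample_rate,
                           config = detector_config()) {
  if (any(r_peaks < 1 | r_peaks > length(x))) {
    stop("r_peaks out of range for signal")
  }
  w <- round(config$qs_search_window / 1000 * sample_rate)
  mins <- .local_minima(x)
  vapply(as.integer(r_peaks), function(r) {
    m <- mins[mins > r & mins <= r + w]
    if (!length(m)) return(NA_integer_)
    m[1]                                     # nearest inversion after R
  }, integer(1))
}

#' Locate Q troughs before each R peak via time flipping
#'
#' Runs the S-trough search of [locate_s_peaks()] on the time-flipped
#' signal at the mirrored R positions, then maps the results back:
#' `q = N + 1 - s'`, where `s'` is the trough found on the flipped signal
#' and `N` the signal length. This is exactly the mirrored S detector, so
#' the identity `locate_q_peaks(x, r) == N + 1 - locate_s_peaks(rev(x),
#' N + 1 - r)` holds bit-exactly.
#'
#' @inheritParams locate_s_peaks
#' @return Integer vector, one Q index (or `NA`) per R peak.
#' @export
locate_q_peaks <- function(x, r_peaks, sample_rate,
                           config = detector_config()) {
  n <- length(x)
  r_peaks <- as.integer(r_peaks)
  rf <- rev(n + 1L - r_peaks)                # mirrored positions, increasing
  sf <- locate_s_peaks(time_flip(x), rf, sample_rate, config)
  rev(n + 1L - sf)
}

#' Full Q/R/S delineation of one lead
#'
#' Convenience wrapper: R peaks from Pan-Tompkins (or reused from another
#' lead), S troughs by forward derivative-inversion search, Q troughs by
#' the time-flip mirror of the S search.
#'
#' @param record An [ecg_record()].
#' @param lead Lead to delineate.
#' @param config A [detector_config()].
#' @param r_peaks Optional externally supplied R-peak indices (e.g. from a
#'   lead with a clearer R projection); when `NULL` they are detected on
#'   `lead` itself.
#' @param auto_invert Detect an electrically inverted lead (negative net
#'   QRS deflection at the R indices, as on aVF when the axis dips below
#'   zero) and run the trough searches on the negated signal; annotation
#'   indices are polarity-independent, amplitudes keep their true sign.
#' @return A [beat_annotations()] object (Q/S may contain `NA` sentinels
#'   for failed beats).
#' @export
delineate <- function(record, lead = "I", config = detector_config(),
                      r_peaks = NULL, auto_invert = FALSE) {
  x <- ecg_lead(record, lead)
  if (is.null(r_peaks)) {
    r_peaks <- detect_r_peaks(x, record$sample_rate, config)
  }
  if (!length(r_peaks)) {
    return(beat_annotations(integer(0), integer(0), integer(0)))
  }
  if (auto_invert &&
      stats::median(x[r_peaks]) < stats::median(x)) {
    base <- stats::median(x)
    x <- 2 * base - x                       # mirror about the baseline
  }
  s <- locate_s_peaks(x, r_peaks, record$sample_rate, config)
  q <- locate_q_peaks(x, r_peaks, record$sample_rate, config)
  # a trough on the wrong side of R (possible in pathological windows)
  # counts as a failed beat, keeping the q < r < s contract
  q[!is.na(q) & q >= r_peaks] <- NA_integer_
  s[!is.na(s) & s <= r_peaks] <- NA_integer_
  beat_annotations(q, as.integer(r_peaks), s)
}

#' Compare detected against reference R peaks
#'
#' Greedy one-to-one nearest matching within a tolerance; the standard
#' beat-detection bookkeeping behind sensitivity/PPV.
#'
#' @param detected,reference Integer sample-index vectors (sorted).
#' @param sample_rate Samples per second.
#' @param tolerance_ms Maximum |detected - reference| for a match (ms).
#' @return List with `n_matched`, `sensitivity`, `ppv`, `errors_ms`
#'   (signed detected - reference errors of matched pairs), and the index
#'   pairs.
#' @export
match_peaks <- function(detected, reference, sample_rate,
                        tolerance_ms = 50) {
  tol <- tolerance_ms / 1000 * sample_rate
  pairs <- matrix(integer(0), ncol = 2)
  used_d <- rep(FALSE, length(detected))
  for (j in seq_along(reference)) {
    if (!length(detected)) break
    d <- abs(detected - reference[j])
    k <- which.min(d)
    if (d[k] <= tol && !used_d[k]) {
      used_d[k] <- TRUE
      pairs <- rbind(pairs, c(k, j))
    }
  }
  nm <- nrow(pairs)
  errs <- if (nm) (detected[pairs[, 1]] - reference[pairs[, 2]]) /
    sample_rate * 1000 else numeric(0)
  list(n_matched = nm,
       sensitivity = if (length(reference)) nm / length(reference) else NA,
       ppv = if (length(detected)) nm / length(detected) else NA,
       errors_ms = errs,
       detected_idx = pairs[, 1], reference_idx = pairs[, 2])
}
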