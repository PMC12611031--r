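# Multi-lead ECG record container and file I/O (CSV and minimal WFDB).

#' Recognized oral glucose tolerance test stages
#'
#' The five recording epochs of the protocol: fasting baseline and 30, 60,
#' 90 and 120 minutes after glucose intake.
#'
#' @export
OGTT_STAGES <- c("basal", "30min", "60min", "90min", "120min")

#' Construct a multi-lead ECG record
#'
#' An `ecg_record` bundles a lead-by-sample amplitude matrix (millivolts)
#' with its sampling rate and subject metadata (group label and OGTT stage).
#' Leads `"I"` and `"aVF"` are the two frontal-plane leads used by the
#' hand-crafted feature set; other leads are allowed.
#'
#' @param samples Numeric matrix, one row per lead, amplitudes in mV.
#' @param sample_rate Sampling frequency in samples/second (> 0).
#' @param lead_names Character vector of unique lead names, one per row.
#' @param subject_id Subject identifier string.
#' @param group `"control"` or `"ms"` (metabolic syndrome).
#' @param stage One of [OGTT_STAGES].
#' @return An object of class `ecg_record`.
#' @examples
#' x <- matrix(rnorm(2000), nrow = 2)
#' rec <- ecg_record(x, 500, c("I", "aVF"))
#' rec
#' @export
ecg_record <- function(samples, sample_rate, lead_names,
                       subject_id = "S01", group = c("control", "ms"),
                       stage = "basal") {
  group <- match.arg(group)
  if (!stage %in% OGTT_STAGES) {
    stop("unknown OGTT stage: ", stage, " (expected one of ",
         paste(OGTT_STAGES, collapse = ", "), ")")
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (leads x samples)")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number")
  }
  if (length(lead_names) != nrow(samples)) {
    stop("`lead_names` must name every row of `samples`")
  }
  if (anyDuplicated(lead_names)) stop("lead names must be unique")
  rownames(samples) <- lead_names
  structure(
    list(subject_id = subject_id, group = group, stage = stage,
         sample_rate = sample_rate, lead_names = as.character(lead_names),
         samples = samples),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> subject %s (%s, %s): %d lead(s) [%s], %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, x$stage, nrow(x$samples),
              paste(x$lead_names, collapse = ","), ncol(x$samples),
              x$sample_rate, ncol(x$samples) / x$sample_rate))
  invisible(x)
}

#' Extract one lead of an ECG record
#'
#' @param record An [ecg_record()].
#' @param lead Lead name, e.g. `"I"`.
#' @return Numeric vector of amplitudes (mV).
#' @export
ecg_lead <- function(record, lead) {
  stopifnot(inherits(record, "ecg_record"))
  if (!lead %in% record$lead_names) {
    stop("record has no lead '", lead, "' (has: ",
         paste(record$lead_names, collapse = ", "), ")")
  }
  record$samples[lead, ]
}

#' Record duration in seconds
#' @param record An [ecg_record()].
#' @export
ecg_duration <- function(record) ncol(record$samples) / record$sample_rate

#' Construct beat-level Q/R/S annotations
#'
#' Per-beat sample indices (1-based, R convention) of the Q trough, R peak
#' and S trough. Association between the three waves is positional: entry
#' `i` of each vector describes beat `i`. `q` and `s` may be `NA` for beats
#' the delineator failed on; `r` must be complete and strictly increasing,
#' and wherever defined the ordering `q < r < s` must hold.
#'
#' @param q,r,s Integer sample indices (same length); `q`/`s` may contain NA.
#' @return An object of class `beat_annotations`.
#' @export
beat_annotations <- function(q, r, s) {
  q <- as.integer(q); r <- as.integer(r); s <- as.integer(s)
  n <- length(r)
  if (length(q) != n || length(s) != n) {
    stop("q, r, s must have equal length (positional beat association)")
  }
  if (anyNA(r)) stop("R-peak indices must not be NA")
  if (n > 1 && any(diff(r) <= 0)) stop("R-peak indices must be strictly increasing")
  ok <- !is.na(q) & !is.na(s)
  if (any(q[ok] >= r[ok]) || any(r[ok] >= s[ok])) {
    stop("every complete beat must satisfy q < r < s")
  }
  structure(list(q = q, r = r, s = s), class = "beat_annotations")
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("<beat_annotations> %d beat(s), %d complete\n",
              length(x$r), sum(!is.na(x$q) & !is.na(x$s))))
  invisible(x)
}

#' Number of annotated beats
#' @param ann A [beat_annotations()] object.
#' @export
n_beats <- function(ann) length(ann$r)

#' Drop beats with failed Q or S delineation
#'
#' @param ann A [beat_annotations()] object possibly containing NA sentinels.
#' @return A [beat_annotations()] object with only complete beats.
#' @export
complete_beats <- function(ann) {
  keep <- !is.na(ann$q) & !is.na(ann$s)
  beat_annotations(ann$q[keep], ann$r[keep], ann$s[keep])
}

# ---------------------------------------------------------------------------
# CSV I/O

#' Write an ECG record to a flat CSV file
#'
#' One row per sample, one column per lead. Metadata (subject, group, stage,
#' sample rate) is stored in `#`-prefixed header comment lines so the file
#' round-trips through [read_record_csv()].
#'
#' @param record An [ecg_record()].
#' @param path Output file path.
#' @export
write_record_csv <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# subject_id: ", record$subject_id),
    paste0("# group: ", record$group),
    paste0("# stage: ", record$stage),
    paste0("# sample_rate: ", format(record$sample_rate, digits = 15))
  ), con)
  df <- as.data.frame(t(record$samples))
  names(df) <- record$lead_names
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read an ECG record from a flat CSV file
#'
#' @param path File written by [write_record_csv()].
#' @return An [ecg_record()].
#' @export
read_record_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list(subject_id = "S01", group = "control", stage = "basal",
               sample_rate = NA_real_)
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    if (key %in% names(meta)) meta[[key]] <- val
  }
  meta$sample_rate <- as.numeric(meta$sample_rate)
  if (is.na(meta$sample_rate)) stop("CSV header lacks '# sample_rate:' line")
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        check.names = FALSE)
  ecg_record(t(as.matrix(df)), meta$sample_rate, names(df),
             subject_id = meta$subject_id, group = meta$group,
             stage = meta$stage)
}

#' Write beat annotations as a CSV table
#'
#' Columns `beat`, `q_idx`, `r_idx`, `s_idx`; indices are 1-based sample
#' positions, `NA` marks beats the delineator failed on.
#'
#' @param ann A [beat_annotations()] object.
#' @param path Output file path.
#' @export
write_annotations_csv <- function(ann, path) {
  utils::write.csv(
    data.frame(beat = seq_along(ann$r), q_idx = ann$q, r_idx = ann$r,
               s_idx = ann$s),
    path, row.names = FALSE)
  invisible(path)
}

#' Read beat annotations from CSV
#' @param path File written by [write_annotations_csv()].
#' @return A [beat_annotations()] object.
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path)
  beat_annotations(df$q_idx, df$r_idx, df$s_idx)
}

# ---------------------------------------------------------------------------
# Minimal WFDB I/O (header + format-16 signal file)

#' Write an ECG record as a WFDB record (header + format-16 signal file)
#'
#' Produces `<name>.hea` and `<name>.dat` in `dir`. Samples are stored as
#' 16-bit little-endian integers interleaved across leads with a fixed gain
#' of 200 adu/mV and zero baseline, the common convention for mV-scaled
#' physiologic signals.
#'
#' @param record An [ecg_record()].
#' @param name Record name (file stem).
#' @param dir Output directory.
#' @return The header path, invisibly.
#' @export
write_wfdb <- function(record, name, dir = ".") {
  gain <- 200
  n_sig <- nrow(record$samples)
  n_samp <- ncol(record$samples)
  adu <- round(record$samples * gain)
  adu[adu > 32767] <- 32767
  adu[adu < -32768] <- -32768
  interleaved <- as.integer(adu)          # column-major = sample-major
  dat <- paste0(name, ".dat")
  writeBin(interleaved, file.path(dir, dat), size = 2, endian = "little")
  chks <- vapply(seq_len(n_sig), function(i) {
    s <- sum(adu[i, ]) %% 65536
    if (s > 32767) s <- s - 65536
    as.integer(s)
  }, integer(1))
  hdr <- c(
    sprintf("%s %d %g %d", name, n_sig, record$sample_rate, n_samp),
    sprintf("%s 16 %d(0)/mV 16 0 %d %d 0 %s",
            dat, gain, as.integer(adu[, 1]), chks, record$lead_names),
    paste0("# subject_id: ", record$subject_id),
    paste0("# group: ", record$group),
    paste0("# stage: ", record$stage)
  )
  writeLines(hdr, file.path(dir, paste0(name, ".hea")))
  invisible(file.path(dir, paste0(name, ".hea")))
}

#' Read a WFDB record written by [write_wfdb()]
#'
#' Supports single-segment format-16 records with a per-signal gain in
#' `gain(baseline)/mV` or plain `gain` notation.
#'
#' @param name Record name (file stem, no extension).
#' @param dir Directory holding `<name>.hea` and the signal file.
#' @return An [ecg_record()].
#' @export
read_wfdb <- function(name, dir = ".") {
  hea <- readLines(file.path(dir, paste0(name, ".hea")))
  meta <- list(subject_id = name, group = "control", stage = "basal")
  for (h in grep("^#", hea, value = TRUE)) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    if (key %in% names(meta)) meta[[key]] <- val
  }
  hea <- hea[!grepl("^#", hea) & nzchar(trimws(hea))]
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n_samp <- as.integer(top[4])
  sig_lines <- hea[2:(1 + n_sig)]
  parse_sig <- function(line) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (f[2] != "16") stop("only WFDB format 16 is supported")
    gain_spec <- f[3]
    gain <- as.numeric(sub("[(/].*$", "", gain_spec))
    baseline <- 0
    if (grepl("\\(", gain_spec)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec))
    }
    list(file = f[1], gain = gain, baseline = baseline,
         lead = f[length(f)])
  }
  sigs <- lapply(sig_lines, parse_sig)
  dat_file <- sigs[[1]]$file
  raw <- readBin(file.path(dir, dat_file), integer(), n = n_sig * n_samp,
                 size = 2, endian = "little", signed = TRUE)
  adu <- matrix(raw, nrow = n_sig)
  mv <- adu
  for (i in seq_len(n_sig)) {
    mv[i, ] <- (adu[i, ] - sigs[[i]]$baseline) / sigs[[i]]$gain
  }
  ecg_record(mv, fs, vapply(sigs, `[[`, "", "lead"),
             subject_id = meta$subject_id, group = meta$group,
             stage = meta$stage)
}
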