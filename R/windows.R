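# Raw-signal windowing for the CNN back-end.

#' Split a record into equal, contiguous, non-overlapping windows
#'
#' The signal is cut into `n_windows` windows of length
#' `floor(L / n_windows)` samples; the trailing remainder is discarded, so
#' the concatenation of the windows reproduces the truncated signal
#' exactly.
#'
#' @param record An [ecg_record()].
#' @param n_windows Number of windows (default 300).
#' @return An object of class `window_set`: list with `windows` (array
#'   `n_leads x window_length x n_windows`), `subject`, `stage`, `label`
#'   (group), `lead_names`, `sample_rate`.
#' @export
window_signal <- function(record, n_windows = 300) {
  stopifnot(inherits(record, "ecg_record"), n_windows >= 1)
  L <- ncol(record$samples)
  wl <- L %/% n_windows
  if (wl < 1) stop("record shorter than n_windows samples")
  H <- nrow(record$samples)
  arr <- array(record$samples[, seq_len(n_windows * wl), drop = FALSE],
               dim = c(H, wl, n_windows))
  structure(list(windows = arr,
                 subject = rep(record$subject_id, n_windows),
                 stage = rep(record$stage, n_windows),
                 label = factor(rep(record$group, n_windows),
                                levels = c("control", "ms")),
                 lead_names = record$lead_names,
                 sample_rate = record$sample_rate),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set> %d window(s) of %d lead(s) x %d samples, %d subject(s)\n",
              d[3], d[1], d[2], length(unique(x$subject))))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws A `window_set`.
#' @export
n_windows <- function(ws) dim(ws$windows)[3]

#' Combine window sets from several records
#'
#' All sets must share the window shape and lead layout.
#'
#' @param ... `window_set` objects, or a single list of them.
#' @return A combined `window_set`.
#' @export
bind_windows <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "window_set")) {
    sets <- sets[[1]]
  }
  d1 <- dim(sets[[1]]$windows)[1:2]
  for (s in sets) {
    if (!identical(dim(s$windows)[1:2], d1)) {
      stop("window sets have incompatible shapes")
    }
  }
  structure(list(
    windows = array(unlist(lapply(sets, `[[`, "windows")),
                    dim = c(d1, sum(vapply(sets, n_windows, 0)))),
    subject = unlist(lapply(sets, `[[`, "subject")),
    stage = unlist(lapply(sets, `[[`, "stage")),
    label = factor(unlist(lapply(sets, function(s) as.character(s$label))),
                   levels = c("control", "ms")),
    lead_names = sets[[1]]$lead_names,
    sample_rate = sets[[1]]$sample_rate), class = "window_set")
}

#' Window an entire cohort
#'
#' @param cohort An `ecg_cohort`.
#' @param n_windows Windows per record.
#' @param stages Optional subset of stages to include.
#' @return A combined `window_set`.
#' @export
cohort_windows <- function(cohort, n_windows = 300, stages = NULL) {
  entries <- cohort$records
  if (!is.null(stages)) {
    entries <- Filter(function(e) e$record$stage %in% stages, entries)
  }
  bind_windows(lapply(entries, function(e) window_signal(e$record, n_windows)))
}

#' Subset a window set
#'
#' @param ws A `window_set`.
#' @param idx Integer or logical window index.
#' @return A `window_set` with the selected windows.
#' @export
subset_windows <- function(ws, idx) {
  structure(list(windows = ws$windows[, , idx, drop = FALSE],
                 subject = ws$subject[idx], stage = ws$stage[idx],
                 label = ws$label[idx], lead_names = ws$lead_names,
                 sample_rate = ws$sample_rate), class = "window_set")
}
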