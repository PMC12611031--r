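# Statistical battery: KS normality screen, Mann-Whitney group tests,
# point-biserial correlation screen, PCA loading-based feature relevance,
# and Bland-Altman agreement for detector validation.

#' Kolmogorov-Smirnov normality screen
#'
#' Plain one-sample KS test of the z-scored sample against the standard
#' normal. Estimating mean and sd from the sample makes the plain KS
#' p-value conservative (the Lilliefors effect); a Lilliefors-corrected
#' variant is available with `correct = "lilliefors"`.
#'
#' @param x Numeric sample, `n >= 4`, non-constant.
#' @param correct `"none"` (plain KS on z-scored data) or `"lilliefors"`.
#' @return Two-sided p-value for departure from normality.
#' @export
ks_normality <- function(x, correct = c("none", "lilliefors")) {
  correct <- match.arg(correct)
  x <- as.numeric(x)
  if (length(x) < 4) stop("need at least 4 observations")
  if (!all(is.finite(x))) stop("sample contains non-finite values")
  if (stats::sd(x) == 0) stop("constant sample: normality test undefined")
  if (correct == "lilliefors") {
    if (!requireNamespace("nortest", quietly = TRUE)) {
      stop("the Lilliefors correction needs the 'nortest' package")
    }
    return(nortest::lillie.test(x)$p.value)
  }
  z <- (x - mean(x)) / stats::sd(x)
  suppressWarnings(stats::ks.test(z, "pnorm"))$p.value
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration p-value when the samples are tie-free and
#' `n_a + n_b <= 12`; tie-corrected normal approximation (with continuity
#' correction) otherwise.
#'
#' @param a,b Non-empty numeric samples.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (length(a) + length(b)) <= 12
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  min(p, 1)
}

#' Per-feature, per-stage group screen
#'
#' For every feature column and OGTT stage: the Mann-Whitney p-value for
#' a control-vs-MS location difference, and the Pearson correlation of
#' the feature with the binary group indicator (point-biserial r) with
#' its p-value. Correlation magnitudes are binned into the conventional
#' ranges `[0, 0.2)`, `[0.2, 0.5)`, `[0.5, 0.75)`, `[0.75, 1]`.
#' Constant features yield an undefined (`NA`) correlation, flagged, and
#' raw p-values are reported (Holm adjustment available by flag).
#'
#' @param features Data frame from [cohort_features()].
#' @param adjust `"none"` (raw p-values) or `"holm"`.
#' @return Data frame, one row per (feature, stage): `feature`, `stage`,
#'   `mw_p`, `pearson_r`, `pearson_p`, `significant` (p < 0.05 on the
#'   Mann-Whitney), `r_bin`.
#' @export
feature_screen <- function(features, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  fcols <- intersect(feature_names(), names(features))
  if (!length(fcols)) stop("no feature columns found")
  stages <- unique(features$stage)
  rows <- list()
  for (st in stages) {
    dat <- features[features$stage == st, ]
    ind <- as.integer(dat$group == "ms")
    if (sum(ind) < 2 || sum(1 - ind) < 2) {
      stop("need at least 2 subjects per group per stage")
    }
    for (fc in fcols) {
      v <- dat[[fc]]
      ok <- !is.na(v)
      mw <- mann_whitney(v[ok & ind == 0], v[ok & ind == 1])
      if (stats::sd(v[ok]) == 0) {
        r <- NA_real_; rp <- NA_real_
      } else {
        ct <- suppressWarnings(stats::cor.test(v[ok], ind[ok]))
        r <- unname(ct$estimate); rp <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = fc, stage = st, mw_p = mw, pearson_r = r, pearson_p = rp)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "holm") {
    out$mw_p <- stats::p.adjust(out$mw_p, "holm")
    out$pearson_p <- stats::p.adjust(out$pearson_p, "holm")
  }
  out$significant <- !is.na(out$mw_p) & out$mw_p < 0.05
  out$r_bin <- cut(abs(out$pearson_r),
                   breaks = c(0, 0.2, 0.5, 0.75, 1),
                   labels = c("[0,0.20)", "[0.20,0.50)", "[0.50,0.75)",
                              "[0.75,1]"),
                   right = FALSE, include.lowest = TRUE)
  out
}

#' PCA-based feature relevance filter
#'
#' Principal components of the z-scored feature table (PCA on the
#' correlation structure, since the features mix ms, ms^2, degrees and
#' dimensionless ratios). Components are retained either as a fixed
#' count (default 13) or by a cumulative-variance threshold; a feature is
#' retained when the magnitude of its loading is at least
#' `coefficient_threshold` in at least one retained component.
#'
#' @param features Feature data frame or plain numeric matrix.
#' @param coefficient_threshold Loading-magnitude cutoff (default 0.2).
#' @param n_components Number of leading components to retain.
#' @param cum_var Alternative retention rule: smallest component count
#'   whose cumulative explained variance reaches this fraction (set to a
#'   value in (0, 1] to activate; overrides `n_components`).
#' @return List with `retained` (character vector of retained feature
#'   names), `loadings` (feature x component matrix), `explained`
#'   (per-component variance fractions), `n_components`.
#' @export
pca_relevance <- function(features, coefficient_threshold = 0.2,
                          n_components = 13, cum_var = NULL) {
  x <- if (is.data.frame(features)) {
    as.matrix(features[, intersect(feature_names(), names(features))])
  } else as.matrix(features)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 complete observations")
  keep <- apply(x, 2, stats::sd) > 0
  pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  if (!is.null(cum_var)) {
    n_components <- which(cumsum(expl) >= cum_var)[1]
  }
  n_components <- min(n_components, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(n_components), drop = FALSE]
  retained <- rownames(load)[
    apply(abs(load) >= coefficient_threshold, 1, any)]
  list(retained = retained, loadings = pc$rotation, explained = expl,
       n_components = n_components)
}

#' Bland-Altman agreement between two sets of event marks
#'
#' Pairs each reference mark with the nearest test mark within
#' `matching_tolerance` (one-to-one), then reports the mean difference
#' (test - reference) and the limits of agreement
#' `mean +- 1.96 * sd` (sample sd). Unmatched marks on either side are
#' counted and reported, not silently folded into the differences.
#'
#' @param reference_marks,test_marks Sorted event times in milliseconds
#'   (convert sample indices with `idx / fs * 1000`).
#' @param matching_tolerance Maximum |test - reference| for a pair (ms).
#' @return An object of class `bland_altman`: `mean_difference`,
#'   `sd_difference`, `limits` (lower, upper), `differences`, `means`
#'   (per-pair averages, the conventional x-axis), `n_pairs`,
#'   `n_unmatched_reference`, `n_unmatched_test`.
#' @export
bland_altman <- function(reference_marks, test_marks,
                         matching_tolerance = 50) {
  r <- sort(as.numeric(reference_marks))
  t2 <- sort(as.numeric(test_marks))
  used <- rep(FALSE, length(t2))
  d <- numeric(0); mids <- numeric(0)
  for (x in r) {
    if (!length(t2)) break
    cand <- which(!used)
    if (!length(cand)) break
    j <- cand[which.min(abs(t2[cand] - x))]
    if (abs(t2[j] - x) <= matching_tolerance) {
      used[j] <- TRUE
      d <- c(d, t2[j] - x)
      mids <- c(mids, (t2[j] + x) / 2)
    }
  }
  if (!length(d)) stop("no marks matched within the tolerance")
  m <- mean(d)
  s <- if (length(d) > 1) stats::sd(d) else 0
  structure(list(mean_difference = m, sd_difference = s,
                 limits = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
                 differences = d, means = mids, n_pairs = length(d),
                 n_unmatched_reference = length(r) - length(d),
                 n_unmatched_test = length(t2) - length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> %d pair(s): mean diff %.3f ms, limits [%.3f, %.3f] ms; unmatched ref %d / test %d\n",
              x$n_pairs, x$mean_difference, x$limits[1], x$limits[2],
              x$n_unmatched_reference, x$n_unmatched_test))
  invisible(x)
}

#' Bland-Altman scatter of differences against pair means
#'
#' @param x A `bland_altman` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "mean of pair (ms)",
                 ylab = "difference test - reference (ms)", ...)
  graphics::abline(h = c(x$mean_difference, x$limits), lty = c(1, 2, 2))
  invisible(x)
}
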