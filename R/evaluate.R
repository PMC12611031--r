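# Subject-wise k-fold cross-validation and confusion-matrix metrics.
# The positive class is "ms" throughout.

#' Confusion matrix from counts
#'
#' @param tp,tn,fp,fn Non-negative counts, at least one positive.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  if (sum(v) < 1) stop("empty confusion matrix")
  structure(as.list(v), class = "confusion_matrix")
}

#' Tabulate a confusion matrix from labels
#'
#' @param truth,pred Factors or characters with levels `control`/`ms`.
#' @param positive The positive class (default `"ms"`).
#' @return A `confusion_matrix`.
#' @export
tabulate_confusion <- function(truth, pred, positive = "ms") {
  truth_pos <- truth == positive
  pred_pos <- pred == positive
  confusion_matrix(tp = sum(truth_pos & pred_pos),
                   tn = sum(!truth_pos & !pred_pos),
                   fp = sum(!truth_pos & pred_pos),
                   fn = sum(truth_pos & !pred_pos))
}

#' Performance metrics from a confusion matrix
#'
#' The seven standard proportions: false positive rate
#' `FPR = FP/(FP+TN)`, false negative rate `FNR = FN/(TP+FN)`, positive
#' predictive value `PPV = TP/(TP+FP)`, negative predictive value
#' `NPV = TN/(TN+FN)`, sensitivity `Se = TP/(TP+FN)`, specificity
#' `Sp = TN/(TN+FP)` and accuracy `Acc = (TP+TN)/(TP+TN+FP+FN)`.
#' A metric whose denominator is zero is undefined and returned as `NA`
#' (flagged, never silently 0).
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `metrics_report`: named list of proportions
#'   in `[0, 1]` (or `NA` where undefined).
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  with(cm, structure(list(
    fpr = rat(fp, fp + tn),
    fnr = rat(fn, tp + fn),
    ppv = rat(tp, tp + fp),
    npv = rat(tn, tn + fn),
    se  = rat(tp, tp + fn),
    sp  = rat(tn, tn + fp),
    acc = (tp + tn) / (tp + tn + fp + fn)
  ), class = "metrics_report"))
}

#' @export
print.metrics_report <- function(x, ...) {
  v <- unlist(x)
  cat(paste(sprintf("%s=%s", toupper(names(v)),
                    ifelse(is.na(v), "undef", sprintf("%.1f%%", 100 * v))),
            collapse = "  "), "\n")
  invisible(x)
}

#' Assign subjects to cross-validation folds
#'
#' Subject-level partition, stratified by default so that each fold's
#' class mix stays within one subject of the global ratio (with a 15/10
#' imbalance and k = 10, unstratified folding regularly yields
#' single-class test folds).
#'
#' @param subject_ids Character vector of unique subject ids.
#' @param labels Group label per subject (`control`/`ms`).
#' @param k Number of folds (`2 <= k <=` number of subjects).
#' @param seed Seed for the random assignment.
#' @param stratified Stratify by class.
#' @return An object of class `fold_plan`: data frame `subject_id`,
#'   `label`, `fold` with attributes `k` and `seed`.
#' @export
make_folds <- function(subject_ids, labels, k = 10, seed = 1,
                       stratified = TRUE) {
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  n <- length(subject_ids)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k exceeds the number of subjects")
  stopifnot(length(labels) == n)
  fold <- integer(n)
  .with_seed(.mix_seed(seed, "folds"), {
    if (stratified) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
      }
    } else {
      fold <- rep_len(seq_len(k), n)[sample.int(n)]
    }
  })
  plan <- data.frame(subject_id = subject_ids, label = labels, fold = fold)
  attr(plan, "k") <- k
  attr(plan, "seed") <- seed
  class(plan) <- c("fold_plan", "data.frame")
  plan
}

#' Classifier specification for cross-validation
#'
#' A light descriptor naming the back-end and its parameters, consumed by
#' [cross_validate()].
#'
#' @param method `"svm"`, `"robustboost"` or `"cnn"`; the diagnostic
#'   baselines `"majority"` (always predicts the training-set majority
#'   class) and `"oracle"` (returns the true labels, an upper bound) are
#'   also accepted.
#' @param ... Passed to the back-end trainer ([train_svm_rbf()],
#'   [train_robustboost()] or [train_cnn()]).
#' @export
classifier_spec <- function(method = c("svm", "robustboost", "cnn",
                                       "majority", "oracle"), ...) {
  structure(list(method = match.arg(method), args = list(...)),
            class = "classifier_spec")
}

.fit_predict <- function(spec, x_train, y_train, x_test, y_test, seed) {
  lv <- c("control", "ms")
  if (spec$method == "svm") {
    model <- do.call(train_svm_rbf, c(list(x = x_train, y = y_train),
                                      spec$args))
    stats::predict(model, x_test)
  } else if (spec$method == "robustboost") {
    cfg <- spec$args$config
    if (is.null(cfg)) cfg <- boost_config()
    model <- train_robustboost(x_train, y_train, cfg, seed = seed)
    stats::predict(model, x_test)
  } else if (spec$method == "majority") {
    maj <- names(which.max(table(factor(y_train, levels = lv))))
    factor(rep(maj, nrow(x_test)), levels = lv)
  } else if (spec$method == "oracle") {
    factor(y_test, levels = lv)
  } else stop("unsupported method for feature-table CV: ", spec$method)
}

#' Subject-wise k-fold cross-validation
#'
#' For each fold: train on the other k-1 folds' rows, predict the
#' held-out fold, compute the confusion-matrix metrics on those test
#' predictions only. The pooled report is the per-metric mean and
#' standard deviation across folds (the protocol's "average of folds"),
#' with pooled-count metrics also reported for transparency. Folding is
#' always at subject level, so no subject contributes to both sides.
#'
#' For `method = "cnn"` supply a `window_set` as `data`; feature-based
#' methods take the [cohort_features()] data frame.
#'
#' @param data Feature data frame (with `subject_id`, `group` and feature
#'   columns) or a `window_set`.
#' @param spec A [classifier_spec()].
#' @param folds A `fold_plan` from [make_folds()]; built automatically
#'   when `NULL`.
#' @param k,seed Used when `folds` is `NULL`.
#' @return An object of class `cv_result`: list with `per_fold` (data
#'   frame of per-fold metrics), `pooled` (mean and sd per metric),
#'   `pooled_counts` (metrics of the summed confusion matrix) and
#'   `accuracy` (mean fold accuracy).
#' @export
cross_validate <- function(data, spec, folds = NULL, k = 10, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  is_windows <- inherits(data, "window_set")
  if (is_windows != (spec$method == "cnn")) {
    stop("cnn needs a window_set; feature methods need a feature table")
  }
  subj <- if (is_windows) data$subject else data$subject_id
  lab <- if (is_windows) as.character(data$label) else data$group
  subj_tab <- unique(data.frame(subject_id = subj, label = lab))
  if (is.null(folds)) {
    folds <- make_folds(subj_tab$subject_id, subj_tab$label, k = k,
                        seed = seed)
  }
  fold_of <- stats::setNames(folds$fold, folds$subject_id)
  if (anyNA(fold_of[subj])) stop("fold plan does not cover all subjects")

  kk <- attr(folds, "k")
  per_fold <- vector("list", kk)
  totals <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  feat_cols <- if (!is_windows) setdiff(names(data),
                                        c("subject_id", "group", "stage"))
  for (f in seq_len(kk)) {
    test_mask <- fold_of[subj] == f
    if (!any(test_mask) || all(test_mask)) next
    if (is_windows) {
      test_subjects <- unique(subj[test_mask])
      model <- do.call(train_cnn, c(
        list(train_windows = subset_windows(data, !test_mask),
             seed = .mix_seed(seed, "cvfit", f),
             test_subjects = test_subjects),
        spec$args))
      pred <- stats::predict(model, subset_windows(data, test_mask))$label
      truth <- lab[test_mask]
    } else {
      x <- as.matrix(data[, feat_cols])
      xtr <- x[!test_mask, , drop = FALSE]
      xte <- x[test_mask, , drop = FALSE]
      # undefined feature cells (e.g. ratio features of a lead the axis
      # leaves silent) are imputed with training-fold medians; test rows
      # never inform the imputation
      med <- apply(xtr, 2, stats::median, na.rm = TRUE)
      med[is.na(med)] <- 0
      for (j in seq_along(med)) {
        xtr[is.na(xtr[, j]), j] <- med[j]
        xte[is.na(xte[, j]), j] <- med[j]
      }
      truth <- lab[test_mask]
      pred <- .fit_predict(spec, xtr, lab[!test_mask], xte, truth,
                           seed = .mix_seed(seed, "cvfit", f))
    }
    cm <- tabulate_confusion(truth, pred)
    totals <- totals + unlist(cm)
    met <- compute_metrics(cm)
    per_fold[[f]] <- cbind(data.frame(fold = f),
                           as.data.frame(unclass(met)))
  }
  per_fold <- do.call(rbind, per_fold)
  if (is.null(per_fold)) stop("no usable folds")
  mnames <- c("fpr", "fnr", "ppv", "npv", "se", "sp", "acc")
  pooled <- data.frame(
    metric = mnames,
    mean = vapply(mnames, function(m) mean(per_fold[[m]], na.rm = TRUE), 0),
    sd = vapply(mnames, function(m) stats::sd(per_fold[[m]], na.rm = TRUE), 0),
    n_defined = vapply(mnames, function(m) sum(!is.na(per_fold[[m]])), 0L))
  structure(list(per_fold = per_fold, pooled = pooled,
                 pooled_counts = compute_metrics(do.call(
                   confusion_matrix, as.list(totals))),
                 accuracy = mean(per_fold$acc), folds = folds, spec = spec),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d fold(s): mean Acc %.1f%% (sd %.1f)\n",
              x$spec$method, nrow(x$per_fold), 100 * x$accuracy,
              100 * stats::sd(x$per_fold$acc)))
  p <- x$pooled
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-4s %5.1f%% +- %.1f\n", toupper(p$metric[i]),
                100 * p$mean[i], 100 * p$sd[i]))
  }
  invisible(x)
}

#' Accuracy distribution over repeated cross-validation runs
#'
#' Re-runs k-fold cross-validation `n_reps` times with independently
#' seeded fold plans (and classifier fits), collecting the per-run pooled
#' accuracy -- the repeated train/test protocol behind an accuracy
#' histogram.
#'
#' @param data Feature table (see [cross_validate()]).
#' @param spec A [classifier_spec()] (feature-based methods).
#' @param n_reps Number of repetitions (default 500).
#' @param k Folds per repetition.
#' @param seed Master seed; repetition `i` uses a seed derived from
#'   `seed` and `i`.
#' @param bins Number of histogram bins for the binned summary.
#' @return List with `accuracies` (length `n_reps`), `histogram` (data
#'   frame `bin_left`, `bin_right`, `relative_frequency`), `mean`, `sd`.
#' @export
repeated_cv <- function(data, spec, n_reps = 500, k = 10, seed = 1,
                        bins = 20) {
  acc <- vapply(seq_len(n_reps), function(i) {
    cross_validate(data, spec, k = k,
                   seed = .mix_seed(seed, "rep", i))$accuracy
  }, numeric(1))
  h <- graphics::hist(acc, breaks = bins, plot = FALSE)
  hist_df <- data.frame(bin_left = utils::head(h$breaks, -1),
                        bin_right = utils::tail(h$breaks, -1),
                        relative_frequency = h$counts / length(acc))
  list(accuracies = acc, histogram = hist_df,
       mean = mean(acc), sd = stats::sd(acc))
}
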