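#' Balance a training set by seeded undersampling
#'
#' Randomly undersamples the majority class (without replacement) to the
#' minority count. Test sets are never balanced; this is applied to
#' training folds only.
#'
#' @param segments a [segment_set] with both classes present.
#' @param seed integer seed.
#' @return a balanced [segment_set].
#' @export
balance_training_set <- function(segments, seed = 1L) {
  stopifnot(inherits(segments, "segment_set"))
  i0 <- which(segments$label == 0L)
  i1 <- which(segments$label == 1L)
  if (!length(i0) || !length(i1))
    stop("balance error: one class absent from the training set")
  set.seed(seed)
  m <- min(length(i0), length(i1))
  keep <- sort(c(sample(i0, m), sample(i1, m)))
  subset_segments(segments, keep)
}

#' Confusion counts for one test subject
#'
#' The positive class defaults to label 0 (high engagement / manual
#' driving); the convention is recorded in the result.
#'
#' @param truth,predicted integer 0/1 label vectors.
#' @param positive which label counts as positive.
#' @return an object of class `confusion_counts` with fields TP, FP, TN,
#'   FN.
#' @export
confusion_counts <- function(truth, predicted, positive = 0L) {
  stopifnot(length(truth) == length(predicted))
  pos <- truth == positive
  ppos <- predicted == positive
  structure(list(TP = sum(pos & ppos), FP = sum(!pos & ppos),
                 TN = sum(!pos & !ppos), FN = sum(pos & !ppos),
                 positive = positive),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes, in percent: accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(FP+TN)`, balanced accuracy
#' `(sensitivity+specificity)/2` and the geometric mean
#' `sqrt(sensitivity x specificity)` (on the fractional scale). A metric
#' with an empty denominator is reported as `NA` rather than 0.
#'
#' @param counts a [confusion_counts] (or a list with TP/FP/TN/FN).
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `BA`, `GM`, percentages in \[0, 100\].
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  if (total <= 0) stop("compute_metrics needs at least one observation")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
  c(accuracy = 100 * (tp + tn) / total,
    sensitivity = 100 * sens,
    specificity = 100 * spec,
    BA = 100 * (sens + spec) / 2,
    GM = 100 * sqrt(sens * spec))
}

#' Leave-one-subject-out evaluation
#'
#' For every subject: train on the balanced union of all other subjects'
#' segments and test on all of that subject's segments (left imbalanced),
#' recording confusion counts and the five metrics. Training and test
#' subject sets are disjoint in every fold. Per-metric cohort mean and
#' standard deviation are computed over subjects; folds where a metric is
#' undefined are excluded from that metric's aggregate with a warning.
#'
#' @param segments a [segment_set] covering at least two subjects, each
#'   with both classes.
#' @param spec a [model_spec].
#' @param seed root seed; expands to per-fold substreams for balancing and
#'   training.
#' @param positive positive-class label for sensitivity/specificity.
#' @param verbose print fold progress.
#' @return an object of class `loso_result`: `per_subject` data frame,
#'   `confusion` list, `mean`, `sd`, `spec`.
#' @export
loso_evaluate <- function(segments, spec, seed = 1L, positive = 0L,
                          verbose = FALSE) {
  stopifnot(inherits(segments, "segment_set"))
  subjects <- unique(segments$subject_id)
  if (length(subjects) < 2)
    stop("LOSO needs at least two subjects")
  rows <- list(); conf <- list()
  for (k in seq_along(subjects)) {
    s <- subjects[k]
    test_idx <- segments$subject_id == s
    if (!any(test_idx)) {
      warning("subject ", s, " has zero segments; fold skipped")
      next
    }
    train <- subset_segments(segments, !test_idx)
    test <- subset_segments(segments, test_idx)
    stopifnot(!any(train$subject_id %in% s))
    fold_seed <- seed * 1000L + k
    train <- balance_training_set(train, seed = fold_seed)
    fspec <- spec
    fspec$seed <- fold_seed
    fit <- engagement_net(train, spec = fspec, verbose = FALSE)
    pred <- predict(fit, test)
    cc <- confusion_counts(test$label, pred, positive = positive)
    met <- compute_metrics(cc)
    rows[[s]] <- data.frame(subject_id = s, t(met),
                            n_test = length(test),
                            check.names = FALSE)
    conf[[s]] <- cc
    if (verbose)
      message(sprintf("fold %s: accuracy %.1f%% (%d test segments)",
                      s, met[["accuracy"]], length(test)))
  }
  per_subject <- do.call(rbind, rows)
  rownames(per_subject) <- NULL
  metric_cols <- c("accuracy", "sensitivity", "specificity", "BA", "GM")
  if (anyNA(per_subject[metric_cols]))
    warning("some folds have undefined metrics; they are excluded from the aggregate")
  structure(list(per_subject = per_subject,
                 confusion = conf,
                 mean = colMeans(per_subject[metric_cols], na.rm = TRUE),
                 sd = apply(per_subject[metric_cols], 2, stats::sd,
                            na.rm = TRUE),
                 positive = positive, spec = spec, seed = seed),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("LOSO evaluation: %s / %s, %d subjects (positive class = %d)\n",
              x$spec$arch, x$spec$sensors, nrow(x$per_subject), x$positive))
  for (m in names(x$mean))
    cat(sprintf("  %-12s %5.1f +/- %4.1f %%\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Percent-of-total confusion matrix
#'
#' @param counts a [confusion_counts].
#' @return 2 x 2 matrix (actual x predicted) in percent of all segments.
#' @export
confusion_percent <- function(counts) {
  tot <- counts$TP + counts$FP + counts$TN + counts$FN
  m <- matrix(c(counts$TP, counts$FN, counts$FP, counts$TN), 2, 2) / tot * 100
  dimnames(m) <- list(actual = c("positive", "negative"),
                      predicted = c("positive", "negative"))
  m
}

#' Accuracy as a function of segmentation window length
#'
#' Re-segments the cleaned sessions at each window length, rebuilds the
#' networks (the flatten width follows the conv/pool floor rule) and runs
#' a full LOSO evaluation per length. Lengths below the architecture's
#' minimal valid input are reported as errors per length rather than
#' failing the sweep.
#'
#' @param clean_list list of [clean_session] objects (the cohort before
#'   segmentation).
#' @param spec a [model_spec]; `window_samples` is overridden per length.
#' @param lengths_s numeric vector of window lengths in seconds.
#' @param seed root seed forwarded to [loso_evaluate()].
#' @return data frame with `window_s`, `mean_accuracy`, `sd_accuracy`,
#'   `error` (NA or message).
#' @export
window_length_sweep <- function(clean_list, spec, lengths_s, seed = 1L) {
  fs <- clean_list[[1]]$fs
  out <- lapply(lengths_s, function(w) {
    win <- round(w * fs)
    res <- tryCatch({
      if (win < deep4_min_input())
        stop(sprintf("architecture error: %g s (%d samples) below minimal input %d",
                     w, win, deep4_min_input()))
      segs <- segment_cohort(clean_list, window_s = w)
      sp <- spec
      sp$window_samples <- win
      lr <- loso_evaluate(segs, sp, seed = seed)
      data.frame(window_s = w, mean_accuracy = lr$mean[["accuracy"]],
                 sd_accuracy = lr$sd[["accuracy"]], error = NA_character_)
    }, error = function(e) {
      data.frame(window_s = w, mean_accuracy = NA_real_,
                 sd_accuracy = NA_real_, error = conditionMessage(e))
    })
    res
  })
  do.call(rbind, out)
}
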