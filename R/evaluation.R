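#' Confusion counts for a binary recumbency classification
#'
#' Tallies a predicted against a true binary coding with "standing"
#' (code 1) as the positive class: TP = standing labelled standing,
#' TN = recumbent labelled recumbent, FP = recumbent labelled standing,
#' FN = standing labelled recumbent.
#'
#' @param truth,pred Integer vectors of codes in {0, 1}, same length.
#'
#' @return A `confusion_counts` object (list with `tp`, `fp`, `tn`, `fn`).
#' @export
confusion_counts <- function(truth, pred) {
  stop_if_not(length(truth) == length(pred), "truth and pred lengths differ")
  stop_if_not(all(truth %in% c(0L, 1L)) && all(pred %in% c(0L, 1L)),
              "codes must be 0 or 1")
  structure(list(tp = sum(truth == 1 & pred == 1),
                 fp = sum(truth == 0 & pred == 1),
                 tn = sum(truth == 0 & pred == 0),
                 fn = sum(truth == 1 & pred == 0)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), accuracy =
#' (TP + TN) / (TP + FP + TN + FN), each as a percentage at full
#' precision (round only at report time). A metric whose denominator is
#' zero is reported as `NA` (undefined), not as 0.
#'
#' @param counts A [confusion_counts()] object, or a list with fields
#'   `tp`, `fp`, `tn`, `fn`.
#'
#' @return Named numeric vector: `sensitivity`, `specificity`,
#'   `accuracy`, in percent.
#' @export
#' @examples
#' classification_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 0)))
classification_metrics <- function(counts) {
  cc <- counts[c("tp", "fp", "tn", "fn")]
  stop_if_not(!anyNA(cc) && all(unlist(cc) >= 0), "counts must be nonnegative")
  total <- cc$tp + cc$fp + cc$tn + cc$fn
  stop_if_not(total > 0, "all-zero confusion counts")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(sensitivity = ratio(cc$tp, cc$tp + cc$fn),
    specificity = ratio(cc$tn, cc$tn + cc$fp),
    accuracy = 100 * (cc$tp + cc$tn) / total)
}

#' K-fold cross-validation of the velocity-threshold classifier
#'
#' Shuffles the linked samples with a fixed seed into `k` folds whose
#' sizes differ by at most one; in each iteration one fold is the test
#' set, the threshold is fitted on the remaining folds, the test
#' velocities are classified, and the Table-2 metrics are computed.
#' Per-fold values and their unweighted averages are reported; a metric
#' undefined in a fold (missing class in the test set) is recorded `NA`
#' and excluded from that metric's average, with a message.
#'
#' @param samples Tibble with `v_mps` and `code`; both classes required,
#'   and `n >= k`.
#' @param k Number of folds (default 10, minimum 2).
#' @param seed Integer seed controlling the fold assignment.
#' @param method,step Passed to [fit_threshold()].
#'
#' @return An `eval_report`: list with `per_fold` (tibble of fold,
#'   threshold_mps, tp, fp, tn, fn, sensitivity, specificity, accuracy),
#'   `averages` (named vector), `k`, `seed`, `method`, `n`.
#' @export
cross_validate <- function(samples, k = 10, seed = 123, method = "exhaustive",
                           step = NULL) {
  check_samples(samples)
  n <- nrow(samples)
  stop_if_not(is_count(k) && k >= 2, "k must be an integer >= 2")
  stop_if_not(n >= k, "need at least k samples")

  fold <- with_seed(seed, {
    f <- integer(n)
    f[sample.int(n)] <- rep(seq_len(k), length.out = n)
    f
  })

  per_fold <- lapply(seq_len(k), function(i) {
    train <- samples[fold != i, , drop = FALSE]
    test <- samples[fold == i, , drop = FALSE]
    model <- fit_threshold(train, method = method, step = step)
    cc <- confusion_counts(test$code, classify_velocity(test$v_mps, model))
    m <- classification_metrics(cc)
    tibble::tibble(fold = i, threshold_mps = model$threshold_mps,
                   tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
                   sensitivity = m[["sensitivity"]],
                   specificity = m[["specificity"]],
                   accuracy = m[["accuracy"]])
  })
  per_fold <- dplyr::bind_rows(per_fold)
  metric_cols <- c("sensitivity", "specificity", "accuracy")
  n_undef <- sum(is.na(per_fold[metric_cols]))
  if (n_undef > 0) {
    log_msg("%d undefined per-fold metrics excluded from averages", n_undef)
  }
  averages <- colMeans(per_fold[metric_cols], na.rm = TRUE)
  structure(list(per_fold = per_fold, averages = averages,
                 k = as.integer(k), seed = as.integer(seed),
                 method = method, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold CV (%s fit, n = %d, seed %d)\n",
              x$k, x$method, x$n, x$seed))
  cat(sprintf("  average accuracy    %6.2f%%\n", x$averages[["accuracy"]]))
  cat(sprintf("  average sensitivity %6.2f%%\n", x$averages[["sensitivity"]]))
  cat(sprintf("  average specificity %6.2f%%\n", x$averages[["specificity"]]))
  invisible(x)
}

#' Welch t-test of velocity between the two behaviour classes
#'
#' Tests whether mean group velocity differs between images coded 1
#' (some pigs active) and 0 (group recumbency). The unequal-variance
#' Welch variant is used because the two classes typically differ grossly
#' in size and spread.
#'
#' @param samples Tibble with `v_mps` and `code`; at least 2 samples per
#'   class.
#' @param alpha Significance level used only for the reported
#'   `significant` flag (default 0.05).
#'
#' @return List with `t`, `df`, `p_value`, `mean_active`,
#'   `mean_recumbent`, `significant`.
#' @export
velocity_ttest <- function(samples, alpha = 0.05) {
  check_samples(samples)
  v1 <- samples$v_mps[samples$code == 1]
  v0 <- samples$v_mps[samples$code == 0]
  stop_if_not(length(v1) >= 2 && length(v0) >= 2, "need >= 2 samples per class")
  tt <- stats::t.test(v1, v0, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_active = mean(v1), mean_recumbent = mean(v0),
       significant = tt$p.value < alpha)
}

#' Accuracy as a function of the velocity cutoff
#'
#' Classification accuracy of the rule `v > threshold` at each candidate
#' cutoff — the accuracy-versus-threshold curve whose maximum the
#' exhaustive fitter attains.
#'
#' @param samples Tibble with `v_mps` and `code`.
#' @param thresholds Numeric vector of candidate cutoffs (>= 1).
#'
#' @return Tibble with `threshold_mps` and `accuracy` (percent).
#' @export
accuracy_curve <- function(samples, thresholds) {
  check_samples(samples, need_both_classes = FALSE)
  stop_if_not(length(thresholds) >= 1, "need at least one candidate threshold")
  acc <- vapply(thresholds, function(t) {
    100 * mean(as.integer(samples$v_mps > t) == samples$code)
  }, numeric(1))
  tibble::tibble(threshold_mps = as.numeric(thresholds), accuracy = acc)
}
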