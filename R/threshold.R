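#' Threshold model constructor
#'
#' A one-feature cutoff classifier on group velocity: a sample is
#' classified 1 (at least one pig standing) if and only if its velocity
#' strictly exceeds the threshold, and 0 (group recumbency) otherwise.
#' The boundary case is assigned to recumbency deliberately: the method's
#' purpose is to surface only images in which every pig is lying, so
#' false positives are the costly error.
#'
#' @param threshold_mps Velocity cutoff in m/s (nonnegative).
#' @param method One of `"exhaustive"`, `"paper_loop"`, `"mean_plus_sd"`.
#' @param fitted_on_n Number of samples the cutoff was fitted on.
#' @param train_accuracy Training accuracy in percent, when applicable.
#'
#' @return A `threshold_model` object.
#' @export
threshold_model <- function(threshold_mps, method, fitted_on_n = NA_integer_,
                            train_accuracy = NA_real_) {
  stop_if_not(is_scalar_number(threshold_mps) && threshold_mps >= 0,
              "threshold_mps must be >= 0")
  structure(list(threshold_mps = threshold_mps,
                 rule = "classify 1 iff v > threshold_mps",
                 method = method,
                 fitted_on_n = as.integer(fitted_on_n),
                 train_accuracy = train_accuracy),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> %s: v > %.10g m/s -> standing (fit on n = %s%s)\n",
              x$method, x$threshold_mps, x$fitted_on_n,
              ifelse(is.na(x$train_accuracy), "",
                     sprintf(", train accuracy %.1f%%", x$train_accuracy))))
  invisible(x)
}

check_samples <- function(samples, need_both_classes = TRUE) {
  stop_if_not(all(c("v_mps", "code") %in% names(samples)),
              "samples need columns v_mps and code")
  stop_if_not(all(samples$code %in% c(0L, 1L)), "codes must be 0 or 1")
  stop_if_not(all(samples$v_mps >= 0), "velocities must be >= 0")
  if (need_both_classes) {
    stop_if_not(any(samples$code == 0) && any(samples$code == 1),
                "both classes are required to fit a threshold")
  }
  invisible(samples)
}

# Number of correctly classified samples for each candidate cutoff, via a
# single sort: for cutoff t, predicted 1 are the velocities strictly above t.
candidate_accuracy <- function(v, code, candidates) {
  ord <- order(v)
  v_sorted <- v[ord]; y_sorted <- code[ord]
  cum0 <- cumsum(y_sorted == 0)
  cum1 <- cumsum(y_sorted == 1)
  tot1 <- sum(code == 1)
  i <- findInterval(candidates, v_sorted)  # samples with v <= candidate
  correct <- ifelse(i == 0, 0, cum0[pmax(i, 1)]) +
    (tot1 - ifelse(i == 0, 0, cum1[pmax(i, 1)]))
  list(accuracy = 100 * correct / length(v),
       sensitivity = 100 * (tot1 - ifelse(i == 0, 0, cum1[pmax(i, 1)])) / tot1)
}

#' Fit the velocity cutoff by exhaustive accuracy maximisation
#'
#' Tries every classification the data admits and keeps the cutoff that
#' maximises training accuracy. Candidates are the midpoints between
#' consecutive distinct sorted velocities, plus one candidate below the
#' minimum and one above the maximum (candidates are clamped at 0, since
#' a velocity cutoff cannot be negative). Ties are broken in favour of
#' higher sensitivity and then of the smaller threshold.
#'
#' @param samples Tibble of linked samples with `v_mps` and `code`; both
#'   classes must be present.
#'
#' @return A [threshold_model()] with `train_accuracy` set.
#' @export
#' @examples
#' s <- data.frame(v_mps = c(1e-4, 2e-4, 0.01, 0.02), code = c(0, 0, 1, 1))
#' fit_threshold_exhaustive(s)$threshold_mps  # 0.0051, the separating midpoint
fit_threshold_exhaustive <- function(samples) {
  check_samples(samples)
  v <- samples$v_mps; y <- samples$code
  sv <- sort(unique(v))
  gaps <- if (length(sv) > 1) diff(sv) else max(sv[1], 1e-9)
  below <- max(0, sv[1] - gaps[1] / 2)
  above <- sv[length(sv)] + gaps[length(gaps)] / 2
  mids <- if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2 else numeric(0)
  cand <- c(below, mids, above)
  ca <- candidate_accuracy(v, y, cand)
  best <- order(-ca$accuracy, -ca$sensitivity, cand)[1]
  threshold_model(cand[best], "exhaustive", fitted_on_n = length(v),
                  train_accuracy = ca$accuracy[best])
}

#' Fit the velocity cutoff by the stepwise loop heuristic
#'
#' A literal transcription of the narrative stepwise procedure: starting
#' from the smallest velocity, the cutoff is raised by `step` while the
#' number of code-1 samples above it keeps decreasing, and the last
#' cutoff before the count stops decreasing is recorded. If that cutoff
#' lies below the highest velocity observed in a code-0 sample, the loop
#' restarts from that velocity. The step size is a tunable the procedure
#' itself does not pin down; the exhaustive fitter is the canonical one.
#'
#' @inheritParams fit_threshold_exhaustive
#' @param step Positive cutoff increment in m/s; must not exceed the
#'   velocity range of the samples.
#'
#' @return A [threshold_model()] with `train_accuracy` set.
#' @export
fit_threshold_loop <- function(samples, step) {
  check_samples(samples)
  v <- samples$v_mps; y <- samples$code
  stop_if_not(is_scalar_number(step) && step > 0, "step must be > 0")
  rng <- diff(range(v))
  stop_if_not(step <= max(rng, .Machine$double.eps), "step larger than the velocity range")

  count_above <- function(t) sum(y == 1 & v > t)
  run_loop <- function(start) {
    t <- start
    n_above <- count_above(t)
    while (t <= max(v)) {
      t_next <- t + step
      n_next <- count_above(t_next)
      if (n_next >= n_above) break
      t <- t_next
      n_above <- n_next
    }
    t
  }
  cutoff <- run_loop(min(v))
  highest_recumbent <- max(v[y == 0])
  if (cutoff < highest_recumbent) cutoff <- run_loop(highest_recumbent)
  acc <- 100 * mean(as.integer(v > cutoff) == y)
  threshold_model(cutoff, "paper_loop", fitted_on_n = length(v), train_accuracy = acc)
}

#' Fit the velocity cutoff as recumbent mean plus one SD
#'
#' The screening rule first used before cutoff optimisation: the
#' threshold is the mean of the velocities observed during group
#' recumbency plus one sample standard deviation.
#'
#' @param recumbent_velocities Numeric vector of code-0 window
#'   velocities; at least 2 values.
#'
#' @return A [threshold_model()].
#' @export
fit_threshold_mean_sd <- function(recumbent_velocities) {
  v <- recumbent_velocities
  stop_if_not(is.numeric(v) && length(v) >= 2, "need >= 2 recumbent velocities")
  stop_if_not(all(v >= 0), "velocities must be >= 0")
  threshold_model(mean(v) + stats::sd(v), "mean_plus_sd", fitted_on_n = length(v))
}

#' Fit a threshold model by a named method
#'
#' Dispatcher used by cross-validation and the pipeline.
#'
#' @inheritParams fit_threshold_exhaustive
#' @param method `"exhaustive"` (default), `"paper_loop"` or
#'   `"mean_plus_sd"`.
#' @param step Step size for `"paper_loop"`; defaults to 1/100 of the
#'   velocity range.
#'
#' @return A [threshold_model()].
#' @export
fit_threshold <- function(samples, method = c("exhaustive", "paper_loop", "mean_plus_sd"),
                          step = NULL) {
  method <- match.arg(method)
  switch(method,
         exhaustive = fit_threshold_exhaustive(samples),
         paper_loop = {
           check_samples(samples)
           step <- step %||% (diff(range(samples$v_mps)) / 100)
           fit_threshold_loop(samples, step)
         },
         mean_plus_sd = {
           check_samples(samples)
           fit_threshold_mean_sd(samples$v_mps[samples$code == 0])
         })
}

#' Classify velocities with a fitted threshold model
#'
#' @param v Numeric vector of nonnegative group velocities in m/s.
#' @param model A [threshold_model()].
#'
#' @return Integer codes: 1 where `v > threshold`, else 0 (a velocity
#'   exactly at the threshold is classified as group recumbency).
#' @export
classify_velocity <- function(v, model) {
  stop_if_not(inherits(model, "threshold_model"), "model must be a threshold_model")
  stop_if_not(all(v >= 0), "velocities must be >= 0")
  as.integer(v > model$threshold_mps)
}
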