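#' Sample-wise binary confusion counts
#'
#' Compares a predicted artifact mask with an annotated truth mask sample
#' by sample, with artifact as the positive class.
#'
#' @param pred,truth logical vectors of equal length.
#' @return A list of class `confusion_counts` with fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_from_masks <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("prediction and truth masks must have equal length")
  }
  stopifnot(is.logical(pred), is.logical(truth))
  structure(
    list(tp = sum(pred & truth), tn = sum(!pred & !truth),
         fp = sum(pred & !truth), fn = sum(!pred & truth)),
    class = "confusion_counts"
  )
}

#' Binary detector performance metrics
#'
#' `accuracy` is the fraction of the signal classified correctly,
#' `(TP + TN) / (TP + FP + FN + TN)`.  `hit_rate` is the proportion of
#' signal annotated as artifact that was detected, `TP / (TP + FN)`.
#' `false_discovery_rate` is the proportion of detected signal that was
#' not annotated as artifact, `FP / (TP + FP)`.  A zero denominator
#' yields `NA` (never silently 0).
#'
#' @param counts a [confusion_from_masks()] result.
#' @return A fraction in `[0, 1]`, or `NA_real_` when undefined.
#' @export
accuracy <- function(counts) {
  tot <- counts$tp + counts$tn + counts$fp + counts$fn
  if (tot == 0) return(NA_real_)
  (counts$tp + counts$tn) / tot
}

#' @rdname accuracy
#' @export
hit_rate <- function(counts) {
  den <- counts$tp + counts$fn
  if (den == 0) return(NA_real_)
  counts$tp / den
}

#' @rdname accuracy
#' @export
false_discovery_rate <- function(counts) {
  den <- counts$tp + counts$fp
  if (den == 0) return(NA_real_)
  counts$fp / den
}

#' Multi-class (extended confusion matrix) metrics
#'
#' For a K-by-K confusion matrix with rows as true class and columns as
#' predicted class: overall accuracy is `trace / sum`; per-class precision
#' is the diagonal over the column sum (one class vs all); per-class
#' sensitivity is the diagonal over the row sum; the mean precision and
#' mean sensitivity are unweighted averages over the K classes.
#' Components with a zero denominator are `NA` and are excluded from the
#' means with a warning.
#'
#' @param m numeric K-by-K matrix of epoch counts, optionally with
#'   dimnames giving the class labels.
#' @return A list with `overall_accuracy`, `precision`, `sensitivity`,
#'   `mean_precision`, `mean_sensitivity`.
#' @export
multiclass_metrics <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (any(m < 0)) stop("confusion matrix entries must be >= 0")
  if (sum(m) == 0) stop("confusion matrix is all zero")
  dg <- diag(m)
  prec <- ifelse(colSums(m) > 0, dg / colSums(m), NA_real_)
  sens <- ifelse(rowSums(m) > 0, dg / rowSums(m), NA_real_)
  if (anyNA(prec) || anyNA(sens)) {
    warning("undefined per-class components excluded from the means")
  }
  labs <- colnames(m)
  if (!is.null(labs)) names(prec) <- names(sens) <- labs
  list(overall_accuracy = sum(dg) / sum(m),
       precision = prec, sensitivity = sens,
       mean_precision = mean(prec, na.rm = TRUE),
       mean_sensitivity = mean(sens, na.rm = TRUE))
}

#' Mean classifier confidence
#'
#' For each epoch's class-probability row, the confidence is the
#' difference between the two highest probabilities; a winning class just
#' ahead of the runner-up gives low confidence.  Returns the mean over
#' epochs.
#'
#' @param probs epochs-by-K matrix of class probabilities; each row must
#'   be non-negative and sum to 1 within 1e-6; K >= 2.
#' @return Mean confidence in `[0, 1]`.
#' @export
classifier_confidence <- function(probs) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) >= 2L)
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("each probability row must sum to 1 (within 1e-6)")
  }
  conf <- apply(probs, 1L, function(p) {
    s <- sort(p, decreasing = TRUE)
    s[1L] - s[2L]
  })
  mean(conf)
}

#' Rank-test effect sizes
#'
#' `epsilon_squared` converts a Kruskal-Wallis H statistic over `n` total
#' observations into the epsilon-squared effect size,
#' `H * (n + 1) / (n^2 - 1)`; `eta_squared_z` converts a rank-sum
#' Z statistic over `n = n1 + n2` observations into `Z^2 / n`.  Both
#' range from 0 (negligible) to 1 (very strong) and are clipped to that
#' range.
#'
#' @param h Kruskal-Wallis chi-squared statistic.
#' @param z rank-sum (Wilcoxon/Mann-Whitney) Z statistic.
#' @param n total number of observations (> 1).
#' @return Effect size in `[0, 1]`.
#' @export
epsilon_squared <- function(h, n) {
  if (n <= 1) stop("effect size needs n > 1")
  min(max(h * (n + 1) / (n^2 - 1), 0), 1)
}

#' @rdname epsilon_squared
#' @export
eta_squared_z <- function(z, n) {
  if (n <= 1) stop("effect size needs n > 1")
  min(max(z^2 / n, 0), 1)
}

#' Evaluate a detector against annotations, per window duration
#'
#' Runs the full pipeline once per window duration and scores the
#' detected large-amplitude intervals against truth annotations sample by
#' sample, giving a window-sweep summary (accuracy, hit rate, FDR and
#' their product) like the tables used to choose the operating window.
#'
#' @param rec a [recording()].
#' @param truth an [interval_set()] of annotated artifact intervals.
#' @param window_s numeric vector of window durations to sweep (s).
#' @param config base [detector_config()]; its `window_s` is overridden.
#' @return Data frame with one row per window duration: `window_s`,
#'   `accuracy`, `hit_rate`, `fdr`, `acc_x_hr`, `removed_fraction`.
#' @export
sweep_windows <- function(rec, truth, window_s = 1:7,
                          config = detector_config()) {
  views <- prepare_views(rec, config)
  truth_mask <- intervals_to_mask(truth, rec$fs, n_samples(rec))
  rows <- lapply(window_s, function(w) {
    cfg <- config
    cfg$window_s <- w
    iv <- detect_large_amplitude(views$band, views$notched, cfg)
    pred <- intervals_to_mask(iv, rec$fs, n_samples(rec))
    cc <- confusion_from_masks(pred, truth_mask)
    data.frame(window_s = w, accuracy = accuracy(cc), hit_rate = hit_rate(cc),
               fdr = false_discovery_rate(cc),
               acc_x_hr = accuracy(cc) * hit_rate(cc),
               removed_fraction = mean(pred))
  })
  do.call(rbind, rows)
}
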