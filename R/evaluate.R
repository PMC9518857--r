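#' Positive-class scores for feature segments
#'
#' Softmax probability of the positive (mTBI) class per segment; inference
#' mode, so deterministic.
#'
#' @param model A trained `bilstm_a`.
#' @param segments `n x frames x coefs` array, matrix, list of matrices, or
#'   a `feature_dataset`.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict_scores <- function(model, segments) {
  if (inherits(segments, "feature_dataset")) {
    segments <- dataset_arrays(segments)$x
  }
  forward(model, segments, training = FALSE)$probs[, 2L]
}

#' @export
predict.bilstm_a <- function(object, newdata, type = c("prob", "class"),
                             threshold = 0.5, ...) {
  type <- match.arg(type)
  s <- predict_scores(object, newdata)
  if (type == "prob") s else as.integer(s >= threshold)
}

#' Confusion matrix at a decision threshold
#'
#' Scores at or above the threshold predict positive (mTBI).
#'
#' @param scores Positive-class scores in `[0, 1]`.
#' @param labels Binary labels (1 = mTBI).
#' @param threshold Decision threshold, default 0.5.
#' @return A list of class `confusion_matrix` with counts `tp`, `fp`, `tn`,
#'   `fn` and derived `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0L) stop("confusion_at_threshold: empty inputs")
  if (length(scores) != length(labels)) {
    stop("confusion_at_threshold: scores and labels differ in length")
  }
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = (tp + tn) / length(labels),
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         threshold = threshold),
    class = "confusion_matrix"
  )
}

#' ROC curve and AUROC
#'
#' Sweeps the threshold over the unique scores (plus sentinels) from high to
#' low, producing points from (0,0) to (1,1); tied scores move horizontally
#' and vertically in one simultaneous step, which makes the trapezoidal area
#' equal the pairwise-ranking (rank-sum) estimator with the half-credit tie
#' convention.
#'
#' @param scores Positive-class scores.
#' @param labels Binary labels; both classes must be present.
#' @return A list of class `roc_curve` with `points` (data.frame
#'   `threshold`, `fpr`, `tpr`) and `auroc`.
#' @export
roc_and_auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_and_auroc: both classes must be present")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, cumsum(vapply(thr, function(t) {
    sum(labels == 1L & scores == t)
  }, numeric(1))) / n_pos)
  fpr <- c(0, cumsum(vapply(thr, function(t) {
    sum(labels == 0L & scores == t)
  }, numeric(1))) / n_neg)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(
    list(points = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
         auroc = auroc),
    class = "roc_curve"
  )
}

#' Evaluate a trained model on one partition
#'
#' Segment-level by default; participant-level granularity averages each
#' participant's segment scores (the threshold on the mean score then acts
#' as a majority vote for the confusion matrix).
#'
#' @param model A trained `bilstm_a`.
#' @param data A `feature_dataset`.
#' @param split A `split_assignment`.
#' @param partition Which partition to evaluate, default `"test"`.
#' @param granularity `"segment"` or `"participant"`.
#' @param threshold Decision threshold for the confusion matrix.
#' @return A list of class `evaluation_report`: `confusion`, `accuracy`,
#'   `sensitivity`, `specificity`, `roc`, `auroc`, `granularity`, `n_units`.
#' @export
evaluate_model <- function(model, data, split, partition = "test",
                           granularity = c("segment", "participant"),
                           threshold = 0.5) {
  granularity <- match.arg(granularity)
  arr <- dataset_arrays(data)
  part <- setNames(as.character(split$partition), split$participant_id)
  keep <- which(part[arr$participant_id] == partition)
  if (!length(keep)) stop("evaluate_model: no segments in partition ",
                          partition)
  scores <- predict_scores(model, arr$x[keep, , , drop = FALSE])
  labels <- arr$y[keep]
  if (granularity == "participant") {
    pid <- arr$participant_id[keep]
    scores <- tapply(scores, pid, mean)
    labels <- tapply(labels, pid, function(l) l[1L])
    scores <- as.numeric(scores)
    labels <- as.integer(labels)
  }
  cm <- confusion_at_threshold(scores, labels, threshold)
  roc <- roc_and_auroc(scores, labels)
  structure(
    list(confusion = cm, accuracy = cm$accuracy,
         sensitivity = cm$sensitivity, specificity = cm$specificity,
         roc = roc, auroc = roc$auroc, granularity = granularity,
         n_units = length(labels), scores = scores, labels = labels),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %s-level, n=%d\n  accuracy %.3f | sensitivity %.3f | specificity %.3f | AUROC %.3f\n  confusion: tp=%d fp=%d tn=%d fn=%d\n",
    x$granularity, x$n_units, x$accuracy, x$sensitivity, x$specificity,
    x$auroc, x$confusion$tp, x$confusion$fp, x$confusion$tn,
    x$confusion$fn))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `metrics.csv` (granularity, tp, fp, tn, fn, accuracy, sensitivity,
#' specificity, auroc) and `roc.csv` (threshold, fpr, tpr) into a directory.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  if (nrow(report$roc$points) == 0L) stop("write_report: empty ROC")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- data.frame(
    granularity = report$granularity, tp = report$confusion$tp,
    fp = report$confusion$fp, tn = report$confusion$tn,
    fn = report$confusion$fn, accuracy = report$accuracy,
    sensitivity = report$sensitivity, specificity = report$specificity,
    auroc = report$auroc
  )
  utils::write.csv(metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(report$roc$points, file.path(dir, "roc.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read back a written evaluation report
#' @param dir Directory written by [write_report].
#' @return List with `metrics` and `roc` data.frames.
#' @export
read_report <- function(dir) {
  list(metrics = utils::read.csv(file.path(dir, "metrics.csv"),
                                 stringsAsFactors = FALSE),
       roc = utils::read.csv(file.path(dir, "roc.csv"),
                             stringsAsFactors = FALSE))
}
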