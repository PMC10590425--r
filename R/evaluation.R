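as_phase_labels <- function(x) {
  if (inherits(x, "annotation_track") || inherits(x, "prediction_track")) {
    x <- x$labels
  }
  x <- as.character(x)
  phase_code(x)
  x
}

#' Confusion matrix over the four phases
#'
#' Entry `(r, c)` counts frames whose true phase is `r` and predicted phase
#' is `c`; rows are the true phases in canonical order.
#'
#' @param pred Predicted labels (a [prediction_track()] or character vector).
#' @param truth True labels (an [annotation_track()] or character vector).
#' @return 4x4 integer matrix with phase dimnames.
#' @export
confusion_matrix <- function(pred, truth) {
  p <- as_phase_labels(pred)
  t_ <- as_phase_labels(truth)
  if (length(p) != length(t_)) {
    stop("prediction and truth differ in length (", length(p), " vs ",
         length(t_), ")", call. = FALSE)
  }
  cm <- table(factor(t_, levels = esd_phases()),
              factor(p, levels = esd_phases()))
  m <- matrix(as.integer(cm), 4L, 4L,
              dimnames = list(truth = esd_phases(), predicted = esd_phases()))
  m
}

#' Overall frame-level metrics from a confusion matrix
#'
#' Accuracy is the multi-class frame accuracy `trace / total`. Precision and
#' recall are computed one-vs-rest per phase (`TP/(TP+FP)` and `TP/(TP+FN)`)
#' and macro-averaged over the phases present in the truth; a phase with no
#' predicted positives contributes precision 0. `average = "micro"` pools the
#' one-vs-rest counts instead (for single-label multi-class data micro
#' precision and recall both equal the accuracy).
#'
#' @param cm 4x4 confusion matrix from [confusion_matrix()].
#' @param average `"macro"` (default) or `"micro"`.
#' @return Named list: `accuracy`, `precision`, `recall`, plus per-phase
#'   vectors `precision_by_phase`, `recall_by_phase`.
#' @export
overall_metrics <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  total <- sum(cm)
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  present <- rowSums(cm) > 0
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  if (average == "macro") {
    precision <- mean(prec[present])
    recall <- mean(rec[present])
  } else {
    precision <- sum(tp) / sum(tp + fp)
    recall <- sum(tp) / sum(tp + fn)
  }
  list(accuracy = sum(tp) / total, precision = precision, recall = recall,
       precision_by_phase = prec, recall_by_phase = rec)
}

#' ROC curve and AUROC for one phase (one-vs-rest)
#'
#' Sweeps the decision threshold over the unique scores (predict positive
#' when `score >= threshold`); the area under the curve is computed by
#' trapezoidal integration, which for this construction equals the
#' Mann-Whitney U statistic with ties given half credit.
#'
#' @param scores Numeric per-frame scores (e.g. the phase probability).
#' @param truth Binary labels (logical or 0/1): 1 = frame belongs to the
#'   phase.
#' @return Object of class `roc_curve`: `thresholds` (decreasing, starting
#'   at `Inf`), `fpr`, `tpr`, `auroc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("length mismatch", call. = FALSE)
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to form a ROC curve", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  t_sorted <- truth[ord]
  n <- length(s_sorted)
  cum_tp <- cumsum(t_sorted)
  cum_fp <- cumsum(!t_sorted)
  # index of the last element of each tied run = last element >= that score
  last_at <- c(which(s_sorted[-1L] != s_sorted[-n]), n)
  thr <- c(Inf, s_sorted[last_at])
  tpr <- c(0, cum_tp[last_at] / n_pos)
  fpr <- c(0, cum_fp[last_at] / n_neg)
  auroc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auroc = auroc),
            class = "roc_curve")
}

#' @rdname roc_curve
#' @details `auroc_rank()` computes the same area directly from the
#'   Mann-Whitney rank formulation (mean mid-ranks; ties half credit) without
#'   forming the curve.
#' @return `auroc_rank()`: scalar AUROC.
#' @export
auroc_rank <- function(scores, truth) {
  truth <- as.logical(truth)
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-index optimal threshold of a ROC curve
#'
#' Returns the threshold maximising `J = sensitivity + specificity - 1 =
#' TPR - FPR`; ties are broken toward the higher threshold (the more
#' conservative positive call).
#'
#' @param curve A [roc_curve()].
#' @return Named list: `threshold`, `j` (the Youden index there).
#' @export
youden_threshold <- function(curve) {
  j <- curve$tpr - curve$fpr
  best <- which.max(j)  # thresholds are decreasing: first max = highest
  list(threshold = curve$thresholds[best], j = j[best])
}

#' Per-phase metrics at the Youden operating point
#'
#' For one phase (one-vs-rest): the AUROC, the Youden-optimal threshold on
#' the phase probability, and the thresholded confusion counts, from which
#' specificity `TN/(TN+FP)`, sensitivity `TP/(TP+FN)` and orderliness
#' `(TP+TN)/(TP+TN+FP+FN)` are computed. When the phase is absent from the
#' truth the metrics are marked unavailable rather than raising an error.
#'
#' @param pred A [prediction_track()] (its probability column for `phase` is
#'   used) or a numeric score vector.
#' @param truth An [annotation_track()] or character label vector.
#' @param phase Phase name.
#' @return Object of class `phase_metrics` with fields `phase`, `available`,
#'   `auroc`, `youden_threshold`, `specificity`, `sensitivity`,
#'   `orderliness`, `counts` (tp, tn, fp, fn).
#' @export
phase_metrics <- function(pred, truth, phase) {
  stopifnot(phase %in% esd_phases())
  scores <- if (inherits(pred, "prediction_track")) pred$probs[, phase] else as.numeric(pred)
  y <- as_phase_labels(truth) == phase
  if (length(scores) != length(y)) stop("length mismatch", call. = FALSE)
  if (!any(y) || all(y)) {
    return(structure(list(phase = phase, available = FALSE, auroc = NA_real_,
                          youden_threshold = NA_real_, specificity = NA_real_,
                          sensitivity = NA_real_, orderliness = NA_real_,
                          counts = c(tp = NA, tn = NA, fp = NA, fn = NA)),
                     class = "phase_metrics"))
  }
  curve <- roc_curve(scores, y)
  yt <- youden_threshold(curve)
  pos <- scores >= yt$threshold
  tp <- sum(pos & y)
  tn <- sum(!pos & !y)
  fp <- sum(pos & !y)
  fn <- sum(!pos & y)
  structure(list(phase = phase, available = TRUE, auroc = curve$auroc,
                 youden_threshold = yt$threshold,
                 specificity = tn / (tn + fp),
                 sensitivity = tp / (tp + fn),
                 orderliness = (tp + tn) / (tp + tn + fp + fn),
                 counts = c(tp = tp, tn = tn, fp = fp, fn = fn)),
            class = "phase_metrics")
}

#' @export
print.phase_metrics <- function(x, ...) {
  if (!x$available) {
    cat("<phase_metrics>", x$phase, ": unavailable (phase absent)\n")
  } else {
    cat(sprintf("<phase_metrics> %s: AUROC %.4f, thr %.4f, sens %.4f, spec %.4f, orderliness %.4f\n",
                x$phase, x$auroc, x$youden_threshold, x$sensitivity,
                x$specificity, x$orderliness))
  }
  invisible(x)
}

#' Student-t confidence interval for per-case metric values
#'
#' `mean +/- t_{n-1, (1+level)/2} * sd / sqrt(n)`, symmetric about the mean.
#' At least two cases are required (the interval is not computed for a single
#' case).
#'
#' @param values Numeric vector of per-case metric values (n >= 2).
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(mean, lower, upper)`.
#' @export
t_confidence_interval <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2L) stop("confidence interval requires at least 2 values", call. = FALSE)
  m <- mean(values)
  half <- stats::qt((1 + level) / 2, df = n - 1L) * stats::sd(values) / sqrt(n)
  c(mean = m, lower = m - half, upper = m + half)
}

#' Two-sided paired t-test
#'
#' Wrapper around the standard paired Student t-test with explicit
#' degeneracy checks: equal lengths, n >= 2, and nonzero variance of the
#' differences (identical vectors are rejected rather than returning NaN).
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return Two-sided p-value.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors differ in length", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (stats::sd(a - b) == 0) {
    stop("degenerate paired test: differences have zero variance", call. = FALSE)
  }
  stats::t.test(a, b, paired = TRUE)$p.value
}

#' Evaluate one predicted case against its annotation
#'
#' @param pred A [prediction_track()].
#' @param truth An [annotation_track()].
#' @return List: `confusion`, `overall` ([overall_metrics()]) and
#'   `per_phase` (list of [phase_metrics()], phases absent from the truth
#'   marked unavailable).
#' @export
evaluate_predictions <- function(pred, truth) {
  cm <- confusion_matrix(pred, truth)
  per_phase <- lapply(esd_phases(), function(ph) phase_metrics(pred, truth, ph))
  names(per_phase) <- esd_phases()
  list(confusion = cm, overall = overall_metrics(cm), per_phase = per_phase)
}

#' Pool evaluation over multiple cases
#'
#' Frames from all cases are pooled for the confusion matrix, overall
#' metrics and per-phase AUROC; per-case accuracy/precision/recall are also
#' tabulated and aggregated with a 95% Student-t confidence interval across
#' cases (the paper-style n = cases aggregation).
#'
#' @param predictions Named list of [prediction_track()]s.
#' @param truths Named list of matching [annotation_track()]s.
#' @return List: `pooled` (confusion, overall, per_phase), `per_case` (data
#'   frame), `aggregate` (mean and CI of per-case accuracy).
#' @export
evaluate_cases <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths))
  ids <- names(predictions)
  pooled_pred <- unlist(lapply(predictions, `[[`, "labels"), use.names = FALSE)
  pooled_truth <- unlist(lapply(truths, `[[`, "labels"), use.names = FALSE)
  pooled_probs <- do.call(rbind, lapply(predictions, `[[`, "probs"))
  cm <- confusion_matrix(pooled_pred, pooled_truth)
  pooled <- list(confusion = cm, overall = overall_metrics(cm),
                 per_phase = stats::setNames(lapply(esd_phases(), function(ph) {
                   phase_metrics(pooled_probs[, ph], pooled_truth, ph)
                 }), esd_phases()))
  per_case <- do.call(rbind, lapply(seq_along(ids), function(i) {
    om <- overall_metrics(confusion_matrix(predictions[[i]], truths[[i]]))
    data.frame(case_id = ids[i], n_frames = length(truths[[i]]$labels),
               accuracy = om$accuracy, precision = om$precision,
               recall = om$recall)
  }))
  aggregate <- if (nrow(per_case) >= 2L) {
    list(accuracy = t_confidence_interval(per_case$accuracy),
         precision = t_confidence_interval(per_case$precision),
         recall = t_confidence_interval(per_case$recall))
  }
  list(pooled = pooled, per_case = per_case, aggregate = aggregate)
}
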