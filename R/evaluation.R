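#' Confusion matrix from image-level predictions
#'
#' Counts TP, FN, TN, FP; when histopathology grades are supplied
#' (Healthy, MiD, MoD, HiD, SCC) a per-grade breakdown is attached whose
#' rows sum to the binary totals.
#'
#' @param predictions Predicted labels (`"positive"`/`"negative"` or any
#'   encoding accepted by the package).
#' @param labels True labels, same length.
#' @param grades Optional character vector of histopathology grades.
#' @return Object of class `confusion_matrix` with fields `TP`, `FN`,
#'   `TN`, `FP` and optionally `by_grade`.
#' @export
confusion <- function(predictions, labels, grades = NULL) {
  if (length(predictions) != length(labels))
    abort_validation("predictions and labels differ in length")
  p <- as_label01(predictions)
  y <- as_label01(labels)
  cm <- list(TP = sum(p == 1 & y == 1), FN = sum(p == 0 & y == 1),
             TN = sum(p == 0 & y == 0), FP = sum(p == 1 & y == 0))
  if (!is.null(grades)) {
    if (length(grades) != length(labels))
      abort_validation("grades and labels differ in length")
    lv <- c("Healthy", "MiD", "MoD", "HiD", "SCC")
    g <- factor(grades, levels = union(lv, unique(grades)))
    cm$by_grade <- t(vapply(levels(g), function(gr) {
      i <- which(g == gr)
      c(pred_neg = sum(p[i] == 0), pred_pos = sum(p[i] == 1))
    }, c(pred_neg = 0, pred_pos = 0)))
  }
  structure(cm, class = "confusion_matrix")
}

#' Build a confusion matrix directly from counts
#'
#' @param TP,FN,TN,FP Nonnegative integer counts.
#' @param by_grade Optional grade-by-prediction count matrix (columns
#'   `pred_neg`, `pred_pos`).
#' @return A `confusion_matrix`.
#' @export
confusion_from_counts <- function(TP, FN, TN, FP, by_grade = NULL) {
  counts <- c(TP, FN, TN, FP)
  if (any(counts < 0) || any(counts != round(counts)))
    abort_validation("counts must be nonnegative integers")
  structure(list(TP = TP, FN = FN, TN = TN, FP = FP, by_grade = by_grade),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TN, x$FP, x$FN, x$TP), 2, 2, byrow = TRUE,
              dimnames = list(c("true neg", "true pos"),
                              c("pred neg", "pred pos")))
  print(m)
  if (!is.null(x$by_grade)) {
    cat("by grade:\n")
    print(x$by_grade)
  }
  invisible(x)
}

metric_or_flag <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator)", what), call. = FALSE)
    return(structure(NA_real_, undefined = TRUE))
  }
  num / den
}

#' Sensitivity, specificity and F1 from a confusion matrix
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `f1 = TP / (TP + (FP + FN) / 2)`. Undefined metrics (zero denominator)
#' return `NA` flagged with attribute `undefined`, never a silent 0.
#'
#' @param cm A [confusion()] result.
#' @return Scalar in `[0, 1]` (or flagged `NA`).
#' @export
sensitivity <- function(cm) metric_or_flag(cm$TP, cm$TP + cm$FN, "sensitivity")

#' @rdname sensitivity
#' @export
specificity <- function(cm) metric_or_flag(cm$TN, cm$TN + cm$FP, "specificity")

#' @rdname sensitivity
#' @export
f1 <- function(cm)
  metric_or_flag(cm$TP, cm$TP + (cm$FP + cm$FN) / 2, "F1")

#' All classification metrics, with report-style rounding
#'
#' Convenience wrapper computing sensitivity, specificity (as half-up
#' rounded integer percentages) and F1 (rounded to 2 decimals) alongside
#' the exact values.
#'
#' @param cm A [confusion()] result.
#' @return List with `sensitivity`, `specificity`, `f1` (exact) and
#'   `sensitivity_pct`, `specificity_pct`, `f1_2dp` (printed precision).
#' @export
classification_metrics <- function(cm) {
  se <- sensitivity(cm); sp <- specificity(cm); f <- f1(cm)
  list(sensitivity = se, specificity = sp, f1 = f,
       sensitivity_pct = percent_half_up(se),
       specificity_pct = percent_half_up(sp),
       f1_2dp = round_half_up(f, 2))
}

# Half-up rounding (R's round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
percent_half_up <- function(x) round_half_up(100 * x, 0)

#' ROC area under the curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) score
#' pairs where the positive scores higher, with half credit for ties;
#' identical to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Class labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_label01(labels)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0)
    abort_validation("ROC-AUC requires both classes")
  r <- rank(scores)                       # midranks handle ties
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Empirical ROC curve
#'
#' Stepwise curve including the (0,0) and (1,1) endpoints; thresholds are
#' the unique score cut points (prediction positive iff
#' `score >= threshold`).
#'
#' @inheritParams roc_auc
#' @return `data.frame` with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_label01(labels)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0)
    abort_validation("ROC curve requires both classes")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / npos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / nneg, 0)
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
             threshold = c(Inf, thr, -Inf))
}

#' Bundled reference cross-validation confusion matrices
#'
#' Reference confusion matrices from a 7-fold cross-validation of the three
#' headline classifier configurations — a spectral-feature linear SVM, a
#' time-resolved-feature QDA, and their weighted-posterior ensemble — on a
#' paired 34-patient oral maFLIM dataset (34 lesion + 34 contralateral
#' healthy images; lesion grades MiD/MoD/HiD/SCC pooled as positive). Used
#' to validate the metric arithmetic: feeding these counts through
#' [sensitivity()], [specificity()] and [f1()] reproduces the reference
#' operating points (ensemble 94% / 74% / 0.85).
#'
#' @return Named list of three [confusion_from_counts()] objects:
#'   `svm_spectral`, `qda_time`, `ensemble`.
#' @export
reference_confusions <- function() {
  grades <- c("Healthy", "MiD", "MoD", "HiD", "SCC")
  bg <- function(neg, pos)
    matrix(c(neg, pos), ncol = 2,
           dimnames = list(grades, c("pred_neg", "pred_pos")))
  list(
    svm_spectral = confusion_from_counts(
      TP = 28, FN = 6, TN = 25, FP = 9,
      by_grade = bg(c(25, 1, 0, 1, 4), c(9, 0, 1, 2, 25))),
    qda_time = confusion_from_counts(
      TP = 31, FN = 3, TN = 24, FP = 10,
      by_grade = bg(c(24, 0, 0, 0, 3), c(10, 1, 1, 3, 26))),
    ensemble = confusion_from_counts(
      TP = 32, FN = 2, TN = 25, FP = 9,
      by_grade = bg(c(25, 0, 0, 0, 2), c(9, 1, 1, 3, 27)))
  )
}
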