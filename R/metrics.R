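#' Confusion counts from TP/FP/TN/FN tallies
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return An object of class \code{confusion_counts}.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  if (sum(counts) < 1) stop("confusion counts sum to zero", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d tn=%d fn=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Tally a confusion table for one positive class
#'
#' One-vs-rest reduction: every label equal to \code{positive} is a positive,
#' everything else a negative, so multi-class inputs reduce to binary counts.
#'
#' @param true,predicted Equal-length label vectors.
#' @param positive The label treated as the positive class; must occur in the
#'   label universe of \code{true} or \code{predicted}.
#' @return A \code{\link{confusion_counts}} object.
#' @export
confusion <- function(true, predicted, positive) {
  if (length(true) != length(predicted))
    stop("true and predicted labels differ in length", call. = FALSE)
  if (length(true) == 0L) stop("empty label vectors", call. = FALSE)
  universe <- unique(c(as.character(true), as.character(predicted)))
  if (!positive %in% universe)
    stop(sprintf("positive class '%s' absent from label universe", positive),
         call. = FALSE)
  tpos <- as.character(true) == positive
  ppos <- as.character(predicted) == positive
  confusion_counts(tp = sum(tpos & ppos), fp = sum(!tpos & ppos),
                   tn = sum(!tpos & !ppos), fn = sum(tpos & !ppos))
}

# Zero-denominator policy for the ratio metrics: by default return 0 with a
# warning so batch evaluation stays total; strict = TRUE raises instead.
safe_ratio <- function(num, den, what, strict = FALSE) {
  if (den == 0) {
    if (strict) stop(sprintf("%s undefined: zero denominator", what),
                     call. = FALSE)
    warning(sprintf("%s has zero denominator; returning 0", what),
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Classification accuracy
#'
#' \code{(TP + TN) / (TP + TN + FP + FN)}, the proportion of correct calls.
#'
#' @param c A \code{\link{confusion_counts}} object.
#' @return Value in [0, 1].
#' @export
accuracy <- function(c) {
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0) stop("accuracy undefined for zero total", call. = FALSE)
  (c$tp + c$tn) / total
}

#' Precision (positive predictive value)
#' @param c A \code{\link{confusion_counts}} object.
#' @param strict Error (rather than warn and return 0) on a zero denominator.
#' @return Value in [0, 1].
#' @export
precision <- function(c, strict = FALSE) {
  safe_ratio(c$tp, c$tp + c$fp, "precision", strict)
}

#' Recall (sensitivity, true-positive rate)
#' @inheritParams precision
#' @return Value in [0, 1].
#' @export
recall <- function(c, strict = FALSE) {
  safe_ratio(c$tp, c$tp + c$fn, "recall", strict)
}

#' Specificity (true-negative rate)
#' @inheritParams precision
#' @return Value in [0, 1].
#' @export
specificity <- function(c, strict = FALSE) {
  safe_ratio(c$tn, c$tn + c$fp, "specificity", strict)
}

#' F1 score
#'
#' Harmonic mean of precision and recall.
#' @inheritParams precision
#' @return Value in [0, 1].
#' @export
f1_score <- function(c, strict = FALSE) {
  p <- precision(c, strict); r <- recall(c, strict)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Classification success index (CSI)
#'
#' \code{precision + recall - 1}; ranges from -1 (all predictions are false
#' positives or false negatives) through 0 (random) to 1 (perfect).
#' @inheritParams precision
#' @return Value in [-1, 1].
#' @export
csi <- function(c, strict = FALSE) {
  precision(c, strict) + recall(c, strict) - 1
}

#' Geometric mean of recall and specificity (G-mean)
#'
#' \code{sqrt(recall * specificity)}, the balance measure between class-wise
#' performances.
#' @inheritParams precision
#' @return Value in [0, 1].
#' @export
gmean <- function(c, strict = FALSE) {
  sqrt(recall(c, strict) * specificity(c, strict))
}

#' Matthews correlation coefficient (MCC)
#'
#' \code{(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))}; 0 is returned
#' when any factor of the denominator is 0 (standard convention).
#' @param c A \code{\link{confusion_counts}} object.
#' @return Value in [-1, 1].
#' @export
mcc <- function(c) {
  num <- c$tp * c$tn - c$fp * c$fn
  den <- sqrt((c$tp + c$fp)) * sqrt((c$tp + c$fn)) *
         sqrt((c$tn + c$fp)) * sqrt((c$tn + c$fn))
  if (den == 0) return(0)
  num / den
}

#' Cohen's kappa for a binary confusion table
#'
#' Chance-corrected agreement,
#' \code{2(TP*TN - FP*FN) / [(TP+FP)(FP+TN) + (TP+FN)(FN+TN)]}.
#' @param c A \code{\link{confusion_counts}} object.
#' @return Value at most 1.
#' @export
cohen_kappa <- function(c) {
  den <- (c$tp + c$fp) * (c$fp + c$tn) + (c$tp + c$fn) * (c$fn + c$tn)
  if (den == 0) stop("kappa undefined: zero denominator", call. = FALSE)
  2 * (c$tp * c$tn - c$fp * c$fn) / den
}

#' ROC curve for one positive class
#'
#' Threshold sweep over the observed score values: each point is the
#' (false-positive rate, true-positive rate) pair obtained by predicting
#' positive at-or-above a threshold. The curve starts at (0,0) and ends at
#' (1,1); tied scores collapse into a single point, so the trapezoidal area
#' equals the concordant-pair (Mann-Whitney) statistic with half-credit for
#' ties.
#'
#' @param true Label vector.
#' @param scores Numeric score for the positive class.
#' @param positive Label treated as positive.
#' @return A \code{data.frame} (class \code{roc_curve}) with columns
#'   \code{threshold}, \code{fpr}, \code{tpr}.
#' @export
roc_curve <- function(true, scores, positive) {
  if (length(true) != length(scores))
    stop("labels and scores differ in length", call. = FALSE)
  y <- as.character(true) == positive
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop(sprintf("ROC needs both classes present (positive '%s')", positive),
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  keep <- !duplicated(s, fromLast = TRUE)   # last index of each tie group
  tpr <- cumsum(y)[keep] / n_pos
  fpr <- cumsum(!y)[keep] / n_neg
  out <- data.frame(threshold = c(Inf, s[keep]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  class(out) <- c("roc_curve", "data.frame")
  attr(out, "mode") <- "per-class"
  attr(out, "positive") <- positive
  out
}

# Trapezoidal area under an ROC curve.
auc_trapezoid <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                         utils::tail(curve$tpr, -1)) / 2)
}

#' ROC-AUC with per-class, micro, or macro averaging
#'
#' Binary truth with a score vector gives the positive-class AUC. With a
#' score matrix (one column per class, column names = class labels), micro
#' averaging pools every one-vs-rest (label, score) pair into a single
#' binary problem, while macro averaging computes each class AUC and takes
#' their unweighted mean; classes absent from the truth are skipped with a
#' warning in macro mode.
#'
#' @param true Label vector.
#' @param scores Numeric vector (binary) or matrix with one named column per
#'   class.
#' @param mode \code{"per-class"}, \code{"micro"}, or \code{"macro"}.
#' @param positive Positive label for \code{mode = "per-class"} with a score
#'   vector; defaults to the alphabetically larger... see Details.
#' @return List with elements \code{auc} and \code{curve} (the pooled curve
#'   for micro mode; per-class curves for macro mode).
#' @details For a plain score vector the positive class defaults to the
#'   first label in alphabetical order, matching the package-wide convention
#'   that class order is fixed alphabetically.
#' @export
roc_auc <- function(true, scores, mode = c("per-class", "micro", "macro"),
                    positive = NULL) {
  mode <- match.arg(mode)
  true <- as.character(true)
  if (is.matrix(scores) || is.data.frame(scores)) {
    scores <- as.matrix(scores)
    classes <- colnames(scores)
    if (is.null(classes)) stop("score matrix needs class column names",
                               call. = FALSE)
    if (mode == "per-class") {
      if (is.null(positive)) positive <- sort(unique(true))[1]
      curve <- roc_curve(true, scores[, positive], positive)
      return(list(auc = auc_trapezoid(curve), curve = curve))
    }
    if (mode == "micro") {
      pooled_y <- as.vector(vapply(classes, function(cl) true == cl,
                                   logical(length(true))))
      pooled_s <- as.vector(scores[, classes])
      curve <- roc_curve(ifelse(pooled_y, "pos", "neg"), pooled_s, "pos")
      attr(curve, "mode") <- "micro"
      return(list(auc = auc_trapezoid(curve), curve = curve))
    }
    # macro
    present <- classes[classes %in% true]
    missing <- setdiff(classes, present)
    if (length(missing) > 0)
      warning(sprintf("class(es) absent from truth skipped in macro AUC: %s",
                      paste(missing, collapse = ", ")), call. = FALSE)
    curves <- lapply(present, function(cl) roc_curve(true, scores[, cl], cl))
    names(curves) <- present
    aucs <- vapply(curves, auc_trapezoid, numeric(1))
    return(list(auc = mean(aucs), curve = curves, per_class = aucs))
  }
  # plain score vector: binary positive-class ROC
  if (is.null(positive)) positive <- sort(unique(true))[1]
  curve <- roc_curve(true, scores, positive)
  list(auc = auc_trapezoid(curve), curve = curve)
}

#' Interpret an AUC score
#'
#' Standard interpretation bins: below 0.50 no distinction, 0.50-0.69 poor,
#' 0.70-0.79 acceptable, 0.80-0.89 great, 0.90-1.00 outstanding
#' classification.
#'
#' @param auc Value in [0, 1].
#' @return Category label.
#' @export
interpret_auc <- function(auc) {
  if (!is.finite(auc) || auc < 0 || auc > 1)
    stop("auc must lie in [0, 1]", call. = FALSE)
  if (auc < 0.50) "No distinction"
  else if (auc < 0.70) "Poor classification"
  else if (auc < 0.80) "Acceptable classification"
  else if (auc < 0.90) "Great classification"
  else "Outstanding classification"
}

#' Interpret a Cohen's kappa coefficient
#'
#' Standard agreement bins: below 0.10 no agreement, 0.10-0.20 slight,
#' 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-0.99
#' almost perfect, 1.00 perfect agreement. Negative kappa reports
#' "No agreement".
#'
#' @param k Kappa value (at most 1).
#' @return Category label.
#' @export
interpret_kappa <- function(k) {
  if (!is.finite(k) || k > 1) stop("kappa must be finite and at most 1",
                                   call. = FALSE)
  if (k < 0.10) "No agreement"
  else if (k < 0.21) "Slight agreement"
  else if (k < 0.41) "Fair agreement"
  else if (k < 0.61) "Moderate agreement"
  else if (k < 0.81) "Substantial agreement"
  else if (k < 1) "Almost perfect agreement"
  else "Perfect agreement"
}

# The nine scalar metrics for one positive class.
scalar_metrics <- function(cc) {
  c(accuracy = accuracy(cc), precision = precision(cc), recall = recall(cc),
    specificity = specificity(cc), f1 = f1_score(cc), csi = csi(cc),
    gmean = gmean(cc), mcc = mcc(cc), kappa = cohen_kappa(cc))
}

#' Full metric report for a set of predictions
#'
#' Binary problems are scored directly on the positive class (alphabetically
#' first label by default). Multi-class problems macro-average the one-vs-rest
#' value of every scalar metric, treating classes symmetrically. When class
#' scores are supplied, micro- and macro-averaged ROC-AUCs are added.
#'
#' @param true,predicted Equal-length label vectors (at least two classes in
#'   \code{true}).
#' @param scores Optional: numeric vector (binary, positive-class score) or
#'   matrix with one named column per class.
#' @param positive Positive class for binary problems (default: first label
#'   alphabetically).
#' @return A \code{metric_report} list: \code{metrics} (named numeric),
#'   \code{confusion} (class-by-class table, truth in rows),
#'   \code{per_class} (matrix of one-vs-rest metrics), \code{auc_micro},
#'   \code{auc_macro}, and interpretation labels.
#' @export
metric_report <- function(true, predicted, scores = NULL, positive = NULL) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted))
    stop("true and predicted labels differ in length", call. = FALSE)
  classes <- sort(unique(true))
  if (length(classes) < 2)
    stop("metric report needs at least two classes in the truth",
         call. = FALSE)
  levels_all <- sort(unique(c(true, predicted)))
  cm <- table(true = factor(true, levels_all),
              predicted = factor(predicted, levels_all))
  binary <- length(classes) == 2
  if (binary) {
    if (is.null(positive)) positive <- classes[1]
    cc <- confusion(true, predicted, positive)
    metrics <- scalar_metrics(cc)
    per_class <- NULL
  } else {
    per_class <- t(vapply(classes, function(cl)
      scalar_metrics(confusion(true, predicted, cl)), numeric(9)))
    metrics <- colMeans(per_class)
  }
  auc_micro <- auc_macro <- NA_real_
  roc <- NULL
  if (!is.null(scores)) {
    if (!is.matrix(scores) && !is.data.frame(scores)) {
      stopifnot(binary)
      neg <- setdiff(classes, positive)
      scores <- cbind(scores, 1 - scores)
      colnames(scores) <- c(positive, neg)
    }
    scores <- as.matrix(scores)
    auc_micro <- roc_auc(true, scores, "micro")$auc
    mac <- roc_auc(true, scores, "macro")
    auc_macro <- mac$auc
    roc <- mac$curve
  }
  structure(list(
    metrics = metrics,
    auc_micro = auc_micro,
    auc_macro = auc_macro,
    auc_interpretation = if (is.finite(auc_macro)) interpret_auc(auc_macro)
                         else NA_character_,
    kappa_interpretation = interpret_kappa(metrics[["kappa"]]),
    confusion = cm,
    per_class = per_class,
    positive = if (binary) positive else NA_character_,
    classes = classes,
    roc = roc
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat("<metric_report>\n")
  print(round(x$metrics, digits))
  if (is.finite(x$auc_macro))
    cat(sprintf("AUC (macro) %.4f [%s]; AUC (micro) %.4f\n",
                x$auc_macro, x$auc_interpretation, x$auc_micro))
  cat(sprintf("kappa: %s\n", x$kappa_interpretation))
  cat("confusion (truth in rows):\n")
  print(x$confusion)
  invisible(x)
}

#' Serialize a metric report as a one-row table
#'
#' Column order mirrors the standard report layout: Accuracy, Precision,
#' Recall, F1-Score, CSI, G-Mean, MCC, Kappa, AUC.
#'
#' @param report A \code{\link{metric_report}}.
#' @return One-row \code{data.frame}.
#' @export
report_row <- function(report) {
  m <- report$metrics
  data.frame(accuracy = m[["accuracy"]], precision = m[["precision"]],
             recall = m[["recall"]], f1 = m[["f1"]], csi = m[["csi"]],
             gmean = m[["gmean"]], mcc = m[["mcc"]], kappa = m[["kappa"]],
             auc = report$auc_macro)
}
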