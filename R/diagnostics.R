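## Diagnostic evaluation: ROC with explicit tie handling, Youden cut-off
## selection, 2x2 confusion-table statistics, and two-reader ICC.

#' ROC curve with tie handling
#'
#' Computes the ROC curve of a real-valued feature against binary
#' benign/malignant labels.  Thresholds are placed at the distinct
#' observed scores; tied scores shared by both classes produce diagonal
#' segments.  The AUC is the trapezoidal area under the curve, which for
#' this construction equals the tie-corrected Mann-Whitney rank statistic
#' (tied benign/malignant pairs count 1/2).
#'
#' @param scores numeric feature values.
#' @param labels parallel vector with values `"benign"` / `"malignant"`
#'   (malignant is the positive class).
#' @param positive_direction `"greater"` (default) if larger scores
#'   indicate malignancy, `"less"` otherwise.
#' @return A `roc_result` with `points` (data.frame `fpr`, `tpr`,
#'   `threshold`, starting at (0,0) and ending at (1,1)), `auc`, and the
#'   Youden-optimal `cutoff`, `cutoff_sensitivity`, `cutoff_specificity`.
#' @export
roc_curve <- function(scores, labels,
                      positive_direction = c("greater", "less")) {
  positive_direction <- match.arg(positive_direction)
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  lab <- as.character(labels)
  if (!all(lab %in% c("benign", "malignant")))
    stop("labels must be 'benign' or 'malignant'")
  pos <- lab == "malignant"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  s <- if (positive_direction == "greater") scores else -scores
  thr <- sort(unique(s), decreasing = TRUE)
  n1 <- sum(pos); n0 <- sum(!pos)
  tpr <- vapply(thr, function(t) sum(s >= t & pos) / n1, 0)
  fpr <- vapply(thr, function(t) sum(s >= t & !pos) / n0, 0)
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                    threshold = c(Inf, thr, -Inf))
  if (positive_direction == "less") pts$threshold <- -pts$threshold
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  res <- structure(list(points = pts, auc = auc,
                        positive_direction = positive_direction,
                        n_malignant = n1, n_benign = n0),
                   class = "roc_result")
  cut <- best_cutoff(res)
  res$cutoff <- cut$cutoff
  res$cutoff_sensitivity <- cut$sensitivity
  res$cutoff_specificity <- cut$specificity
  res
}

## tie-corrected rank (Mann-Whitney) AUC; used as the dual computation
## route in the test suite
rank_auc <- function(scores, labels,
                     positive_direction = c("greater", "less")) {
  positive_direction <- match.arg(positive_direction)
  s <- if (positive_direction == "greater") scores else -scores
  pos <- as.character(labels) == "malignant"
  r <- rank(s)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal cut-off
#'
#' Selects the ROC operating point maximising the Youden index
#' (sensitivity + specificity - 1).  Exact ties in the index are broken
#' toward higher specificity (a benign-sparing screen).
#'
#' @param roc a `roc_result`.
#' @param method only `"youden"` is implemented.
#' @return A list with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
best_cutoff <- function(roc, method = c("youden")) {
  method <- match.arg(method)
  stopifnot(inherits(roc, "roc_result"))
  pts <- roc$points[is.finite(roc$points$threshold), , drop = FALSE]
  if (nrow(pts) == 0L)  # constant scores: single threshold point
    pts <- roc$points[-c(1, nrow(roc$points)), , drop = FALSE]
  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[which.min(pts$fpr[best])]
  list(cutoff = pts$threshold[best], sensitivity = pts$tpr[best],
       specificity = 1 - pts$fpr[best], youden = j[best])
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.3f (%d malignant vs %d benign)\n",
              x$auc, x$n_malignant, x$n_benign))
  cat(sprintf("  Youden cut-off %g: sensitivity %.3f, specificity %.3f\n",
              x$cutoff, x$cutoff_sensitivity, x$cutoff_specificity))
  invisible(x)
}

#' Published reference cut-offs
#'
#' The reference operating thresholds reported for the study data:
#' malignancy is called for KUR values above 6 and SKW values above 3.1.
#' These are applied as strict `score > cutoff` rules, separate from any
#' data-derived Youden cut-off.
#'
#' @return Named list `list(KUR = 6, SKW = 3.1)`.
#' @export
published_cutoffs <- function() list(KUR = 6, SKW = 3.1)

#' Apply a fixed cut-off to scored cases
#'
#' @param scores numeric feature values.
#' @param labels parallel `"benign"`/`"malignant"` labels.
#' @param cutoff threshold; malignancy is predicted for
#'   `score > cutoff` (strict, matching the published "KUR > 6" rule).
#' @return A `confusion_table`.
#' @export
apply_cutoff <- function(scores, labels, cutoff) {
  pos <- as.character(labels) == "malignant"
  pred <- scores > cutoff
  confusion_table(tp = sum(pred & pos), fn = sum(!pred & pos),
                  tn = sum(!pred & !pos), fp = sum(pred & !pos))
}

#' 2x2 confusion table and its statistics
#'
#' `confusion_table` builds the table; `confusion_stats` computes
#' sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy, positive
#' and negative predictive values.  All ratios are exact integer
#' quotients (no intermediate rounding); a zero denominator raises an
#' error naming the undefined ratio.
#'
#' @param tp,fn,tn,fp non-negative integer cell counts (true positive,
#'   false negative, true negative, false positive).
#' @return `confusion_table`: an object with the four counts.
#'   `confusion_stats`: a named list `sensitivity`, `specificity`,
#'   `accuracy`, `ppv`, `npv`.
#' @export
confusion_table <- function(tp, fn, tn, fp) {
  cells <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  structure(as.list(as.integer(cells)), names = names(cells),
            class = "confusion_table")
}

#' @rdname confusion_table
#' @param table a `confusion_table`.
#' @export
confusion_stats <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  rat <- function(num, den, name) {
    if (den == 0) stop("undefined ratio: ", name, " (zero denominator)")
    num / den
  }
  with(table, list(
    sensitivity = rat(tp, tp + fn, "sensitivity"),
    specificity = rat(tn, tn + fp, "specificity"),
    accuracy = rat(tp + tn, tp + fn + tn + fp, "accuracy"),
    ppv = rat(tp, tp + fp, "ppv"),
    npv = rat(tn, tn + fn, "npv")))
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("confusion_table: TP %d  FN %d  TN %d  FP %d\n",
              x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Two-reader intraclass correlation coefficient
#'
#' Single-measure ICC between two readers of the same subjects.  The
#' default model is two-way random effects with absolute agreement
#' (ICC(2,1)): readers are treated as a random sample and systematic
#' offsets between readers count against agreement.  The consistency
#' variant (two-way mixed, ICC(3,1)) is available by flag.  Agreement is
#' considered acceptable at ICC >= 0.85.
#'
#' @param reader_a,reader_b numeric vectors of paired readings,
#'   length >= 3.
#' @param model `"agreement"` (default, ICC(2,1)) or `"consistency"`
#'   (ICC(3,1)).
#' @return A list with `icc`, `acceptable` (icc >= 0.85), `model`, and
#'   the ANOVA mean squares `msr`, `msc`, `mse`.
#' @export
icc_two_reader <- function(reader_a, reader_b,
                           model = c("agreement", "consistency")) {
  model <- match.arg(model)
  if (length(reader_a) != length(reader_b)) stop("readers' lengths differ")
  n <- length(reader_a)
  if (n < 3L) stop("need at least 3 subjects")
  x <- cbind(reader_a, reader_b)
  if (max(x) == min(x)) stop("degenerate input: no variance")
  k <- 2L
  gm <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - gm)^2) / (n - 1)
  msc <- n * sum((col_m - gm)^2) / (k - 1)
  sse <- sum((x - gm)^2) - k * sum((row_m - gm)^2) - n * sum((col_m - gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- if (model == "agreement")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
  list(icc = icc, acceptable = icc >= 0.85, model = model,
       msr = msr, msc = msc, mse = mse)
}
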