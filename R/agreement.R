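#' Rater matrix for interobserver agreement
#'
#' A complete-case subjects x raters matrix of quantitative elastography
#' readings (e.g. maximum Young's modulus Emax per lesion per reader).
#' Missing entries are rejected rather than dropped pairwise.
#'
#' @param values Numeric matrix, >= 2 subjects (rows) and >= 2 raters
#'   (columns), all entries finite.
#' @param metric_name Name of the metric the readings represent.
#' @return Object of class `rater_matrix`.
#' @export
rater_matrix <- function(values, metric_name = "Emax") {
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 subjects and 2 raters")
  if (any(!is.finite(values)))
    stop("rater matrix must be complete-case: all entries finite")
  structure(list(values = values, metric_name = metric_name),
            class = "rater_matrix")
}

#' Intraclass correlation coefficient for interobserver agreement
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC — the
#' Shrout-Fleiss ICC(2,1) — computed from the mean squares of the two-way
#' (subject x rater) layout:
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' with n subjects, k raters, MSR/MSC/MSE the subject, rater and residual
#' mean squares. Consistency (3,1) and average-measure (2,k) forms are
#' available for sensitivity analysis.
#'
#' @param matrix A [rater_matrix()] (or plain numeric matrix).
#' @param form `"ICC2_1"` (default), `"ICC3_1"` or `"ICC2_k"`.
#' @return The ICC, a unitless value in (-1, 1].
#' @export
icc_agreement <- function(matrix, form = c("ICC2_1", "ICC3_1", "ICC2_k")) {
  form <- match.arg(form)
  if (!inherits(matrix, "rater_matrix")) matrix <- rater_matrix(matrix)
  v <- matrix$values
  n <- nrow(v); k <- ncol(v)
  if (stats::var(as.vector(v)) == 0)
    stop("zero total variance: ICC undefined")
  gm <- mean(v)
  row_m <- rowMeans(v); col_m <- colMeans(v)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((v - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  switch(form,
         ICC2_1 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
         ICC3_1 = (msr - mse) / (msr + (k - 1) * mse),
         ICC2_k = (msr - mse) / (msr + (msc - mse) / n))
}

#' Summarise repeated readings of one lesion
#'
#' The clinical protocol reads each region of interest several times (three in
#' the reference protocol) and reports the mean of the repeats as the final
#' value, and the range (max - min) as the extreme difference of the metric's
#' change across repeats.
#'
#' @param values Numeric vector of repeated readings, n >= 2, all finite.
#' @return List with `mean`, `range` (max - min, >= 0) and `n`.
#' @export
summarize_repeats <- function(values) {
  if (length(values) < 2L) stop("need at least 2 repeated readings")
  if (any(!is.finite(values))) stop("repeated readings must be finite")
  list(mean = mean(values), range = max(values) - min(values),
       n = length(values))
}

#' Scored cohort for diagnostic-performance analysis
#'
#' @param labels Binary truth, 1 = malignant (positive), 0 = benign.
#' @param scores Numeric stiffness index per lesion; higher = more suspicious.
#' @return Object of class `scored_cohort`.
#' @export
scored_cohort <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("labels and scores must have equal length")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 (benign) or 1 (malignant)")
  if (any(!is.finite(scores))) stop("scores must be finite")
  structure(list(labels = labels, scores = as.numeric(scores)),
            class = "scored_cohort")
}

require_both_classes <- function(cohort) {
  if (!any(cohort$labels == 1L) || !any(cohort$labels == 0L))
    stop("cohort must contain both classes for ROC analysis")
  invisible(cohort)
}

#' ROC curve and area under it
#'
#' The AUC is the Mann-Whitney pair-ranking statistic: the fraction of
#' (malignant, benign) pairs in which the malignant lesion scores higher,
#' ties counted one half. The ROC points are (1 - specificity, sensitivity)
#' under the rule `score >= threshold => positive` at every distinct score,
#' plus the (0,0) and (1,1) endpoints — a monotone staircase.
#'
#' @param cohort A [scored_cohort()] containing both classes.
#' @return List with `auc` and `roc_points` (data frame `threshold`, `fpr`,
#'   `tpr`), ordered by increasing `fpr`.
#' @export
roc_auc <- function(cohort) {
  stopifnot(inherits(cohort, "scored_cohort"))
  require_both_classes(cohort)
  s <- cohort$scores; y <- cohort$labels
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(th) mean(s[y == 1L] >= th), numeric(1))
  fpr <- vapply(thr, function(th) mean(s[y == 0L] >= th), numeric(1))
  pts <- data.frame(threshold = c(Inf, thr, -Inf),
                    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  list(auc = auc, roc_points = pts)
}

#' Youden-optimal diagnostic threshold
#'
#' Scans every distinct score as a candidate threshold for the rule
#' `score >= threshold => positive` and returns the one maximising the Youden
#' index J = sensitivity + specificity - 1. Ties are broken toward higher
#' specificity (and then the higher threshold). A marker whose best J is 0
#' (no threshold beats chance, e.g. an inverted marker) is flagged
#' `degenerate`, never silently re-oriented.
#'
#' @param cohort A [scored_cohort()] containing both classes.
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden`,
#'   `degenerate`.
#' @export
youden_threshold <- function(cohort) {
  stopifnot(inherits(cohort, "scored_cohort"))
  require_both_classes(cohort)
  s <- cohort$scores; y <- cohort$labels
  thr <- sort(unique(s), decreasing = TRUE)
  sens <- vapply(thr, function(th) mean(s[y == 1L] >= th), numeric(1))
  spec <- vapply(thr, function(th) mean(s[y == 0L] < th), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[order(-spec[best], -thr[best])][1]
  list(threshold = thr[best], sensitivity = sens[best],
       specificity = spec[best], youden = j[best],
       degenerate = max(j) <= 0)
}

#' Diagnostic metrics from a 2x2 confusion table
#'
#' Standard ratios: sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive
#' and negative predictive values, accuracy. Metrics with a zero denominator
#' are reported as `NA` (undefined), not 0.
#'
#' @param tp,fp,fn,tn Non-negative counts; total must be positive.
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
diagnostic_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("table total must be positive")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       ppv = ratio(tp, tp + fp),
       npv = ratio(tn, tn + fn),
       accuracy = (tp + tn) / sum(counts))
}
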