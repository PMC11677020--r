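#' Empirical ROC curve
#'
#' Standard empirical ROC over the unique score thresholds: a record is
#' called positive when its score is greater than or equal to the threshold;
#' the curve starts at (0, 0) (threshold `Inf`) and ends at (1, 1). The AUC
#' is the trapezoidal area, which with ties equals the Mann-Whitney
#' U-statistic with half-weight ties.
#'
#' @param scores numeric scores (higher = more tumor-like).
#' @param labels logical or `"healthy"`/`"tumor"` labels (`TRUE` = tumor).
#' @return A [RocCurve-class].
#' @export
rocCurve <- function(scores, labels) {
  y <- asTumorLogical(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  if (!any(y) || all(y)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  n1 <- sum(y); n0 <- length(y) - n1
  grp <- !duplicated(s)                    # first index of each tie group
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- c(which(grp)[-1] - 1L, length(s)) # last index of each tie group
  thr <- c(Inf, s[grp])
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  new("RocCurve", thresholds = thr, fpr = fpr, tpr = tpr,
      auc = trapz(fpr, tpr))
}

asTumorLogical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels <- as.character(labels)
  if (!all(labels %in% c("healthy", "tumor")))
    stop("labels must be 'healthy'/'tumor' (or logical)")
  labels == "tumor"
}

## fast tie-aware AUC (Mann-Whitney with half-weight ties); equals the
## trapezoidal area of rocCurve() and is used in inner tuning loops
fastAuc <- function(scores, y) {
  n1 <- sum(y); n0 <- length(y) - n1
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Operating points on a ROC curve
#'
#' `youdenPoint` maximizes `tpr - fpr` (ties broken towards the lowest
#' fpr, then the highest threshold). `pointAtTpr` walks the curve from the
#' most conservative threshold and returns the first point whose achieved
#' sensitivity meets or exceeds the requested rate (screening test,
#' `q = 0.9`). `pointAtFpr` returns the most sensitive point whose achieved
#' false positive rate does not exceed the requested rate (confirmatory
#' test, `q = 0.1`); on a finite ROC the requested rate itself may fall
#' between achievable points, and overshooting it would defeat the
#' high-specificity purpose of the operating point.
#'
#' @param roc a [RocCurve-class].
#' @param q requested rate.
#' @return list of class `"OperatingPoint"` with `kind`, `threshold`,
#'   `fpr`, `tpr`.
#' @export
youdenPoint <- function(roc) {
  j <- roc@tpr - roc@fpr
  best <- which(j == max(j))
  best <- best[which.min(roc@fpr[best])]
  makeOp("youden", roc, best)
}

#' @rdname youdenPoint
#' @export
pointAtFpr <- function(roc, q = 0.1) {
  i <- max(which(roc@fpr <= q))
  makeOp("fixed_fpr", roc, i)
}

#' @rdname youdenPoint
#' @export
pointAtTpr <- function(roc, q = 0.9) {
  i <- which(roc@tpr >= q)[1]
  makeOp("fixed_tpr", roc, i)
}

makeOp <- function(kind, roc, i) {
  structure(list(kind = kind, threshold = roc@thresholds[i],
                 fpr = roc@fpr[i], tpr = roc@tpr[i]),
            class = "OperatingPoint")
}

#' @export
print.OperatingPoint <- function(x, ...) {
  cat(sprintf("OperatingPoint [%s]: threshold %.4g, FPR %.3f, TPR %.3f\n",
              x$kind, x$threshold, x$fpr, x$tpr))
  invisible(x)
}

#' Confusion-matrix statistics
#'
#' Derived fractions from raw counts: sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, precision `tp/(tp+fp)`, negative predictive value
#' `tn/(tn+fn)` and accuracy `(tp+tn)/total`. Ratios with a zero denominator
#' are reported as `NA` (undefined), never as 0. The `rounded` element uses
#' conventional half-up rounding at 2 decimals, matching how such tables are
#' printed.
#'
#' @param tp,fn,fp,tn non-negative integer counts, total > 0.
#' @return list of class `"ConfusionMatrix"` with `counts`, `stats`
#'   (exact fractions) and `rounded`.
#' @export
confusionStats <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  stats <- c(sensitivity = ratio(tp, tp + fn),
             specificity = ratio(tn, tn + fp),
             precision = ratio(tp, tp + fp),
             npv = ratio(tn, tn + fn),
             accuracy = (tp + tn) / sum(counts))
  structure(list(counts = counts, stats = stats,
                 rounded = roundHalfUp(stats, 2)),
            class = "ConfusionMatrix")
}

#' @export
print.ConfusionMatrix <- function(x, ...) {
  cat("ConfusionMatrix (tp fn fp tn):", x$counts, "\n")
  print(x$rounded)
  invisible(x)
}

## confusion counts from scores at a threshold (score >= thr is positive)
confusionAt <- function(scores, labels, threshold) {
  y <- asTumorLogical(labels)
  pos <- scores >= threshold
  confusionStats(tp = sum(pos & y), fn = sum(!pos & y),
                 fp = sum(pos & !y), tn = sum(!pos & !y))
}
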