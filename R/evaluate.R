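# Evaluation suite: confusion metrics incl. MCC, ROC/AUC, per-kinase AUC
# distributions and thresholds, rank/Fisher model comparisons, and
# activity-matrix difference maps.

#' Confusion counts from binary labels and calls
#'
#' @param labels 0/1 experimental activity; @param calls 0/1 predictions,
#'   same length.
#' @return list with integers `tp` (active, called active), `fp`
#'   (inactive, called active), `tn`, `fn`.
#' @export
confusionCounts <- function(labels, calls) {
  labels <- as.integer(labels); calls <- as.integer(calls)
  if (length(labels) != length(calls))
    stop("labels and calls differ in length")
  if (!length(labels)) stop("empty input")
  list(tp = sum(labels == 1L & calls == 1L),
       fp = sum(labels == 0L & calls == 1L),
       tn = sum(labels == 0L & calls == 0L),
       fn = sum(labels == 1L & calls == 0L))
}

#' Derived classification metrics
#'
#' Computes sensitivity `SEN = TP/(TP+FN)`, selectivity (specificity)
#' `SEL = TN/(TN+FP)`, accuracy `ACC = (TP+TN)/total`, positive and
#' negative predictive values, and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as `NA` and named in
#' `$undefined`, except MCC which falls back to 0 (flagged): a classifier
#' that never varies carries no correlation signal.
#'
#' @param counts a list with `tp`, `fp`, `tn`, `fn` (see
#'   [confusionCounts()]).
#' @return list: `counts`, fractions `sen`, `sel`, `acc`, `mcc`, `ppv`,
#'   `npv`, and `undefined` (character vector of flagged metrics).
#' @export
classificationMetrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total <= 0) stop("all confusion counts are zero")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  sen <- safe(tp, tp + fn); sel <- safe(tn, tn + fp)
  ppv <- safe(tp, tp + fp); npv <- safe(tn, tn + fn)
  acc <- (tp + tn) / total
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0)
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom) else 0
  undef <- c(if (tp + fn == 0) "sen", if (tn + fp == 0) "sel",
             if (tp + fp == 0) "ppv", if (tn + fn == 0) "npv",
             if (denom <= 0) "mcc")
  list(counts = counts, sen = sen, sel = sel, acc = acc, mcc = mcc,
       ppv = ppv, npv = npv, undefined = undef %||% character())
}

#' Format a metrics report in the panel-profiling table layout
#'
#' ACC/SEN/SEL in percent, MCC/PPV/NPV as fractions, two decimals.
#'
#' @param m a [classificationMetrics()] result.
#' @return one-row data.frame.
#' @export
formatMetricsReport <- function(m) {
  data.frame(MCC = round(m$mcc, 2), ACC = round(100 * m$acc, 2),
             SEN = round(100 * m$sen, 2), SEL = round(100 * m$sel, 2),
             TP = m$counts$tp, FP = m$counts$fp, TN = m$counts$tn,
             FN = m$counts$fn, PPV = round(m$ppv, 2),
             NPV = round(m$npv, 2))
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the distinct score values in descending order
#' (tied scores grouped), tracing (FPR, TPR) from (0,0) to (1,1); the AUC
#' is the trapezoidal area, identical to the Mann-Whitney U statistic
#' scaled by `1/(n_pos * n_neg)` with ties counted one half.
#'
#' @param scores real prediction scores; @param labels 0/1 truth, both
#'   classes present.
#' @return list: `points` data.frame (threshold, fpr, tpr) including the
#'   (0,0) origin, and `auc`.
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0 || nNeg == 0)
    stop("ROC/AUC undefined: only one class present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp <- cumsum(!duplicated(s))
  tpCum <- cumsum(l == 1L); fpCum <- cumsum(l == 0L)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tpCum[last] / nPos)
  fpr <- c(0, fpCum[last] / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = c(Inf, s[last]), fpr = fpr,
                           tpr = tpr),
       auc = auc)
}

#' Per-kinase AUC vector and distribution summary
#'
#' Computes the ROC AUC of every kinase column; columns with a single
#' class get `NA` and are listed in `$skipped`. The summary reports the
#' five-number boxplot statistics plus the 1.5 x IQR whisker bounds
#' (clipped to observed values), matching the usual AUC-distribution box
#' plot.
#'
#' @param scores numeric matrix compounds x kinases;
#' @param labels 0/1 matrix of the same shape.
#' @return list: `auc` (named vector), `skipped`, `summary` (min, q1,
#'   median, q3, max, whiskerLow, whiskerHigh).
#' @export
perKinaseAUC <- function(scores, labels) {
  stopifnot(all(dim(scores) == dim(labels)))
  ids <- colnames(scores) %||% sprintf("k%03d", seq_len(ncol(scores)))
  auc <- vapply(seq_len(ncol(scores)), function(j) {
    l <- labels[, j]
    if (length(unique(l)) < 2) return(NA_real_)
    rocCurve(scores[, j], l)$auc
  }, numeric(1))
  names(auc) <- ids
  list(auc = auc, skipped = ids[is.na(auc)],
       summary = aucSummary(auc[!is.na(auc)]))
}

#' @rdname perKinaseAUC
#' @param auc numeric vector of AUC values.
#' @export
aucSummary <- function(auc) {
  q <- stats::quantile(auc, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lowBound <- q[1] - 1.5 * iqr; highBound <- q[3] + 1.5 * iqr
  inside <- auc[auc >= lowBound & auc <= highBound]
  c(min = min(auc), q1 = q[1], median = q[2], q3 = q[3], max = max(auc),
    whiskerLow = min(inside), whiskerHigh = max(inside))
}

#' Per-kinase decision threshold
#'
#' Scans the midpoints of consecutive distinct sorted scores and returns
#' the one maximizing the criterion (default: MCC of the calls
#' `score >= threshold`). Ties are broken toward the higher threshold,
#' i.e. the more conservative caller.
#'
#' @param scores real scores; @param labels 0/1 truth with both classes.
#' @param criterion function(counts) -> numeric to maximize.
#' @return list: `threshold`, `value` of the criterion.
#' @export
chooseThreshold <- function(scores, labels,
                            criterion = function(co)
                              classificationMetrics(co)$mcc) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("threshold selection needs both classes")
  s <- sort(unique(scores))
  if (length(s) < 2)
    stop("threshold selection needs at least two distinct scores")
  cand <- (utils::head(s, -1) + utils::tail(s, -1)) / 2
  best <- -Inf; bestT <- NA_real_
  for (t in cand) {
    v <- criterion(confusionCounts(labels, as.integer(scores >= t)))
    if (is.na(v)) next
    if (v > best || (v == best && (is.na(bestT) || t > bestT))) {
      best <- v; bestT <- t
    }
  }
  list(threshold = bestT, value = best)
}

#' Paired rank test on per-kinase AUC vectors
#'
#' Wilcoxon signed-rank test on the paired differences (the paired analog
#' of the Mann-Whitney test), pairing by kinase. Zero differences are
#' dropped; for up to 12 non-zero pairs the two-sided p-value is computed
#' by exact enumeration of all 2^n sign patterns (valid under ties in the
#' rank magnitudes), above that by the normal approximation with tie
#' correction and continuity correction.
#'
#' @param aucA,aucB equal-length (>= 5) paired vectors.
#' @param method `"auto"` (exact for n <= 12, else normal approximation),
#'   or force `"exact"` / `"approx"`.
#' @return list: `statistic` (V, sum of positive ranks), `pValue`, `n`
#'   (non-zero pairs), `method`, `allZero` flag.
#' @export
pairedRankTest <- function(aucA, aucB,
                           method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  stopifnot(length(aucA) == length(aucB), length(aucA) >= 5)
  d <- aucA - aucB
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, pValue = 1, n = 0L, method = "degenerate",
                allZero = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  useExact <- switch(method, auto = n <= 12, exact = TRUE, approx = FALSE)
  if (useExact && n > 20)
    stop("exact enumeration limited to 20 non-zero pairs")
  if (useExact) {
    # enumerate all sign assignments; distribution of V under H0
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vall <- as.numeric(signs %*% r)
    pLe <- mean(Vall <= V); pGe <- mean(Vall >= V)
    p <- min(1, 2 * min(pLe, pGe))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(statistic = V, pValue = p, n = as.integer(n), method = method,
       allZero = FALSE)
}

#' Unpaired Mann-Whitney U test (for completeness)
#'
#' @param a,b numeric samples.
#' @return htest object from [stats::wilcox.test()].
#' @export
mannWhitneyTest <- function(a, b) {
  suppressWarnings(stats::wilcox.test(a, b))
}

#' Two-sided Fisher exact p-value of a 2x2 table
#'
#' @param tbl 2x2 matrix of non-negative counts.
#' @return p-value from the exact hypergeometric test.
#' @export
fisherExactP <- function(tbl) {
  stopifnot(all(dim(tbl) == c(2, 2)))
  stats::fisher.test(round(tbl))$p.value
}

#' Fisher comparison of a model against a random 50% caller
#'
#' Builds the 2x2 table rows = \{model, random\}, columns = \{correct,
#' incorrect\}: the model row is (TP+TN, FP+FN); the random row is a
#' caller labelling 50% of cases positive, which on the same actives and
#' inactives gets half of each right, i.e. (total/2, total/2). Returns the
#' two-sided Fisher exact p-value.
#'
#' @param counts a confusion-count list (`tp`, `fp`, `tn`, `fn`).
#' @return list: `pValue`, `table`.
#' @export
fisherVsRandom <- function(counts) {
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  stopifnot(total > 0)
  half <- round(total / 2)
  tbl <- rbind(model = c(correct = counts$tp + counts$tn,
                         incorrect = counts$fp + counts$fn),
               random = c(correct = half, incorrect = total - half))
  list(pValue = fisherExactP(tbl), table = tbl)
}

#' Difference map of experimental vs predicted activity matrices
#'
#' Cell-wise comparison of two binary matrices of identical shape and
#' ordering: `"correct"` where they agree, `"FP"` where the prediction is
#' active but the experiment inactive, `"FN"` for the converse.
#'
#' @param expected,predicted [LabelMatrix-class] objects or 0/1 matrices
#'   of the same shape.
#' @return list: `map` (character matrix), counts `correct`, `fp`, `fn`
#'   (summing to the number of cells).
#' @export
diffMatrix <- function(expected, predicted) {
  E <- if (methods::is(expected, "LabelMatrix")) labelMatrix(expected)
       else expected
  P <- if (methods::is(predicted, "LabelMatrix")) labelMatrix(predicted)
       else predicted
  if (!all(dim(E) == dim(P)))
    stop("expected and predicted matrices differ in shape")
  map <- matrix("correct", nrow(E), ncol(E), dimnames = dimnames(E))
  map[P == 1L & E == 0L] <- "FP"
  map[P == 0L & E == 1L] <- "FN"
  list(map = map, correct = sum(map == "correct"), fp = sum(map == "FP"),
       fn = sum(map == "FN"))
}

#' Plot helpers: difference map and AUC box plot
#'
#' `plotDiffMatrix` renders the difference map (white = correct, red =
#' false positive, blue = false negative); `plotAucDistribution` draws the
#' per-cutoff AUC box plots with 1.5 x IQR whiskers.
#'
#' @param dm a [diffMatrix()] result.
#' @param file optional PNG path; when given the plot is written there.
#' @export
plotDiffMatrix <- function(dm, file = NULL) {
  codes <- matrix(match(dm$map, c("FN", "correct", "FP")), nrow(dm$map))
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::image(t(codes)[, rev(seq_len(nrow(codes))), drop = FALSE],
                  col = c("blue", "white", "red"), zlim = c(1, 3),
                  axes = FALSE,
                  main = sprintf("correct %d | FP %d | FN %d",
                                 dm$correct, dm$fp, dm$fn))
  invisible(NULL)
}

#' @rdname plotDiffMatrix
#' @param aucList named list of per-kinase AUC vectors (one per cutoff).
#' @export
plotAucDistribution <- function(aucList, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::boxplot(aucList, range = 1.5, ylab = "AUC",
                    xlab = "activity cutoff (uM)")
  graphics::abline(h = 0.5, lty = 2)
  invisible(NULL)
}
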