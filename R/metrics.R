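# Classification metrics: confusion matrices, the scalar metric formulas
# (accuracy, precision, sensitivity, specificity, F1, MCC, Cohen's kappa)
# with binary and macro one-vs-rest averaging, and threshold-sweep ROC/AUC.
# Zero denominators yield 0 with a warning throughout.

.safe_div <- function(num, den, what) {
  if (den == 0) {
    warning("zero denominator in ", what, "; reporting 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Build a confusion matrix
#'
#' Counts[i, j] is the number of samples with true class i predicted as
#' class j.  Labels are integers in `[0, K)` (or factors, converted in level
#' order).  For K = 2, class 1 is the positive class.
#'
#' @param yTrue,yPred label vectors of equal length.
#' @param nClasses K; inferred from the labels when missing.
#' @param classLabels optional class names.
#' @return a [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(yTrue, yPred, nClasses = NULL, classLabels = NULL) {
  if (is.factor(yTrue)) {
    if (is.null(classLabels)) classLabels <- levels(yTrue)
    yTrue <- as.integer(yTrue) - 1L
  }
  if (is.factor(yPred)) yPred <- as.integer(yPred) - 1L
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  K <- as.integer(nClasses %||% (max(c(yTrue, yPred)) + 1L))
  if (any(yTrue < 0 | yTrue >= K) || any(yPred < 0 | yPred >= K))
    stop("labels must lie in [0, ", K, ")")
  counts <- matrix(0, K, K)
  for (i in seq_along(yTrue))
    counts[yTrue[i] + 1L, yPred[i] + 1L] <- counts[yTrue[i] + 1L, yPred[i] + 1L] + 1
  labs <- classLabels %||% as.character(seq_len(K) - 1L)
  new("ConfusionMatrix", counts = counts, classLabels = labs)
}

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = true, cols = predicted),",
      sum(object@counts), "samples\n")
  m <- object@counts
  dimnames(m) <- list(true = object@classLabels, pred = object@classLabels)
  print(m)
})

#' Binary-class TP/FP/TN/FN of a 2x2 confusion matrix
#'
#' @param cm a 2x2 [ConfusionMatrix-class]; class 1 is positive.
#' @return named list with TP, FP, TN, FN.
#' @export
binaryCounts <- function(cm) {
  if (nrow(cm@counts) != 2) stop("binary counts need a 2x2 matrix")
  m <- cm@counts
  list(TP = m[2, 2], FN = m[2, 1], FP = m[1, 2], TN = m[1, 1])
}

.mcc_binary <- function(TP, TN, FP, FN) {
  den <- sqrt((TP + FP)) * sqrt((TP + FN)) * sqrt((TN + FP)) * sqrt((TN + FN))
  if (den == 0) {
    warning("zero denominator in MCC; reporting 0", call. = FALSE)
    return(0)
  }
  (TP * TN - FP * FN) / den
}

.kappa_from_cm <- function(m) {
  s <- sum(m)
  p0 <- sum(diag(m)) / s
  pe <- sum(rowSums(m) * colSums(m)) / s^2
  .safe_div(p0 - pe, 1 - pe, "kappa")
}

#' Binary classification metrics
#'
#' Accuracy (TP+TN over all), precision TP/(TP+FP), sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP), F1 (harmonic mean of precision and recall), the
#' Matthews correlation coefficient and Cohen's kappa, from a 2x2 confusion
#' matrix.
#'
#' @param cm a 2x2 [ConfusionMatrix-class].
#' @param auc optional AUC to embed in the report (from [rocCurve()]).
#' @return a [MetricReport-class].
#' @export
binaryMetrics <- function(cm, auc = NA_real_) {
  if (sum(cm@counts) == 0) stop("empty confusion matrix")
  b <- binaryCounts(cm)
  acc <- (b$TP + b$TN) / sum(cm@counts)
  prec <- .safe_div(b$TP, b$TP + b$FP, "precision")
  sens <- .safe_div(b$TP, b$TP + b$FN, "sensitivity")
  spec <- .safe_div(b$TN, b$TN + b$FP, "specificity")
  f1 <- .safe_div(2 * prec * sens, prec + sens, "F1")
  new("MetricReport", accuracy = acc, precision = prec, sensitivity = sens,
      specificity = spec, f1 = f1,
      mcc = .mcc_binary(b$TP, b$TN, b$FP, b$FN),
      kappa = .kappa_from_cm(cm@counts), auc = auc, averaging = "binary")
}

#' Multiclass classification metrics
#'
#' Macro-averaged one-vs-rest precision, recall, specificity and F1 (F1 is
#' macro-averaged over per-class F1 values), overall accuracy, the multiclass
#' Matthews correlation coefficient in its covariance form (which reduces to
#' the binary formula at K = 2), and Cohen's kappa from observed versus
#' chance agreement of the full matrix.
#'
#' @param cm a K x K [ConfusionMatrix-class].
#' @param auc optional macro one-vs-rest AUC to embed.
#' @return a [MetricReport-class].
#' @export
multiclassMetrics <- function(cm, auc = NA_real_) {
  m <- cm@counts
  if (sum(m) == 0) stop("empty confusion matrix")
  K <- nrow(m)
  s <- sum(m)
  prec <- sens <- spec <- f1 <- numeric(K)
  for (k in seq_len(K)) {
    TP <- m[k, k]; FP <- sum(m[-k, k]); FN <- sum(m[k, -k])
    TN <- s - TP - FP - FN
    prec[k] <- .safe_div(TP, TP + FP, paste0("precision[", k, "]"))
    sens[k] <- .safe_div(TP, TP + FN, paste0("recall[", k, "]"))
    spec[k] <- .safe_div(TN, TN + FP, paste0("specificity[", k, "]"))
    f1[k] <- .safe_div(2 * prec[k] * sens[k], prec[k] + sens[k],
                       paste0("F1[", k, "]"))
  }
  # covariance form of the multiclass MCC
  tr <- sum(diag(m)); tk <- rowSums(m); pk <- colSums(m)
  num <- tr * s - sum(pk * tk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  mcc <- if (den == 0) {
    warning("zero denominator in MCC; reporting 0", call. = FALSE); 0
  } else num / den
  new("MetricReport", accuracy = tr / s, precision = mean(prec),
      sensitivity = mean(sens), specificity = mean(spec), f1 = mean(f1),
      mcc = mcc, kappa = .kappa_from_cm(m), auc = auc, averaging = "macro")
}

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport (", object@averaging, " averaging )\n", sep = "")
  v <- c(accuracy = object@accuracy, precision = object@precision,
         sensitivity = object@sensitivity, specificity = object@specificity,
         f1 = object@f1, mcc = object@mcc, kappa = object@kappa,
         auc = object@auc)
  for (nm in names(v)) cat(sprintf("  %-12s %s\n", nm,
                                   ifelse(is.na(v[nm]), "NA", sprintf("%.4f", v[nm]))))
})

#' Coerce a metric report to a data.frame / list
#'
#' @param report a [MetricReport-class].
#' @return one-row data.frame of all metrics.
#' @export
metricsAsDataFrame <- function(report) {
  data.frame(accuracy = report@accuracy, precision = report@precision,
             sensitivity = report@sensitivity, specificity = report@specificity,
             f1 = report@f1, mcc = report@mcc, kappa = report@kappa,
             auc = report@auc, averaging = report@averaging)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every unique score as a threshold (ties grouped), accumulating the
#' false and true positive rates from (0,0) to (1,1); the AUC is the
#' trapezoidal area, equal to the Mann-Whitney pair-counting statistic.
#'
#' @param yTrue binary labels (0/1 integers or logicals); 1 is positive
#'   unless `positive` says otherwise.
#' @param scores real-valued scores, larger = more positive.
#' @param positive the label value treated as positive (default 1).
#' @return a [ROCCurve-class].
#' @export
rocCurve <- function(yTrue, scores, positive = 1L) {
  pos <- as.numeric(yTrue == positive)
  nP <- sum(pos); nN <- sum(1 - pos)
  if (nP == 0 || nN == 0)
    stop("AUC undefined: need at least one positive and one negative sample")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(p, grp, sum)
  fp <- tapply(1 - p, grp, sum)
  tpr <- c(0, cumsum(tp)) / nP
  fpr <- c(0, cumsum(fp)) / nN
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  new("ROCCurve", thresholds = c(Inf, s[!duplicated(s)]),
      fpr = as.numeric(fpr), tpr = as.numeric(tpr), auc = auc,
      positiveClass = as.character(positive))
}

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve: %d thresholds, AUC = %.4f (positive class %s)\n",
              length(object@thresholds), object@auc, object@positiveClass))
})

#' Macro one-vs-rest multiclass AUC
#'
#' The unweighted mean of per-class one-vs-rest AUCs over a score matrix
#' (e.g. softmax probabilities).
#'
#' @param yTrue integer labels in `[0, K)`.
#' @param scoreMatrix (n, K) score matrix, column k scoring class k-1.
#' @return list with `auc` (macro mean) and `perClass` vector.
#' @export
multiclassAuc <- function(yTrue, scoreMatrix) {
  K <- ncol(scoreMatrix)
  per <- vapply(seq_len(K) - 1L, function(k) {
    rocCurve(as.integer(yTrue == k), scoreMatrix[, k + 1L])@auc
  }, 0)
  list(auc = mean(per), perClass = per)
}

#' Serialize reports and curves
#'
#' `writeMetricReport` writes a metric report as JSON (round-trips
#' losslessly via `readMetricReport`); `writeRocPoints` writes the ROC
#' points as CSV.
#'
#' @param report a [MetricReport-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMetricReport <- function(report, path) {
  jsonlite::write_json(as.list(metricsAsDataFrame(report)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMetricReport
#' @export
readMetricReport <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("MetricReport", accuracy = o$accuracy, precision = o$precision,
      sensitivity = o$sensitivity, specificity = o$specificity, f1 = o$f1,
      mcc = o$mcc, kappa = o$kappa,
      auc = if (is.null(o$auc)) NA_real_ else o$auc,
      averaging = o$averaging)
}

#' @rdname writeMetricReport
#' @param roc a [ROCCurve-class].
#' @export
writeRocPoints <- function(roc, path) {
  utils::write.csv(data.frame(threshold = roc@thresholds, fpr = roc@fpr,
                              tpr = roc@tpr), path, row.names = FALSE)
  invisible(path)
}

#' Plot helpers (PNG output)
#'
#' Renders a confusion-matrix heat map or ROC curve to a PNG file using base
#' graphics.
#'
#' @param cm a [ConfusionMatrix-class].
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
plotConfusionMatrix <- function(cm, path) {
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  m <- cm@counts
  K <- nrow(m)
  image(seq_len(K), seq_len(K), t(m[K:1, , drop = FALSE]),
        col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
        axes = FALSE, xlab = "predicted", ylab = "true")
  axis(1, seq_len(K), cm@classLabels)
  axis(2, seq_len(K), rev(cm@classLabels))
  for (i in seq_len(K)) for (j in seq_len(K))
    text(j, K - i + 1, m[i, j])
  invisible(path)
}

#' @rdname plotConfusionMatrix
#' @param roc a [ROCCurve-class].
#' @export
plotRocCurve <- function(roc, path) {
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  plot(roc@fpr, roc@tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", main = sprintf("AUC = %.4f", roc@auc))
  abline(0, 1, lty = 2)
  invisible(path)
}
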