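# Evaluation metrics: confusion-matrix construction, the printed scalar
# formulas, multiclass aggregation, and threshold-sweep ROC/AUC, checked
# against brute-force oracles and an independent ROC implementation.

test_that("confusion matrices count true/predicted pairs correctly", {
  # perfect predictions give a diagonal matrix
  cm <- confusionMatrix(c(0, 1, 2, 1), c(0, 1, 2, 1), nClasses = 3)
  expect_equal(cm@counts, diag(c(1, 2, 1)))
  # hand-counted binary case: TP=2, FN=1, FP=0, TN=1 (class 1 positive)
  cm2 <- confusionMatrix(c(1, 1, 1, 0), c(1, 1, 0, 0))
  b <- binaryCounts(cm2)
  expect_equal(unlist(b), c(TP = 2, FN = 1, FP = 0, TN = 1))
  # row sums equal per-class true counts on 200 random labels
  set.seed(40)
  yt <- sample(0:3, 200, TRUE); yp <- sample(0:3, 200, TRUE)
  cm4 <- confusionMatrix(yt, yp, nClasses = 4)
  expect_equal(rowSums(cm4@counts), as.numeric(table(factor(yt, 0:3))))
  expect_equal(sum(cm4@counts), 200)
  expect_error(confusionMatrix(c(0, 5), c(0, 1), nClasses = 2), "labels")
})

test_that("binary metrics evaluate the printed formulas exactly", {
  # perfect classifier
  perf <- new("ConfusionMatrix", counts = matrix(c(50, 0, 0, 50), 2, 2),
              classLabels = c("neg", "pos"))
  r <- binaryMetrics(perf)
  expect_equal(c(r@accuracy, r@precision, r@sensitivity, r@specificity,
                 r@f1, r@mcc, r@kappa), rep(1, 7))
  # TP=50, FN=10, FP=5, TN=35: frozen values from direct evaluation
  cm <- new("ConfusionMatrix",
            counts = matrix(c(35, 10, 5, 50), 2, 2),  # rows true, cols pred
            classLabels = c("0", "1"))
  b <- binaryCounts(cm)
  expect_equal(unlist(b), c(TP = 50, FN = 10, FP = 5, TN = 35))
  r <- binaryMetrics(cm)
  expect_equal(r@accuracy, 0.85)
  expect_equal(r@precision, 50 / 55)
  expect_equal(r@sensitivity, 50 / 60)
  expect_equal(r@specificity, 35 / 40)
  expect_equal(r@f1, 2 * (50 / 55) * (50 / 60) / (50 / 55 + 50 / 60),
               tolerance = 1e-12)
  expect_equal(r@mcc, 1700 / sqrt(55 * 60 * 40 * 45), tolerance = 1e-12)
  expect_equal(r@kappa, (0.85 - 0.51) / 0.49, tolerance = 1e-12)
  # all-one-class predictions: MCC 0 by the zero-denominator convention
  deg <- new("ConfusionMatrix", counts = matrix(c(0, 0, 40, 60), 2, 2),
             classLabels = c("0", "1"))
  expect_warning(rd <- binaryMetrics(deg), "zero denominator")
  expect_equal(rd@mcc, 0)
})

test_that("binary and multiclass metrics agree with brute force on random matrices", {
  set.seed(41)
  for (i in 1:100) {
    K <- sample(2:5, 1)
    m <- matrix(rpois(K * K, 8), K, K)
    if (sum(m) == 0) m[1, 1] <- 1
    cm <- new("ConfusionMatrix", counts = m,
              classLabels = as.character(seq_len(K) - 1))
    r <- suppressWarnings(multiclassMetrics(cm))
    # brute-force macro aggregation
    s <- sum(m); prec <- sens <- f1 <- numeric(K)
    for (k in 1:K) {
      TP <- m[k, k]; FP <- sum(m[, k]) - TP; FN <- sum(m[k, ]) - TP
      prec[k] <- if (TP + FP == 0) 0 else TP / (TP + FP)
      sens[k] <- if (TP + FN == 0) 0 else TP / (TP + FN)
      f1[k] <- if (prec[k] + sens[k] == 0) 0 else
        2 * prec[k] * sens[k] / (prec[k] + sens[k])
    }
    expect_equal(r@accuracy, sum(diag(m)) / s, tolerance = 1e-12)
    expect_equal(r@precision, mean(prec), tolerance = 1e-12)
    expect_equal(r@sensitivity, mean(sens), tolerance = 1e-12)
    expect_equal(r@f1, mean(f1), tolerance = 1e-12)
    p0 <- sum(diag(m)) / s
    pe <- sum(rowSums(m) * colSums(m)) / s^2
    expect_equal(r@kappa, (p0 - pe) / (1 - pe), tolerance = 1e-12)
    if (K == 2) {
      rb <- suppressWarnings(binaryMetrics(cm))
      ob <- oracle_binary(m[2, 2], m[2, 1], m[1, 2], m[1, 1])
      for (nm in names(ob))
        expect_equal(slot(rb, nm), ob[[nm]], tolerance = 1e-12)
      # the covariance-form multiclass MCC reduces to the binary formula
      expect_equal(r@mcc, rb@mcc, tolerance = 1e-12)
    }
  }
})

test_that("chance-level predictions give near-zero kappa and MCC", {
  set.seed(42)
  n <- 3000
  yt <- sample(0:2, n, TRUE)
  yp <- sample(0:2, n, TRUE)
  r <- multiclassMetrics(confusionMatrix(yt, yp, nClasses = 3))
  expect_lt(abs(r@kappa), 0.05)
  expect_lt(abs(r@mcc), 0.05)
})

test_that("label permutation leaves accuracy, kappa and multiclass MCC invariant", {
  set.seed(43)
  yt <- sample(0:3, 400, TRUE)
  yp <- ifelse(runif(400) < 0.6, yt, sample(0:3, 400, TRUE))
  perm <- c(2L, 0L, 3L, 1L)
  r1 <- multiclassMetrics(confusionMatrix(yt, yp, nClasses = 4))
  r2 <- multiclassMetrics(confusionMatrix(perm[yt + 1], perm[yp + 1],
                                          nClasses = 4))
  expect_equal(r1@accuracy, r2@accuracy, tolerance = 1e-12)
  expect_equal(r1@kappa, r2@kappa, tolerance = 1e-12)
  expect_equal(r1@mcc, r2@mcc, tolerance = 1e-12)
})

test_that("ROC/AUC handles trivial cases and equals the pair-counting statistic", {
  # perfectly separating scores
  y <- c(0, 0, 0, 1, 1)
  expect_equal(rocCurve(y, c(0.1, 0.2, 0.3, 0.8, 0.9))@auc, 1.0)
  # all-tied scores collapse to the diagonal
  expect_equal(rocCurve(y, rep(0.5, 5))@auc, 0.5)
  expect_error(rocCurve(c(1, 1), c(0.2, 0.4)), "positive and one negative")
  # Mann-Whitney pair counting on random scores (with ties)
  set.seed(44)
  yy <- sample(0:1, 100, TRUE)
  ss <- round(rnorm(100), 1)
  roc <- rocCurve(yy, ss)
  expect_lt(abs(roc@auc - oracle_auc_pairs(yy, ss)), 1e-10)
  # curve endpoints and monotonicity
  expect_equal(roc@fpr[1], 0); expect_equal(roc@tpr[1], 0)
  expect_equal(tail(roc@fpr, 1), 1); expect_equal(tail(roc@tpr, 1), 1)
  expect_false(is.unsorted(roc@fpr)); expect_false(is.unsorted(roc@tpr))
  # invariance under strictly monotone transforms of the scores
  expect_equal(rocCurve(yy, exp(2 * ss))@auc, roc@auc, tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(45)
  y <- sample(0:1, 150, TRUE)
  s <- rnorm(150) + y
  ours <- rocCurve(y, s)@auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("macro one-vs-rest AUC averages per-class AUCs over score columns", {
  set.seed(46)
  n <- 120; K <- 3
  y <- sample(0:(K - 1), n, TRUE)
  sc <- matrix(rnorm(n * K), n, K)
  sc[cbind(1:n, y + 1)] <- sc[cbind(1:n, y + 1)] + 1.5
  r <- multiclassAuc(y, sc)
  per <- vapply(0:(K - 1), function(k)
    rocCurve(as.integer(y == k), sc[, k + 1])@auc, 0)
  expect_equal(r$perClass, per)
  expect_equal(r$auc, mean(per))
  expect_true(all(per > 0.5))
})

test_that("metric reports and ROC points serialize losslessly", {
  cm <- confusionMatrix(c(0, 1, 1, 0, 1), c(0, 1, 0, 0, 1))
  r <- binaryMetrics(cm, auc = 0.875)
  path <- tempfile(fileext = ".json")
  writeMetricReport(r, path)
  back <- readMetricReport(path)
  for (sn in slotNames(r)) expect_equal(slot(back, sn), slot(r, sn))
  roc <- rocCurve(c(0, 1, 0, 1), c(0.1, 0.9, 0.4, 0.6))
  csv <- tempfile(fileext = ".csv")
  writeRocPoints(roc, csv)
  pts <- read.csv(csv)
  expect_equal(pts$fpr, roc@fpr)
  expect_equal(pts$tpr, roc@tpr)
  # plot helpers produce PNG files
  p1 <- tempfile(fileext = ".png"); p2 <- tempfile(fileext = ".png")
  plotConfusionMatrix(cm, p1); plotRocCurve(roc, p2)
  expect_true(file.exists(p1) && file.size(p1) > 0)
  expect_true(file.exists(p2) && file.size(p2) > 0)
})
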