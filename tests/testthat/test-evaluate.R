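test_that("confusion counting matches the category definitions", {
  co <- confusionCounts(c(1, 0), c(1, 0))
  expect_equal(co, list(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  co2 <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(co2, list(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  set.seed(2)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    l <- rbinom(n, 1, 0.5); c_ <- rbinom(n, 1, 0.5)
    co <- confusionCounts(l, c_)
    expect_equal(co$tp + co$fp + co$tn + co$fn, n)
  }
  expect_error(confusionCounts(c(1, 0), c(1)), "length")
})

test_that("derived metrics: perfect classifier, undefined flags, identities", {
  perfect <- classificationMetrics(list(tp = 5L, fp = 0L, tn = 5L,
                                        fn = 0L))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$sen, 1)
  expect_equal(perfect$ppv, 1)

  # no experimental negatives: SEL undefined, MCC flagged to 0
  nonneg <- classificationMetrics(list(tp = 3L, fp = 0L, tn = 0L,
                                       fn = 7L))
  expect_true(is.na(nonneg$sel))
  expect_true(all(c("sel", "mcc") %in% nonneg$undefined))
  expect_equal(nonneg$mcc, 0)

  set.seed(3)
  for (i in 1:25) {
    co <- as.list(stats::setNames(rpois(4, 20) + 1,
                                  c("tp", "fp", "tn", "fn")))
    m <- classificationMetrics(co)
    # MCC is symmetric under swapping the positive and negative class
    sw <- classificationMetrics(list(tp = co$tn, fp = co$fn, tn = co$tp,
                                     fn = co$fp))
    expect_equal(m$mcc, sw$mcc, tolerance = 1e-12)
    # ACC decomposes over prevalence
    prev <- (co$tp + co$fn) / (co$tp + co$fp + co$tn + co$fn)
    expect_equal(m$acc, m$sen * prev + m$sel * (1 - prev),
                 tolerance = 1e-12)
  }
  expect_error(classificationMetrics(list(tp = 0L, fp = 0L, tn = 0L,
                                          fn = 0L)), "zero")
})

test_that("ROC/AUC: separation, ties, pair-count oracle and pROC cross-check", {
  perfect <- rocCurve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$points$fpr[1], 0)
  expect_equal(utils::tail(perfect$points$tpr, 1), 1)

  flat <- rocCurve(rep(0.5, 10), rep(c(1, 0), 5))
  expect_equal(flat$auc, 0.5)

  set.seed(14)
  for (i in 1:100) {
    n <- 20
    sc <- round(runif(n), 2)   # rounding forces ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(rocCurve(sc, lb)$auc, bruteAuc(sc, lb),
                 tolerance = 1e-12)
  }

  # monotone curve coordinates
  r <- rocCurve(runif(50), rbinom(50, 1, 0.4))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))

  expect_error(rocCurve(runif(5), rep(1, 5)), "one class")

  skip_if_not_installed("pROC")
  set.seed(15)
  sc <- runif(40); lb <- rbinom(40, 1, 0.5)
  refRoc <- suppressMessages(pROC::roc(lb, sc, direction = "<",
                                       levels = c(0, 1)))
  expect_equal(rocCurve(sc, lb)$auc, as.numeric(pROC::auc(refRoc)),
               tolerance = 1e-10)
})

test_that("AUC of negated scores mirrors around one half when tie-free", {
  set.seed(9)
  sc <- rnorm(30); lb <- rbinom(30, 1, 0.5)
  expect_equal(rocCurve(-sc, lb)$auc, 1 - rocCurve(sc, lb)$auc,
               tolerance = 1e-12)
})

test_that("per-kinase AUC vector and quartile summary", {
  scores <- cbind(a = c(0.9, 0.8, 0.2, 0.1), b = c(0.1, 0.2, 0.8, 0.9),
                  c = rep(0.5, 4))
  labels <- cbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(1, 1, 1, 1))
  pk <- perKinaseAUC(scores, labels)
  expect_equal(unname(pk$auc[c("a", "b")]), c(1, 0))
  expect_true(is.na(pk$auc["c"]))
  expect_equal(pk$skipped, "c")

  s <- aucSummary(c(0.5, 0.6, 0.7, 0.8))
  expect_equal(unname(s["median"]), 0.65)

  set.seed(16)
  for (i in 1:100) {
    v <- runif(sample(8:40, 1))
    s <- aucSummary(v)
    q <- sort(v)
    expect_equal(unname(s[c("min", "max")]), c(min(v), max(v)))
    expect_equal(unname(s["median"]), stats::median(v))
    expect_equal(unname(s["q1"]), unname(stats::quantile(v, 0.25)))
    iqr <- unname(s["q3"] - s["q1"])
    expect_gte(s["whiskerLow"], s["q1"] - 1.5 * iqr - 1e-12)
    expect_lte(s["whiskerHigh"], s["q3"] + 1.5 * iqr + 1e-12)
  }
})

test_that("threshold choice: midpoint rule, exhaustive oracle, degenerate input", {
  res <- chooseThreshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(res$threshold, 0.5)
  expect_equal(res$value, 1)

  set.seed(23)
  for (i in 1:30) {
    sc <- round(runif(30), 2)
    lb <- rbinom(30, 1, 0.4)
    if (length(unique(lb)) < 2 || length(unique(sc)) < 2) next
    got <- chooseThreshold(sc, lb)
    # independent exhaustive scan with tie-break toward higher threshold
    ss <- sort(unique(sc))
    cand <- (head(ss, -1) + tail(ss, -1)) / 2
    mccs <- vapply(cand, function(t) {
      tab <- table(factor(lb, 0:1), factor(as.integer(sc >= t), 0:1))
      tp <- tab["1", "1"]; fp <- tab["0", "1"]
      tn <- tab["0", "0"]; fn <- tab["1", "0"]
      den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      if (den <= 0) NA_real_
      else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
    }, numeric(1))
    best <- max(mccs, na.rm = TRUE)
    expBest <- max(cand[!is.na(mccs) & mccs == best])
    expect_equal(got$threshold, expBest)
    expect_equal(got$value, best, tolerance = 1e-12)
  }

  expect_error(chooseThreshold(runif(5), rep(1, 5)), "both classes")
})

test_that("paired signed-rank test: exact enumeration, approximation, degeneracies", {
  a <- c(0.7, 0.8, 0.75, 0.9, 0.65)
  expect_equal(pairedRankTest(a, a)$pValue, 1)
  expect_true(pairedRankTest(a, a)$allZero)

  # n = 5, all differences positive: two-sided p = 2 / 2^5
  b <- a - c(0.01, 0.02, 0.03, 0.015, 0.025)
  expect_equal(pairedRankTest(a, b)$pValue, 2 / 32, tolerance = 1e-12)

  # exact branch agrees with wilcox.test on tie-free data
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10)
    ours <- pairedRankTest(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$pValue, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }

  # exact and normal branches agree closely at the n = 12 branch point:
  # on average within 0.01, never beyond 0.05
  set.seed(32)
  gaps <- replicate(20, {
    x <- rnorm(12); y <- rnorm(12)
    abs(pairedRankTest(x, y, method = "exact")$pValue -
          pairedRankTest(x, y, method = "approx")$pValue)
  })
  expect_lt(mean(gaps), 0.01)
  expect_lt(max(gaps), 0.05)
})

test_that("Fisher comparisons: proportional tables, hypergeometric oracle, symmetry", {
  # proportionally identical classifier and random caller -> p = 1
  co <- list(tp = 10L, fp = 10L, tn = 10L, fn = 10L)  # 50% correct
  expect_equal(fisherVsRandom(co)$pValue, 1)

  # exact diagonal table vs direct hypergeometric enumeration
  tbl <- rbind(c(10, 0), c(0, 10))
  pObs <- fisherExactP(tbl)
  # enumerate tables with margins (10,10)x(10,10)
  probs <- vapply(0:10, function(k)
    stats::dhyper(k, 10, 10, 10), numeric(1))
  pEnum <- sum(probs[probs <= probs[11] + 1e-12])
  expect_equal(pObs, pEnum, tolerance = 1e-10)

  set.seed(41)
  for (i in 1:10) {
    t2 <- matrix(rpois(4, 15), 2, 2)
    expect_equal(fisherExactP(t2), fisherExactP(t(t2)), tolerance = 1e-12)
  }

  # a strong classifier beats the random caller decisively
  strong <- list(tp = 45L, fp = 5L, tn = 45L, fn = 5L)
  expect_lt(fisherVsRandom(strong)$pValue, 1e-6)
  expect_equal(unname(fisherVsRandom(strong)$table["model", ]),
               c(90, 10))
  expect_equal(unname(fisherVsRandom(strong)$table["random", ]),
               c(50, 50))
})

test_that("difference maps classify cells and conserve counts", {
  E <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
              dimnames = list(c("c1", "c2"), c("k1", "k2")))
  same <- diffMatrix(E, E)
  expect_equal(same$correct, 4)
  expect_equal(same$fp + same$fn, 0)

  P <- E; P[1, 2] <- 1L
  one <- diffMatrix(E, P)
  expect_equal(one$fp, 1)
  expect_equal(one$map[1, 2], "FP")

  set.seed(55)
  for (i in 1:10) {
    E2 <- matrix(rbinom(35, 1, 0.4), 5, 7)
    P2 <- matrix(rbinom(35, 1, 0.4), 5, 7)
    dm <- diffMatrix(E2, P2)
    expect_equal(dm$correct + dm$fp + dm$fn, 35)
  }
  expect_error(diffMatrix(E, matrix(0L, 3, 3)), "shape")
})

test_that("metric reports print in the table layout", {
  rep10 <- formatMetricsReport(classificationMetrics(
    list(tp = 3765L, fp = 2944L, tn = 17048L, fn = 2773L)))
  expect_equal(rep10$ACC, 78.45)
  expect_equal(rep10$MCC, 0.42)
  expect_named(rep10, c("MCC", "ACC", "SEN", "SEL", "TP", "FP", "TN",
                        "FN", "PPV", "NPV"))
})
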