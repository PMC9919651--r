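# metrics, cross-validation, external validation, Y-randomization,
# attribute ranking

test_that("confusion metrics match hand evaluation and conventions", {
  m <- confusionMetrics(3, 1, 3, 1)
  expect_equal(m$TPR, 0.75)
  expect_equal(m$TNR, 0.75)
  expect_equal(m$MCC, 0.5)
  p <- confusionMetrics(5, 0, 5, 0)
  expect_equal(unlist(p), c(TPR = 1, TNR = 1, MCC = 1))
  # all predictions one class: MCC 0 by the zero-denominator convention
  expect_equal(confusionMetrics(5, 5, 0, 0)$MCC, 0)
  expect_error(confusionMetrics(-1, 0, 0, 0), "negative")
  # swapping the positive/negative convention flips the MCC sign
  set.seed(42)
  for (i in 1:20) {
    cnt <- rpois(4, 5) + 1
    a <- confusionMetrics(cnt[1], cnt[2], cnt[3], cnt[4])$MCC
    b <- confusionMetrics(cnt[3], cnt[4], cnt[1], cnt[2])$MCC
    expect_equal(a, b)                      # symmetric relabeling
    d <- confusionMetrics(cnt[4], cnt[3], cnt[2], cnt[1])$MCC
    expect_equal(a, -d)                     # prediction flip changes sign
  }
})

test_that("rocAuc equals brute-force pair counting", {
  expect_equal(rocAuc(c(0.9, 0.4, 0.8, 0.3), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)
  expect_equal(rocAuc(c(3, 2), c(TRUE, FALSE)), 1)
  set.seed(7)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    sc <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # many ties
    expect_equal(rocAuc(sc, lab), oracleRocAuc(sc, lab))
  }
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  # random scores concentrate near 1/2
  set.seed(123)
  auc <- rocAuc(runif(2000), rep(c(TRUE, FALSE), 1000))
  expect_lt(abs(auc - 0.5), 0.05)
})

makeSeparableTable <- function(n = 60, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * 7), n, 7,
              dimnames = list(NULL, c("MW", "nC", "nAR", "nHAcc", "nHDon",
                                      "TPSA", "PHI")))
  df <- as.data.frame(x)
  df$TPSA <- df$TPSA + 3 * rep(c(1, -1), length.out = n)
  df$active <- rep(c(TRUE, FALSE), length.out = n)
  df$id <- sprintf("s%02d", seq_len(n))
  df
}

test_that("cross-validation separates a planted threshold rule", {
  tab <- makeSeparableTable()
  for (alg in c("RF", "NB", "KNN5", "SVM_linear")) {
    rep <- crossvalidateClassifier(tab, alg, k = 10, seed = 1)
    expect_gte(rep$MCC, 0.9)
    expect_equal(rep$phase, "cv_training")
  }
  # determinism
  r1 <- crossvalidateClassifier(tab, "RF", seed = 5)
  r2 <- crossvalidateClassifier(tab, "RF", seed = 5)
  expect_equal(modelReportRow(r1), modelReportRow(r2))
  expect_error(crossvalidateClassifier(
    transform(tab, active = TRUE), "RF", seed = 1), "both classes")
  expect_error(crossvalidateClassifier(tab, "bogus", seed = 1), "unknown")
})

test_that("shuffled labels collapse the cross-validated MCC", {
  tab <- makeSeparableTable(n = 50)
  set.seed(9)
  mccs <- vapply(1:8, function(i) {
    tab$active <- sample(tab$active)
    crossvalidateClassifier(tab, "NB", k = 5, seed = i)$MCC
  }, 0)
  expect_lt(abs(mean(mccs)), 0.2)
})

test_that("fold sizes differ by at most one", {
  # observable through determinism and the pigeonhole bound via pooled n
  tab <- makeSeparableTable(n = 42)
  rep <- crossvalidateClassifier(tab, "NB", k = 10, seed = 3)
  expect_equal(rep$n, 42L)
  expect_equal(rep$TP + rep$FP + rep$TN + rep$FN, 42L)
})

test_that("external evaluation matches confusion metrics and guards ids", {
  tab <- makeSeparableTable(n = 60)
  train <- tab[1:40, ]; test <- tab[41:60, ]
  fit <- trainClassifier(train, "SVM_linear", seed = 2)
  rep <- evaluateOnTest(fit, test)
  expect_equal(rep$phase, "external_test")
  m <- confusionMetrics(rep$TP, rep$FP, rep$TN, rep$FN)
  expect_equal(rep$MCC, m$MCC)
  expect_equal(rep$TPR, m$TPR)
  expect_error(evaluateOnTest(fit, tab[35:45, ]), "overlap")
})

test_that("Y-randomization preserves counts and centres near zero", {
  tab <- makeSeparableTable(n = 50)
  yr <- yRandomization(tab, "NB", nPerm = 10, k = 5, seed = 4)
  expect_length(yr$mccs, 10L)
  expect_lt(abs(yr$mean_mcc), 0.3)
  expect_lt(yr$mean_mcc,
            crossvalidateClassifier(tab, "NB", k = 5, seed = 4)$MCC)
  yr2 <- yRandomization(tab, "NB", nPerm = 10, k = 5, seed = 4)
  expect_identical(yr$mccs, yr2$mccs)
  expect_error(yRandomization(tab, "NB", nPerm = 5, seed = 1), "nPerm")
})

test_that("attribute evaluators score planted and degenerate attributes", {
  tab <- makeSeparableTable(n = 40)
  tab$MIRROR <- ifelse(tab$active, 1, 0)   # identical to the class
  tab$CONST <- 5
  ig <- rankAttributes(tab, "InfoGain")
  expect_equal(ig$attribute[1], "MIRROR")
  h <- -mean(tab$active) * log2(mean(tab$active)) -
    (1 - mean(tab$active)) * log2(1 - mean(tab$active))
  expect_equal(ig$score[1], h, tolerance = 1e-9)
  expect_equal(ig$score[ig$attribute == "CONST"], 0)
  pc <- rankAttributes(tab, "PearsonCorrelation")
  expect_equal(pc$attribute[1], "MIRROR")
  expect_equal(pc$score[1], 1, tolerance = 1e-9)
  onr <- rankAttributes(tab, "OneR")
  expect_equal(onr$attribute[1], "MIRROR")
  expect_equal(onr$score[1], 1)
  cfs <- rankAttributes(tab, "CFS")
  expect_equal(cfs$attribute[1], "MIRROR")
  expect_error(rankAttributes(tab, "wavelets"))
})
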