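# Binary degradation-activity modeling: seeded cross-validation, external
# validation, confusion metrics, ROC area, Y-randomization and attribute
# ranking.  Classifier internals are delegated to standard backends
# (randomForest, e1071, class); folds, metrics and evaluators are native.

.ALGORITHMS <- c("RF", "RT", "NB", "KNN5", "SVM_linear")
.DESCRIPTOR_COLS <- c("MW", "nC", "nAR", "nHAcc", "nHDon", "TPSA", "PHI")

#' Build a feature table
#'
#' Joins the seven descriptors of every compound with its binary activity
#' label.
#'
#' @param set a [DegradationSet-class].
#' @param threshold activity cutoff in percent.
#' @param concentration readout used for the label.
#' @param subset \code{"all"}, \code{"VHL"} or \code{"CRBN"}.
#' @return data.frame (id, MW, nC, nAR, nHAcc, nHDon, TPSA, PHI, active)
#'   with attribute \code{"subset"}.
#' @export
featureTable <- function(set, threshold = 75,
                         concentration = c("low", "high"),
                         subset = c("all", "VHL", "CRBN")) {
  concentration <- match.arg(concentration)
  subset <- match.arg(subset)
  if (subset != "all") set <- set[e3Class(set) == subset]
  if (length(set) == 0L) stop("empty subset ", subset)
  desc <- computeDescriptors(moleculeList(set))
  out <- cbind(data.frame(id = compoundIds(set)), desc)
  out$active <- as.logical(binarizeActivity(degradation(set, concentration),
                                            threshold))
  attr(out, "subset") <- subset
  attr(out, "threshold") <- threshold
  rownames(out) <- NULL
  out
}

.checkFeatureTable <- function(table) {
  stopifnot(is.data.frame(table), "active" %in% names(table))
  feats <- names(table)[vapply(table, is.numeric, TRUE)]
  feats <- setdiff(feats, c("active", "deg_low", "deg_high"))
  if (!length(feats)) stop("feature table has no descriptor columns")
  if (anyNA(table[, feats])) stop("feature table contains missing values")
  feats
}

# fit one classifier; returns a closure predicting (class, score) on new X.
# Zero-variance columns are dropped before fitting (they carry no signal
# and break Gaussian class densities and feature scaling).
.fitClassifier <- function(X, y, algorithm) {
  y <- factor(y, levels = c(FALSE, TRUE), labels = c("inactive", "active"))
  keep <- apply(X, 2L, function(col) stats::sd(col) > 0)
  if (!any(keep)) keep[] <- TRUE
  X <- X[, keep, drop = FALSE]
  inner <- .fitClassifierKept(X, y, algorithm)
  function(newX) inner(newX[, keep, drop = FALSE])
}

.fitClassifierKept <- function(X, y, algorithm) {
  switch(algorithm,
    RF = {
      fit <- randomForest::randomForest(X, y, ntree = 100L)
      function(newX) {
        p <- stats::predict(fit, newX, type = "prob")[, "active"]
        list(class = p >= 0.5, score = p)
      }
    },
    RT = {
      fit <- randomForest::randomForest(X, y, ntree = 1L)
      function(newX) {
        p <- stats::predict(fit, newX, type = "prob")[, "active"]
        list(class = p >= 0.5, score = p)
      }
    },
    NB = {
      fit <- e1071::naiveBayes(X, y)
      function(newX) {
        p <- stats::predict(fit, newX, type = "raw")[, "active"]
        # zero within-class variance yields NaN densities: uninformative
        p[!is.finite(p)] <- 0.5
        list(class = p >= 0.5, score = p)
      }
    },
    KNN5 = {
      trainX <- X; trainY <- y
      function(newX) {
        # knn breaks distance/vote ties by drawing from the RNG; pin the
        # stream so predictions are reproducible
        pr <- withSeed(1L, class::knn(trainX, newX, trainY, k = 5L,
                                      prob = TRUE))
        pwin <- attr(pr, "prob")
        score <- ifelse(pr == "active", pwin, 1 - pwin)
        list(class = pr == "active", score = score)
      }
    },
    SVM_linear = {
      fit <- e1071::svm(X, y, kernel = "linear", cost = 1)
      # orient decision values so larger means active
      function(newX) {
        pr <- stats::predict(fit, newX, decision.values = TRUE)
        dv <- attr(pr, "decision.values")[, 1L]
        if (grepl("^inactive", colnames(attr(pr, "decision.values"))[1L]))
          dv <- -dv
        list(class = pr == "active", score = dv)
      }
    },
    stop("unknown algorithm '", algorithm, "' (choose from ",
         paste(.ALGORITHMS, collapse = ", "), ")")
  )
}

#' Confusion-matrix metrics
#'
#' TPR = TP/(TP+FN), TNR = TN/(TN+FP) and the Matthews correlation
#' coefficient; a zero denominator yields MCC = 0 by convention.
#'
#' @param tp,fp,tn,fn nonnegative counts.
#' @return list (TPR, TNR, MCC).
#' @examples
#' confusionMetrics(3, 1, 3, 1)  # TPR 0.75, TNR 0.75, MCC 0.5
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("negative confusion counts")
  tpr <- if (tp + fn >= 1) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp >= 1) tn / (tn + fp) else NA_real_
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(TPR = tpr, TNR = tnr, MCC = mcc)
}

#' Rank-based ROC area
#'
#' The Mann-Whitney estimator: the probability that a random active
#' scores above a random inactive, ties contributing one half.
#'
#' @param scores numeric prediction scores (larger = more active).
#' @param labels logical (or 0/1) true labels; both classes required.
#' @return area in [0, 1].
#' @examples
#' rocAuc(c(0.9, 0.4, 0.8, 0.3), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L)
    stop("ROC area requires both classes present")
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

.reportFromPredictions <- function(pred, score, truth, algorithm, phase, seed) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  m <- confusionMetrics(tp, fp, tn, fn)
  auc <- if (sum(truth) > 0L && sum(!truth) > 0L) rocAuc(score, truth)
         else NA_real_
  out <- list(algorithm = algorithm, phase = phase, n = length(truth),
              TP = tp, FP = fp, TN = tn, FN = fn,
              TPR = m$TPR, TNR = m$TNR, MCC = m$MCC, roc_area = auc,
              seed = seed)
  class(out) <- "ModelReport"
  out
}

#' @export
print.ModelReport <- function(x, ...) {
  cat(sprintf("ModelReport %s [%s]: TPR %.3f TNR %.3f MCC %.3f ROC %.3f (n=%d)\n",
              x$algorithm, x$phase, x$TPR, x$TNR, x$MCC, x$roc_area, x$n))
  invisible(x)
}

#' @rdname crossvalidateClassifier
#' @export
modelReportRow <- function(report) {
  data.frame(algorithm = report$algorithm, phase = report$phase,
             n = report$n, TPR = report$TPR, TNR = report$TNR,
             MCC = report$MCC, roc_area = report$roc_area,
             seed = report$seed)
}

#' Cross-validated classification
#'
#' k-fold cross-validation with plain random folds (unstratified, sizes
#' differing by at most one); the pooled out-of-fold predictions yield one
#' confusion matrix and one ROC area.  Deterministic given the seed.
#'
#' @param table a feature table from [featureTable()].
#' @param algorithm one of \code{RF}, \code{RT}, \code{NB}, \code{KNN5},
#'   \code{SVM_linear}.
#' @param k number of folds (default 10).
#' @param seed integer seed driving fold assignment and stochastic
#'   learners.
#' @return a \code{ModelReport} (list with TPR, TNR, MCC, roc_area, the
#'   confusion counts and phase \code{"cv_training"}).
#' @export
crossvalidateClassifier <- function(table, algorithm, k = 10L, seed) {
  feats <- .checkFeatureTable(table)
  y <- table$active
  n <- length(y)
  stopifnot(n >= k)
  if (length(unique(y)) < 2L)
    stop("cross-validation requires both classes in the table")
  X <- as.matrix(table[, feats])
  withSeed(seed, {
    folds <- split(sample.int(n), cut(seq_len(n), k, labels = FALSE))
    pred <- logical(n); score <- numeric(n)
    for (f in folds) {
      if (length(unique(y[-f])) < 2L) {
        # degenerate fold (tiny imbalanced subset): constant prediction
        pred[f] <- y[-f][1L]; score[f] <- as.numeric(y[-f][1L])
        next
      }
      model <- .fitClassifier(X[-f, , drop = FALSE], y[-f], algorithm)
      p <- model(X[f, , drop = FALSE])
      pred[f] <- p$class; score[f] <- p$score
    }
    .reportFromPredictions(pred, score, y, algorithm, "cv_training", seed)
  })
}

#' Train a classifier on a full table
#'
#' @param table feature table (training partition).
#' @param algorithm see [crossvalidateClassifier()].
#' @param seed integer seed for stochastic learners.
#' @return a \code{TrainedClassifier} for [evaluateOnTest()].
#' @export
trainClassifier <- function(table, algorithm, seed) {
  feats <- .checkFeatureTable(table)
  if (length(unique(table$active)) < 2L)
    stop("training requires both classes in the table")
  X <- as.matrix(table[, feats])
  model <- withSeed(seed, .fitClassifier(X, table$active, algorithm))
  out <- list(model = model, algorithm = algorithm, features = feats,
              train_ids = table$id, seed = seed)
  class(out) <- "TrainedClassifier"
  out
}

#' External-test evaluation
#'
#' Applies a trained classifier to an untouched test partition; the train
#' and test id sets must be disjoint.
#'
#' @param model a \code{TrainedClassifier}.
#' @param testTable feature table of the external test set.
#' @return a \code{ModelReport} with phase \code{"external_test"}.
#' @export
evaluateOnTest <- function(model, testTable) {
  stopifnot(inherits(model, "TrainedClassifier"))
  overlap <- intersect(model$train_ids, testTable$id)
  if (length(overlap))
    stop("train/test overlap for id(s): ", paste(overlap, collapse = ", "))
  X <- as.matrix(testTable[, model$features])
  p <- model$model(X)
  .reportFromPredictions(p$class, p$score, testTable$active,
                         model$algorithm, "external_test", model$seed)
}

#' Y-randomization
#'
#' Repeats the full cross-validation after permuting the activity labels
#' (class counts preserved); an informative model collapses to chance
#' level, so the permuted-MCC distribution should centre near zero.
#'
#' @param table feature table.
#' @param algorithm see [crossvalidateClassifier()].
#' @param nPerm number of permutations (at least 10; default 20).
#' @param k folds per permutation.
#' @param seed integer seed.
#' @return list (mccs, mean_mcc, n_perm).
#' @export
yRandomization <- function(table, algorithm, nPerm = 20L, k = 10L, seed) {
  stopifnot(nPerm >= 10L)
  permSeeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, nPerm + 1L))
  mccs <- vapply(seq_len(nPerm), function(i) {
    tab <- table
    tab$active <- withSeed(permSeeds[i], sample(tab$active))
    crossvalidateClassifier(tab, algorithm, k = k,
                            seed = permSeeds[nPerm + 1L])$MCC
  }, 0)
  list(mccs = mccs, mean_mcc = mean(mccs), n_perm = nPerm)
}

# --- attribute evaluators -------------------------------------------------

.entropy <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# best single binary cut of a continuous attribute against a binary class,
# by information gain; returns list(cut, gain)
.bestCut <- function(x, y) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(list(cut = NA_real_, gain = 0))
  cuts <- (ux[-1L] + ux[-length(ux)]) / 2
  h0 <- .entropy(y)
  n <- length(y)
  gains <- vapply(cuts, function(cc) {
    lo <- x <= cc
    h0 - (sum(lo) / n) * .entropy(y[lo]) - (sum(!lo) / n) * .entropy(y[!lo])
  }, 0)
  best <- which.max(gains)
  list(cut = cuts[best], gain = gains[best])
}

#' Attribute ranking
#'
#' Ranks the descriptors by one of four evaluators: \code{InfoGain}
#' (information gain of the class given the attribute, continuous
#' attributes discretized by the single binary cut maximizing the gain),
#' \code{PearsonCorrelation} (absolute Pearson correlation with the 0/1
#' class), \code{OneR} (training accuracy of the best one-attribute
#' single-cut rule) and \code{CFS} (correlation-based feature-subset
#' selection by greedy forward search; returns the selected subset with
#' the merit at each inclusion).
#'
#' @param table feature table.
#' @param evaluator one of \code{InfoGain}, \code{PearsonCorrelation},
#'   \code{OneR}, \code{CFS}.
#' @return data.frame (attribute, score) sorted by decreasing score, with
#'   attribute \code{"evaluator"}; for CFS only the selected subset is
#'   returned, with the cumulative merit as score.
#' @export
rankAttributes <- function(table,
                           evaluator = c("InfoGain", "PearsonCorrelation",
                                         "OneR", "CFS")) {
  evaluator <- match.arg(evaluator)
  feats <- .checkFeatureTable(table)
  y <- table$active
  if (length(unique(y)) < 2L) stop("attribute ranking requires both classes")
  scoreOf <- switch(evaluator,
    InfoGain = function(x) .bestCut(x, y)$gain,
    PearsonCorrelation = function(x) {
      if (stats::sd(x) == 0) return(0)
      abs(stats::cor(x, as.numeric(y)))
    },
    OneR = function(x) {
      bc <- .bestCut(x, y)
      if (is.na(bc$cut)) return(max(mean(y), 1 - mean(y)))
      lo <- x <= bc$cut
      (max(sum(y[lo]), sum(!y[lo])) + max(sum(y[!lo]), sum(!y[!lo]))) /
        length(y)
    },
    CFS = NULL)
  if (evaluator != "CFS") {
    scores <- vapply(feats, function(f) scoreOf(table[[f]]), 0)
    out <- data.frame(attribute = feats, score = unname(scores))
    out <- out[order(-out$score, out$attribute), , drop = FALSE]
  } else {
    out <- .cfsForward(table, feats, y)
  }
  rownames(out) <- NULL
  attr(out, "evaluator") <- evaluator
  out
}

# CFS merit: k * mean(|r_cf|) / sqrt(k + k (k-1) mean(|r_ff|))
.cfsForward <- function(table, feats, y) {
  ynum <- as.numeric(y)
  rcf <- vapply(feats, function(f) {
    if (stats::sd(table[[f]]) == 0) 0 else abs(stats::cor(table[[f]], ynum))
  }, 0)
  merit <- function(sel) {
    k <- length(sel)
    rff <- if (k > 1L) {
      cm <- abs(suppressWarnings(stats::cor(as.matrix(table[, sel]))))
      cm[is.na(cm)] <- 0  # constant attributes: no intercorrelation
      mean(cm[upper.tri(cm)])
    } else 0
    k * mean(rcf[sel]) / sqrt(k + k * (k - 1) * rff)
  }
  sel <- character(); rows <- list(); best <- -Inf
  repeat {
    rest <- setdiff(feats, sel)
    if (!length(rest)) break
    ms <- vapply(rest, function(f) merit(c(sel, f)), 0)
    if (max(ms) <= best) break
    pick <- rest[which.max(ms)]
    best <- max(ms)
    sel <- c(sel, pick)
    rows[[length(rows) + 1L]] <- data.frame(attribute = pick, score = best)
  }
  do.call(rbind, rows)
}

#' Full model comparison
#'
#' Cross-validates and externally validates every algorithm on a
#' train/test split of a feature table.
#'
#' @param table feature table.
#' @param split a \code{SplitAssignment} over the table's ids.
#' @param algorithms algorithms to run (default all five).
#' @param k CV folds.
#' @param seed integer seed.
#' @return data.frame of [modelReportRow()] rows, CV and external phases.
#' @export
compareClassifiers <- function(table, split, algorithms = .ALGORITHMS,
                               k = 10L, seed) {
  train <- table[table$id %in% split$train_ids, , drop = FALSE]
  test <- table[table$id %in% split$test_ids, , drop = FALSE]
  rows <- list()
  if (length(unique(train$active)) < 2L)
    return(data.frame(algorithm = character(), phase = character(),
                      n = integer(), TPR = numeric(), TNR = numeric(),
                      MCC = numeric(), roc_area = numeric(),
                      seed = integer()))
  for (alg in algorithms) {
    cv <- crossvalidateClassifier(train, alg, k = min(k, nrow(train)),
                                  seed = seed)
    rows[[length(rows) + 1L]] <- modelReportRow(cv)
    if (length(unique(test$active)) >= 1L && nrow(test) > 0L) {
      fit <- trainClassifier(train, alg, seed = seed)
      rows[[length(rows) + 1L]] <- modelReportRow(evaluateOnTest(fit, test))
    }
  }
  do.call(rbind, rows)
}
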