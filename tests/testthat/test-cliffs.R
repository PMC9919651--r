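# degradation-cliff detection

test_that("similarPairs returns exactly the pairs at or above threshold", {
  mols <- lapply(smallMoleculePool[1:10], parseSmiles)
  names(mols) <- paste0("m", 1:10)
  fps <- sphereFingerprints(mols)
  for (sMin in c(0, 0.3, 0.6)) {
    got <- similarPairs(fps, sMin = sMin)
    want <- oracleSimilarPairs(fps@counts, sMin)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_setequal(pairKey(got$id_i, got$id_j),
                      pairKey(paste0("m", want$i), paste0("m", want$j)))
    }
  }
  expect_equal(nrow(similarPairs(fps, sMin = 0)), choose(10, 2))
  # duplicate molecules give similarity exactly 1
  dup <- sphereFingerprints(lapply(c(a = "CCO", b = "CCO"), parseSmiles))
  sp <- similarPairs(dup, 0.99)
  expect_equal(sp$similarity, 1)
})

test_that("dual-concentration consistency decides the cliff flag", {
  df <- data.frame(id = c("a", "b", "c"),
                   smiles = c("CCO", "CCN", "CCC"),
                   e3_class = "VHL",
                   deg_low = c(95, 35, 90), deg_high = c(96, 26, 88))
  set <- DegradationSet(df)
  pairs <- data.frame(id_i = c("a", "a"), id_j = c("b", "c"),
                      similarity = c(0.95, 0.95))
  cl <- detectDegradationCliffs(pairs, set, deltaMin = 40)
  expect_equal(cl$passes_dual, c(TRUE, FALSE))
  expect_equal(cl$delta_low, c(60, 5))
  expect_equal(cl$delta_high, c(70, 8))
  # a large delta at one concentration only is rejected under the dual rule
  df2 <- df; df2$deg_high <- c(95, 85, 88)  # b catches up at 1 uM
  cl2 <- detectDegradationCliffs(pairs, DegradationSet(df2), deltaMin = 40)
  expect_equal(cl2$passes_dual, c(FALSE, FALSE))
  # single-concentration mode decides on the low readout alone
  cl3 <- detectDegradationCliffs(pairs, DegradationSet(df2), deltaMin = 40,
                                 requireBoth = FALSE)
  expect_equal(cl3$passes_dual, c(TRUE, FALSE))
})

test_that("raising the delta threshold never increases the flagged count", {
  gen <- .sharedGen()
  fps <- sphereFingerprints(moleculeList(gen$set))
  cand <- similarPairs(fps, 0.9)
  counts <- vapply(c(10, 20, 40, 60, 80), function(d)
    sum(detectDegradationCliffs(cand, gen$set, deltaMin = d)$passes_dual), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("output is invariant to record order and pair orientation", {
  gen <- .sharedGen()
  fps <- sphereFingerprints(moleculeList(gen$set))
  cand <- similarPairs(fps, 0.9)
  cl1 <- detectDegradationCliffs(cand, gen$set)
  flip <- cand
  flip[, c("id_i", "id_j")] <- flip[, c("id_j", "id_i")]
  perm <- gen$set[rev(seq_len(length(gen$set)))]
  cl2 <- detectDegradationCliffs(flip, perm)
  expect_setequal(pairKey(cl1$id_i, cl1$id_j)[cl1$passes_dual],
                  pairKey(cl2$id_i, cl2$id_j)[cl2$passes_dual])
})

test_that("manual pairs are annotated and tagged", {
  gen <- .sharedGen()
  fps <- sphereFingerprints(moleculeList(gen$set))
  cand <- similarPairs(fps, 0.9)
  ids <- compoundIds(gen$set)
  man <- data.frame(id_i = ids[1], id_j = ids[2])
  cl <- detectDegradationCliffs(cand, gen$set, manualPairs = man, fps = fps)
  mrow <- cl[cl$provenance == "manual", ]
  expect_equal(nrow(mrow), 1L)
  expect_false(is.na(mrow$similarity))
  expect_false(is.na(mrow$delta_low))
})

test_that("missing records or concentrations are reported by compound", {
  df <- data.frame(id = c("a", "b"), smiles = c("CCO", "CCN"),
                   e3_class = "VHL", deg_low = c(90, 10),
                   deg_high = c(95, 15))
  set <- DegradationSet(df)
  pairs <- data.frame(id_i = "a", id_j = "zz", similarity = 0.95)
  expect_error(detectDegradationCliffs(pairs, set), "zz")
})

test_that("planted dead-analog cliffs are detected with high sensitivity", {
  gen <- .sharedGen()
  fps <- sphereFingerprints(moleculeList(gen$set))
  cl <- detectDegradationCliffs(similarPairs(fps, 0.9), gen$set,
                                deltaMin = 40)
  flagged <- cl[cl$passes_dual, ]
  tp <- gen$truth$cliff_pairs
  hit <- pairKey(tp$id_parent, tp$id_dead) %in%
    pairKey(flagged$id_i, flagged$id_j)
  expect_gte(mean(hit), 0.9)
  # specificity floor: no flagged pair has both deltas tiny
  expect_true(all(pmax(flagged$delta_low, flagged$delta_high) >= 20))
})
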