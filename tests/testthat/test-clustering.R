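# MMP pairs and Murcko/MMP clustering

test_that("single-cut MMP identifies textbook pairs", {
  mols <- lapply(c(tol = "Cc1ccccc1", eb = "CCc1ccccc1", ph = "Oc1ccccc1"),
                 parseSmiles)
  mmp <- findMmpPairs(mols)
  expect_setequal(pairKey(mmp$id_i, mmp$id_j),
                  c("eb tol", "ph tol", "eb ph"))
  row <- mmp[pairKey(mmp$id_i, mmp$id_j) == "eb tol", ]
  expect_match(row$core_smiles, "c1")  # shared benzene core
})

test_that("identical molecules and oversized substituents never pair", {
  mols <- lapply(c(a = "Cc1ccccc1", b = "Cc1ccccc1"), parseSmiles)
  expect_equal(nrow(findMmpPairs(mols)), 0L)
  # a substituent larger than maxSubAtoms blocks the pair
  mols2 <- lapply(c(a = "Cc1ccc2ccccc2c1", b = "CCCCCCCCCc1ccc2ccccc2c1"),
                  parseSmiles)
  expect_equal(nrow(findMmpPairs(mols2, maxSubAtoms = 8L)), 0L)
  expect_equal(nrow(findMmpPairs(mols2, maxSubAtoms = 9L)), 1L)
  # and the core is never smaller than the exchanged substituent
  mols3 <- lapply(c(a = "CCCCc1ccccc1", b = "CCCCc1ccncc1"), parseSmiles)
  expect_equal(nrow(findMmpPairs(mols3, maxSubAtoms = 8L)), 0L)
})

test_that("findMmpPairs agrees with the brute-force oracle", {
  pool <- c(tol = "Cc1ccccc1", eb = "CCc1ccccc1", ph = "Oc1ccccc1",
            an = "Nc1ccccc1", mo = "COc1ccccc1", py = "Cc1ccncc1",
            naph = "Cc1ccc2ccccc2c1", cyc = "CC1CCCCC1",
            ac = "CC(=O)Nc1ccccc1", bn = "N#Cc1ccccc1",
            prop = "CCCc1ccccc1", dim = "CC(C)c1ccccc1")
  mols <- lapply(pool, parseSmiles)
  got <- findMmpPairs(mols)
  want <- oracleMmpPairs(mols)
  expect_setequal(pairKey(got$id_i, got$id_j),
                  pairKey(want$id_i, want$id_j))
})

test_that("clusters are components of scaffold-identity and MMP edges", {
  df <- data.frame(
    id = c("t", "e", "p", "n1", "n2"),
    smiles = c("Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1",
               "Cc1ccc2ccccc2c1", "CCc1ccc2ccccc2c1"),
    e3_class = "VHL", deg_low = c(80, 90, 10, 50, 60),
    deg_high = c(85, 95, 20, 55, 65))
  set <- DegradationSet(df)
  asg <- murckoMmpClusters(set, "full")
  cl <- asg$cluster
  names(cl) <- asg$id
  # benzene-scaffold molecules together, naphthalene-scaffold separate
  expect_length(unique(cl[c("t", "e", "p")]), 1L)
  expect_length(unique(cl[c("n1", "n2")]), 1L)
  expect_false(cl[["t"]] == cl[["n1"]])
  # cluster assignment invariant to input order
  asg2 <- murckoMmpClusters(set[c(5, 3, 1, 4, 2)], "full")
  cl2 <- asg2$cluster; names(cl2) <- asg2$id
  expect_equal(outer(cl[asg$id], cl[asg$id], "=="),
               outer(cl2[asg$id], cl2[asg$id], "=="))
})

test_that("an MMP edge bridges two scaffold groups into one cluster", {
  # phenyl vs pyridyl analogs: different scaffolds, single-ring swap
  # (chains long enough that the ring is the smaller exchanged fragment)
  df <- data.frame(
    id = c("a1", "a2", "b1"),
    smiles = c("CCCCCCCc1ccccc1", "CCCCCCCCc1ccccc1", "CCCCCCCc1ccncc1"),
    e3_class = "CRBN", deg_low = c(10, 20, 30), deg_high = c(15, 25, 35))
  set <- DegradationSet(df)
  asg <- murckoMmpClusters(set, "full")
  expect_length(unique(asg$cluster), 1L)
  # every same-cluster pair is connected by an edge chain (path search on
  # the scaffold/MMP relation computed independently)
  mols <- moleculeList(set)
  scaff <- vapply(mols, scaffoldSignature, "")
  mmp <- findMmpPairs(mols)
  n <- length(mols)
  adj <- outer(scaff, scaff, "==")
  for (k in seq_len(nrow(mmp))) {
    i <- match(mmp$id_i[k], names(mols)); j <- match(mmp$id_j[k], names(mols))
    adj[i, j] <- adj[j, i] <- TRUE
  }
  reach <- adj
  for (m in seq_len(n)) reach <- reach | (reach %*% reach > 0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    expect_equal(asg$cluster[i] == asg$cluster[j], reach[i, j])
})

test_that("cluster activity summaries match hand computation", {
  df <- data.frame(id = c("a", "b", "c", "d"),
                   smiles = c("Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1",
                              "CC1CCCCC1"),
                   e3_class = "VHL", deg_low = c(80, 90, 100, 70),
                   deg_high = c(85, 95, 100, 75))
  set <- DegradationSet(df)
  asg <- murckoMmpClusters(set, "full")
  summ <- clusterActivitySummary(asg, set, threshold = 75)
  big <- summ[summ$n == 3L, ]
  expect_equal(big$mean, 90)
  expect_equal(big$min, 80)
  expect_equal(big$max, 100)
  expect_equal(big$active_fraction, 1)
  single <- summ[summ$n == 1L, ]
  expect_equal(single$min, single$mean)
  expect_equal(single$mean, single$max)
  expect_equal(single$active_fraction, 0)
  # values {70, 80} at threshold 75 -> active fraction 0.5
  df2 <- df; df2$deg_low <- c(70, 80, 70, 80)
  set2 <- DegradationSet(df2)
  s2 <- clusterActivitySummary(
    data.frame(id = df2$id, level = "full", cluster = "a"), set2)
  expect_equal(s2$active_fraction, 0.5)
})
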