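# synthetic PROTAC generator: blocks, assembly, simulation, dataset

test_that("building blocks are valid attachment-labeled fragments", {
  bl <- generateBuildingBlocks(defaultGeneratorConfig(seed = 1))
  nDummies <- function(s) sum(parseSmiles(s)@atoms$element == "*")
  expect_gte(nrow(bl$warheads), 3L)
  expect_true(any(bl$warheads$dead))
  for (s in c(bl$warheads$smiles, bl$e3$smiles))
    expect_equal(nDummies(s), 1L)
  for (s in bl$linkers$smiles) expect_equal(nDummies(s), 2L)
  # rigid linkers contain at least one ring
  rig <- bl$linkers[bl$linkers$type == "rigid", ]
  for (s in rig$smiles) expect_true(any(parseSmiles(s)@bonds$ring))
  # the dead variant is a single-cut MMP partner of its parent
  dead <- bl$warheads[bl$warheads$dead, ][1L, ]
  parent <- bl$warheads[bl$warheads$name == dead$parent, ]
  mols <- lapply(c(p = parent$smiles, d = dead$smiles), function(s)
    parseSmiles(gsub("(*)", "C", s, fixed = TRUE)))
  expect_equal(nrow(findMmpPairs(mols)), 1L)
})

test_that("assembly conserves heavy atoms and round-trips", {
  bl <- generateBuildingBlocks(defaultGeneratorConfig(seed = 1))
  heavy <- function(s) sum(parseSmiles(s)@atoms$element != "*")
  asm <- assembleProtac(bl$warheads$smiles[1], "*CCC*", bl$e3$smiles[1])
  expect_equal(nrow(asm$mol@atoms),
               heavy(bl$warheads$smiles[1]) + 3L + heavy(bl$e3$smiles[1]))
  expect_equal(length(unique(ProtacSAR:::moleculeComponents(asm$mol))), 1L)
  expect_equal(graphSignature(parseSmiles(asm$smiles)),
               graphSignature(asm$mol))
  expect_error(assembleProtac(bl$warheads$smiles[1], "*CCC",
                              bl$e3$smiles[1]), "attachment")
})

test_that("degradation model matches its formula without noise", {
  cfg <- defaultGeneratorConfig(seed = 1)
  cfg$noise_sd <- 0
  feats <- data.frame(e3_class = c("VHL", "VHL", "CRBN"),
                      n_carbon = c(10, 13, 6),
                      linker_class = "alkyl",
                      penalty = c(0, 0, 120),
                      TPSA = c(96, 96, 93))
  deg <- ProtacSAR:::withSeed(1, simulateDegradation(feats, cfg))
  expect_equal(deg$deg_low, c(95, 95 - 2 * 9, 0))   # Dmax; parabola; clipped
  expect_equal(deg$deg_high[3], 0 + cfg$concentration_gain)
  # TPSA above tau is penalized at slope gamma
  feats2 <- feats[1, ]; feats2$TPSA <- cfg$tpsa_rule$tau + 10
  deg2 <- ProtacSAR:::withSeed(1, simulateDegradation(feats2, cfg))
  expect_equal(deg2$deg_low, 95 - 10 * cfg$tpsa_rule$gamma)
})

test_that("generated datasets are reproducible and well formed", {
  g1 <- generateDataset(defaultGeneratorConfig(n = 40, seed = 7))
  g2 <- generateDataset(defaultGeneratorConfig(n = 40, seed = 7))
  expect_identical(recordTable(g1$set), recordTable(g2$set))
  expect_identical(g1$truth$cliff_pairs, g2$truth$cliff_pairs)
  g3 <- generateDataset(defaultGeneratorConfig(n = 40, seed = 8))
  expect_false(identical(recordTable(g1$set), recordTable(g3$set)))
  expect_equal(length(g1$set), 40L)
  # dead-variant share approximates the cliff fraction
  expect_equal(sum(g1$truth$recipes$dead), round(0.15 * 40))
  # all records survive a CSV round trip with validation
  p <- tempfile(fileext = ".csv")
  writeDegradationTable(g1$set, p)
  expect_equal(length(loadDegradationTable(p)), 40L)
})

test_that("the VHL share stays within binomial bounds", {
  gen <- generateDataset(defaultGeneratorConfig(n = 300, seed = 31))
  nV <- sum(e3Class(gen$set) == "VHL")
  p <- 53 / 92
  bounds <- qbinom(c(0.005, 0.995), 300, p)
  expect_gte(nV, bounds[1])
  expect_lte(nV, bounds[2])
})

test_that("the higher concentration degrades at least as much (median)", {
  gen <- .sharedGen()
  expect_gte(median(degradation(gen$set, "high") -
                    degradation(gen$set, "low")), 0)
  # null-control mode: same ordering property, no structural signal
  nullGen <- generateDataset(defaultGeneratorConfig(n = 40, seed = 3,
                                                    signal = FALSE))
  expect_gte(median(degradation(nullGen$set, "high") -
                    degradation(nullGen$set, "low")), 0)
  expect_length(nullGen$truth$signal_descriptors, 0L)
})

test_that("planted cliff pairs have large consistent activity gaps", {
  gen <- .sharedGen()
  tp <- gen$truth$cliff_pairs
  r <- recordTable(gen$set)
  dl <- abs(r$deg_low[match(tp$id_parent, r$id)] -
            r$deg_low[match(tp$id_dead, r$id)])
  dh <- abs(r$deg_high[match(tp$id_parent, r$id)] -
            r$deg_high[match(tp$id_dead, r$id)])
  expect_true(all(dl >= 40))
  expect_true(all(dh >= 40))
})
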