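# tripartite decomposition, linker metrics, matched series and LDR fits

test_that("decomposition recovers the generator's planted atom map", {
  bl <- generateBuildingBlocks(defaultGeneratorConfig(seed = 1))
  anchors <- defaultAnchorLibrary()
  for (wi in 1:3) for (ei in 1:2) {
    asm <- assembleProtac(bl$warheads$smiles[wi], "*CCCCCCC*",
                          bl$e3$smiles[ei])
    d <- decomposeProtac(asm$mol, anchors)
    expect_equal(sort(d$warhead_atoms), which(asm$map == "warhead"))
    expect_equal(sort(d$linker_atoms), which(asm$map == "linker"))
    expect_equal(sort(d$e3_atoms), which(asm$map == "e3"))
    # partition invariant
    expect_setequal(c(d$warhead_atoms, d$linker_atoms, d$e3_atoms),
                    seq_len(nrow(asm$mol@atoms)))
    expect_equal(nrow(d$attachment_bonds), 2L)
  }
})

test_that("missing anchors raise role-specific errors", {
  anchors <- defaultAnchorLibrary()
  expect_error(decomposeProtac(parseSmiles("CCc1ccccc1"), anchors),
               "NoAnchorMatch.*warhead")
  # a bare warhead with a methyl linker stub has no E3 match
  bl <- generateBuildingBlocks(defaultGeneratorConfig(seed = 1))
  wOnly <- parseSmiles(gsub("(*)", "(C)", bl$warheads$smiles[1],
                            fixed = TRUE))
  expect_error(decomposeProtac(wOnly, anchors), "NoAnchorMatch.*e3")
})

test_that("largest match wins when same-role candidates overlap", {
  bl <- generateBuildingBlocks(defaultGeneratorConfig(seed = 1))
  # the fluorinated warhead contains the plain warhead as a subgraph;
  # both role patterns match, the larger (fluorinated) must be chosen
  asm <- assembleProtac(bl$warheads$smiles[2], "*CCCCCC*", bl$e3$smiles[1])
  d <- decomposeProtac(asm$mol, defaultAnchorLibrary())
  expect_equal(d$warhead_name, "wh_nitrile_F")
  expect_equal(length(d$warhead_atoms), sum(asm$map == "warhead"))
})

test_that("linker metrics count carbons and classify chemistry", {
  bl <- generateBuildingBlocks(defaultGeneratorConfig(seed = 1))
  anchors <- defaultAnchorLibrary()
  cases <- list(
    list(smi = "*CCCCCC*", nC = 6L, topo = 6L, cls = "alkyl"),
    list(smi = "*CCOCCOCC*", nC = 6L, topo = 8L, cls = "ether"),
    list(smi = "*C(O)CCC*", nC = 4L, topo = 4L, cls = "ether"),
    list(smi = "*C1CCC(CC2CCN(*)CC2)CC1", nC = 12L, topo = 9L,
         cls = "rigid"))
  for (cs in cases) {
    asm <- assembleProtac(bl$warheads$smiles[1], cs$smi, bl$e3$smiles[1])
    lm <- linkerMetrics(decomposeProtac(asm$mol, anchors), asm$mol)
    expect_equal(lm$n_carbon, cs$nC, label = cs$smi)
    expect_equal(lm$topo_length, cs$topo, label = cs$smi)
    expect_equal(lm$linker_class, cs$cls, label = cs$smi)
  }
})

test_that("decomposition is invariant to atom reindexing", {
  bl <- generateBuildingBlocks(defaultGeneratorConfig(seed = 1))
  asm <- assembleProtac(bl$warheads$smiles[1], "*CCOCC*", bl$e3$smiles[2])
  # reparse from canonical SMILES: different atom numbering, same metrics
  re <- parseSmiles(asm$smiles)
  anchors <- defaultAnchorLibrary()
  lm1 <- linkerMetrics(decomposeProtac(asm$mol, anchors), asm$mol)
  lm2 <- linkerMetrics(decomposeProtac(re, anchors), re)
  expect_equal(lm1[c("n_carbon", "topo_length", "linker_class")],
               lm2[c("n_carbon", "topo_length", "linker_class")])
})

test_that("matched series group identical blocks and drop small groups", {
  gen <- .sharedGen()
  dd <- decomposeDataset(gen$set)
  series <- selectMatchedSeries(gen$set, dd$decomps)
  expect_true(all(vapply(series, nrow, 0L) >= 4L))
  tr <- gen$truth$recipes
  for (s in series) {
    sub <- tr[match(s$id, tr$id), ]
    expect_length(unique(sub$warhead), 1L)
    expect_length(unique(sub$e3_class), 1L)
    expect_length(unique(sub$linker_class), 1L)
  }
})

test_that("parabola fit recovers exact and noisy planted optima", {
  L <- 5:11
  f <- fitLinkerParabola(L, 90 - 2 * (L - 8)^2)
  expect_equal(f$vertex, 8, tolerance = 1e-9)
  expect_equal(f$curvature, -2, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_false(f$degenerate)

  set.seed(5)
  Ln <- rep(5:11, length.out = 30)
  fn <- fitLinkerParabola(Ln, 90 - 2 * (Ln - 8)^2 + rnorm(30, 0, 3))
  expect_lt(abs(fn$vertex - 8), 1)

  fc <- fitLinkerParabola(1:5, 2 * (1:5) + 3)   # collinear
  expect_true(fc$degenerate)
  expect_error(fitLinkerParabola(c(1, 1, 2, 2, 3), c(1, 2, 3, 4, 5)),
               "4 distinct")
})
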