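# the seven permeability-related descriptors

test_that("hand-checked descriptor values for small molecules", {
  bz <- computeDescriptors(parseSmiles("c1ccccc1"))
  expect_equal(bz$MW, 78.11, tolerance = 1e-3)
  expect_equal(bz$nC, 6L)
  expect_equal(bz$nAR, 1L)
  expect_equal(bz$nHAcc, 0L)
  expect_equal(bz$nHDon, 0L)
  expect_equal(bz$TPSA, 0)

  et <- computeDescriptors(parseSmiles("CCO"))
  expect_equal(et$nHAcc, 1L)
  expect_equal(et$nHDon, 1L)
  expect_equal(et$TPSA, 20.23)

  py <- computeDescriptors(parseSmiles("c1ccncc1"))
  expect_equal(py$nAR, 1L)
  expect_equal(py$nHDon, 0L)
  expect_equal(py$nHAcc, 1L)
  expect_equal(py$TPSA, 12.89)
})

test_that("TPSA sums Ertl fragment contributions", {
  expect_equal(tpsa(parseSmiles("NC(=O)c1ccccc1")), 43.09)  # 26.02 + 17.07
  expect_equal(tpsa(parseSmiles("CC(=O)Nc1ccccc1")), 29.10) # 12.03 + 17.07
  expect_equal(tpsa(parseSmiles("N#Cc1ccccc1")), 23.79)
  expect_equal(tpsa(parseSmiles("COC")), 9.23)
  expect_equal(tpsa(parseSmiles("c1cc[nH]c1")), 15.79)
  for (hc in c("CCCC", "c1ccccc1", "C1CCCCC1", "CC(C)Cc1ccccc1"))
    expect_equal(tpsa(parseSmiles(hc)), 0)
})

test_that("TPSA is additive over disconnected unions", {
  pairs <- list(c("CCO", "NC(=O)c1ccccc1"), c("c1ccncc1", "OCCO"),
                c("CC(=O)O", "COC"))
  for (p in pairs) {
    joint <- tpsa(parseSmiles(paste(p, collapse = ".")))
    expect_equal(joint, tpsa(parseSmiles(p[1])) + tpsa(parseSmiles(p[2])))
  }
})

test_that("Kier PHI reproduces closed forms", {
  expect_equal(kierPhi(parseSmiles("CCCCCC")), 5, tolerance = 1e-9)
  # unbranched alkanes: PHI = A - 1 exactly
  for (A in 3:20) {
    m <- parseSmiles(strrep("C", A))
    expect_equal(kierPhi(m), A - 1, tolerance = 1e-9)
  }
  expect_equal(kierPhi(parseSmiles("C1CCCCC1")), (25 / 6) * (20 / 9) / 6,
               tolerance = 1e-9)
  expect_error(kierPhi(parseSmiles("CC")), "at least 3")
})

test_that("acceptor/donor counting follows the frozen rules", {
  d <- computeDescriptors(parseSmiles("CC(=O)Nc1ccccc1"))  # acetanilide
  expect_equal(d$nHDon, 1L)   # the amide NH
  expect_equal(d$nHAcc, 1L)   # carbonyl O only; amide N excluded
  d2 <- computeDescriptors(parseSmiles("c1cc[nH]c1"))      # pyrrole
  expect_equal(d2$nHAcc, 0L)  # pyrrole-type aromatic N excluded
  d3 <- computeDescriptors(parseSmiles("FC(F)(F)c1ccccc1"))
  expect_equal(d3$nHAcc, 0L)  # fluorine never counted
})

test_that("correlation matrix is symmetric with unit diagonal", {
  gen <- .sharedGen()
  desc <- computeDescriptors(moleculeList(gen$set))
  cm <- descriptorCorrelationMatrix(desc)
  ok <- !apply(is.na(cm), 1L, all)
  expect_true(all(diag(cm)[ok] == 1))
  expect_equal(cm, t(cm))
  dup <- cbind(desc, TPSA2 = desc$TPSA)
  cm2 <- descriptorCorrelationMatrix(dup)
  expect_equal(cm2["TPSA", "TPSA2"], 1)
  cst <- cbind(desc, K = 1)
  expect_true(all(is.na(descriptorCorrelationMatrix(cst)[, "K"])))
})

test_that("planted polarity makes TPSA covary with H-bond counts", {
  gen <- .sharedGen()
  desc <- computeDescriptors(moleculeList(gen$set))
  expect_gt(cor(desc$TPSA, desc$nHAcc), 0)
  expect_gt(cor(desc$TPSA, desc$nHDon), 0)
})
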