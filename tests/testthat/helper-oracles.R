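# shared fixtures and independent oracles used across test files

# a small pool of drug-like SMILES for property-style tests
smallMoleculePool <- c(
  "CCO", "COC", "CCC", "CCN", "CC(C)O", "CC(=O)O", "CC(=O)N",
  "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
  "c1ccncc1", "Cc1ccncc1", "c1ccc2ccccc2c1", "C1CCCCC1", "C1CCNCC1",
  "CC(C)Cc1ccccc1", "COc1ccccc1", "N#Cc1ccccc1", "CC(=O)Nc1ccccc1",
  "OCCOCCO", "C1CCOC1", "FC(F)(F)c1ccccc1", "Clc1ccccc1")

# brute-force positive/negative pair-counting ROC area (ties count 1/2)
oracleRocAuc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# brute-force all-pairs similarity search on a fingerprint count matrix
oracleSimilarPairs <- function(counts, sMin) {
  n <- nrow(counts)
  out <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- tanimoto(counts[i, ], counts[j, ])
    if (s >= sMin) out <- rbind(out, data.frame(i = i, j = j, sim = s))
  }
  out
}

# independent fragment identity for the MMP oracle: the fragment subgraph
# with an explicit dummy atom at the cut, canonicalized by OpenBabel
# (a code path entirely separate from graphSignature)
obFragmentKey <- function(mol, atoms, attachAtom) {
  sub <- ProtacSAR:::subgraphMol(mol, atoms)
  a <- rbind(sub@atoms,
             data.frame(element = "*", aromatic = FALSE, charge = 0L,
                        nH = 0L, stereo = ""))
  b <- rbind(sub@bonds,
             data.frame(a1 = match(attachAtom, sort(atoms)),
                        a2 = nrow(a), order = 1L, aromatic = FALSE,
                        ring = FALSE))
  frag <- ProtacSAR:::newMolGraph(a, b)
  smi <- writeSmiles(frag)
  out <- ChemmineOB::convertFormat("SMI", "CAN", source = smi)
  trimws(sub("\t.*$", "", out))
}

# brute-force single-cut MMP oracle over a list of molecules
oracleMmpPairs <- function(mols, maxSubAtoms = 8L) {
  ids <- names(mols)
  cutsOf <- function(mol) {
    b <- mol@bonds
    n <- nrow(mol@atoms)
    res <- list()
    for (k in which(!b$ring)) {
      g <- ProtacSAR:::asIgraph(mol)
      g2 <- igraph::delete_edges(g, paste0(b$a1[k], "|", b$a2[k]))
      memb <- igraph::components(g2)$membership
      s1 <- which(memb == memb[b$a1[k]]); s2 <- which(memb == memb[b$a2[k]])
      for (ori in 1:2) {
        core <- if (ori == 1) s1 else s2
        sub <- if (ori == 1) s2 else s1
        if (length(sub) > maxSubAtoms || length(core) < length(sub)) next
        coreAtt <- if (ori == 1) b$a1[k] else b$a2[k]
        subAtt <- if (ori == 1) b$a2[k] else b$a1[k]
        res[[length(res) + 1L]] <- list(
          core = obFragmentKey(mol, core, coreAtt),
          sub = obFragmentKey(mol, sub, subAtt))
      }
    }
    res
  }
  allCuts <- lapply(mols, cutsOf)
  molKey <- vapply(mols, function(m)
    trimws(sub("\t.*$", "", ChemmineOB::convertFormat(
      "SMI", "CAN", source = writeSmiles(m)))), "")
  pairs <- NULL
  n <- length(mols)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (molKey[i] == molKey[j]) next
    hit <- FALSE
    for (ci in allCuts[[i]]) {
      for (cj in allCuts[[j]]) {
        if (ci$core == cj$core && ci$sub != cj$sub) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) pairs <- rbind(pairs, data.frame(id_i = ids[i], id_j = ids[j]))
  }
  pairs
}

pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))

# small synthetic dataset shared by several files (cached per test run)
.sharedGen <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateDataset(defaultGeneratorConfig(n = 60, seed = 2024))
    cache
  }
})
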