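# Murcko-scaffold clusters merged through matched-molecular-pair (MMP)
# relationships, at the whole-molecule and building-block levels.

# all single-cut fragmentations of a molecule: every acyclic (non-ring)
# bond is cut; both orientations with |core| >= |substituent| and
# |substituent| <= maxSubAtoms are emitted.  Fragments are identified by
# canonical signatures with the cut atom marked as attachment point.
# Every acyclic bond is a bridge, so one DFS gives both sides of every
# cut: the descendants of the deeper endpoint are a contiguous run of the
# DFS preorder.
.singleCuts <- function(mol, maxSubAtoms = 8L) {
  b <- mol@bonds
  cuts <- which(!b$ring)
  n <- nrow(mol@atoms)
  if (!length(cuts) || n < 2L) return(list())
  g <- asIgraph(mol)
  d <- igraph::dfs(g, root = 1, father = TRUE)
  ord <- as.integer(d$order)
  father <- as.integer(d$father)
  pos <- integer(n); pos[ord] <- seq_len(n)
  size <- rep(1L, n)
  for (v in rev(ord)) {
    f <- father[v]
    if (!is.na(f) && f > 0L) size[f] <- size[f] + size[v]
  }
  out <- list()
  for (k in cuts) {
    u <- b$a1[k]; v <- b$a2[k]
    child <- if (!is.na(father[v]) && father[v] == u) v
             else if (!is.na(father[u]) && father[u] == v) u
             else next  # unreachable for a bridge in a connected molecule
    par <- if (child == v) u else v
    sideC <- ord[pos[child]:(pos[child] + size[child] - 1L)]
    inC <- logical(n); inC[sideC] <- TRUE
    sideP <- which(!inC)
    for (ori in 1:2) {
      core <- if (ori == 1L) sideC else sideP
      sub <- if (ori == 1L) sideP else sideC
      if (length(sub) > maxSubAtoms || length(core) < length(sub)) next
      coreAtt <- if (ori == 1L) child else par
      subAtt <- if (ori == 1L) par else child
      coreS <- sort(core)
      subS <- sort(sub)
      out[[length(out) + 1L]] <- list(
        coreSig = graphSignature(subgraphMol(mol, coreS),
                                 marked = match(coreAtt, coreS)),
        subSig = graphSignature(subgraphMol(mol, subS),
                                marked = match(subAtt, subS)),
        coreAtoms = coreS, subAtoms = subS, bond = k)
    }
  }
  out
}

#' Find matched molecular pairs
#'
#' Enumerates all single cuts of acyclic non-ring bonds of every
#' molecule.  Two molecules form an MMP when they share a canonical core
#' fragment but differ in the substituent attached at the same position,
#' with each substituent at most \code{maxSubAtoms} heavy atoms and never
#' larger than the core.
#'
#' @param mols named list of [MolGraph-class] objects (2 or more).
#' @param maxSubAtoms maximum substituent size in heavy atoms (default 8,
#'   which keeps "single localized structural change" meaningful on
#'   700-1200 Da molecules).
#' @param ringSubOnly if \code{TRUE}, keep only pairs whose exchanged
#'   substituents contain a ring (ring-system substitutions).
#' @return data.frame with columns \code{id_i}, \code{id_j},
#'   \code{core_smiles}, \code{sub_smiles_i}, \code{sub_smiles_j}; one row
#'   per unordered pair (the first shared core found).  Structurally
#'   identical molecules never pair.
#' @export
findMmpPairs <- function(mols, maxSubAtoms = 8L, ringSubOnly = FALSE) {
  stopifnot(is.list(mols), length(mols) >= 2L)
  ids <- names(mols)
  if (is.null(ids)) ids <- as.character(seq_along(mols))
  frags <- lapply(mols, .singleCuts, maxSubAtoms = maxSubAtoms)
  molSig <- vapply(mols, graphSignature, "")
  empty <- data.frame(id_i = character(), id_j = character(),
                      core_smiles = character(), sub_smiles_i = character(),
                      sub_smiles_j = character())
  # index: core signature -> (molecule, fragment) occurrences
  coreIdx <- new.env(parent = emptyenv())
  for (i in seq_along(frags)) {
    f <- frags[[i]]
    for (j in seq_along(f)) {
      key <- f[[j]]$coreSig
      hit <- get0(key, envir = coreIdx, inherits = FALSE)
      assign(key, rbind(hit, c(i, j)), envir = coreIdx)
    }
  }
  smiCache <- new.env(parent = emptyenv())
  fragSmiles <- function(sig, mol, atoms) {
    s <- get0(sig, envir = smiCache, inherits = FALSE)
    if (is.null(s)) {
      s <- writeSmiles(subgraphMol(mol, atoms))
      assign(sig, s, envir = smiCache)
    }
    s
  }
  hasRing <- function(m, atoms) any(subgraphMol(m, atoms)@bonds$ring)
  seen <- new.env(parent = emptyenv())
  rows <- list()
  for (key in ls(coreIdx)) {
    occ <- get(key, envir = coreIdx)
    molsIn <- unique(occ[, 1L])
    if (length(molsIn) < 2L) next
    for (ii in seq_along(molsIn)) for (jj in seq_along(molsIn)) {
      if (ii >= jj) next
      mi <- molsIn[ii]; mj <- molsIn[jj]
      pkey <- paste(min(mi, mj), max(mi, mj))
      if (!is.null(get0(pkey, envir = seen, inherits = FALSE))) next
      if (molSig[mi] == molSig[mj]) next  # identical structures: no pair
      fi <- occ[occ[, 1L] == mi, 2L]
      fj <- occ[occ[, 1L] == mj, 2L]
      si <- vapply(frags[[mi]][fi], `[[`, "", "subSig")
      sj <- vapply(frags[[mj]][fj], `[[`, "", "subSig")
      hit <- NULL
      for (x in seq_along(si)) {
        y <- which(sj != si[x])
        if (length(y)) { hit <- c(fi[x], fj[y[1L]]); break }
      }
      if (is.null(hit)) next
      f1 <- frags[[mi]][[hit[1L]]]
      f2 <- frags[[mj]][[hit[2L]]]
      if (ringSubOnly &&
          !hasRing(mols[[mi]], f1$subAtoms) &&
          !hasRing(mols[[mj]], f2$subAtoms)) next
      assign(pkey, TRUE, envir = seen)
      o <- order(c(mi, mj))
      rows[[length(rows) + 1L]] <- data.frame(
        id_i = ids[min(mi, mj)], id_j = ids[max(mi, mj)],
        core_smiles = fragSmiles(f1$coreSig, mols[[mi]], f1$coreAtoms),
        sub_smiles_i = fragSmiles(
          if (o[1L] == 1L) f1$subSig else f2$subSig,
          mols[[if (o[1L] == 1L) mi else mj]],
          if (o[1L] == 1L) f1$subAtoms else f2$subAtoms),
        sub_smiles_j = fragSmiles(
          if (o[1L] == 1L) f2$subSig else f1$subSig,
          mols[[if (o[1L] == 1L) mj else mi]],
          if (o[1L] == 1L) f2$subAtoms else f1$subAtoms))
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$id_i, out$id_j), , drop = FALSE]
}

#' Murcko/MMP cluster assignment
#'
#' Clusters are the connected components of the graph whose vertices are
#' compounds and whose edges join (i) compounds with identical canonical
#' Murcko scaffolds and (ii) MMP partners.  At the building-block levels
#' (\code{warhead}, \code{e3}, \code{linker}) the scaffold and MMP
#' relations are computed on the extracted fragment only.  Acyclic
#' structures all share the empty scaffold.
#'
#' @param set a [DegradationSet-class].
#' @param level \code{full}, \code{warhead}, \code{e3} or \code{linker}.
#' @param decomps decompositions (required for building-block levels).
#' @param maxSubAtoms passed to [findMmpPairs()].
#' @param ringSubOnly restrict MMP merges to ring-system substitutions.
#' @return data.frame (id, level, cluster); cluster labels are letters in
#'   order of first appearance.
#' @export
murckoMmpClusters <- function(set, level = c("full", "warhead", "e3", "linker"),
                              decomps = NULL, maxSubAtoms = 8L,
                              ringSubOnly = FALSE) {
  level <- match.arg(level)
  mols <- moleculeList(set)
  ids <- compoundIds(set)
  if (level != "full") {
    if (is.null(decomps))
      stop("building-block clustering requires decompositions")
    slot <- c(warhead = "warhead_atoms", e3 = "e3_atoms",
              linker = "linker_atoms")[[level]]
    mols <- lapply(ids, function(id)
      subgraphMol(mols[[id]], decomps[[id]][[slot]]))
    names(mols) <- ids
  }
  # collapse structurally identical molecules to one representative each
  # (frequent at building-block levels); they trivially share a cluster
  molSig <- vapply(mols, graphSignature, "")
  repIdx <- which(!duplicated(molSig))
  group <- match(molSig, molSig[repIdx])  # molecule -> representative rank
  repMols <- mols[repIdx]
  names(repMols) <- as.character(seq_along(repIdx))
  scaff <- vapply(repMols, scaffoldSignature, "")
  edges <- matrix(integer(), ncol = 2L)
  # scaffold-identity edges: chain within each identical-scaffold group
  for (sgn in unique(scaff)) {
    idx <- which(scaff == sgn)
    if (length(idx) > 1L)
      edges <- rbind(edges, cbind(idx[-length(idx)], idx[-1L]))
  }
  if (length(repMols) >= 2L) {
    mmp <- findMmpPairs(repMols, maxSubAtoms = maxSubAtoms,
                        ringSubOnly = ringSubOnly)
    if (nrow(mmp))
      edges <- rbind(edges, cbind(as.integer(mmp$id_i),
                                  as.integer(mmp$id_j)))
  }
  g <- igraph::make_empty_graph(length(repMols), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership[group]
  # stable labels: letters by order of first appearance
  lab <- match(memb, unique(memb))
  labels <- c(letters, paste0(rep(letters, each = 26L), letters))
  data.frame(id = ids, level = level, cluster = labels[lab])
}

#' Per-cluster activity summary
#'
#' @param assignment data.frame from [murckoMmpClusters()].
#' @param set a [DegradationSet-class] covering every clustered id.
#' @param threshold activity cutoff in percent.
#' @param concentration which readout to summarise.
#' @return data.frame (cluster, n, mean, min, max, active_fraction).
#' @export
clusterActivitySummary <- function(assignment, set, threshold = 75,
                                   concentration = c("low", "high")) {
  concentration <- match.arg(concentration)
  r <- recordTable(set)
  if (!all(assignment$id %in% r$id))
    stop("clustered id(s) missing from the dataset: ",
         paste(setdiff(assignment$id, r$id), collapse = ", "))
  deg <- if (concentration == "low") r$deg_low else r$deg_high
  names(deg) <- r$id
  out <- lapply(split(assignment$id, assignment$cluster), function(idsIn) {
    v <- deg[idsIn]
    data.frame(cluster = NA_character_, n = length(v), mean = mean(v),
               min = min(v), max = max(v),
               active_fraction = mean(v >= threshold))
  })
  res <- do.call(rbind, out)
  res$cluster <- names(out)
  rownames(res) <- NULL
  res[order(res$cluster), , drop = FALSE]
}
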