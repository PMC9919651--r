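# Graph-level utilities on MolGraph objects.  All generic graph work
# (connectivity, shortest paths, canonical labeling via BLISS, VF2
# subgraph matching) is delegated to igraph; chemistry-aware logic lives
# here.

#' @importFrom igraph graph_from_edgelist make_empty_graph bridges
#'   components distances canonical_permutation subgraph_isomorphisms
#'   V E delete_edges shortest_paths vcount
NULL

# plain igraph (undirected, unlabeled) from a MolGraph
asIgraph <- function(mol) {
  n <- nrow(mol@atoms)
  if (nrow(mol@bonds) == 0L)
    return(igraph::make_empty_graph(n, directed = FALSE))
  igraph::graph_from_edgelist(cbind(mol@bonds$a1, mol@bonds$a2),
                              directed = FALSE) |>
    (\(g) if (igraph::vcount(g) < n) igraph::add_vertices(g, n - igraph::vcount(g)) else g)()
}

# ring membership flags per bond: a bond is in a ring iff it is not a bridge
ringBondFlags <- function(natoms, bonds) {
  if (nrow(bonds) == 0L) return(logical(0))
  g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2), directed = FALSE)
  br <- igraph::bridges(g)
  res <- rep(TRUE, nrow(bonds))
  res[as.integer(br)] <- FALSE
  res
}

# connected-component id per atom
moleculeComponents <- function(mol) {
  igraph::components(asIgraph(mol))$membership
}

# ring atom flags
ringAtomFlags <- function(mol) {
  f <- logical(nrow(mol@atoms))
  rb <- mol@bonds[mol@bonds$ring, , drop = FALSE]
  f[unique(c(rb$a1, rb$a2))] <- TRUE
  f
}

# smallest set of smallest rings (approximate SSSR): for every ring bond,
# the smallest cycle through it (BFS avoiding the bond itself);
# deduplicated by atom set.  Exact for the simple ring systems this
# workflow handles (isolated and ortho-fused).
smallestRings <- function(mol) {
  b <- mol@bonds
  ringB <- which(b$ring)
  if (!length(ringB)) return(list())
  n <- nrow(mol@atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], b$a2[k])
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], b$a1[k])
  }
  seen <- character()
  rings <- list()
  for (k in ringB) {
    src <- b$a1[k]; dst <- b$a2[k]
    # BFS from src to dst not using the src-dst bond
    parent <- integer(n); parent[src] <- -1L
    frontier <- src
    found <- FALSE
    while (length(frontier) && !found) {
      nxt <- integer()
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (v == src && w == dst) next
          if (parent[w] == 0L && w != src) {
            parent[w] <- v
            if (w == dst) { found <- TRUE; break }
            nxt <- c(nxt, w)
          }
        }
        if (found) break
      }
      frontier <- nxt
    }
    if (!found) next
    cyc <- dst
    v <- dst
    while (parent[v] != -1L) { v <- parent[v]; cyc <- c(cyc, v) }
    key <- paste(sort(cyc), collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- cyc
    }
  }
  rings
}

# bond index lookup table: returns function(a1, a2) -> bond row or NA
bondIndexer <- function(mol) {
  b <- mol@bonds
  key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
  function(x, y) match(paste(pmin(x, y), pmax(x, y)), key)
}

# atom color strings used for canonical labeling and matching
atomColorStrings <- function(mol, skeleton = FALSE, marked = integer()) {
  a <- mol@atoms
  if (skeleton) {
    cols <- rep("A", nrow(a))
  } else {
    cols <- paste(a$element, a$charge, as.integer(a$aromatic), a$nH, sep = "|")
  }
  if (length(marked)) cols[marked] <- paste0(cols[marked], "|*")
  cols
}

bondColorCodes <- function(mol, skeleton = FALSE) {
  if (skeleton) rep(1L, nrow(mol@bonds))
  else ifelse(mol@bonds$aromatic, 4L, mol@bonds$order)
}

# auxiliary colored graph for BLISS/VF2: atoms keep their colors, every
# bond becomes an extra vertex colored by its bond code, linked to both
# endpoints; this encodes edge colors using vertex colors only
.auxGraph <- function(mol, skeleton = FALSE, marked = integer()) {
  n <- nrow(mol@atoms)
  nb <- nrow(mol@bonds)
  acol <- atomColorStrings(mol, skeleton, marked)
  bcol <- if (nb) paste0("bond|", bondColorCodes(mol, skeleton)) else character()
  if (nb) {
    el <- rbind(cbind(mol@bonds$a1, n + seq_len(nb)),
                cbind(mol@bonds$a2, n + seq_len(nb)))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (igraph::vcount(g) < n + nb)
      g <- igraph::add_vertices(g, n + nb - igraph::vcount(g))
  } else {
    g <- igraph::make_empty_graph(n, directed = FALSE)
  }
  list(graph = g, colors = c(acol, bcol), natoms = n)
}

# canonical atom order of a MolGraph (BLISS on the auxiliary graph);
# returns the atom indices in canonical order
canonicalAtomOrder <- function(mol, skeleton = FALSE, marked = integer()) {
  n <- nrow(mol@atoms)
  if (n == 1L) return(1L)
  aux <- .auxGraph(mol, skeleton, marked)
  colInt <- match(aux$colors, sort(unique(aux$colors)))
  cp <- igraph::canonical_permutation(aux$graph, colors = colInt)$labeling
  # cp[i] = canonical label of vertex i; restrict to atom vertices
  atomLab <- cp[seq_len(n)]
  order(atomLab)
}

#' Canonical graph signature
#'
#' A string that is identical for two molecular graphs if and only if they
#' are isomorphic as colored graphs (atom colors: element, charge,
#' aromaticity, implicit-H count; bond colors: order/aromaticity).  With
#' \code{skeleton = TRUE} all atom and bond colors are erased first, so
#' the signature compares pure graph topology.  \code{marked} atoms (for
#' example attachment points of a fragment) receive a distinguishing tag.
#'
#' @param mol a [MolGraph-class].
#' @param skeleton erase atom labels and bond orders first.
#' @param marked integer vector of atom indices to tag.
#' @return a character scalar.
#' @export
graphSignature <- function(mol, skeleton = FALSE, marked = integer()) {
  n <- nrow(mol@atoms)
  ordr <- canonicalAtomOrder(mol, skeleton, marked)
  pos <- integer(n); pos[ordr] <- seq_len(n)
  cols <- atomColorStrings(mol, skeleton, marked)
  b <- mol@bonds
  if (nrow(b)) {
    bc <- bondColorCodes(mol, skeleton)
    e1 <- pmin(pos[b$a1], pos[b$a2])
    e2 <- pmax(pos[b$a1], pos[b$a2])
    eo <- order(e1, e2)
    es <- paste(e1[eo], e2[eo], bc[eo], sep = ":", collapse = ";")
  } else es <- ""
  paste0(paste(cols[ordr], collapse = ","), "//", es)
}

# induced subgraph on a set of atoms, as a new MolGraph; implicit H counts
# are inherited from the parent (dangling valences are represented by the
# `marked` mechanism of graphSignature, not by added hydrogens)
subgraphMol <- function(mol, atomIdx) {
  atomIdx <- sort(unique(as.integer(atomIdx)))
  map <- integer(nrow(mol@atoms))
  map[atomIdx] <- seq_along(atomIdx)
  keep <- mol@bonds$a1 %in% atomIdx & mol@bonds$a2 %in% atomIdx
  b <- mol@bonds[keep, , drop = FALSE]
  b$a1 <- map[b$a1]; b$a2 <- map[b$a2]
  a <- mol@atoms[atomIdx, , drop = FALSE]
  rownames(a) <- NULL; rownames(b) <- NULL
  b$ring <- ringBondFlags(nrow(a), b)
  new("MolGraph", atoms = a, bonds = b, smiles = NA_character_)
}

# all matches of a pattern MolGraph in a molecule (VF2, non-induced,
# matching element/aromatic/charge atom colors and bond orders).  Dummy
# atoms in the pattern are removed first; their neighbors become recorded
# attachment positions.  Returns a list of integer maps (pattern atom ->
# molecule atom, dummies excluded) with an `attachment` attribute per map.
matchSubstructure <- function(mol, pattern) {
  dumm <- which(pattern@atoms$element == "*")
  attachP <- integer()
  if (length(dumm)) {
    nb <- pattern@bonds
    attachP <- unique(c(nb$a1[nb$a2 %in% dumm], nb$a2[nb$a1 %in% dumm]))
    attachP <- setdiff(attachP, dumm)
    keep <- setdiff(seq_len(nrow(pattern@atoms)), dumm)
    remap <- integer(nrow(pattern@atoms)); remap[keep] <- seq_along(keep)
    attachP <- remap[attachP]
    pattern <- subgraphMol(pattern, keep)
  }
  pcols <- paste(pattern@atoms$element, as.integer(pattern@atoms$aromatic),
                 pattern@atoms$charge, sep = "|")
  mcols <- paste(mol@atoms$element, as.integer(mol@atoms$aromatic),
                 mol@atoms$charge, sep = "|")
  universe <- sort(unique(c(pcols, mcols)))
  auxM <- .molPatternAux(mol, match(mcols, universe))
  auxP <- .molPatternAux(pattern, match(pcols, universe))
  res <- igraph::subgraph_isomorphisms(auxP$graph, auxM$graph, method = "vf2",
                                       vertex.color1 = auxM$colors,
                                       vertex.color2 = auxP$colors)
  np <- nrow(pattern@atoms)
  maps <- lapply(res, function(m) as.integer(m)[seq_len(np)])
  # deduplicate automorphic matches covering the same atom set
  if (length(maps) > 1L) {
    keysets <- vapply(maps, function(m) paste(sort(m), collapse = ","), "")
    ordm <- order(keysets, vapply(maps, paste, "", collapse = ","))
    maps <- maps[ordm][!duplicated(keysets[ordm])]
  }
  lapply(maps, function(m) { attr(m, "attachment") <- m[attachP]; m })
}

# aux graph for VF2 with separate color namespaces for atoms and bonds
.molPatternAux <- function(mol, atomColInt) {
  n <- nrow(mol@atoms); nb <- nrow(mol@bonds)
  bcol <- if (nb) 10000L + bondColorCodes(mol) else integer()
  if (nb) {
    el <- rbind(cbind(mol@bonds$a1, n + seq_len(nb)),
                cbind(mol@bonds$a2, n + seq_len(nb)))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (igraph::vcount(g) < n + nb)
      g <- igraph::add_vertices(g, n + nb - igraph::vcount(g))
  } else {
    g <- igraph::make_empty_graph(n, directed = FALSE)
  }
  list(graph = g, colors = c(atomColInt, bcol))
}

# topological distance matrix (bond counts) between atoms
atomDistances <- function(mol, from = NULL, to = NULL) {
  g <- asIgraph(mol)
  d <- igraph::distances(g,
    v = if (is.null(from)) igraph::V(g) else from,
    to = if (is.null(to)) igraph::V(g) else to)
  d
}
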