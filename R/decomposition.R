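# Tripartite decomposition of PROTACs into warhead / linker / E3 ligand,
# linker metrics, matched-series selection and linker-degradation
# (parabolic) fits.
#
# Anchors are fragment patterns (SMILES with one "*" attachment dummy)
# for the warhead and E3-ligand roles; the linker is the complement of
# the two matched anchor sets.

#' Default anchor library
#'
#' The warhead and E3-ligand anchor patterns matching the synthetic
#' generator's building blocks.  Users analysing their own series supply
#' their own library with the same shape.
#'
#' @return data.frame with columns \code{name}, \code{role}
#'   (\code{warhead} or \code{e3_ligand}) and \code{smiles} (one \code{*}
#'   attachment point each).
#' @export
defaultAnchorLibrary <- function() {
  bl <- generateBuildingBlocks(defaultGeneratorConfig(seed = 1L))
  data.frame(
    name = c(bl$warheads$name, paste0("e3_", bl$e3$class)),
    role = c(rep("warhead", nrow(bl$warheads)),
             rep("e3_ligand", nrow(bl$e3))),
    smiles = c(bl$warheads$smiles, bl$e3$smiles))
}

#' Read / write an anchor library CSV
#'
#' @param path CSV with columns \code{name}, \code{role}, \code{smiles}.
#' @return data.frame as in [defaultAnchorLibrary()].
#' @export
readAnchorLibrary <- function(path) {
  lines <- readLines(path)
  lines <- lines[cumsum(!startsWith(lines, "#")) > 0]
  df <- utils::read.csv(text = lines, stringsAsFactors = FALSE)
  need <- c("name", "role", "smiles")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("anchor library lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!df$role %in% c("warhead", "e3_ligand"))
  if (length(bad)) stop("anchor row ", bad[1L], ": unknown role '",
                        df$role[bad[1L]], "'")
  df
}

# best match for one role: all anchor patterns of the role are tried; the
# largest match wins, then the lowest canonical atom-rank vector
.bestRoleMatch <- function(mol, anchors, role, forbidden = integer()) {
  rows <- which(anchors$role == role)
  if (!length(rows)) stop("anchor library has no pattern for role ", role)
  cand <- list()
  for (rw in rows) {
    pat <- parseSmilesCached(anchors$smiles[rw])
    if (sum(pat@atoms$element != "*") < 3L)
      stop("anchor '", anchors$name[rw], "' has fewer than 3 heavy atoms")
    for (m in matchSubstructure(mol, pat)) {
      if (any(m %in% forbidden)) next
      cand[[length(cand) + 1L]] <- list(name = anchors$name[rw], map = m)
    }
  }
  if (!length(cand)) return(NULL)
  sizes <- vapply(cand, function(x) length(x$map), 0L)
  cand <- cand[sizes == max(sizes)]
  if (length(cand) > 1L) {
    rk <- canonicalAtomOrder(mol)
    pos <- integer(nrow(mol@atoms)); pos[rk] <- seq_along(rk)
    keys <- vapply(cand, function(x)
      paste(sprintf("%06d", sort(pos[x$map])), collapse = ","), "")
    cand <- cand[order(keys)]
  }
  cand[[1L]]
}

#' Decompose a PROTAC into warhead, linker and E3 ligand
#'
#' Matches one warhead-role and one E3-role anchor pattern as disjoint
#' substructures; every remaining heavy atom is assigned to the linker.
#' When several matches exist the largest is chosen, ties broken by the
#' lowest canonical atom rank (deterministic, never an error).  Junction
#' groups such as linkage amides belong to the linker exactly when their
#' atoms are outside both anchors, i.e. on the inter-anchor path.
#'
#' @param mol a [MolGraph-class].
#' @param anchors an anchor library data.frame (see
#'   [defaultAnchorLibrary()]).
#' @return a list of class \code{TripartiteDecomposition} with integer
#'   atom-index vectors \code{warhead_atoms}, \code{linker_atoms},
#'   \code{e3_atoms}, a two-row data.frame \code{attachment_bonds}
#'   (columns \code{anchor_atom}, \code{linker_atom}, \code{role}) and the
#'   matched anchor names.
#' @export
decomposeProtac <- function(mol, anchors = defaultAnchorLibrary()) {
  stopifnot(is(mol, "MolGraph"))
  w <- .bestRoleMatch(mol, anchors, "warhead")
  if (is.null(w)) stop("NoAnchorMatch: no warhead-role anchor matches")
  e <- .bestRoleMatch(mol, anchors, "e3_ligand", forbidden = w$map)
  if (is.null(e)) {
    # maybe only overlapping matches exist: distinguish the two errors
    eAny <- .bestRoleMatch(mol, anchors, "e3_ligand")
    if (is.null(eAny)) stop("NoAnchorMatch: no e3_ligand-role anchor matches")
    # try the converse order before declaring overlap
    e2 <- eAny
    w2 <- .bestRoleMatch(mol, anchors, "warhead", forbidden = e2$map)
    if (is.null(w2))
      stop("OverlappingAnchors: warhead and e3_ligand matches always overlap")
    w <- w2; e <- e2
  }
  wa <- sort(unname(w$map)); ea <- sort(unname(e$map))
  la <- setdiff(seq_len(nrow(mol@atoms)), c(wa, ea))
  if (!length(la))
    stop("decomposition leaves no linker atoms between the anchors")
  b <- mol@bonds
  cross <- function(anchor) {
    k <- which((b$a1 %in% anchor & b$a2 %in% la) |
               (b$a2 %in% anchor & b$a1 %in% la))
    data.frame(anchor_atom = ifelse(b$a1[k] %in% anchor, b$a1[k], b$a2[k]),
               linker_atom = ifelse(b$a1[k] %in% la, b$a1[k], b$a2[k]))
  }
  cw <- cross(wa); ce <- cross(ea)
  if (nrow(cw) != 1L || nrow(ce) != 1L)
    stop("decomposition is not tripartite: ", nrow(cw),
         " warhead-linker and ", nrow(ce), " e3-linker attachment bonds")
  sub <- subgraphMol(mol, la)
  if (length(unique(moleculeComponents(sub))) != 1L)
    stop("linker atoms do not form a connected subgraph")
  out <- list(
    warhead_atoms = wa, linker_atoms = la, e3_atoms = ea,
    attachment_bonds = rbind(
      cbind(cw, role = "warhead"), cbind(ce, role = "e3_ligand")),
    warhead_name = w$name, e3_name = e$name)
  class(out) <- "TripartiteDecomposition"
  out
}

#' @export
print.TripartiteDecomposition <- function(x, ...) {
  cat("TripartiteDecomposition: warhead ", length(x$warhead_atoms),
      " atoms (", x$warhead_name, "), linker ", length(x$linker_atoms),
      " atoms, E3 ligand ", length(x$e3_atoms), " atoms (", x$e3_name,
      ")\n", sep = "")
  invisible(x)
}

#' Linker metrics
#'
#' \code{n_carbon} counts every carbon atom in the linker (ring carbons
#' included); \code{topo_length} is the number of atoms on the shortest
#' intra-linker path connecting the two attachment bonds; the class is
#' \code{alkyl} (all acyclic carbon), \code{ether} (acyclic C/O with at
#' least one oxygen), \code{rigid} (any linker atom in a ring) or
#' \code{mixed}.
#'
#' @param decomp a \code{TripartiteDecomposition}.
#' @param mol the decomposed [MolGraph-class].
#' @return a list of class \code{LinkerProfile} with \code{n_carbon},
#'   \code{topo_length}, \code{linker_class}.
#' @export
linkerMetrics <- function(decomp, mol) {
  stopifnot(inherits(decomp, "TripartiteDecomposition"), is(mol, "MolGraph"))
  la <- decomp$linker_atoms
  el <- mol@atoms$element[la]
  nC <- sum(el == "C")
  att <- decomp$attachment_bonds$linker_atom
  sub <- subgraphMol(mol, la)
  l1 <- match(att[1L], la); l2 <- match(att[2L], la)
  topo <- as.integer(atomDistances(sub, from = l1, to = l2)[1L, 1L]) + 1L
  inRing <- ringAtomFlags(mol)[la]
  cls <- if (any(inRing)) "rigid"
    else if (all(el == "C")) "alkyl"
    else if (all(el %in% c("C", "O")) && any(el == "O")) "ether"
    else "mixed"
  out <- list(n_carbon = nC, topo_length = topo, linker_class = cls)
  class(out) <- "LinkerProfile"
  out
}

#' Decomposition report for a dataset
#'
#' Runs [decomposeProtac()] and [linkerMetrics()] over a whole
#' [DegradationSet-class].
#'
#' @param set a [DegradationSet-class].
#' @param anchors anchor library.
#' @return a list with \code{decomps} (named list of decompositions) and
#'   \code{table}: data.frame (id, warhead_smiles, linker_smiles,
#'   e3_smiles, n_carbon, topo_length, linker_class).
#' @export
decomposeDataset <- function(set, anchors = defaultAnchorLibrary()) {
  mols <- moleculeList(set)
  decomps <- vector("list", length(mols)); names(decomps) <- names(mols)
  rows <- vector("list", length(mols))
  for (i in seq_along(mols)) {
    d <- decomposeProtac(mols[[i]], anchors)
    lm <- linkerMetrics(d, mols[[i]])
    decomps[[i]] <- d
    rows[[i]] <- data.frame(
      id = names(mols)[i],
      warhead_smiles = writeSmiles(subgraphMol(mols[[i]], d$warhead_atoms)),
      linker_smiles = writeSmiles(subgraphMol(mols[[i]], d$linker_atoms)),
      e3_smiles = writeSmiles(subgraphMol(mols[[i]], d$e3_atoms)),
      n_carbon = lm$n_carbon, topo_length = lm$topo_length,
      linker_class = lm$linker_class)
  }
  list(decomps = decomps, table = do.call(rbind, rows))
}

# series key: warhead fragment + its attachment atom, E3 fragment + its
# attachment atom, and linker class must all be identical
.seriesKey <- function(mol, decomp, linkerClass) {
  ab <- decomp$attachment_bonds
  wAtt <- ab$anchor_atom[ab$role == "warhead"]
  eAtt <- ab$anchor_atom[ab$role == "e3_ligand"]
  wSub <- subgraphMol(mol, decomp$warhead_atoms)
  eSub <- subgraphMol(mol, decomp$e3_atoms)
  wSig <- graphSignature(wSub, marked = match(wAtt, decomp$warhead_atoms))
  eSig <- graphSignature(eSub, marked = match(eAtt, decomp$e3_atoms))
  paste(wSig, eSig, linkerClass, sep = " $ ")
}

#' Select matched linker series
#'
#' A series is a maximal group of compounds sharing the same warhead
#' fragment (including its linkage point), the same E3-ligand fragment
#' (including its linkage point) and the same linker chemical class,
#' differing only in linker length.  Groups with fewer than 4 members are
#' discarded (3 points fit any quadratic exactly).
#'
#' @param set a [DegradationSet-class].
#' @param decomps named list of decompositions, as from
#'   [decomposeDataset()].
#' @param minSize minimum series size (default 4).
#' @return a list of data.frames (id, e3_class, linker_class, n_carbon,
#'   deg_low, deg_high), one per series; may be empty.
#' @export
selectMatchedSeries <- function(set, decomps, minSize = 4L) {
  mols <- moleculeList(set)
  stopifnot(all(compoundIds(set) %in% names(decomps)))
  r <- recordTable(set)
  keys <- character(length(mols)); nc <- integer(length(mols))
  cls <- character(length(mols))
  for (i in seq_along(mols)) {
    d <- decomps[[compoundIds(set)[i]]]
    lm <- linkerMetrics(d, mols[[i]])
    cls[i] <- lm$linker_class
    nc[i] <- lm$n_carbon
    keys[i] <- .seriesKey(mols[[i]], d, lm$linker_class)
  }
  out <- list()
  for (key in unique(keys)) {
    idx <- which(keys == key)
    if (length(idx) < minSize) next
    out[[length(out) + 1L]] <- data.frame(
      id = r$id[idx], e3_class = r$e3_class[idx], linker_class = cls[idx],
      n_carbon = nc[idx], deg_low = r$deg_low[idx], deg_high = r$deg_high[idx])
  }
  out
}

#' Fit a linker-length / degradation parabola
#'
#' Ordinary least-squares quadratic \eqn{D = c + b L + a L^2} on
#' (linker carbon count, degradation) pairs; the vertex \eqn{-b / 2a}
#' estimates the optimal linker length.  The fit is flagged degenerate
#' when the curvature is non-negative or negligibly small
#' (\eqn{|a| < 10^{-6}}).
#'
#' @param n_carbon,degradation numeric vectors (at least 4 distinct
#'   lengths).
#' @return a list of class \code{LdrFit}: \code{vertex},
#'   \code{curvature}, \code{r2}, \code{degenerate}, \code{n}.
#' @examples
#' L <- 5:11; fitLinkerParabola(L, 90 - 2 * (L - 8)^2)  # vertex 8
#' @export
fitLinkerParabola <- function(n_carbon, degradation) {
  stopifnot(length(n_carbon) == length(degradation))
  if (length(unique(n_carbon)) < 4L)
    stop("parabola fit requires at least 4 distinct linker lengths")
  fit <- stats::lm(degradation ~ n_carbon + I(n_carbon^2))
  cf <- stats::coef(fit)
  a <- unname(cf[3L]); bcoef <- unname(cf[2L])
  degen <- is.na(a) || a >= 0 || abs(a) < 1e-6
  out <- list(
    vertex = if (degen) NA_real_ else -bcoef / (2 * a),
    curvature = a,
    r2 = suppressWarnings(summary(fit)$r.squared),
    degenerate = degen,
    n = length(n_carbon))
  class(out) <- "LdrFit"
  out
}

#' @export
print.LdrFit <- function(x, ...) {
  if (x$degenerate) {
    cat("LdrFit (degenerate): curvature ", signif(x$curvature, 3),
        ", r2 ", round(x$r2, 3), ", n = ", x$n, "\n", sep = "")
  } else {
    cat("LdrFit: optimum at ", round(x$vertex, 2), " linker carbons ",
        "(curvature ", signif(x$curvature, 3), ", r2 ", round(x$r2, 3),
        ", n = ", x$n, ")\n", sep = "")
  }
  invisible(x)
}

#' Linker-degradation analysis over a dataset
#'
#' Selects matched series and fits the parabola per series.
#'
#' @param set a [DegradationSet-class].
#' @param decomps decompositions from [decomposeDataset()].
#' @param concentration which readout to analyse.
#' @param minSize minimum series size.
#' @return data.frame with one row per series: e3_class, linker_class, n,
#'   n_lengths, vertex, curvature, r2, degenerate.
#' @export
ldrAnalysis <- function(set, decomps, concentration = c("low", "high"),
                        minSize = 4L) {
  concentration <- match.arg(concentration)
  series <- selectMatchedSeries(set, decomps, minSize = minSize)
  rows <- lapply(series, function(s) {
    y <- if (concentration == "low") s$deg_low else s$deg_high
    nlen <- length(unique(s$n_carbon))
    if (nlen < 4L) {
      return(data.frame(e3_class = s$e3_class[1L],
                        linker_class = s$linker_class[1L], n = nrow(s),
                        n_lengths = nlen, vertex = NA_real_,
                        curvature = NA_real_, r2 = NA_real_,
                        degenerate = TRUE))
    }
    f <- fitLinkerParabola(s$n_carbon, y)
    data.frame(e3_class = s$e3_class[1L], linker_class = s$linker_class[1L],
               n = nrow(s), n_lengths = nlen, vertex = f$vertex,
               curvature = f$curvature, r2 = f$r2, degenerate = f$degenerate)
  })
  if (!length(rows))
    return(data.frame(e3_class = character(), linker_class = character(),
                      n = integer(), n_lengths = integer(),
                      vertex = numeric(), curvature = numeric(),
                      r2 = numeric(), degenerate = logical()))
  do.call(rbind, rows)
}
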