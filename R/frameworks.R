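# Bemis-Murcko frameworks and sphere fingerprints.
#
# The scaffold keeps every ring system plus the direct inter-ring
# connections (atom labels and stereo tags retained); the skeleton is the
# scaffold with atom labels and bond orders erased, i.e. pure topology.

#' Bemis-Murcko scaffold
#'
#' Iteratively prunes terminal side-chain atoms until only ring systems
#' and the linker atoms directly connecting them remain.  Exocyclic atoms
#' attached by a double bond to a retained atom (e.g. a carbonyl oxygen on
#' a retained carbon) are kept, following the common Bemis-Murcko
#' convention.  An acyclic molecule yields an empty scaffold.
#'
#' @param mol a [MolGraph-class].
#' @return a [MolGraph-class] with the scaffold (0 atoms when the molecule
#'   is acyclic), with attribute \code{"atomIndices"} giving the retained
#'   atom indices of the input.
#' @examples
#' writeSmiles(murckoScaffold(parseSmiles("CCc1ccccc1")))  # benzene
#' @export
murckoScaffold <- function(mol) {
  stopifnot(is(mol, "MolGraph"))
  n <- nrow(mol@atoms)
  keep <- rep(TRUE, n)
  deg <- integer(n)
  b <- mol@bonds
  repeat {
    deg[] <- 0L
    act <- b$a1[keep[b$a1] & keep[b$a2]]
    act2 <- b$a2[keep[b$a1] & keep[b$a2]]
    for (v in act) deg[v] <- deg[v] + 1L
    for (v in act2) deg[v] <- deg[v] + 1L
    inRing <- logical(n)
    rb <- b[b$ring, , drop = FALSE]
    inRing[unique(c(rb$a1, rb$a2))] <- TRUE
    prunable <- which(keep & deg <= 1L & !inRing)
    if (!length(prunable)) break
    keep[prunable] <- FALSE
  }
  core <- which(keep)
  if (!length(core)) {
    empty <- new("MolGraph",
                 atoms = mol@atoms[0, , drop = FALSE],
                 bonds = mol@bonds[0, , drop = FALSE],
                 smiles = NA_character_)
    attr(empty, "atomIndices") <- integer()
    return(empty)
  }
  # retain exocyclic double-bonded atoms on the core
  dbl <- b[b$order == 2L & !b$aromatic, , drop = FALSE]
  extra <- unique(c(dbl$a2[keep[dbl$a1] & !keep[dbl$a2]],
                    dbl$a1[keep[dbl$a2] & !keep[dbl$a1]]))
  core <- sort(unique(c(core, extra)))
  out <- subgraphMol(mol, core)
  # broken exocyclic bonds become implicit hydrogens, so the scaffold is a
  # valid molecule (ethylbenzene -> benzene, not a benzene radical)
  oldDeg <- .atomDegrees(mol)[core]
  newDeg <- .atomDegrees(out)
  out@atoms$nH <- out@atoms$nH + pmax(oldDeg - newDeg, 0L)
  attr(out, "atomIndices") <- core
  out
}

#' Bemis-Murcko skeleton
#'
#' The scaffold with all atom labels erased (every atom becomes a
#' carbon-equivalent node) and all bond orders erased (single-equivalent),
#' so only the graph topology of the framework remains.
#'
#' @param mol a [MolGraph-class].
#' @return a [MolGraph-class]; compare skeletons with
#'   [skeletonSignature()] or \code{graphSignature(x, skeleton = TRUE)}.
#' @export
murckoSkeleton <- function(mol) {
  sc <- murckoScaffold(mol)
  a <- sc@atoms
  if (nrow(a)) {
    a$element <- "C"; a$aromatic <- FALSE; a$charge <- 0L
    a$nH <- 0L; a$stereo <- ""
  }
  b <- sc@bonds
  if (nrow(b)) { b$order <- 1L; b$aromatic <- FALSE }
  out <- new("MolGraph", atoms = a, bonds = b, smiles = NA_character_)
  attr(out, "atomIndices") <- attr(sc, "atomIndices")
  out
}

#' Canonical scaffold / skeleton strings
#'
#' Convenience wrappers: canonical identity strings for the Murcko
#' scaffold (labels kept) and skeleton (labels erased) of a molecule.
#' The empty scaffold yields \code{""}.
#'
#' @param mol a [MolGraph-class].
#' @return a character scalar.
#' @export
scaffoldSignature <- function(mol) {
  sc <- murckoScaffold(mol)
  if (nrow(sc@atoms) == 0L) return("")
  graphSignature(sc)
}

#' @rdname scaffoldSignature
#' @export
skeletonSignature <- function(mol) {
  sk <- murckoSkeleton(mol)
  if (nrow(sk@atoms) == 0L) return("")
  graphSignature(sk, skeleton = TRUE)
}

# --- hashed sphere fingerprints ------------------------------------------

# deterministic polynomial string hash modulo a Mersenne prime; pure R,
# exact in double arithmetic, platform independent
.HASH_P <- 2147483647
.hashPowers <- local({
  pows <- numeric(512)
  pows[1] <- 1
  for (i in 2:512) pows[i] <- (pows[i - 1] * 131) %% 2147483647
  pows
})
hashString <- function(s) {
  ints <- utf8ToInt(s)
  np <- length(ints)
  if (np > length(.hashPowers)) {
    ints <- ints[seq_len(length(.hashPowers))]
    np <- length(ints)
  }
  sum(ints * .hashPowers[seq_len(np)]) %% .HASH_P
}

# iterative sphere identifiers (Morgan-style): id_r(atom) encodes the
# canonical content of the atom's r-neighborhood.  Sorting the neighbor
# contributions makes the identifier independent of atom numbering.
.sphereIds <- function(mol, radius, skeleton = FALSE) {
  n <- nrow(mol@atoms)
  b <- mol@bonds
  nbIdx <- vector("list", n)   # neighbor atom indices
  nbCode <- vector("list", n)  # bond codes to those neighbors
  bcode <- if (skeleton) rep("1", nrow(b)) else
    ifelse(b$aromatic, "a", as.character(b$order))
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    nbIdx[[b$a1[k]]] <- c(nbIdx[[b$a1[k]]], b$a2[k])
    nbIdx[[b$a2[k]]] <- c(nbIdx[[b$a2[k]]], b$a1[k])
    nbCode[[b$a1[k]]] <- c(nbCode[[b$a1[k]]], bcode[k])
    nbCode[[b$a2[k]]] <- c(nbCode[[b$a2[k]]], bcode[k])
  }
  a <- mol@atoms
  deg <- lengths(nbIdx)
  init <- if (skeleton) paste0("S|", deg)
          else paste("L", a$element, a$charge, as.integer(a$aromatic),
                     a$nH, deg, sep = "|")
  ids <- matrix(0, nrow = n, ncol = radius + 1L)
  cur <- vapply(init, hashString, 0, USE.NAMES = FALSE)
  ids[, 1L] <- cur
  if (radius > 0L) for (r in seq_len(radius)) {
    nxt <- numeric(n)
    for (v in seq_len(n)) {
      if (deg[v]) {
        parts <- sort(paste0(nbCode[[v]], ":", cur[nbIdx[[v]]]))
        nxt[v] <- hashString(paste0(r, "|", cur[v], "|",
                                    paste(parts, collapse = ",")))
      } else {
        nxt[v] <- hashString(paste0(r, "|", cur[v]))
      }
    }
    cur <- nxt
    ids[, r + 1L] <- cur
  }
  ids
}

# fingerprint count vector for one molecule
.sphereCounts <- function(mol, radius, nbits) {
  idsL <- .sphereIds(mol, radius, skeleton = FALSE)
  idsS <- .sphereIds(mol, radius, skeleton = TRUE)
  bins <- c(idsL, idsS) %% nbits
  counts <- tabulate(bins + 1L, nbins = nbits)
  as.integer(counts)
}

#' Sphere fingerprints
#'
#' Hashed count fingerprints over circular atom environments: for every
#' atom and every radius r in 0..\code{radius}, the canonical identifier
#' of the atom's r-sphere is hashed into a fixed-length count vector twice
#' -- once with atom labels and bond orders ("labeled"), once with both
#' erased ("skeleton-abstracted").  The dual hashing makes the descriptor
#' partially tolerant to heteroatom substitutions, in the spirit of
#' framework-aware fingerprints used for similarity analysis of large
#' molecules; it is a documented in-package stand-in, not a reimplementation
#' of any proprietary descriptor.
#'
#' @param mols a list of [MolGraph-class] objects (or a single one).
#' @param radius maximum sphere radius (default 5).
#' @param nbits count-vector length (default 1024).
#' @return a [SphereFingerprintSet-class].
#' @examples
#' fps <- sphereFingerprints(lapply(c("CCO", "COC"), parseSmiles))
#' tanimoto(fps)[1, 2] < 1
#' @export
sphereFingerprints <- function(mols, radius = 5L, nbits = 1024L) {
  if (is(mols, "MolGraph")) mols <- list(mols)
  stopifnot(length(mols) >= 1L, radius >= 0L, nbits >= 2L)
  counts <- t(vapply(mols, .sphereCounts, integer(nbits),
                     radius = as.integer(radius), nbits = as.integer(nbits)))
  rownames(counts) <- names(mols)
  new("SphereFingerprintSet", counts = counts,
      radius = as.integer(radius), nbits = as.integer(nbits))
}

#' Count Tanimoto similarity
#'
#' For count vectors a and b the similarity is
#' \eqn{\sum_i \min(a_i, b_i) / \sum_i \max(a_i, b_i)}; for 0/1 vectors
#' this reduces to the classical set Tanimoto |A n B| / |A u B|.  Two
#' all-zero vectors have similarity 0 by convention.
#'
#' @param x a [SphereFingerprintSet-class], or a numeric count vector.
#' @param y optional second fingerprint set or count vector.
#' @return with two vectors, a scalar; with fingerprint sets, the full
#'   similarity matrix between rows of \code{x} and rows of \code{y}
#'   (default \code{y = x}).
#' @export
tanimoto <- function(x, y = NULL) {
  if (is.numeric(x)) {
    stopifnot(is.numeric(y), length(x) == length(y))
    tot <- sum(pmax(x, y))
    if (tot == 0) return(0)
    return(sum(pmin(x, y)) / tot)
  }
  stopifnot(is(x, "SphereFingerprintSet"))
  if (is.null(y)) y <- x
  stopifnot(is(y, "SphereFingerprintSet"), x@nbits == y@nbits)
  cx <- x@counts; cy <- y@counts
  nx <- nrow(cx); ny <- nrow(cy)
  out <- matrix(0, nx, ny, dimnames = list(rownames(cx), rownames(cy)))
  sx <- rowSums(cx); sy <- rowSums(cy)
  for (i in seq_len(nx)) {
    mins <- colSums(pmin(t(cy), cx[i, ]))
    maxs <- sx[i] + sy - mins
    out[i, ] <- ifelse(maxs == 0, 0, mins / maxs)
  }
  out
}
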