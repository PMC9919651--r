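# SMILES parsing and writing for hydrogen-suppressed molecular graphs.
# Supported dialect: organic subset + brackets (charge, explicit H, @/@@),
# aromatic lowercase atoms, bonds - = # : / \, branches, ring closures
# (1-9 and %nn), dot-disconnection, and the dummy atom "*" used as an
# attachment point.  Isotopes and atom maps are accepted and ignored;
# tetrahedral/cis-trans stereo tags are recorded but do not affect graph
# identity.

.ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")
.DEFAULT_VALENCE <- list(B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
                         Cl = 1L, Br = 1L, I = 1L,
                         P = c(3L, 5L), S = c(2L, 4L, 6L))

# default implicit hydrogen count for an uncharged organic-subset atom,
# given the sum of its bond orders (aromatic bonds counted as 1) and its
# aromatic flag; returns NA when no default applies
.implicitH <- function(element, aromatic, bondsum) {
  val <- .DEFAULT_VALENCE[[element]]
  if (is.null(val)) return(NA_integer_)
  # aromatic C and N hold one pi bond not visible in the bond-order sum
  adj <- if (aromatic && element %in% c("C", "N")) 1L else 0L
  val <- val[val >= bondsum + adj]
  if (!length(val)) return(0L)
  max(val[1L] - bondsum - adj, 0L)
}

# memoized parsing for strings that recur (building blocks, anchors)
.parseCache <- new.env(parent = emptyenv())
parseSmilesCached <- function(smiles) {
  hit <- get0(smiles, envir = .parseCache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  mol <- parseSmiles(smiles)
  if (length(ls(.parseCache)) < 512L) assign(smiles, mol, envir = .parseCache)
  mol
}

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles a single SMILES string.
#' @return a [MolGraph-class] object.
#' @examples
#' mol <- parseSmiles("N#Cc1ccc(cc1)C1CCN(C)CC1")
#' mol
#' @export
parseSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  s <- trimws(smiles)
  if (!nzchar(s)) stop("empty SMILES string")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)

  element <- character(); aromatic <- logical(); charge <- integer()
  explH <- integer(); stereo <- character()
  b_a1 <- integer(); b_a2 <- integer(); b_sym <- character()

  prev <- NA_integer_          # atom to bond the next atom to
  stack <- integer()           # branch stack
  pending <- ""                # pending bond symbol
  ring <- list()               # open ring closures: label -> c(atom, sym)

  addAtom <- function(el, arom, chg, h, st) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    explH[length(explH) + 1L] <<- h
    stereo[length(stereo) + 1L] <<- st
    idx <- length(element)
    if (!is.na(prev)) {
      b_a1[length(b_a1) + 1L] <<- prev
      b_a2[length(b_a2) + 1L] <<- idx
      b_sym[length(b_sym) + 1L] <<- pending
    }
    pending <<- ""
    prev <<- idx
    idx
  }

  closeRing <- function(lab) {
    if (is.na(prev)) stop("ring closure before any atom in SMILES: ", smiles)
    if (is.null(ring[[lab]])) {
      ring[[lab]] <<- list(atom = prev, sym = pending)
    } else {
      op <- ring[[lab]]
      sym <- if (nzchar(pending)) pending else op$sym
      if (nzchar(op$sym) && nzchar(pending) && op$sym != pending)
        stop("conflicting ring-closure bond symbols in SMILES: ", smiles)
      b_a1[length(b_a1) + 1L] <<- op$atom
      b_a2[length(b_a2) + 1L] <<- prev
      b_sym[length(b_sym) + 1L] <<- sym
      ring[[lab]] <<- NULL
    }
    pending <<- ""
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- if (ch %in% c("/", "\\")) "-" else ch
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch opened before any atom in SMILES: ", smiles)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- ""; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      closeRing(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring closure in SMILES: ", smiles)
      closeRing(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else if (ch == "*") {
      addAtom("*", FALSE, 0L, 0L, ""); i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced '[' in SMILES: ", smiles)
      tok <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(tok, regexec(
        "^([0-9]*)(\\*|[A-Z][a-z]?|[a-z]{1,2})(@{1,2})?(H[0-9]*)?([+-]+[0-9]*)?(:[0-9]+)?$",
        tok))[[1L]]
      if (!length(m)) stop("cannot parse bracket atom [", tok, "] in SMILES: ", smiles)
      el <- m[3L]
      arom <- grepl("^[a-z]", el)
      if (arom) {
        if (!el %in% .AROMATIC_OK) stop("invalid aromatic element [", tok, "]")
        el <- paste0(toupper(substr(el, 1L, 1L)), substring(el, 2L))
      }
      if (!el %in% c("*", "H", names(.ATOMIC_MASS)))
        stop("unsupported element in bracket atom [", tok, "]")
      st <- if (is.na(m[4L])) "" else m[4L]
      h <- 0L
      if (!is.na(m[5L]) && nzchar(m[5L])) {
        h <- if (m[5L] == "H") 1L else as.integer(substring(m[5L], 2L))
      }
      chg <- 0L
      if (!is.na(m[6L]) && nzchar(m[6L])) {
        cs <- m[6L]
        sign <- if (substr(cs, 1L, 1L) == "+") 1L else -1L
        digs <- gsub("[+-]", "", cs)
        chg <- if (nzchar(digs)) sign * as.integer(digs)
               else sign * nchar(gsub("[^+-]", "", cs))
      }
      addAtom(el, arom, chg, h, st)
      i <- j + 1L
    } else if (grepl("[A-Za-z]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        addAtom(two, FALSE, 0L, NA_integer_, ""); i <- i + 2L
      } else if (ch %in% .ORGANIC) {
        addAtom(ch, FALSE, 0L, NA_integer_, ""); i <- i + 1L
      } else if (ch %in% .AROMATIC_OK) {
        addAtom(toupper(ch), TRUE, 0L, NA_integer_, ""); i <- i + 1L
      } else stop("unexpected character '", ch, "' in SMILES: ", smiles)
    } else if (ch == " ") {
      break  # title field
    } else stop("unexpected character '", ch, "' in SMILES: ", smiles)
  }
  if (length(stack)) stop("unbalanced '(' in SMILES: ", smiles)
  if (length(ring)) stop("unclosed ring bond in SMILES: ", smiles)

  natoms <- length(element)
  if (natoms == 0L) stop("SMILES contains no atoms: ", smiles)

  # resolve bond orders: explicit symbol wins; otherwise aromatic when both
  # endpoints are aromatic, else single
  nb <- length(b_a1)
  order <- integer(nb); barom <- logical(nb)
  for (k in seq_len(nb)) {
    sym <- b_sym[k]
    if (sym == "=") { order[k] <- 2L
    } else if (sym == "#") { order[k] <- 3L
    } else if (sym == ":") { order[k] <- 1L; barom[k] <- TRUE
    } else if (sym == "-") { order[k] <- 1L
    } else {
      order[k] <- 1L
      barom[k] <- aromatic[b_a1[k]] && aromatic[b_a2[k]]
    }
  }

  atoms <- data.frame(element = element, aromatic = aromatic,
                      charge = charge, nH = explH, stereo = stereo,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = b_a1, a2 = b_a2, order = order,
                      aromatic = barom, ring = logical(nb))
  newMolGraph(atoms, bonds, smiles = smiles)
}

# construct a MolGraph: fills implicit hydrogens where NA, perceives ring
# membership, and validates
newMolGraph <- function(atoms, bonds, smiles = NA_character_) {
  natoms <- nrow(atoms)
  bondsum <- integer(natoms)
  if (nrow(bonds)) {
    ord <- ifelse(bonds$aromatic, 1L, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      bondsum[bonds$a1[k]] <- bondsum[bonds$a1[k]] + ord[k]
      bondsum[bonds$a2[k]] <- bondsum[bonds$a2[k]] + ord[k]
    }
  }
  fill <- which(is.na(atoms$nH))
  for (a in fill) {
    if (atoms$element[a] == "*" || atoms$charge[a] != 0L) {
      atoms$nH[a] <- 0L
    } else {
      h <- .implicitH(atoms$element[a], atoms$aromatic[a], bondsum[a])
      atoms$nH[a] <- if (is.na(h)) 0L else h
    }
  }
  atoms$nH <- as.integer(atoms$nH)
  bonds$ring <- ringBondFlags(natoms, bonds)
  mol <- new("MolGraph", atoms = atoms, bonds = bonds,
             smiles = as.character(smiles))
  validObject(mol)
  mol
}

#' Write a molecular graph as a SMILES string
#'
#' Emits a deterministic SMILES; with \code{canonical = TRUE} (default) the
#' atom ordering comes from an exact canonical labeling of the colored
#' graph, so isomorphic graphs yield byte-identical strings.  Stereo tags
#' are not emitted (the canonical form is two-dimensional).
#'
#' @param mol a [MolGraph-class].
#' @param canonical use the canonical atom order.
#' @return a SMILES string.
#' @examples
#' writeSmiles(parseSmiles("OCC"))
#' @export
writeSmiles <- function(mol, canonical = TRUE) {
  stopifnot(is(mol, "MolGraph"))
  a <- mol@atoms; b <- mol@bonds
  natoms <- nrow(a)
  ordr <- if (canonical) canonicalAtomOrder(mol) else seq_len(natoms)
  pos <- integer(natoms); pos[ordr] <- seq_len(natoms)  # rank of each atom

  adj <- vector("list", natoms)
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], k)
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], k)
  }
  other <- function(k, at) if (b$a1[k] == at) b$a2[k] else b$a1[k]

  bondToken <- function(k) {
    if (b$aromatic[k]) return("")
    if (b$order[k] == 2L) return("=")
    if (b$order[k] == 3L) return("#")
    if (a$aromatic[b$a1[k]] && a$aromatic[b$a2[k]]) return("-")
    ""
  }
  atomToken <- function(at) {
    el <- a$element[at]
    if (el == "*") return("*")
    arom <- a$aromatic[at]
    sym <- if (arom) tolower(el) else el
    bondsum <- sum(ifelse(b$aromatic[adj[[at]]], 1L, b$order[adj[[at]]]))
    plain <- el %in% .ORGANIC && (!arom || tolower(el) %in% .AROMATIC_OK) &&
      a$charge[at] == 0L &&
      identical(.implicitH(el, arom, bondsum), a$nH[at])
    if (plain) return(sym)
    h <- a$nH[at]
    htok <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    chg <- a$charge[at]
    ctok <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
            else sprintf("%+d", chg)
    paste0("[", sym, htok, ctok, "]")
  }

  # pass 1: DFS (children in canonical rank order) to classify bonds into
  # tree bonds and ring closures
  visited <- logical(natoms)
  parentBond <- rep(NA_integer_, natoms)
  childBonds <- vector("list", natoms)
  closureB <- logical(max(nrow(b), 1L))
  isTree <- logical(max(nrow(b), 1L))
  othv <- function(ks, at) vapply(ks, other, 0L, at = at)
  dfs <- function(at) {
    visited[at] <<- TRUE
    ks <- adj[[at]]
    if (!is.na(parentBond[at])) ks <- ks[ks != parentBond[at]]
    if (length(ks)) ks <- ks[order(pos[othv(ks, at)])]
    for (k in ks) {
      o <- other(k, at)
      if (visited[o]) {
        if (!isTree[k]) closureB[k] <<- TRUE
      } else {
        isTree[k] <<- TRUE
        parentBond[o] <<- k
        childBonds[[at]] <<- c(childBonds[[at]], k)
        dfs(o)
      }
    }
  }
  roots <- integer()
  for (root in ordr) if (!visited[root]) { roots <- c(roots, root); dfs(root) }

  # pass 2: emit; ring-closure digits appear at both endpoints
  ringLab <- integer(max(nrow(b), 1L))
  nextNum <- 0L
  fmtnum <- function(x) if (x > 9L) paste0("%", x) else as.character(x)
  emit <- function(at) {
    out <- atomToken(at)
    ks <- adj[[at]]
    cl <- ks[closureB[ks]]
    if (length(cl)) cl <- cl[order(pos[othv(cl, at)])]
    for (k in cl) {
      if (ringLab[k] == 0L) {
        nextNum <<- nextNum + 1L
        ringLab[k] <<- nextNum
        out <- paste0(out, bondToken(k), fmtnum(nextNum))
      } else {
        out <- paste0(out, fmtnum(ringLab[k]))
      }
    }
    ch <- childBonds[[at]]
    for (idx in seq_along(ch)) {
      k <- ch[idx]
      frag <- paste0(bondToken(k), emit(other(k, at)))
      if (idx < length(ch)) frag <- paste0("(", frag, ")")
      out <- paste0(out, frag)
    }
    out
  }
  paste(vapply(roots, emit, ""), collapse = ".")
}

#' Molecular formula
#'
#' Hill-ordered formula of a molecular graph, implicit hydrogens included;
#' dummy atoms are ignored.
#'
#' @param mol a [MolGraph-class].
#' @return a character scalar, e.g. \code{"C6H6"}.
#' @export
molecularFormula <- function(mol) {
  a <- mol@atoms
  counts <- table(a$element[a$element != "*"])
  h <- sum(a$nH)
  els <- sort(names(counts))
  els <- c(intersect("C", els), if (h > 0) "H", setdiff(els, c("C", "H")))
  paste0(vapply(els, function(e) {
    k <- if (e == "H") h else counts[[e]]
    paste0(e, if (k > 1) k else "")
  }, ""), collapse = "")
}
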