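# Seven permeability-related 2D descriptors: MW, nC, nAR, nHAcc, nHDon,
# TPSA (Ertl fragment contributions, N/O variant) and Kier's flexibility
# index PHI.  log P is deliberately not offered: current calculators are
# unreliable for beyond-rule-of-five molecules such as PROTACs.

.ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, P = 30.974, S = 32.06, Cl = 35.45,
                  Br = 79.904, I = 126.904)

# Kier alpha contributions: covalent radius relative to sp3 carbon minus 1,
# keyed by element and hybridisation (sp3/sp2/sp).
.KIER_ALPHA <- list(
  C  = c(sp3 = 0.00,  sp2 = -0.13, sp = -0.22),
  N  = c(sp3 = -0.04, sp2 = -0.20, sp = -0.29),
  O  = c(sp3 = -0.04, sp2 = -0.20, sp = -0.20),
  F  = c(sp3 = -0.07, sp2 = -0.07, sp = -0.07),
  Cl = c(sp3 = 0.29,  sp2 = 0.29,  sp = 0.29),
  Br = c(sp3 = 0.48,  sp2 = 0.48,  sp = 0.48),
  I  = c(sp3 = 0.73,  sp2 = 0.73,  sp = 0.73),
  P  = c(sp3 = 0.43,  sp2 = 0.43,  sp = 0.43),
  S  = c(sp3 = 0.35,  sp2 = 0.22,  sp = 0.22)
)

# per-atom hybridisation from bond orders: sp when a triple bond or two
# double bonds, sp2 when aromatic or any double bond, else sp3
.hybridisation <- function(mol) {
  n <- nrow(mol@atoms)
  ndbl <- integer(n); ntrp <- integer(n)
  b <- mol@bonds
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    if (b$aromatic[k]) next
    if (b$order[k] == 2L) {
      ndbl[b$a1[k]] <- ndbl[b$a1[k]] + 1L
      ndbl[b$a2[k]] <- ndbl[b$a2[k]] + 1L
    } else if (b$order[k] == 3L) {
      ntrp[b$a1[k]] <- ntrp[b$a1[k]] + 1L
      ntrp[b$a2[k]] <- ntrp[b$a2[k]] + 1L
    }
  }
  hyb <- rep("sp3", n)
  hyb[mol@atoms$aromatic | ndbl >= 1L] <- "sp2"
  hyb[ntrp >= 1L | ndbl >= 2L] <- "sp"
  hyb
}

.atomDegrees <- function(mol) {
  n <- nrow(mol@atoms)
  deg <- integer(n)
  b <- mol@bonds
  if (nrow(b)) {
    t1 <- table(factor(b$a1, levels = seq_len(n)))
    t2 <- table(factor(b$a2, levels = seq_len(n)))
    deg <- as.integer(t1 + t2)
  }
  deg
}

#' Topological polar surface area (Ertl, N/O variant)
#'
#' Sum of published fragment contributions over nitrogen and oxygen
#' environments (the classical N/O-only TPSA; sulfur and phosphorus
#' contribute 0).  Environments are classified by element, aromaticity,
#' charge, hydrogen count, degree, bond-order pattern and 3-ring
#' membership; an unrecognised polar environment falls back to the closest
#' generic contribution of the same element/charge/H-count class.
#'
#' @param mol a [MolGraph-class].
#' @return TPSA in square Angstroms.
#' @examples
#' tpsa(parseSmiles("CCO"))           # 20.23
#' tpsa(parseSmiles("NC(=O)c1ccccc1")) # 43.09
#' @export
tpsa <- function(mol) {
  stopifnot(is(mol, "MolGraph"))
  a <- mol@atoms
  b <- mol@bonds
  deg <- .atomDegrees(mol)
  n <- nrow(a)
  # per-atom bond-order multiset (aromatic as "a"), and 3-ring flag
  bnd <- vector("list", n)
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    code <- if (b$aromatic[k]) "a" else as.character(b$order[k])
    bnd[[b$a1[k]]] <- c(bnd[[b$a1[k]]], code)
    bnd[[b$a2[k]]] <- c(bnd[[b$a2[k]]], code)
  }
  ring3 <- logical(n)
  for (cyc in smallestRings(mol)) if (length(cyc) == 3L) ring3[cyc] <- TRUE

  total <- 0
  for (v in seq_len(n)) {
    el <- a$element[v]
    if (!el %in% c("N", "O")) next
    h <- a$nH[v]; chg <- a$charge[v]; ar <- a$aromatic[v]
    bb <- sort(bnd[[v]])
    pat <- paste(bb, collapse = "")
    contrib <- if (el == "N" && chg == 0L && !ar) {
      if (h == 0L && pat == "111") { if (ring3[v]) 3.01 else 3.24 }
      else if (h == 0L && pat == "12") 12.36
      else if (h == 0L && pat == "3") 23.79
      else if (h == 0L && pat == "122") 11.68
      else if (h == 0L && pat == "23") 13.60
      else if (h == 1L && pat == "11") { if (ring3[v]) 21.94 else 12.03 }
      else if (h == 1L && pat == "2") 23.85
      else if (h == 2L && pat == "1") 26.02
      else c(3.24, 12.03, 26.02, 26.02)[min(h, 3L) + 1L]
    } else if (el == "N" && chg == 1L && !ar) {
      if (h == 0L && pat == "1111") 0.00
      else if (h == 0L && pat == "112") 3.01
      else if (h == 0L && pat == "13") 4.36
      else if (h == 1L && pat == "111") 4.44
      else if (h == 1L && pat == "12") 13.97
      else if (h == 2L && pat == "11") 16.61
      else if (h == 2L && pat == "2") 25.59
      else if (h == 3L && pat == "1") 27.64
      else c(0.00, 4.44, 16.61, 27.64)[min(h, 3L) + 1L]
    } else if (el == "N" && ar) {
      if (chg == 1L) {
        if (h == 1L) 14.14 else if (deg[v] == 3L) 3.88 else 4.10
      } else if (h >= 1L) 15.79
      else if (deg[v] == 3L && pat == "aaa") 4.41
      else if (deg[v] == 3L) 4.93
      else if (deg[v] == 3L && any(bnd[[v]] == "2")) 8.39
      else 12.89
    } else if (el == "O" && chg == 0L && !ar) {
      if (h == 0L && pat == "11") { if (ring3[v]) 12.53 else 9.23 }
      else if (h == 0L && pat == "2") 17.07
      else if (h == 1L) 20.23
      else if (h == 0L) 9.23 else 20.23
    } else if (el == "O" && chg == -1L) {
      23.06
    } else if (el == "O" && ar) {
      13.14
    } else 0
    total <- total + contrib
  }
  round(total, 2)
}

#' Kier molecular flexibility index (PHI)
#'
#' \deqn{\Phi = \kappa_1^\alpha \kappa_2^\alpha / A} with the
#' alpha-modified kappa shape indices
#' \deqn{\kappa_1^\alpha = (A+\alpha)(A+\alpha-1)^2 / (P_1+\alpha)^2}
#' \deqn{\kappa_2^\alpha = (A+\alpha-1)(A+\alpha-2)^2 / (P_2+\alpha)^2}
#' where A is the heavy-atom count, P1 the bond count, P2 the number of
#' paths of length 2, and alpha the sum of covalent-radius contributions
#' relative to sp3 carbon.  For an unbranched alkane of A atoms PHI equals
#' A - 1 exactly.
#'
#' @param mol a [MolGraph-class] with at least 3 heavy atoms.
#' @return the dimensionless flexibility index.
#' @examples
#' kierPhi(parseSmiles("CCCCCC"))  # 5
#' @export
kierPhi <- function(mol) {
  stopifnot(is(mol, "MolGraph"))
  A <- nrow(mol@atoms)
  if (A < 3L) stop("Kier PHI requires at least 3 heavy atoms")
  P1 <- nrow(mol@bonds)
  deg <- .atomDegrees(mol)
  P2 <- sum(choose(deg, 2))
  hyb <- .hybridisation(mol)
  alpha <- 0
  for (v in seq_len(A)) {
    tab <- .KIER_ALPHA[[mol@atoms$element[v]]]
    if (!is.null(tab)) alpha <- alpha + tab[[hyb[v]]]
  }
  k1 <- (A + alpha) * (A + alpha - 1)^2 / (P1 + alpha)^2
  k2 <- (A + alpha - 1) * (A + alpha - 2)^2 / (P2 + alpha)^2
  k1 * k2 / A
}

# pyrrole-type aromatic nitrogen: contributes its lone pair to the ring
# (bears H or a third substituent), hence not counted as an acceptor
.pyrroleTypeN <- function(mol) {
  deg <- .atomDegrees(mol)
  mol@atoms$element == "N" & mol@atoms$aromatic &
    (mol@atoms$nH >= 1L | deg >= 3L)
}

# amide nitrogen: single-bonded to a carbon carrying a double bond to O
.amideN <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  carbonylC <- rep(FALSE, nrow(a))
  if (nrow(b)) {
    co <- b$order == 2L & !b$aromatic &
      ((a$element[b$a1] == "C" & a$element[b$a2] == "O") |
       (a$element[b$a2] == "C" & a$element[b$a1] == "O"))
    carbonylC[b$a1[co & a$element[b$a1] == "C"]] <- TRUE
    carbonylC[b$a2[co & a$element[b$a2] == "C"]] <- TRUE
  }
  res <- rep(FALSE, nrow(a))
  if (nrow(b)) for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1L || b$aromatic[k]) next
    if (a$element[b$a1[k]] == "N" && carbonylC[b$a2[k]]) res[b$a1[k]] <- TRUE
    if (a$element[b$a2[k]] == "N" && carbonylC[b$a1[k]]) res[b$a2[k]] <- TRUE
  }
  res
}

#' Compute the seven 2D descriptors
#'
#' Molecular weight (average atomic masses, implicit hydrogens included),
#' carbon count nC, aromatic-ring count nAR, hydrogen-bond acceptor and
#' donor atom counts nHAcc / nHDon, Ertl TPSA and Kier flexibility PHI.
#' Counting rules (frozen): nHDon = N/O atoms bearing at least one
#' hydrogen; nHAcc = N/O atoms excluding pyrrole-type aromatic nitrogens
#' and amide nitrogens; fluorine is not counted as an acceptor.
#'
#' @param mol a [MolGraph-class], or a list of them.
#' @return a one-row data.frame (or a row-bound data.frame for a list)
#'   with columns \code{MW, nC, nAR, nHAcc, nHDon, TPSA, PHI}.
#' @examples
#' computeDescriptors(parseSmiles("c1ccccc1"))
#' @export
computeDescriptors <- function(mol) {
  if (is.list(mol)) {
    out <- do.call(rbind, lapply(mol, computeDescriptors))
    rownames(out) <- names(mol)
    return(out)
  }
  stopifnot(is(mol, "MolGraph"))
  a <- mol@atoms
  mw <- sum(.ATOMIC_MASS[a$element[a$element != "*"]]) + sum(a$nH) * .ATOMIC_MASS[["H"]]
  nC <- sum(a$element == "C")
  rings <- smallestRings(mol)
  bi <- bondIndexer(mol)
  nAR <- 0L
  for (cyc in rings) {
    ringBondIdx <- bi(cyc, c(cyc[-1L], cyc[1L]))
    if (all(!is.na(ringBondIdx)) && all(mol@bonds$aromatic[ringBondIdx]))
      nAR <- nAR + 1L
  }
  isNO <- a$element %in% c("N", "O")
  nHDon <- sum(isNO & a$nH >= 1L)
  nHAcc <- sum(isNO & !.pyrroleTypeN(mol) & !.amideN(mol))
  phi <- if (nrow(a) >= 3L) kierPhi(mol) else NA_real_
  data.frame(MW = round(unname(mw), 2), nC = nC, nAR = nAR,
             nHAcc = nHAcc, nHDon = nHDon,
             TPSA = tpsa(mol), PHI = phi)
}

#' Descriptor Pearson correlation matrix
#'
#' @param vectors a data.frame or matrix of descriptor values (compounds
#'   in rows), e.g. the output of [computeDescriptors()] on a list.
#' @return the symmetric Pearson correlation matrix with unit diagonal;
#'   correlations involving a constant column are \code{NA}.
#' @export
descriptorCorrelationMatrix <- function(vectors) {
  m <- as.matrix(vectors)
  stopifnot(is.numeric(m), nrow(m) >= 3L)
  const <- apply(m, 2L, function(x) stats::sd(x) == 0 || all(is.na(x)))
  out <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  out[const, ] <- NA_real_
  out[, const] <- NA_real_
  diag(out) <- ifelse(const, NA_real_, 1)
  out
}
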