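# Synthetic PROTAC dataset generator.  Emits degrader-like tripartite
# molecules (warhead - linker - E3 ligand) with two correlated percent
# degradation readouts and a planted ground truth: a parabolic
# linker-length dependence with class-specific optima, dead-warhead cliff
# pairs, and a polarity (TPSA) activity signal.

# building blocks; attachment points are "*" dummies, linkers carry two
# (warhead side first)
.WARHEADS <- data.frame(
  name = c("wh_nitrile", "wh_nitrile_F", "wh_alkyne_dead"),
  smiles = c(
    "N#Cc1ccc(cc1)c1ccc(cc1)C1CCN(CC1)c1ccc(*)cc1",
    "N#Cc1ccc(cc1)c1cc(F)c(cc1)C1CCN(CC1)c1ccc(*)cc1",
    "C#Cc1ccc(cc1)c1ccc(cc1)C1CCN(CC1)c1ccc(*)cc1"),
  penalty = c(0, 4, 85),
  dead = c(FALSE, FALSE, TRUE),
  parent = c(NA, NA, "wh_nitrile"))

.E3_LIGANDS <- data.frame(
  class = c("VHL", "CRBN"),
  smiles = c(
    "OC1CN(C(=O)C(NC(C)=O)C(C)(C)C)CC1c1ccc(*)cc1",
    "O=C1CCC(N2Cc3cccc(*)c3C2=O)C(=O)N1"))

.RIGID_LINKERS <- data.frame(
  name = c("chx_ch2_pip", "azet_ch2_chx"),
  smiles = c("*C1CCC(CC2CCN(*)CC2)CC1", "*C1CN(C1)CC1CCC(*)CC1"),
  n_carbon = c(12L, 10L))

# linker SMILES builders
.alkylLinker <- function(nC) paste0("*", strrep("C", nC), "*")
# polar linker: nO oxygens total, of which nOH (0, 1 or 2) are pendant
# hydroxyls on the leading carbons and the rest are in-chain ethers
.etherLinker <- function(nC, nO, nOH = 0L) {
  stopifnot(nOH %in% 0:2, nO >= nOH)
  nEther <- nO - nOH
  sizes <- rep(nC %/% (nEther + 1L), nEther + 1L)
  extra <- nC %% (nEther + 1L)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  if (any(sizes < 1L))
    stop("ether linker needs at least ", nEther + 1L, " carbons")
  chain <- paste(vapply(sizes, function(s) strrep("C", s), ""), collapse = "O")
  if (nOH >= 1L) chain <- sub("^C", "C(O)", chain)
  if (nOH == 2L) {
    # second hydroxyl on the next unbranched carbon
    chain <- sub("^(C\\(O\\))C", "\\1C(O)", chain)
  }
  paste0("*", chain, "*")
}

#' Default generator configuration
#'
#' The study conditions emulated by the generator: 92 compounds with a
#' VHL fraction of 53/92; optimal linker carbon counts (L*) of 10 for VHL
#' and 6 for CRBN with curvature 2 percent per carbon squared; linker
#' lengths sampled uniformly within L* +/- 3; maximum degradation 95
#' percent; a dead-warhead penalty of 85 points planting cliff pairs for
#' 15 percent of the compounds; a polarity rule subtracting
#' \code{gamma * max(0, TPSA - tau)} with tau = 105 A^2 and gamma = 2.5;
#' Gaussian readout noise (sd 4 points) and a concentration gain of 15
#' (the 1 uM readout closes 15 percent of the gap to 100).
#'
#' @param n number of compounds.
#' @param seed integer seed (mandatory; one stream drives all draws).
#' @param signal plant the structure-activity signals; with
#'   \code{FALSE}, degradation is drawn independently of structure
#'   (Normal(70, 15), clipped) as a null control.
#' @return a \code{GeneratorConfig} list.
#' @export
defaultGeneratorConfig <- function(n = 92L, seed, signal = TRUE) {
  list(n = as.integer(n),
       vhl_fraction = 53 / 92,
       l_star = c(VHL = 10L, CRBN = 6L),
       linker_offsets = -3:3,
       curvature = 2,
       rigid_curvature_factor = 0.1,
       dmax = 95,
       warhead_probs = c(wh_nitrile = 0.7, wh_nitrile_F = 0.3),
       dead_penalty = 85,
       cliff_fraction = 0.15,
       tpsa_rule = list(tau = 105, gamma = 4),
       linker_type_probs = c(alkyl = 0.5, ether = 0.4, rigid = 0.1),
       min_ether_o = 2L,
       max_ether_o = 2L,
       noise_sd = 4,
       concentration_gain = 15,
       null_mean = 70, null_sd = 15,
       signal = isTRUE(signal),
       seed = as.integer(seed))
}

.checkConfig <- function(config) {
  stopifnot(is.list(config), config$n >= 1L,
            config$vhl_fraction >= 0, config$vhl_fraction <= 1,
            config$curvature > 0, config$dmax > 0, config$dmax <= 100,
            config$cliff_fraction >= 0, config$cliff_fraction <= 0.5,
            config$noise_sd >= 0, config$concentration_gain >= 0,
            !is.null(config$seed))
  invisible(config)
}

#' Generate the building-block library
#'
#' Warhead variants (including the dead analog differing from its parent
#' by a single terminal atom edit: the nitrile key acceptor replaced by an
#' ethynyl group), the two E3-ligand classes, and example linkers of the
#' three chemical classes spanning the configured length range.
#'
#' @param config a \code{GeneratorConfig}.
#' @return list with data.frames \code{warheads} (name, smiles, penalty,
#'   dead, parent), \code{e3} (class, smiles) and \code{linkers} (type,
#'   n_carbon, n_oxygen, smiles).
#' @export
generateBuildingBlocks <- function(config = defaultGeneratorConfig(seed = 1L)) {
  .checkConfig(config)
  lens <- sort(unique(c(config$l_star["VHL"] + config$linker_offsets,
                        config$l_star["CRBN"] + config$linker_offsets)))
  lens <- lens[lens >= 2L]
  linkers <- rbind(
    data.frame(type = "alkyl", n_carbon = as.integer(lens), n_oxygen = 0L,
               smiles = vapply(lens, .alkylLinker, "")),
    data.frame(type = "ether",
               n_carbon = as.integer(lens[lens >= 4L]),
               n_oxygen = pmin(2L, lens[lens >= 4L] %/% 2L),
               smiles = vapply(lens[lens >= 4L], function(l)
                 .etherLinker(l, min(2L, l %/% 2L)), "")),
    data.frame(type = "rigid", n_carbon = .RIGID_LINKERS$n_carbon,
               n_oxygen = 0L, smiles = .RIGID_LINKERS$smiles))
  list(warheads = .WARHEADS, e3 = .E3_LIGANDS, linkers = linkers)
}

#' Assemble a PROTAC from three blocks
#'
#' Joins a warhead (one attachment point), a linker (two; warhead side
#' first) and an E3 ligand (one) into a single connected molecule.  The
#' returned atom map is the planted ground truth the decomposition module
#' is expected to recover.
#'
#' @param warhead,linker,e3 SMILES with \code{*} attachment dummies.
#' @return list: \code{mol} (a [MolGraph-class]), \code{map} (character
#'   vector warhead/linker/e3 per atom), \code{smiles} (canonical).
#' @export
assembleProtac <- function(warhead, linker, e3) {
  pw <- parseSmilesCached(warhead)
  pl <- parseSmilesCached(linker)
  pe <- parseSmilesCached(e3)
  dummies <- function(m) which(m@atoms$element == "*")
  dw <- dummies(pw); dl <- dummies(pl); de <- dummies(pe)
  if (length(dw) != 1L || length(de) != 1L || length(dl) != 2L)
    stop("malformed attachment points: warhead and E3 ligand need exactly ",
         "one '*', the linker exactly two")
  neigh <- function(m, d) {
    b <- m@bonds
    k <- which(b$a1 == d | b$a2 == d)
    if (length(k) != 1L) stop("attachment dummy must have exactly one bond")
    if (b$a1[k] == d) b$a2[k] else b$a1[k]
  }
  aw <- neigh(pw, dw)
  al <- vapply(dl, function(d) neigh(pl, d), 0L)  # in SMILES order
  ae <- neigh(pe, de)
  offL <- nrow(pw@atoms); offE <- offL + nrow(pl@atoms)
  atoms <- rbind(pw@atoms, pl@atoms, pe@atoms)
  shift <- function(b, off) { b$a1 <- b$a1 + off; b$a2 <- b$a2 + off; b }
  bonds <- rbind(pw@bonds, shift(pl@bonds, offL), shift(pe@bonds, offE))
  bonds <- rbind(bonds,
    data.frame(a1 = aw, a2 = al[1L] + offL, order = 1L, aromatic = FALSE,
               ring = FALSE),
    data.frame(a1 = al[2L] + offL, a2 = ae + offE, order = 1L,
               aromatic = FALSE, ring = FALSE))
  map <- rep(c("warhead", "linker", "e3"),
             c(nrow(pw@atoms), nrow(pl@atoms), nrow(pe@atoms)))
  keep <- setdiff(seq_len(nrow(atoms)), c(dw, dl + offL, de + offE))
  remap <- integer(nrow(atoms)); remap[keep] <- seq_along(keep)
  bkeep <- bonds$a1 %in% keep & bonds$a2 %in% keep
  bonds <- bonds[bkeep, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  mol <- newMolGraph(atoms[keep, , drop = FALSE], bonds)
  if (length(unique(moleculeComponents(mol))) != 1L)
    stop("assembled molecule is not connected")
  list(mol = mol, map = map[keep], smiles = writeSmiles(mol))
}

#' Simulate degradation readouts
#'
#' Additive activity model with clipping:
#' \deqn{D_{0.1} = clip(Dmax - a (L - L^*)^2 - p_w - \gamma
#'   \max(0, TPSA - \tau) + \epsilon, 0, 100)}
#' \deqn{D_{1} = clip(D_{0.1} + \delta (100 - D_{0.1}) / 100 +
#'   \epsilon', 0, 100)}
#' with Gaussian noise of sd \code{noise_sd}.  Rigid linkers use a
#' flattened curvature (\code{curvature * rigid_curvature_factor}).
#' Draws come from the current RNG stream.
#'
#' @param features data.frame with columns \code{e3_class},
#'   \code{n_carbon}, \code{linker_class}, \code{penalty}, \code{TPSA}.
#' @param config a \code{GeneratorConfig}.
#' @return data.frame (deg_low, deg_high).
#' @export
simulateDegradation <- function(features, config) {
  .checkConfig(config)
  n <- nrow(features)
  clip <- function(x) pmin(pmax(x, 0), 100)
  if (config$signal) {
    a <- ifelse(features$linker_class == "rigid",
                config$curvature * config$rigid_curvature_factor,
                config$curvature)
    lstar <- config$l_star[features$e3_class]
    base <- config$dmax - a * (features$n_carbon - lstar)^2 -
      features$penalty -
      config$tpsa_rule$gamma * pmax(0, features$TPSA - config$tpsa_rule$tau)
  } else {
    base <- stats::rnorm(n, config$null_mean, config$null_sd)
  }
  degLow <- clip(base + stats::rnorm(n, 0, config$noise_sd))
  degHigh <- clip(degLow + config$concentration_gain * (100 - degLow) / 100 +
                  stats::rnorm(n, 0, config$noise_sd))
  data.frame(deg_low = round(degLow, 1), deg_high = round(degHigh, 1))
}

#' Generate a synthetic degradation dataset
#'
#' Draws compound recipes (E3 class, warhead variant, linker type and
#' length), plants dead-warhead cliff pairs for a \code{cliff_fraction}
#' share of compounds (parent at the optimal alkyl linker, twin identical
#' except for the dead warhead), assembles the molecules, computes their
#' TPSA and simulates the two readouts.  Fully reproducible from the seed.
#'
#' @param config a \code{GeneratorConfig} from [defaultGeneratorConfig()].
#' @return list: \code{set} (a [DegradationSet-class]) and \code{truth}
#'   (ground truth: per-compound recipes, planted cliff pairs, planted
#'   L*, planted signal descriptors, the config).
#' @export
generateDataset <- function(config) {
  .checkConfig(config)
  withSeed(config$seed, {
    n <- config$n
    nDead <- round(config$cliff_fraction * n)
    nFree <- n - 2L * nDead
    if (nFree < 0L) stop("cliff_fraction too large for n")
    pick <- function(x, prob = NULL) {
      if (length(x) == 1L) x else sample(x, 1L, prob = prob)
    }
    recipes <- vector("list", n)
    cliffPairs <- list()
    idx <- 0L
    mkRecipe <- function(e3, warheadName, type, L, nO, nOH = 0L,
                         motif = NA_character_) {
      wrow <- .WARHEADS[.WARHEADS$name == warheadName, ]
      linkSmi <- if (type == "alkyl") .alkylLinker(L)
        else if (type == "ether") .etherLinker(L, nO, nOH)
        else .RIGID_LINKERS$smiles[.RIGID_LINKERS$name == motif]
      list(e3_class = e3, warhead = warheadName, penalty = wrow$penalty,
           dead = wrow$dead, linker_type = type, n_carbon = L,
           n_oxygen = nO, n_hydroxyl = nOH, rigid_motif = motif,
           linker_smiles = linkSmi)
    }
    for (i in seq_len(nFree)) {
      e3 <- if (stats::runif(1) < config$vhl_fraction) "VHL" else "CRBN"
      type <- pick(names(config$linker_type_probs),
                   prob = config$linker_type_probs)
      if (type == "ether" &&
          (config$l_star[e3] + min(config$linker_offsets)) %/% 2L <
            config$min_ether_o)
        type <- "alkyl"  # too short for a PEG-like linker
      if (type == "rigid") {
        motif <- pick(.RIGID_LINKERS$name)
        L <- .RIGID_LINKERS$n_carbon[.RIGID_LINKERS$name == motif]
        nO <- 0L
        recipes[[idx <- idx + 1L]] <- mkRecipe(e3, pick(
          names(config$warhead_probs), prob = config$warhead_probs),
          "rigid", L, nO, motif = motif)
      } else {
        L <- unname(config$l_star[e3] + pick(config$linker_offsets))
        if (type == "ether" && L %/% 2L < config$min_ether_o)
          type <- "alkyl"
        nO <- if (type == "ether")
          pick(seq(config$min_ether_o, min(config$max_ether_o, L %/% 2L)))
          else 0L
        # pendant hydroxyls diversify the polar linkers: high polarity at
        # near-alkyl flexibility, and the donor count covaries with TPSA
        nOH <- if (type == "ether") pick(0:min(2L, nO)) else 0L
        recipes[[idx <- idx + 1L]] <- mkRecipe(e3, pick(
          names(config$warhead_probs), prob = config$warhead_probs),
          type, L, nO, nOH)
      }
    }
    deadName <- .WARHEADS$name[.WARHEADS$dead][1L]
    parentName <- .WARHEADS$parent[.WARHEADS$dead][1L]
    for (p in seq_len(nDead)) {
      e3 <- if (stats::runif(1) < config$vhl_fraction) "VHL" else "CRBN"
      L <- unname(config$l_star[e3])
      recipes[[idx <- idx + 1L]] <- mkRecipe(e3, parentName, "alkyl", L, 0L)
      recipes[[idx <- idx + 1L]] <- mkRecipe(e3, deadName, "alkyl", L, 0L)
      cliffPairs[[p]] <- c(idx - 1L, idx)
    }
    # shuffle presentation order, keep track of the planted pairs
    perm <- sample.int(n)
    recipes <- recipes[perm]
    where <- order(perm)  # old index -> new position
    cliffPairs <- lapply(cliffPairs, function(pr) where[pr])

    ids <- sprintf("c%03d", seq_len(n))
    mols <- vector("list", n)
    feats <- vector("list", n)
    for (i in seq_len(n)) {
      rc <- recipes[[i]]
      wrow <- .WARHEADS[.WARHEADS$name == rc$warhead, ]
      erow <- .E3_LIGANDS[.E3_LIGANDS$class == rc$e3_class, ]
      asm <- assembleProtac(wrow$smiles, rc$linker_smiles, erow$smiles)
      mols[[i]] <- asm$mol
      feats[[i]] <- data.frame(
        e3_class = rc$e3_class, n_carbon = rc$n_carbon,
        linker_class = if (rc$linker_type == "rigid") "rigid"
                       else if (rc$n_oxygen > 0L) "ether" else "alkyl",
        penalty = rc$penalty, TPSA = tpsa(asm$mol),
        smiles = asm$smiles)
    }
    feats <- do.call(rbind, feats)
    deg <- simulateDegradation(feats, config)
    records <- data.frame(
      id = ids, smiles = feats$smiles, e3_class = feats$e3_class,
      deg_low = deg$deg_low, deg_high = deg$deg_high,
      cell_line = "synthetic", source = "ProtacSAR-generator")
    set <- DegradationSet(records, molecules = mols)
    truth <- list(
      recipes = cbind(id = ids, feats,
                      warhead = vapply(recipes, `[[`, "", "warhead"),
                      linker_type = vapply(recipes, `[[`, "", "linker_type"),
                      dead = vapply(recipes, `[[`, TRUE, "dead")),
      cliff_pairs = if (length(cliffPairs))
        data.frame(id_parent = ids[vapply(cliffPairs, `[`, 0L, 1L)],
                   id_dead = ids[vapply(cliffPairs, `[`, 0L, 2L)])
        else data.frame(id_parent = character(), id_dead = character()),
      l_star = config$l_star,
      signal_descriptors = if (config$signal) c("TPSA", "nHAcc")
                           else character(),
      config = config)
    list(set = set, truth = truth)
  })
}
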