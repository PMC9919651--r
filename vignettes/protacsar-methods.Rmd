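---
title: "Mining structure-degradation relationships in PROTAC data with ProtacSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining structure-degradation relationships in PROTAC data with ProtacSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProtacSAR)
```

# The problem

PROTACs (proteolysis-targeting chimeras) are heterobifunctional degraders
built from three blocks: a warhead binding the protein of interest, an
E3-ligase-recruiting ligand (VHL or CRBN in this package's scope), and a
linker joining the two.  In early discovery the available readout is
usually a percent-degradation value at one or two fixed concentrations --
far from the dose-response parameters (Dmax, DC50) that a rigorous SAR
analysis would prefer.  ProtacSAR implements a ligand-based workflow for
exactly this data format:

* structural characterization by Bemis-Murcko frameworks, merged into
  clusters through matched molecular pairs (MMPs);
* degradation-cliff detection: structurally similar pairs with a large
  activity difference, required to be consistent at both concentrations;
* tripartite warhead/linker/E3 decomposition with linker-degradation
  (parabola) fits;
* seven permeability-related 2D descriptors and a binary classification
  harness with cross-validation, external validation, Y-randomization and
  attribute ranking.

Because public degradation datasets of this shape are typically available
only on request, the package ships a synthetic data generator that plants
every effect the analysis is meant to find, so the whole pipeline can be
validated end to end against known ground truth.

# Molecular graphs

All structural operations work on a hydrogen-suppressed molecular graph
(`MolGraph`) parsed from SMILES.  The supported dialect covers the
organic subset, aromatic lowercase atoms, bracket atoms with charges and
explicit hydrogens, ring closures, branches, dot-disconnection and `*`
attachment dummies.  Tetrahedral and cis/trans stereo tags are accepted
and recorded but do not enter graph identity: the canonical forms used
throughout are two-dimensional.  Kekule-style inputs are parsed with
their explicit bond orders; aromaticity is taken from the lowercase
notation rather than re-perceived, so aromatic systems should be written
in aromatic form (as all generator output is).

Graph identity is decided by an exact canonical labeling (BLISS, via
igraph) of the colored graph -- atom colors from element, charge,
aromaticity and hydrogen count; bond colors from order -- with bond
colors encoded through auxiliary vertices.  The same machinery yields
canonical SMILES output and fragment identities for MMP cores and
substituents, with attachment positions marked by a distinguishing atom
color.  Substructure (anchor) matching uses VF2 monomorphism on the same
colored encoding.

```{r}
mol <- parseSmiles("N#Cc1ccc(cc1)C1CCN(C)CC1")
mol
writeSmiles(mol)
```

# Frameworks and fingerprints

`murckoScaffold()` retains ring systems plus inter-ring connections
(iterative pruning of terminal non-ring atoms), keeping exocyclic atoms
double-bonded to retained atoms -- the common Bemis-Murcko convention.
`murckoSkeleton()` additionally erases atom labels and bond orders, so
only the topology remains (benzene and pyridine share a skeleton).

Similarity uses hashed sphere fingerprints: for every atom and every
radius 0..5 the canonical identifier of the atom's circular environment
is hashed into a 1024-bin count vector twice -- once fully labeled, once
with labels and bond orders erased.  The dual labeled + skeleton hashing
makes the descriptor partially tolerant to heteroatom substitutions, in
the spirit of framework-aware descriptors used for similarity analysis of
large molecules.  The scheme is a documented in-package stand-in, not a
reimplementation of any proprietary descriptor; the published internals
of such descriptors are not available, so all thresholds quoted below
(notably the 0.9 similarity threshold of cliff detection) are defined
against *this* fingerprint.  Identifiers come from an iterative
(Morgan-style) neighborhood hash with a pure-R polynomial string hash
modulo a Mersenne prime, so vectors are bit-identical across platforms
and sessions.  Similarity between count vectors is the count Tanimoto
$\sum_i \min(a_i, b_i) / \sum_i \max(a_i, b_i)$.

# Clustering and degradation cliffs

Compounds are clustered as connected components of the graph whose edges
join molecules with identical canonical Murcko scaffolds or related by an
MMP.  MMP fragmentation cuts every acyclic non-ring bond once; two
molecules pair when they share a canonical core (including the attachment
position) with different substituents, each substituent at most 8 heavy
atoms (configurable) and never larger than the core.  Acyclic structures
all carry the empty scaffold and therefore share a cluster -- a
convention that matters only at the linker level, where it groups all
flexible chains together.  A flag restricts MMP merges to ring-bearing
substituent swaps for users who want strictly ring-system substitutions.

Degradation cliffs are unordered pairs with fingerprint similarity at or
above 0.9 whose absolute degradation difference reaches a threshold at
*both* concentrations (default 40 percentage points; the threshold is
configurable and recorded in every report header, since no universal
value exists for this quantity).  All candidate pairs are always emitted
alongside the passing ones, and analyst-chosen pairs below the similarity
threshold can be appended with a `manual` provenance tag.

# Decomposition and linker-degradation fits

`decomposeProtac()` matches one warhead-role and one E3-role anchor
pattern (fragment SMILES with a `*` attachment point) as disjoint
substructures; every remaining atom belongs to the linker.  When several
matches exist, the largest wins, with ties broken by canonical atom rank
-- deterministically, never an error.  A junction group such as a linkage
amide belongs to the linker exactly when it lies outside both anchors,
which fixes the otherwise ambiguous boundary.  Linker metrics count all
linker carbons (ring carbons included, so rigid series sit on the same
axis), measure topological length as the atom count of the shortest
intra-linker path between the two attachment bonds, and classify the
linker as alkyl, ether (acyclic C/O), rigid (any ring atom) or mixed.

Matched series -- identical warhead fragment, E3 fragment, attachment
positions and linker class, differing only in linker length -- feed an
ordinary least-squares quadratic of degradation on carbon count.  The
vertex $-b/2a$ estimates the optimal linker length.  At least 4 distinct
lengths are required (3 points fit any quadratic exactly), and fits with
non-negative or negligible curvature ($|a| < 10^{-6}$) are flagged
degenerate rather than reported as optima.

# Descriptors

The seven permeability-related 2D descriptors are molecular weight, carbon
count (nC), aromatic-ring count (nAR), hydrogen-bond acceptor and donor
atom counts (nHAcc, nHDon), topological polar surface area (TPSA) and
Kier's flexibility index (PHI).  Conventions, frozen and hand-checked:

* TPSA is the classical N/O-only fragment-additive variant (hydroxyl
  20.23, ether 9.23, carbonyl 17.07, nitrile 23.79, aromatic N 12.89,
  ...); sulfur and phosphorus contribute nothing.
* nHDon counts N/O atoms bearing at least one hydrogen; nHAcc counts N/O
  atoms except pyrrole-type aromatic nitrogens and amide nitrogens.
  Fluorine is never counted as an acceptor.
* PHI combines the alpha-modified kappa shape indices,
  $\Phi = \kappa^\alpha_1 \kappa^\alpha_2 / A$, with alpha contributions
  from covalent radii relative to sp3 carbon.  For an unbranched alkane of
  $A$ atoms $\Phi = A - 1$ exactly, a closed form the test suite checks.
* log P is deliberately absent: no current calculator is reliable for
  beyond-rule-of-five molecules such as PROTACs.

```{r}
computeDescriptors(parseSmiles("NC(=O)c1ccccc1"))  # benzamide
```

# Classification harness

Activity is binarized at 75 percent degradation (inclusive for active).
Splitting is plain uniform sampling without replacement at an 80:20
ratio; the training size is $n \cdot ratio$ rounded half-up, which gives
74/18 for 92 compounds and 42 and 31 training compounds for subsets of 53
and 39.  Cross-validation uses 10 plain random folds with sizes differing
by at most one; the pooled out-of-fold confusion matrix yields TPR, TNR,
MCC (zero denominator defined as 0) and a rank-based (Mann-Whitney) ROC
area with ties counting one half.  Five classifier backends are wrapped:
random forest (100 trees), a single random tree, Gaussian naive Bayes,
5-nearest-neighbors and a linear-kernel SVM at cost 1 -- deliberately
plain configurations; tuning is out of scope.  Zero-variance features are
dropped at fit time, degenerate single-class folds fall back to constant
prediction, and the nearest-neighbor tie-breaks are pinned to a fixed RNG
stream so every run is bit-reproducible.

Y-randomization permutes the labels (class counts preserved) and repeats
the full cross-validation, by default 20 times; an informative model must
collapse to chance.  Attribute ranking offers information gain (numeric
attributes discretized by the single supervised binary cut maximizing the
gain -- a simpler rule than multi-interval MDL discretization, adequate
for monotone planted signals but potentially coarser on real data),
absolute Pearson correlation with the class, a OneR-style single-cut
accuracy, and correlation-based feature-subset selection (CFS) with merit
$k \bar r_{cf} / \sqrt{k + k(k-1) \bar r_{ff}}$ and greedy forward
search.

# The synthetic generator and what it does (not) show

`generateDataset()` emulates a two-concentration AR-degrader table: 92
compounds by default with a VHL fraction of 53/92.  Molecules are
assembled from a nitrile-biphenyl-piperidine-aryl warhead family
(~26 heavy atoms), hydroxyprolinamide-like (VHL) and
glutarimide-isoindolinone-like (CRBN) E3 ligands, and alkyl, polar
(ether/hydroxyl) or rigid N-heterocycle linkers, giving molecular weights
of roughly 660-850 Da -- inside the range real PROTACs occupy.

The planted effects, all recoverable by the pipeline and asserted in the
test suite:

* **Parabolic linker dependence.**  Degradation falls as
  $a (L - L^*)^2$ with curvature $a = 2$ percent per carbon$^2$ around a
  class-specific optimum, $L^* = 10$ carbons for VHL and 6 for CRBN,
  lengths sampled uniformly within $L^* \pm 3$.  Rigid linkers use a
  flattened curvature (factor 0.1), encoding the observation that rigid
  linkers of roughly optimal length degrade well regardless of structure.
* **Dead-warhead cliffs.**  15 percent of compounds are dead analogs of a
  paired parent (same linker and E3 ligand) in which the warhead nitrile
  -- the key hydrogen-bond acceptor -- is replaced by an ethynyl group: a
  single terminal-atom edit costing 85 points of degradation.  The edit
  is terminal so that parent and twin stay above 0.9 fingerprint
  similarity at realistic molecule sizes; a mid-molecule edit of equal
  chemical subtlety would perturb too many atom environments for *any*
  environment-based fingerprint at this threshold, which is also why
  published cliff analyses of degraders report similarity-definition
  sensitivity.
* **Polarity signal.**  Degradation drops by
  $\gamma \max(0, TPSA - \tau)$ with $\tau = 105$ A$^2$ and $\gamma = 4$
  percent per A$^2$.  Polar linkers carry exactly two oxygens as
  ether/hydroxyl mixes: large TPSA and acceptor-count shifts at
  near-alkyl flexibility and size, so the planted signal loads on TPSA
  and nHAcc rather than on PHI or MW as confounds.  Rigid motifs carry a
  single nitrogen for the same reason.
* **Two concentrations.**  The 1 uM readout closes 15 percent of the gap
  to 100 on top of the 0.1 uM value, plus independent noise (sd 4
  points on both readouts).  Both readouts clip to [0, 100].

A `signal = FALSE` mode draws degradation independently of structure
(Normal(70, 15), clipped) as a null control: cross-validated MCC on such
data must stay within sampling noise of zero.

What passing these recovery tests shows is that the *pipeline* finds
exactly what was planted at realistic sizes and noise levels.  It does
not show that real degradation data contain such signals: the generator's
effects are additive and independent by construction, its chemistry is a
stylized AR-degrader vocabulary rather than real pharmacophores, its
readout noise is Gaussian whereas immunoblot quantification is not, and
cell-permeability, kinetics and ternary-complex cooperativity are not
modeled at all.

# Numerical choices and edge cases

* Degradation values outside [0, 100] are rejected at load time, never
  clipped; duplicate ids and disconnected or unparsable SMILES are
  row-level errors naming the row.
* All randomness (splits, folds, permutations, the generator) flows
  through explicitly seeded draws that save and restore the caller's RNG
  state.
* Count-Tanimoto of two all-zero vectors is defined as 0; an MCC with a
  zero denominator is defined as 0; correlations of constant descriptor
  columns are reported as missing values, not numbers.
* The smallest-rings search (for aromatic-ring counting and TPSA
  three-ring contributions) takes the shortest cycle through every ring
  bond -- exact for isolated and ortho-fused systems, which covers the
  chemistry the package targets.
* Problem sizes in the validation suite: 92-compound datasets (the
  default study condition) with 50 replicates for linker-optimum
  recovery, 20 for cliff sensitivity and null controls, 5 for the
  classification signal; the end-to-end pipeline check runs 200
  compounds.  These sizes give stable medians and rates while keeping a
  full validation run in the minutes range on one CPU.

# Known limitations

* The SMILES dialect has no isotope, no explicit aromatic re-perception
  for Kekule input, and stereo tags do not affect identity; two
  stereoisomers are one structure to every operation.  Stereo-driven
  cliffs (such as epimeric E3 ligands) therefore cannot be detected.
* Anchor patterns are exact fragment substructures rather than full SMARTS
  logic; this is sufficient for block libraries with known chemistry but
  not for fuzzy pharmacophore queries.
* The sphere fingerprint is a stand-in: absolute similarity values are
  not comparable to those of other descriptors, only thresholds defined
  against it are meaningful.
* Information-gain discretization is a single binary cut; multi-modal
  attribute-class relationships on real data may rank differently under
  multi-interval schemes.
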