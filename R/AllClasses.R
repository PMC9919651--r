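#' @import methods
NULL

#' Molecular graph
#'
#' An S4 container for a hydrogen-suppressed molecular graph: one row per
#' heavy atom (element, formal charge, aromatic flag, implicit hydrogen
#' count, stereo tag) and one row per bond (endpoint indices, bond order,
#' aromatic and ring-membership flags).  All structural operations in the
#' package (scaffolds, fingerprints, decomposition, MMP fragmentation,
#' descriptors) work on this representation.
#'
#' @slot atoms data.frame with columns \code{element}, \code{aromatic},
#'   \code{charge}, \code{nH}, \code{stereo}.
#' @slot bonds data.frame with columns \code{a1}, \code{a2}, \code{order},
#'   \code{aromatic}, \code{ring}.
#' @slot smiles the input SMILES the graph was built from (may be \code{NA}
#'   for graphs assembled in code).
#'
#' @seealso [parseSmiles()], [writeSmiles()]
#' @exportClass MolGraph
setClass("MolGraph",
  representation(atoms = "data.frame", bonds = "data.frame",
                 smiles = "character"))

setValidity("MolGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  msgs <- character()
  need_a <- c("element", "aromatic", "charge", "nH", "stereo")
  need_b <- c("a1", "a2", "order", "aromatic", "ring")
  if (!all(need_a %in% names(a))) msgs <- c(msgs, "atom table lacks required columns")
  if (!all(need_b %in% names(b))) msgs <- c(msgs, "bond table lacks required columns")
  if (length(msgs) == 0L && nrow(b) > 0L) {
    if (any(b$a1 < 1L | b$a1 > nrow(a) | b$a2 < 1L | b$a2 > nrow(a)))
      msgs <- c(msgs, "bond endpoint out of range")
    if (any(b$a1 == b$a2)) msgs <- c(msgs, "self-bond")
    if (any(!b$order %in% 1:3)) msgs <- c(msgs, "bond order outside 1..3")
  }
  if (length(msgs) == 0L && nrow(a) > 0L && any(a$nH < 0L))
    msgs <- c(msgs, "negative implicit hydrogen count")
  if (length(msgs)) msgs else TRUE
})

#' Degradation dataset
#'
#' An S4 container for a table of degrader records: compound id, SMILES,
#' E3-ligase class (VHL or CRBN) and percent target degradation measured at
#' a low (0.1 uM) and a high (1 uM) concentration, with optional cell-line
#' and source annotations.  Parsed molecular graphs are carried alongside
#' the records so downstream structural operations never re-parse.
#'
#' @slot records data.frame with columns \code{id}, \code{smiles},
#'   \code{e3_class}, \code{deg_low}, \code{deg_high}, \code{cell_line},
#'   \code{source}.
#' @slot molecules list of [MolGraph-class] objects, parallel to the rows
#'   of \code{records}.
#'
#' @seealso [loadDegradationTable()], [DegradationSet()]
#' @exportClass DegradationSet
setClass("DegradationSet",
  representation(records = "data.frame", molecules = "list"))

setValidity("DegradationSet", function(object) {
  r <- object@records
  msgs <- character()
  need <- c("id", "smiles", "e3_class", "deg_low", "deg_high")
  if (!all(need %in% names(r)))
    return(paste("records lack required columns:",
                 paste(setdiff(need, names(r)), collapse = ", ")))
  if (anyDuplicated(r$id)) msgs <- c(msgs, "duplicate compound id")
  if (any(!r$e3_class %in% c("VHL", "CRBN")))
    msgs <- c(msgs, "e3_class must be VHL or CRBN")
  bad <- which(is.na(r$deg_low) | is.na(r$deg_high) |
               r$deg_low < 0 | r$deg_low > 100 |
               r$deg_high < 0 | r$deg_high > 100)
  if (length(bad))
    msgs <- c(msgs, paste0("degradation outside [0,100] in row(s) ",
                           paste(bad, collapse = ", ")))
  if (length(object@molecules) != nrow(r))
    msgs <- c(msgs, "molecules list length differs from record count")
  if (length(msgs)) msgs else TRUE
})

#' Sphere fingerprint set
#'
#' Hashed count fingerprints for a set of molecules: for every atom and
#' every radius up to \code{radius}, the canonical string of the atom's
#' r-sphere environment is hashed into a fixed-length count vector twice,
#' once with atom labels and bond orders ("labeled") and once with both
#' erased ("skeleton").  This is a reproducible stand-in for descriptor
#' schemes of the SkelSpheres family; it is not bit-compatible with any
#' proprietary implementation.
#'
#' @slot counts integer matrix, one row per molecule, \code{nbits} columns.
#' @slot radius maximum sphere radius used.
#' @slot nbits length of the count vector.
#'
#' @seealso [sphereFingerprints()], [tanimoto()]
#' @exportClass SphereFingerprintSet
setClass("SphereFingerprintSet",
  representation(counts = "matrix", radius = "integer", nbits = "integer"))

setValidity("SphereFingerprintSet", function(object) {
  if (ncol(object@counts) != object@nbits)
    return("count matrix width differs from nbits")
  if (any(object@counts < 0)) return("negative counts")
  TRUE
})

#' @describeIn MolGraph-class display summary
#' @param object a \code{MolGraph}
#' @export
setMethod("show", "MolGraph", function(object) {
  cat("MolGraph with", nrow(object@atoms), "heavy atoms and",
      nrow(object@bonds), "bonds\n")
  if (!is.na(object@smiles)) cat("  smiles:", object@smiles, "\n")
  comp <- sum(table(moleculeComponents(object)) > 0)
  cat("  formula:", molecularFormula(object), "| components:", comp, "\n")
})

#' @describeIn DegradationSet-class display summary
#' @param object a \code{DegradationSet}
#' @export
setMethod("show", "DegradationSet", function(object) {
  r <- object@records
  cat("DegradationSet with", nrow(r), "compounds (",
      sum(r$e3_class == "VHL"), "VHL,", sum(r$e3_class == "CRBN"), "CRBN )\n")
  if (nrow(r)) {
    cat("  deg 0.1 uM: ", sprintf("%.1f..%.1f", min(r$deg_low), max(r$deg_low)),
        " | deg 1 uM: ", sprintf("%.1f..%.1f", min(r$deg_high), max(r$deg_high)),
        "\n", sep = "")
  }
})

#' @describeIn SphereFingerprintSet-class display summary
#' @param object a \code{SphereFingerprintSet}
#' @export
setMethod("show", "SphereFingerprintSet", function(object) {
  cat("SphereFingerprintSet:", nrow(object@counts), "molecules,",
      object@nbits, "bins, radius", object@radius, "\n")
})

#' @describeIn DegradationSet-class number of compounds
#' @param x a \code{DegradationSet}
#' @export
setMethod("length", "DegradationSet", function(x) nrow(x@records))

#' @describeIn DegradationSet-class subset by index or compound id
#' @param i index, logical or character vector of ids
#' @param j,drop,... ignored
#' @export
setMethod("[", "DegradationSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@records$id)
  if (anyNA(i)) stop("unknown compound id in subset")
  new("DegradationSet", records = x@records[i, , drop = FALSE],
      molecules = x@molecules[i])
})
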