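# Loading, validating, binarizing and splitting degradation tables.
#
# Expected CSV schema (comma separated, header required, "." decimal):
#   id, smiles, e3_class (VHL|CRBN), deg_low, deg_high[, cell_line, source]
# deg_low / deg_high are percent target degradation at 0.1 uM and 1 uM.

.REQUIRED_COLS <- c("id", "smiles", "e3_class", "deg_low", "deg_high")

# run a seeded computation without disturbing the caller's RNG stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

#' Construct a DegradationSet from a data.frame
#'
#' Validates every row: the SMILES must parse to a single connected
#' molecule with at least one heavy atom, degradation percentages must lie
#' in [0, 100] (values outside are rejected, not clipped), E3 class must
#' be VHL or CRBN, and ids must be unique.
#'
#' @param records data.frame with the schema above.
#' @param molecules optional pre-parsed list of [MolGraph-class] objects.
#' @return a [DegradationSet-class].
#' @export
DegradationSet <- function(records, molecules = NULL) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(.REQUIRED_COLS, names(records))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  records$id <- as.character(records$id)
  records$smiles <- as.character(records$smiles)
  records$e3_class <- as.character(records$e3_class)
  if (!"cell_line" %in% names(records)) records$cell_line <- NA_character_
  if (!"source" %in% names(records)) records$source <- NA_character_
  records <- records[, c(.REQUIRED_COLS, "cell_line", "source")]
  rownames(records) <- NULL

  dup <- records$id[duplicated(records$id)]
  if (length(dup))
    stop("duplicate compound id(s): ", paste(unique(dup), collapse = ", "))
  badE3 <- which(!records$e3_class %in% c("VHL", "CRBN"))
  if (length(badE3))
    stop("row ", badE3[1L], ": e3_class must be VHL or CRBN, got '",
         records$e3_class[badE3[1L]], "'")
  for (col in c("deg_low", "deg_high")) {
    v <- suppressWarnings(as.numeric(records[[col]]))
    bad <- which(is.na(v) | v < 0 | v > 100)
    if (length(bad))
      stop("row ", bad[1L], ": ", col, " = '", records[[col]][bad[1L]],
           "' is not a percentage in [0, 100]")
    records[[col]] <- v
  }
  if (is.null(molecules)) {
    molecules <- vector("list", nrow(records))
    for (i in seq_len(nrow(records))) {
      mol <- tryCatch(parseSmiles(records$smiles[i]), error = function(e)
        stop("row ", i, " (id ", records$id[i], "): unparsable SMILES: ",
             conditionMessage(e), call. = FALSE))
      if (length(unique(moleculeComponents(mol))) != 1L)
        stop("row ", i, " (id ", records$id[i],
             "): SMILES is not a single connected molecule")
      molecules[[i]] <- mol
    }
  }
  names(molecules) <- records$id
  new("DegradationSet", records = records, molecules = molecules)
}

#' Load a degradation table from CSV
#'
#' @param path path to a CSV file with columns \code{id, smiles, e3_class,
#'   deg_low, deg_high} and optionally \code{cell_line, source}.  Lines
#'   starting with \code{#} are treated as comments.
#' @return a [DegradationSet-class]; row order is preserved.
#' @seealso [writeDegradationTable()]
#' @export
loadDegradationTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  # leading comment lines only: "#" inside data would clash with SMILES
  # triple bonds
  lines <- lines[cumsum(!startsWith(lines, "#")) > 0]
  df <- utils::read.csv(text = lines, stringsAsFactors = FALSE)
  DegradationSet(df)
}

#' @rdname loadDegradationTable
#' @param set a [DegradationSet-class].
#' @param header optional character vector of comment lines (each will be
#'   prefixed with \code{# }) written before the CSV header.
#' @export
writeDegradationTable <- function(set, path, header = NULL) {
  stopifnot(is(set, "DegradationSet"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste("#", header), con)
  utils::write.csv(set@records, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- accessors ------------------------------------------------------------

#' Accessors for DegradationSet
#'
#' @param set a [DegradationSet-class].
#' @return \code{compoundIds}: character vector of ids;
#'   \code{moleculeList}: named list of [MolGraph-class];
#'   \code{e3Class}: character vector (VHL/CRBN);
#'   \code{degradation}: numeric vector of percent degradation;
#'   \code{recordTable}: the underlying data.frame.
#' @export
compoundIds <- function(set) set@records$id

#' @rdname compoundIds
#' @export
moleculeList <- function(set) set@molecules

#' @rdname compoundIds
#' @export
e3Class <- function(set) set@records$e3_class

#' @rdname compoundIds
#' @param concentration \code{"low"} (0.1 uM) or \code{"high"} (1 uM).
#' @export
degradation <- function(set, concentration = c("low", "high")) {
  concentration <- match.arg(concentration)
  if (concentration == "low") set@records$deg_low else set@records$deg_high
}

#' @rdname compoundIds
#' @export
recordTable <- function(set) set@records

# --- activity and splits --------------------------------------------------

#' Binarize degradation activity
#'
#' A compound is active when its percent degradation is greater than or
#' equal to the threshold (default 75; the boundary is inclusive for
#' active).
#'
#' @param deg numeric vector of percent degradation in [0, 100].
#' @param threshold activity cutoff in percent.
#' @return logical vector, \code{TRUE} = active, with the threshold
#'   attached as attribute \code{"threshold"}.
#' @examples
#' binarizeActivity(c(75, 74.9, 100))
#' @export
binarizeActivity <- function(deg, threshold = 75) {
  stopifnot(is.numeric(deg), is.numeric(threshold), length(threshold) == 1L)
  if (any(is.na(deg) | deg < 0 | deg > 100))
    stop("degradation values must lie in [0, 100]")
  out <- deg >= threshold
  attr(out, "threshold") <- threshold
  out
}

#' Random train/test split
#'
#' Plain (unstratified) uniform sampling without replacement.  The
#' training size is \code{n * ratio} rounded to the nearest integer with
#' ties rounded up, which reproduces 74/92, 42/53 and 31/39 at the 80:20
#' ratio.  Membership is deterministic given the seed.
#'
#' @param x a [DegradationSet-class] or a character vector of ids.
#' @param ratio training fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @return a list of class \code{SplitAssignment} with elements
#'   \code{train_ids}, \code{test_ids}, \code{ratio}, \code{seed}.
#' @examples
#' sp <- splitDataset(sprintf("c%02d", 1:92), seed = 1)
#' lengths(sp[c("train_ids", "test_ids")])  # 74, 18
#' @export
splitDataset <- function(x, ratio = 0.8, seed) {
  ids <- if (is(x, "DegradationSet")) compoundIds(x) else as.character(x)
  n <- length(ids)
  stopifnot(n >= 2L, ratio > 0, ratio < 1)
  nTrain <- floor(n * ratio + 0.5)
  if (nTrain <= 0L || nTrain >= n)
    stop("split ratio ", ratio, " leaves an empty partition for n = ", n)
  trainIdx <- withSeed(seed, sample.int(n, nTrain))
  out <- list(train_ids = ids[sort(trainIdx)],
              test_ids = ids[sort(setdiff(seq_len(n), trainIdx))],
              ratio = ratio, seed = as.integer(seed))
  class(out) <- "SplitAssignment"
  out
}

#' @export
print.SplitAssignment <- function(x, ...) {
  cat("SplitAssignment: ", length(x$train_ids), " train / ",
      length(x$test_ids), " test (ratio ", x$ratio, ", seed ", x$seed,
      ")\n", sep = "")
  invisible(x)
}

#' @rdname splitDataset
#' @param split a \code{SplitAssignment}.
#' @param path output CSV path (columns id, partition).
#' @export
writeSplit <- function(split, path) {
  df <- data.frame(
    id = c(split$train_ids, split$test_ids),
    partition = rep(c("train", "test"),
                    c(length(split$train_ids), length(split$test_ids))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
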