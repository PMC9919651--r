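# Degradation-cliff detection: structurally similar compound pairs with a
# large degradation difference, required to be consistent at both tested
# concentrations.

#' Similar compound pairs
#'
#' All unordered pairs with count-Tanimoto fingerprint similarity at or
#' above the threshold.
#'
#' @param fps a [SphereFingerprintSet-class] (rows named by compound id).
#' @param sMin similarity threshold in [0, 1] (default 0.9, i.e. the 90
#'   percent similarity convention of cliff analysis).
#' @return data.frame (id_i, id_j, similarity), each unordered pair once.
#' @export
similarPairs <- function(fps, sMin = 0.9) {
  stopifnot(is(fps, "SphereFingerprintSet"), nrow(fps@counts) >= 2L)
  ids <- rownames(fps@counts)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(fps@counts)))
  tm <- tanimoto(fps)
  hit <- which(upper.tri(tm) & tm >= sMin, arr.ind = TRUE)
  out <- data.frame(id_i = ids[hit[, 1L]], id_j = ids[hit[, 2L]],
                    similarity = tm[hit])
  out[order(-out$similarity, out$id_i, out$id_j), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Detect degradation cliffs
#'
#' Annotates candidate similar pairs with the absolute degradation
#' difference at both concentrations; a pair passes when both deltas reach
#' \code{deltaMin} (dual-concentration consistency).  With
#' \code{requireBoth = FALSE} the low-concentration delta alone decides.
#' All candidate pairs are returned (mirroring the un-filtered candidate
#' stage of cliff analysis); filter on \code{passes_dual} for the cliffs.
#' Pairs below the similarity threshold that the analyst nevertheless
#' wants to track can be supplied via \code{manualPairs} and are tagged
#' \code{provenance = "manual"}.
#'
#' @param pairs data.frame from [similarPairs()].
#' @param set a [DegradationSet-class] with both concentrations for every
#'   paired compound.
#' @param deltaMin minimum absolute degradation difference in percentage
#'   points (default 40; configurable, reported in every output header).
#' @param requireBoth require the threshold at both concentrations.
#' @param manualPairs optional data.frame (id_i, id_j) of extra pairs.
#' @param fps optional fingerprint set used to compute similarities for
#'   manual pairs (otherwise their similarity is \code{NA}).
#' @return data.frame (id_i, id_j, similarity, delta_low, delta_high,
#'   passes_dual, provenance).
#' @export
detectDegradationCliffs <- function(pairs, set, deltaMin = 40,
                                    requireBoth = TRUE, manualPairs = NULL,
                                    fps = NULL) {
  r <- recordTable(set)
  degL <- r$deg_low; degH <- r$deg_high
  names(degL) <- names(degH) <- r$id
  prov <- rep("auto", nrow(pairs))
  if (!is.null(manualPairs) && nrow(manualPairs)) {
    sim <- rep(NA_real_, nrow(manualPairs))
    if (!is.null(fps)) {
      tm <- tanimoto(fps)
      sim <- tm[cbind(match(manualPairs$id_i, rownames(tm)),
                      match(manualPairs$id_j, rownames(tm)))]
    }
    pairs <- rbind(pairs[, c("id_i", "id_j", "similarity")],
                   data.frame(id_i = manualPairs$id_i,
                              id_j = manualPairs$id_j, similarity = sim))
    prov <- c(prov, rep("manual", nrow(manualPairs)))
  }
  allIds <- unique(c(pairs$id_i, pairs$id_j))
  missing <- setdiff(allIds, r$id)
  if (length(missing))
    stop("no degradation record for compound(s): ",
         paste(missing, collapse = ", "))
  bad <- allIds[is.na(degL[allIds]) | is.na(degH[allIds])]
  if (length(bad))
    stop("missing concentration value for compound(s): ",
         paste(bad, collapse = ", "))
  dl <- abs(degL[pairs$id_i] - degL[pairs$id_j])
  dh <- abs(degH[pairs$id_i] - degH[pairs$id_j])
  passes <- if (requireBoth) dl >= deltaMin & dh >= deltaMin
            else dl >= deltaMin
  out <- data.frame(id_i = pairs$id_i, id_j = pairs$id_j,
                    similarity = pairs$similarity,
                    delta_low = unname(dl), delta_high = unname(dh),
                    passes_dual = unname(passes), provenance = prov)
  rownames(out) <- NULL
  attr(out, "delta_min") <- deltaMin
  attr(out, "require_both") <- requireBoth
  out
}
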