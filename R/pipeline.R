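# End-to-end orchestration: load or simulate -> descriptors -> clusters ->
# cliffs -> linker analysis -> classification -> Y-randomization ->
# attribute ranking, with CSV/JSON reports and a provenance log.

.PKG_VERSION <- function()
  as.character(utils::packageVersion("ProtacSAR"))

#' Assemble a pipeline configuration
#'
#' @param input path to a degradation CSV, or \code{NULL} to simulate.
#' @param generator a \code{GeneratorConfig} used when \code{input} is
#'   \code{NULL}.
#' @param outDir output directory (created if missing).
#' @param activityThreshold percent cutoff for active compounds.
#' @param similarityThreshold Tanimoto threshold for cliff candidates.
#' @param deltaMin degradation-difference threshold in points.
#' @param splitRatio training fraction.
#' @param seed integer seed for split, folds and learners.
#' @param anchors anchor library data.frame (or path to its CSV).
#' @return a \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(input = NULL, generator = NULL, outDir,
                           activityThreshold = 75,
                           similarityThreshold = 0.9, deltaMin = 40,
                           splitRatio = 0.8, seed = 1L, anchors = NULL) {
  stopifnot(activityThreshold >= 0, activityThreshold <= 100,
            similarityThreshold >= 0, similarityThreshold <= 1,
            deltaMin >= 0, splitRatio > 0, splitRatio < 1)
  if (is.null(input) && is.null(generator))
    generator <- defaultGeneratorConfig(seed = seed)
  if (is.character(anchors)) anchors <- readAnchorLibrary(anchors)
  structure(list(input = input, generator = generator, outDir = outDir,
                 activity_threshold = activityThreshold,
                 similarity_threshold = similarityThreshold,
                 delta_min = deltaMin, split_ratio = splitRatio,
                 seed = as.integer(seed), anchors = anchors),
            class = "PipelineConfig")
}

# provenance header lines for every report
.provHeader <- function(config) {
  c(paste("ProtacSAR", .PKG_VERSION()),
    paste("seed:", config$seed),
    paste("activity_threshold:", config$activity_threshold),
    paste("similarity_threshold:", config$similarity_threshold),
    paste("delta_min:", config$delta_min),
    paste("split_ratio:", config$split_ratio))
}

.writeReport <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", header), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: load (or simulate) and validate; descriptors + correlation
#' matrix; Murcko/MMP clustering at the whole-molecule and, where
#' decomposition succeeds, building-block levels; fingerprint similarity
#' and degradation-cliff detection; tripartite decomposition and
#' linker-degradation fits; classification (per E3 class and pooled) with
#' cross-validation, external validation, Y-randomization and attribute
#' ranking.  Each stage writes a CSV report with a provenance header; a
#' run log names every stage and its outcome.
#'
#' @param config a \code{PipelineConfig} from [pipelineConfig()].
#' @return invisibly, a list with the in-memory results and the report
#'   file paths.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(config$outDir, "run_log.txt")
  logCon <- file(logPath, "w")
  on.exit(close(logCon))
  logLine <- function(...) writeLines(paste0(...), logCon)
  logLine("ProtacSAR pipeline v", .PKG_VERSION())
  for (h in .provHeader(config)[-1L]) logLine(h)
  hdr <- .provHeader(config)
  paths <- character()
  results <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      logLine("stage ", name, ": ERROR: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logLine("stage ", name, ": ok")
    res
  }

  set <- stage("load", {
    if (!is.null(config$input)) {
      s <- loadDegradationTable(config$input)
      results$truth <- NULL
      s
    } else {
      gen <- generateDataset(config$generator)
      results$truth <- gen$truth
      jsonlite::write_json(
        list(cliff_pairs = gen$truth$cliff_pairs,
             l_star = as.list(gen$truth$l_star),
             signal_descriptors = gen$truth$signal_descriptors,
             recipes = gen$truth$recipes[,
               c("id", "e3_class", "linker_class", "n_carbon", "penalty",
                 "warhead", "dead")]),
        file.path(config$outDir, "ground_truth.json"))
      writeDegradationTable(gen$set,
                            file.path(config$outDir, "dataset.csv"),
                            header = hdr)
      gen$set
    }
  })
  results$set <- set

  desc <- stage("descriptors", {
    d <- computeDescriptors(moleculeList(set))
    tab <- cbind(data.frame(id = compoundIds(set)), d)
    paths["descriptors"] <- .writeReport(
      tab, file.path(config$outDir, "descriptors.csv"), hdr)
    cm <- descriptorCorrelationMatrix(d)
    paths["correlation"] <- .writeReport(
      data.frame(descriptor = rownames(cm), cm),
      file.path(config$outDir, "descriptor_correlation.csv"), hdr)
    tab
  })
  results$descriptors <- desc

  decomp <- stage("decomposition", {
    anchors <- if (is.null(config$anchors)) defaultAnchorLibrary()
               else config$anchors
    dd <- tryCatch(decomposeDataset(set, anchors), error = function(e) NULL)
    if (is.null(dd)) {
      logLine("stage decomposition: no full anchor coverage; ",
              "building-block analyses skipped")
    } else {
      paths["decomposition"] <- .writeReport(
        dd$table, file.path(config$outDir, "decomposition.csv"), hdr)
    }
    dd
  })
  results$decomposition <- decomp

  clusters <- stage("clustering", {
    lv <- list(murckoMmpClusters(set, "full"))
    if (!is.null(decomp)) {
      lv <- c(lv, lapply(c("warhead", "e3", "linker"), function(l)
        murckoMmpClusters(set, l, decomps = decomp$decomps)))
    }
    asg <- do.call(rbind, lv)
    paths["clusters"] <- .writeReport(
      asg, file.path(config$outDir, "clusters.csv"), hdr)
    summ <- do.call(rbind, lapply(split(asg, asg$level), function(a)
      cbind(level = a$level[1L],
            clusterActivitySummary(a, set,
                                   threshold = config$activity_threshold))))
    paths["cluster_summary"] <- .writeReport(
      summ, file.path(config$outDir, "cluster_summary.csv"), hdr)
    asg
  })
  results$clusters <- clusters

  cliffs <- stage("cliffs", {
    fps <- sphereFingerprints(moleculeList(set))
    cand <- similarPairs(fps, sMin = config$similarity_threshold)
    cl <- detectDegradationCliffs(cand, set, deltaMin = config$delta_min)
    paths["cliffs"] <- .writeReport(
      cl, file.path(config$outDir, "cliffs.csv"),
      c(hdr, paste("candidate_pairs:", nrow(cand)),
        paste("passing_pairs:", sum(cl$passes_dual))))
    cl
  })
  results$cliffs <- cliffs

  ldr <- stage("ldr", {
    if (is.null(decomp)) return(NULL)
    l <- ldrAnalysis(set, decomp$decomps)
    paths["ldr"] <- .writeReport(
      l, file.path(config$outDir, "ldr.csv"), hdr)
    l
  })
  results$ldr <- ldr

  models <- stage("classification", {
    rows <- list()
    for (sub in c("VHL", "CRBN", "all")) {
      tab <- tryCatch(featureTable(set, threshold = config$activity_threshold,
                                   subset = sub), error = function(e) NULL)
      if (is.null(tab) || length(unique(tab$active)) < 2L || nrow(tab) < 12L)
        next
      sp <- splitDataset(tab$id, ratio = config$split_ratio,
                         seed = config$seed)
      cmp <- compareClassifiers(tab, sp, seed = config$seed)
      if (nrow(cmp)) rows[[sub]] <- cbind(subset = sub, cmp)
    }
    m <- do.call(rbind, rows)
    if (is.null(m))
      m <- data.frame(subset = character(), algorithm = character(),
                      phase = character(), n = integer(), TPR = numeric(),
                      TNR = numeric(), MCC = numeric(),
                      roc_area = numeric(), seed = integer())
    paths["models"] <- .writeReport(
      m, file.path(config$outDir, "models.csv"), hdr)
    m
  })
  results$models <- models

  stage("y_randomization", {
    tab <- tryCatch(featureTable(set, threshold = config$activity_threshold,
                                 subset = "VHL"), error = function(e) NULL)
    if (is.null(tab) || length(unique(tab$active)) < 2L || nrow(tab) < 12L)
      return(NULL)
    yr <- yRandomization(tab, "RF", nPerm = 20L, seed = config$seed)
    paths["y_randomization"] <- .writeReport(
      data.frame(permutation = seq_along(yr$mccs), mcc = yr$mccs),
      file.path(config$outDir, "y_randomization.csv"),
      c(hdr, paste("mean_mcc:", round(yr$mean_mcc, 4))))
    results$y_randomization <- yr
  })

  stage("attribute_ranking", {
    tab <- tryCatch(featureTable(set, threshold = config$activity_threshold,
                                 subset = "VHL"), error = function(e) NULL)
    if (is.null(tab) || length(unique(tab$active)) < 2L) return(NULL)
    rk <- do.call(rbind, lapply(
      c("InfoGain", "PearsonCorrelation", "OneR", "CFS"), function(ev) {
        r <- rankAttributes(tab, ev)
        cbind(evaluator = ev, r, rank = seq_len(nrow(r)))
      }))
    paths["attribute_ranking"] <- .writeReport(
      rk, file.path(config$outDir, "attribute_ranking.csv"), hdr)
    results$rankings <- rk
  })

  logLine("pipeline complete: ", length(paths), " reports")
  results$paths <- paths
  invisible(results)
}
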