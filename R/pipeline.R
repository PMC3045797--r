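#' @include simulate.R read-processing.R alignment.R events.R coding.R
#'   balance.R
#' @importFrom yaml read_yaml write_yaml
NULL

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with the package defaults:
#' QC windowing (20/15/Q20, minimum 50 nt), clustering (40 nt overlap at
#' 95\% identity), alignment thresholds (identity 93, coverage 55), event
#' deduplication, the 50-nt NMD rule and the |2|-fold differential
#' boundary.
#'
#' @param seed integer seed (flows into \code{\link{simParams}}).
#' @param nGenes genes simulated when no input reads are supplied.
#' @param sim a \linkS4class{SimulationParams}.
#' @param qc a \linkS4class{QCParams}.
#' @param minOverlap,minIdentityFrac clustering thresholds.
#' @param minAlnIdentity,minAlnCoverage alignment filter thresholds (%).
#' @param dedupEvents deduplicate events by (type, coords) per cluster.
#' @param nmdRuleNt NMD distance boundary.
#' @param foldThreshold differential-call boundary.
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(seed = 1L, nGenes = 50L, sim = simParams(seed),
                           qc = qcParams(), minOverlap = 40L,
                           minIdentityFrac = 0.95, minAlnIdentity = 93,
                           minAlnCoverage = 55, dedupEvents = TRUE,
                           nmdRuleNt = 50, foldThreshold = 2) {
    structure(list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                   sim = sim, qc = qc, minOverlap = minOverlap,
                   minIdentityFrac = minIdentityFrac,
                   minAlnIdentity = minAlnIdentity,
                   minAlnCoverage = minAlnCoverage,
                   dedupEvents = dedupEvents, nmdRuleNt = nmdRuleNt,
                   foldThreshold = foldThreshold),
              class = "PipelineConfig")
}

#' Read or write a pipeline configuration as YAML
#'
#' The file round-trips losslessly through \code{pipelineConfig}.
#'
#' @param path YAML file.
#' @return \code{readPipelineConfig}: a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    pipelineConfig(
        seed = y$seed, nGenes = y$nGenes,
        sim = do.call(simParams, y$sim), qc = do.call(qcParams, y$qc),
        minOverlap = y$minOverlap, minIdentityFrac = y$minIdentityFrac,
        minAlnIdentity = y$minAlnIdentity,
        minAlnCoverage = y$minAlnCoverage, dedupEvents = y$dedupEvents,
        nmdRuleNt = y$nmdRuleNt, foldThreshold = y$foldThreshold)
}

#' @rdname readPipelineConfig
#' @param config a \code{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
    s <- config$sim; q <- config$qc
    yaml::write_yaml(list(
        seed = config$seed, nGenes = config$nGenes,
        sim = list(seed = s@seed, abundanceMeanlog = s@abundanceMeanlog,
                   abundanceSdlog = s@abundanceSdlog,
                   pcrRedundancy = s@pcrRedundancy,
                   captureNoise = s@captureNoise,
                   readErrorRate = s@readErrorRate, qualMean = s@qualMean,
                   qualSd = s@qualSd, minLoop = s@minLoop),
        qc = list(window = q@window, minGood = q@minGood,
                  minQuality = q@minQuality, minLength = q@minLength),
        minOverlap = config$minOverlap,
        minIdentityFrac = config$minIdentityFrac,
        minAlnIdentity = config$minAlnIdentity,
        minAlnCoverage = config$minAlnCoverage,
        dedupEvents = config$dedupEvents, nmdRuleNt = config$nmdRuleNt,
        foldThreshold = config$foldThreshold), path)
    invisible(path)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Run the end-to-end pipeline
#'
#' Simulate (unless reads are supplied) -> QC -> cluster -> place on
#' models -> filter -> cluster with references -> detect and classify
#' events -> characterize coding consequences, writing every stage table
#' under \code{outDir}. Deterministic under the configured seed.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if needed); \code{NULL} skips
#'   file output.
#' @param genome,models optional genome and transcript models; simulated
#'   when missing.
#' @param reads optional \code{QualityScaledDNAStringSet}; simulated when
#'   missing.
#' @return list with \code{summary}, \code{clusters}, \code{assets},
#'   \code{events}, \code{eventSummary}, \code{coding}, \code{truth} (when
#'   simulated), \code{score} (when truth is available).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL,
                        genome = NULL, models = NULL, reads = NULL) {
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    truth <- NULL; sim <- NULL
    if (is.null(genome) || is.null(models)) {
        gs <- simulateGeneSet(nGenes = config$nGenes, seed = config$seed)
        genome <- gs$genome; models <- gs$models; truth <- gs$truth
    }
    if (is.null(reads)) {
        sim <- simulateLibrary(models, genome, config$sim)
        reads <- sim$reads
    }
    if (length(reads) == 0L) {
        empty <- list(summary = data.frame(), clusters = list(),
                      assets = list(), events = .emptyEvents(),
                      eventSummary = summarizeEvents(.emptyEvents()),
                      coding = data.frame(), truth = truth, score = NULL)
        if (!is.null(outDir))
            writeLines("no reads survived; empty report",
                       file.path(outDir, "summary.txt"))
        return(empty)
    }
    cleaned <- qcReads(reads, config$qc)
    clusters <- clusterReads(cleaned, minOverlap = config$minOverlap,
                             minIdentity = config$minIdentityFrac)
    summary <- librarySummary("simulated", length(cleaned), clusters)

    placed <- alignToModels(consensusSet(clusters), models, genome)
    kept <- filterAlignments(placed$assets, config$minAlnIdentity,
                             config$minAlnCoverage)
    multi <- Filter(function(a) classifyExonCount(a) == "multi_exon", kept)
    intronless <- Filter(function(a) classifyExonCount(a) == "intronless",
                         kept)
    refClusters <- clusterWithReferences(kept, models)
    events <- detectEvents(refClusters, kept, models,
                           dedup = config$dedupEvents)
    evSummary <- summarizeEvents(events)
    coding <- do.call(rbind, lapply(
        Filter(function(m) nExons(m) >= 2L, models),
        function(m) codingAnnotation(m, genome, startCodon = 1L,
                                     ruleNt = config$nmdRuleNt)))
    score <- if (!is.null(truth)) scoreEventRecovery(events, truth) else NULL

    if (!is.null(outDir)) {
        .writeTsv(summary, file.path(outDir, "library_summary.tsv"))
        .writeTsv(evSummary$byType, file.path(outDir, "event_summary.tsv"))
        if (length(events))
            .writeTsv(as.data.frame(events), file.path(outDir, "events.tsv"))
        if (length(kept))
            .writeTsv(assetMetricsTable(kept),
                      file.path(outDir, "asset_metrics.tsv"))
        .writeTsv(coding, file.path(outDir, "coding_annotation.tsv"))
        if (!is.null(truth))
            .writeTsv(truth, file.path(outDir, "planted_truth.tsv"))
        lines <- c(
            sprintf("seed: %d", config$seed),
            sprintf("reads in: %d, surviving QC: %d", length(reads),
                    length(cleaned)),
            sprintf("consensus sequences: %d (%d contigs, %d singlets)",
                    summary$n_consensus, summary$n_contigs,
                    summary$n_singlets),
            sprintf("redundancy: %.2f%%", summary$redundancy),
            sprintf("aligned assets kept: %d (%d multi-exon, %d intronless)",
                    length(kept), length(multi), length(intronless)),
            sprintf("AS events: %d", evSummary$total),
            apply(evSummary$byType, 1L, function(r) sprintf(
                "  %s: %s (%s%%)", r[["type"]], r[["count"]],
                r[["percent"]])))
        if (!is.null(score))
            lines <- c(lines, sprintf("planted-event recall: %.3f",
                                      score$recall))
        writeLines(lines, file.path(outDir, "summary.txt"))
    }
    list(summary = summary, clusters = clusters, assets = kept,
         events = events, eventSummary = evSummary, coding = coding,
         truth = truth, score = score)
}
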