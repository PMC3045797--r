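#' @include AllClasses.R transcript-model.R
NULL

#' @rdname accessors
setMethod("assetId", "AlignedAsset", function(x) x@assetId)
#' @rdname accessors
setMethod("identityPct", "AlignedAsset", function(x)
    100 * x@matches / x@alignedLength)
#' @rdname accessors
setMethod("coveragePct", "AlignedAsset", function(x)
    100 * x@alignedLength / x@queryLength)
#' @rdname accessors
setMethod("nExons", "AlignedAsset", function(x) length(x@chain@exons))
#' @rdname accessors
setMethod("exonRanges", "AlignedAsset", function(x) x@chain@exons)

setMethod("show", "AlignedAsset", function(object) {
    cat(sprintf(
        "AlignedAsset %s: %s:%s, %d block(s), identity %.1f%%, coverage %.1f%%\n",
        object@assetId, object@chain@chrom, object@chain@strand,
        length(object@chain@exons), identityPct(object),
        coveragePct(object)))
})

.mergeAdjacentBlocks <- function(starts, widths) {
    # collapse target blocks separated by 0 nt (query-gap only) into exons
    keepS <- starts[1L]; keepE <- starts[1L] + widths[1L] - 1L
    outS <- integer(); outE <- integer()
    for (i in seq_along(starts)[-1L]) {
        if (starts[i] == keepE + 1L) {
            keepE <- starts[i] + widths[i] - 1L
        } else {
            outS <- c(outS, keepS); outE <- c(outE, keepE)
            keepS <- starts[i]; keepE <- starts[i] + widths[i] - 1L
        }
    }
    IRanges(c(outS, keepS), c(outE, keepE))
}

#' Read spliced alignments of consensus tags
#'
#' PSL (standard 21 columns, BLAT conventions: identity over aligned block
#' bases, coverage over the query length) or BED12 with a sidecar metrics
#' TSV (columns \code{name}, \code{matches}, \code{aligned_length},
#' \code{query_length}).
#'
#' @param path alignment file.
#' @param format \code{"psl"} or \code{"bed12"}.
#' @param metricsPath required for BED12: the sidecar metrics TSV.
#' @return list of \linkS4class{AlignedAsset}.
#' @export
readAlignments <- function(path, format = c("psl", "bed12"),
                           metricsPath = NULL) {
    format <- match.arg(format)
    if (format == "psl") {
        lines <- readLines(path)
        lines <- lines[grepl("^[0-9]", lines)]
        if (length(lines) == 0L) return(list())
        fields <- strsplit(lines, "\t", fixed = TRUE)
        lapply(fields, function(f) {
            if (length(f) < 21L)
                stop("malformed PSL record (", length(f), " fields)")
            blockSizes <- as.integer(strsplit(f[19L], ",")[[1L]])
            tStarts <- as.integer(strsplit(f[21L], ",")[[1L]])
            strand <- substr(f[9L], 1L, 1L)
            chain <- TranscriptModel(
                transcriptId = f[10L], geneId = f[10L], chrom = f[14L],
                strand = strand,
                exons = .mergeAdjacentBlocks(tStarts + 1L, blockSizes))
            AlignedAsset(assetId = f[10L], chain = chain,
                         matches = as.integer(f[1L]),
                         alignedLength = sum(blockSizes),
                         queryLength = as.integer(f[11L]))
        })
    } else {
        if (is.null(metricsPath))
            stop("BED12 alignments need a sidecar metrics TSV")
        chains <- readTranscriptModels(path, "bed12")
        metrics <- utils::read.delim(metricsPath)
        lapply(chains, function(ch) {
            row <- metrics[metrics$name == transcriptId(ch), , drop = FALSE]
            if (nrow(row) != 1L)
                stop("metrics missing for asset '", transcriptId(ch), "'")
            AlignedAsset(assetId = transcriptId(ch), chain = ch,
                         matches = row$matches,
                         alignedLength = row$aligned_length,
                         queryLength = row$query_length)
        })
    }
}

#' Select the best genomic hit per asset
#'
#' Maximal by (matches, identity, coverage) lexicographically -- match
#' count first, the BLAT-style default ranking -- with a deterministic
#' (chrom, start) tie-break.
#'
#' @param alignments list of \linkS4class{AlignedAsset} (>= 1), typically
#'   all hits of one asset.
#' @return the winning \linkS4class{AlignedAsset}.
#' @export
bestHit <- function(alignments) {
    if (length(alignments) == 0L) stop("no alignments")
    key <- vapply(alignments, function(a) c(
        -a@matches, -identityPct(a), -coveragePct(a)), numeric(3))
    chrom <- vapply(alignments, function(a) a@chain@chrom, character(1))
    st <- vapply(alignments, function(a) start(a@chain@exons)[1L], integer(1))
    o <- order(key[1L, ], key[2L, ], key[3L, ], chrom, st)
    alignments[[o[1L]]]
}

#' Filter alignments by identity and coverage
#'
#' Keeps assets with identity >= \code{minIdentity} and coverage >=
#' \code{minCoverage}, both inclusive (defaults 93 and 55 percent).
#' Idempotent and order-preserving.
#'
#' @param assets list of \linkS4class{AlignedAsset}.
#' @param minIdentity,minCoverage thresholds in percent.
#' @return the passing subset.
#' @export
filterAlignments <- function(assets, minIdentity = 93, minCoverage = 55) {
    keep <- vapply(assets, function(a)
        identityPct(a) >= minIdentity && coveragePct(a) >= minCoverage,
        logical(1))
    assets[keep]
}

#' Multi-exon vs intronless classification
#'
#' @param asset an \linkS4class{AlignedAsset}.
#' @return \code{"multi_exon"} when the alignment chain has >= 2 blocks,
#'   else \code{"intronless"}.
#' @export
classifyExonCount <- function(asset) {
    if (nExons(asset) >= 2L) "multi_exon" else "intronless"
}

#' Relative position profile of assets along their reference transcripts
#'
#' Each asset's covered transcript interval is rescaled to 0..100 in
#' transcription orientation (0 = 5' end, 100 = 3' end); the profile counts
#' assets covering each integer percentile.
#'
#' @param txIntervals data.frame with columns \code{start}, \code{end}
#'   (1-based transcript coordinates of the asset on its reference) and
#'   \code{length} (reference transcript length).
#' @return data.frame with columns \code{percentile} (0..100) and
#'   \code{count}.
#' @export
relativePositionProfile <- function(txIntervals) {
    counts <- integer(101L)
    for (i in seq_len(nrow(txIntervals))) {
        s <- txIntervals$start[i]; e <- txIntervals$end[i]
        L <- txIntervals$length[i]
        if (s < 1L || e > L || s > e)
            stop("asset interval outside its transcript (row ", i, ")")
        lo <- round(100 * s / L); hi <- round(100 * e / L)
        counts[(lo:hi) + 1L] <- counts[(lo:hi) + 1L] + 1L
    }
    data.frame(percentile = 0:100, count = counts)
}

#' Place consensus tags on transcript models
#'
#' A transcript-guided placement of consensus sequences: each consensus is
#' matched against the spliced sequence of every candidate model
#' (substitution-only matching, no indels), the best placement (fewest
#' mismatches) is kept, and the matched transcript interval is projected
#' through the exon map into a genomic alignment chain. This consumes
#' transcript models the way a spliced aligner's output would be consumed;
#' it is not a genome-scale aligner.
#'
#' @param consensi named \code{DNAStringSet} (or character vector) of
#'   consensus sequences.
#' @param models list of candidate \linkS4class{TranscriptModel}.
#' @param genome named \code{DNAStringSet}.
#' @param maxMismatchFrac maximum mismatch fraction tolerated in a
#'   placement (default 0.07, matching the 93\% identity floor).
#' @return list with \code{assets} (list of \linkS4class{AlignedAsset}),
#'   \code{placements} (data.frame: asset, model, tx_start, tx_end,
#'   mismatches).
#' @export
alignToModels <- function(consensi, models, genome, maxMismatchFrac = 0.07) {
    consensi <- DNAStringSet(consensi)
    if (is.null(names(consensi)))
        names(consensi) <- sprintf("asset%04d", seq_along(consensi))
    modelSeqs <- lapply(models, splicedSequence, genome = genome)
    assets <- list(); placements <- list()
    for (i in seq_along(consensi)) {
        cons <- consensi[[i]]
        L <- length(cons)
        maxMM <- as.integer(floor(maxMismatchFrac * L))
        best <- NULL
        for (j in seq_along(models)) {
            if (L > length(modelSeqs[[j]])) next
            m <- matchPattern(cons, modelSeqs[[j]], max.mismatch = maxMM,
                              with.indels = FALSE)
            if (length(m) == 0L) next
            mm <- Biostrings::neditStartingAt(cons, modelSeqs[[j]],
                                              starting.at = start(m),
                                              with.indels = FALSE)
            k <- which.min(mm)
            if (is.null(best) || mm[k] < best$mm)
                best <- list(j = j, at = start(m)[k], mm = mm[k])
        }
        if (is.null(best)) next
        model <- models[[best$j]]
        chain <- projectToGenome(model, best$at, best$at + L - 1L)
        chain@transcriptId <- names(consensi)[i]
        assets[[length(assets) + 1L]] <- AlignedAsset(
            assetId = names(consensi)[i], chain = chain,
            matches = L - best$mm, alignedLength = L, queryLength = L)
        placements[[length(placements) + 1L]] <- data.frame(
            asset = names(consensi)[i],
            model = transcriptId(model),
            tx_start = best$at, tx_end = best$at + L - 1L,
            mismatches = best$mm)
    }
    list(assets = assets,
         placements = if (length(placements)) do.call(rbind, placements)
                      else data.frame(asset = character(),
                                      model = character(),
                                      tx_start = integer(),
                                      tx_end = integer(),
                                      mismatches = integer()))
}

#' Project a transcript-coordinate interval to a genomic exon chain
#'
#' @param model a \linkS4class{TranscriptModel}.
#' @param txStart,txEnd 1-based transcript coordinates (transcription
#'   orientation).
#' @return a \linkS4class{TranscriptModel} whose exons are the genomic
#'   blocks covered by the interval (gene id inherited from \code{model}).
#' @export
projectToGenome <- function(model, txStart, txEnd) {
    if (txStart < 1L || txEnd > txLength(model) || txStart > txEnd)
        stop("interval outside transcript '", transcriptId(model), "'")
    pos <- sort(.genomicPositions(model)[txStart:txEnd])
    gap <- which(diff(pos) > 1L)
    starts <- pos[c(1L, gap + 1L)]
    ends <- pos[c(gap, length(pos))]
    TranscriptModel(paste0(transcriptId(model), "_sub"), geneId(model),
                    chromName(model), strandOf(model),
                    IRanges(starts, ends))
}

#' Per-asset alignment metrics table
#'
#' @param assets list of \linkS4class{AlignedAsset}.
#' @return data.frame: asset, chrom, strand, start, end, n_exons, matches,
#'   aligned_length, query_length, identity, coverage, exon_class.
#' @export
assetMetricsTable <- function(assets) {
    do.call(rbind, lapply(assets, function(a) data.frame(
        asset = a@assetId, chrom = a@chain@chrom, strand = a@chain@strand,
        start = start(a@chain@exons)[1L], end = max(end(a@chain@exons)),
        n_exons = nExons(a), matches = a@matches,
        aligned_length = a@alignedLength, query_length = a@queryLength,
        identity = identityPct(a), coverage = coveragePct(a),
        exon_class = classifyExonCount(a))))
}
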