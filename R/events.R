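#' @include AllClasses.R alignment.R
#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges overlapsAny
NULL

.chainOf <- function(x) {
    if (is(x, "AlignedAsset")) x@chain
    else if (is(x, "TranscriptModel")) x
    else stop("expected a TranscriptModel or AlignedAsset")
}

#' Cluster assets with reference transcripts by exonic genomic overlap
#'
#' Single-linkage: two members (asset chains or reference transcripts) are
#' linked when any of their exons overlap by at least 1 nt on the same
#' chromosome and strand; clusters are the connected components. Each
#' cluster is annotated with whether it contains a reference transcript.
#'
#' @param assets list of \linkS4class{AlignedAsset}.
#' @param references list of \linkS4class{TranscriptModel}.
#' @return list of \linkS4class{AssetCluster}; members without any overlap
#'   partner form their own cluster.
#' @export
clusterWithReferences <- function(assets, references) {
    chains <- c(lapply(assets, .chainOf), references)
    kinds <- c(rep("asset", length(assets)), rep("reference",
                                                 length(references)))
    ids <- c(vapply(assets, assetId, character(1)),
             vapply(references, transcriptId, character(1)))
    n <- length(chains)
    if (n == 0L) return(list())
    exGr <- do.call(c, lapply(seq_len(n), function(i) {
        ch <- chains[[i]]
        GRanges(ch@chrom, ch@exons, strand = ch@strand, member = i)
    }))
    hits <- findOverlaps(exGr, exGr, minoverlap = 1L, ignore.strand = FALSE)
    # union-find over members
    parent <- seq_len(n)
    findRoot <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    mi <- S4Vectors::mcols(exGr)$member
    for (h in seq_along(hits)) {
        a <- mi[S4Vectors::queryHits(hits)[h]]
        b <- mi[S4Vectors::subjectHits(hits)[h]]
        ra <- findRoot(a); rb <- findRoot(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(n), findRoot, integer(1))
    comp <- split(seq_len(n), roots)
    out <- list(); ci <- 0L
    for (members in comp) {
        isAsset <- kinds[members] == "asset"
        if (!any(isAsset)) next   # reference-only components are not clusters
        ci <- ci + 1L
        spans <- vapply(members, function(i)
            c(start(chains[[i]]@exons)[1L], max(end(chains[[i]]@exons))),
            integer(2))
        out[[ci]] <- new("AssetCluster",
            clusterId = sprintf("ac%04d", ci),
            assetIds = ids[members][isAsset],
            referenceIds = ids[members][!isAsset],
            chrom = chains[[members[1L]]]@chrom,
            strand = chains[[members[1L]]]@strand,
            span = IRanges(min(spans[1L, ]), max(spans[2L, ])),
            hasReference = any(!isAsset))
    }
    out
}

#' Comparison window between two exon chains
#'
#' The genomic interval from the start of the 5'-most exonic overlap
#' between the two chains to the end of the 3'-most exonic overlap; event
#' search is confined to this window.
#'
#' @param chainA,chainB \linkS4class{TranscriptModel}s on the same
#'   chromosome and strand.
#' @return an \code{IRanges} of length 1.
#' @export
comparisonWindow <- function(chainA, chainB) {
    chainA <- .chainOf(chainA); chainB <- .chainOf(chainB)
    if (chainA@chrom != chainB@chrom || chainA@strand != chainB@strand)
        stop("chains on different chromosomes or strands")
    ov <- IRanges::intersect(chainA@exons, chainB@exons)
    if (length(ov) == 0L)
        stop("chains have no exonic overlap")
    IRanges(min(start(ov)), max(end(ov)))
}

.donorAcceptor <- function(intronStart, intronEnd, strand) {
    # strand-normalized boundary roles: donor is the transcription-5' side
    if (strand == "+") c(donor = intronStart, acceptor = intronEnd)
    else c(donor = intronEnd, acceptor = intronStart)
}

.insideWindow <- function(ir, window) {
    start(ir) >= start(window) & end(ir) <= end(window)
}

.emptyEvents <- function() {
    gr <- GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        type = character(), size = integer(), assetId = character(),
        referenceId = character(), geneId = character())
    gr
}

#' Classify alternative-splicing events between two exon chains
#'
#' Pairwise comparison of exon/intron boundaries inside the comparison
#' window, after strand normalization of donor/acceptor roles:
#' \itemize{
#'   \item identical introns: no event;
#'   \item shared acceptor, different donor: \code{alt_5ss}, size = donor
#'     shift, coordinates = the inter-donor interval;
#'   \item shared donor, different acceptor: \code{alt_3ss} analogously;
#'   \item an intron of one chain strictly inside a single exon of the
#'     other: \code{intron_retention}, size = intron length;
#'   \item one or more complete exons of one chain strictly inside a single
#'     intron of the other, that intron's ends matching the flanking
#'     introns' outer boundaries: \code{exon_skipping}, size = summed
#'     skipped exon length; the alt-site comparisons it explains are
#'     suppressed.
#' }
#' Events are deduplicated by (type, coordinates); the function is
#' symmetric in its two arguments.
#'
#' @param chainA,chainB \linkS4class{TranscriptModel}s (or
#'   \linkS4class{AlignedAsset}s) on one chromosome and strand.
#' @param window optional \code{IRanges}; defaults to
#'   \code{comparisonWindow(chainA, chainB)}.
#' @param dedup deduplicate by (type, coords); default TRUE.
#' @return a \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{type}, \code{size}, \code{assetId}, \code{referenceId},
#'   \code{geneId}.
#' @export
classifyEvents <- function(chainA, chainB, window = NULL, dedup = TRUE) {
    A <- .chainOf(chainA); B <- .chainOf(chainB)
    if (A@chrom != B@chrom || A@strand != B@strand)
        stop("chains on different chromosomes or strands")
    if (is.null(window)) window <- comparisonWindow(A, B)
    strand <- A@strand
    intronsA <- intronRanges(A); intronsB <- intronRanges(B)
    inA <- which(.insideWindow(intronsA, window))
    inB <- which(.insideWindow(intronsB, window))
    ev <- list()
    addEvent <- function(type, s, e, size) {
        ev[[length(ev) + 1L]] <<- data.frame(type = type, start = s,
                                             end = e, size = size)
    }
    consumed <- character()   # "aIdx:bIdx" intron pairs explained by skipping

    skipScan <- function(hostIntrons, hostIn, otherEx, otherIntrons,
                         hostIsA) {
        for (hi in hostIn) {
            I <- hostIntrons[hi]
            inside <- which(start(otherEx) > start(I) &
                            end(otherEx) < end(I))
            if (length(inside) == 0L) next
            first <- min(inside); last <- max(inside)
            up <- first - 1L; down <- last
            if (up < 1L || down > length(otherIntrons)) next
            if (start(otherIntrons)[up] != start(I) ||
                end(otherIntrons)[down] != end(I)) next
            addEvent("exon_skipping", start(otherEx)[first],
                     end(otherEx)[last], sum(width(otherEx[inside])))
            for (oi in c(up, down))
                consumed <<- c(consumed,
                    if (hostIsA) paste0(hi, ":", oi)
                    else paste0(oi, ":", hi))
        }
    }
    skipScan(intronsA, inA, B@exons, intronsB, hostIsA = TRUE)
    skipScan(intronsB, inB, A@exons, intronsA, hostIsA = FALSE)

    retScan <- function(hostIntrons, hostIn, otherEx) {
        for (hi in hostIn) {
            I <- hostIntrons[hi]
            if (any(start(otherEx) < start(I) & end(I) < end(otherEx)))
                addEvent("intron_retention", start(I), end(I), width(I))
        }
    }
    retScan(intronsA, inA, B@exons)
    retScan(intronsB, inB, A@exons)

    for (ia in inA) for (ib in inB) {
        if (paste0(ia, ":", ib) %in% consumed) next
        sA <- start(intronsA)[ia]; eA <- end(intronsA)[ia]
        sB <- start(intronsB)[ib]; eB <- end(intronsB)[ib]
        if (sA == sB && eA == eB) next
        daA <- .donorAcceptor(sA, eA, strand)
        daB <- .donorAcceptor(sB, eB, strand)
        if (daA["acceptor"] == daB["acceptor"] &&
            daA["donor"] != daB["donor"]) {
            d <- sort(c(daA["donor"], daB["donor"]))
            size <- d[2L] - d[1L]
            if (strand == "+") addEvent("alt_5ss", d[1L], d[2L] - 1L, size)
            else addEvent("alt_5ss", d[1L] + 1L, d[2L], size)
        } else if (daA["donor"] == daB["donor"] &&
                   daA["acceptor"] != daB["acceptor"]) {
            a <- sort(c(daA["acceptor"], daB["acceptor"]))
            size <- a[2L] - a[1L]
            if (strand == "+") addEvent("alt_3ss", a[1L] + 1L, a[2L], size)
            else addEvent("alt_3ss", a[1L], a[2L] - 1L, size)
        }
    }

    if (length(ev) == 0L)
        return(.emptyEvents())
    df <- do.call(rbind, ev)
    if (dedup)
        df <- df[!duplicated(df[, c("type", "start", "end")]), , drop = FALSE]
    gr <- GRanges(A@chrom, IRanges(df$start, df$end), strand = strand)
    S4Vectors::mcols(gr)$type <- df$type
    S4Vectors::mcols(gr)$size <- as.integer(df$size)
    S4Vectors::mcols(gr)$assetId <- transcriptId(A)
    S4Vectors::mcols(gr)$referenceId <- transcriptId(B)
    S4Vectors::mcols(gr)$geneId <- geneId(A)
    gr
}

#' Detect events for every asset against every reference in its cluster
#'
#' Multi-exon assets only (intronless chains carry no splice-site
#' direction); events are deduplicated by (type, coords) within a cluster.
#'
#' @param clusters list of \linkS4class{AssetCluster}.
#' @param assets list of \linkS4class{AlignedAsset}.
#' @param references list of \linkS4class{TranscriptModel}.
#' @param dedup deduplicate within each cluster; default TRUE.
#' @return a \code{GRanges} of events (possibly empty).
#' @export
detectEvents <- function(clusters, assets, references, dedup = TRUE) {
    assetById <- setNames(assets, vapply(assets, assetId, character(1)))
    refById <- setNames(references,
                        vapply(references, transcriptId, character(1)))
    all <- list()
    for (cl in clusters) {
        clEv <- list()
        for (aid in cl@assetIds) {
            a <- assetById[[aid]]
            if (nExons(a) < 2L) next
            for (rid in cl@referenceIds) {
                r <- refById[[rid]]
                ov <- IRanges::intersect(a@chain@exons, r@exons)
                if (length(ov) == 0L) next
                e <- classifyEvents(a, r, dedup = dedup)
                if (length(e)) clEv[[length(clEv) + 1L]] <- e
            }
        }
        if (length(clEv) == 0L) next
        gr <- do.call(c, clEv)
        if (dedup) {
            key <- paste(S4Vectors::mcols(gr)$type, start(gr), end(gr))
            gr <- gr[!duplicated(key)]
        }
        all[[length(all) + 1L]] <- gr
    }
    if (length(all) == 0L)
        return(.emptyEvents())
    suppressWarnings(do.call(c, all))
}

#' Summarize detected events
#'
#' Counts and one-decimal percentages by event type, per-asset event
#' counts, and the number of assets with at least one event.
#'
#' @param events \code{GRanges} from \code{\link{detectEvents}} or
#'   \code{\link{classifyEvents}}, or a named count vector.
#' @return list with \code{byType} (data.frame: type, count, percent),
#'   \code{perAsset} (data.frame) and \code{nAssetsWithEvents}.
#' @export
summarizeEvents <- function(events) {
    typeOrder <- c("exon_skipping", "intron_retention", "alt_5ss", "alt_3ss")
    if (is.numeric(events)) {
        counts <- events[typeOrder]
        counts[is.na(counts)] <- 0L
        names(counts) <- typeOrder
        perAsset <- data.frame(asset = character(), n_events = integer())
    } else {
        types <- S4Vectors::mcols(events)$type
        counts <- vapply(typeOrder, function(t) sum(types == t), numeric(1))
        tab <- table(S4Vectors::mcols(events)$assetId)
        perAsset <- data.frame(asset = names(tab),
                               n_events = as.integer(tab))
    }
    total <- sum(counts)
    pct <- if (total > 0) percentOf(counts, total) else rep(0, length(counts))
    list(byType = data.frame(type = typeOrder,
                             count = as.integer(counts),
                             percent = as.numeric(pct)),
         perAsset = perAsset,
         nAssetsWithEvents = nrow(perAsset),
         total = as.integer(total))
}

#' Fraction of intronless assets overlapping known AS event regions
#'
#' @param intronlessAssets list of \linkS4class{AlignedAsset} with
#'   single-block chains (spans are used).
#' @param eventRegions \code{GRanges} of known event coordinates.
#' @return percent (one decimal) of assets whose span intersects any event.
#' @examples
#' # 63 of 96 spans overlapping -> 65.6
#' @export
flagIntronlessOverlap <- function(intronlessAssets, eventRegions) {
    if (length(intronlessAssets) == 0L) return(0)
    spans <- do.call(c, lapply(intronlessAssets, function(a)
        GRanges(a@chain@chrom,
                IRanges(start(a@chain@exons)[1L], max(end(a@chain@exons))))))
    hit <- overlapsAny(spans, eventRegions, ignore.strand = TRUE)
    percentOf(sum(hit), length(intronlessAssets))
}

#' Score detected events against the simulator's planted truth
#'
#' A planted event is recovered when a detected event of the same type
#' overlaps its genomic region. Type precision is the fraction of detected
#' events whose type and coordinates agree with some planted event.
#'
#' @param events \code{GRanges} of detected events.
#' @param truth data.frame from \code{\link{simulateGeneSet}}.
#' @return list with \code{recall}, \code{typePrecision}, \code{byType}
#'   (data.frame of planted/recovered counts).
#' @export
scoreEventRecovery <- function(events, truth) {
    truthGr <- GRanges(truth$chrom, IRanges(truth$start, truth$end))
    recovered <- logical(nrow(truth))
    evTypes <- S4Vectors::mcols(events)$type
    for (i in seq_len(nrow(truth))) {
        same <- which(evTypes == truth$type[i])
        if (length(same))
            recovered[i] <- any(overlapsAny(truthGr[i], events[same],
                                            ignore.strand = TRUE))
    }
    matched <- logical(length(events))
    for (j in seq_along(events)) {
        same <- which(truth$type == evTypes[j])
        if (length(same))
            matched[j] <- any(overlapsAny(events[j], truthGr[same],
                                          ignore.strand = TRUE))
    }
    byType <- do.call(rbind, lapply(split(seq_len(nrow(truth)), truth$type),
        function(idx) data.frame(type = truth$type[idx[1L]],
                                 planted = length(idx),
                                 recovered = sum(recovered[idx]))))
    list(recall = mean(recovered),
         typePrecision = if (length(events)) mean(matched) else NA_real_,
         byType = byType)
}
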