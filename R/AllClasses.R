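#' @import methods
#' @importFrom IRanges IRanges start end width "start<-" "end<-" "width<-"
#' @importFrom S4Vectors isSorted
NULL

#' TranscriptModel: a strand-aware ordered exon chain
#'
#' The universal currency of the package: splice variants, reference
#' transcripts and spliced alignments of consensus tags are all represented
#' as an ordered chain of exons on one chromosome and strand. Exons are
#' stored as 1-based closed \linkS4class{IRanges} in genomic order;
#' transcription order is derived from the strand.
#'
#' @slot transcriptId transcript identifier.
#' @slot geneId gene identifier (equal to \code{transcriptId} when unknown).
#' @slot chrom chromosome name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons \code{IRanges} of exons, sorted by start, non-overlapping,
#'   separated by at least 1 nt.
#'
#' @examples
#' tx <- TranscriptModel("tx1", "geneA", "chr1", "+",
#'                       IRanges::IRanges(start = c(1, 201), end = c(100, 300)))
#' txLength(tx)
#' intronRanges(tx)
#' @name TranscriptModel-class
#' @aliases TranscriptModel-class
#' @exportClass TranscriptModel
setClass("TranscriptModel",
    representation(
        transcriptId = "character",
        geneId       = "character",
        chrom        = "character",
        strand       = "character",
        exons        = "IRanges"
    )
)

setValidity("TranscriptModel", function(object) {
    msg <- character()
    if (length(object@transcriptId) != 1L || !nzchar(object@transcriptId))
        msg <- c(msg, "'transcriptId' must be a single non-empty string")
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "'strand' must be '+' or '-'")
    ex <- object@exons
    if (length(ex) == 0L)
        msg <- c(msg, "a transcript must have at least one exon")
    if (length(ex) >= 1L && any(start(ex) < 1L))
        msg <- c(msg, "exon starts must be >= 1")
    if (length(ex) >= 2L) {
        if (is.unsorted(start(ex)))
            msg <- c(msg, "exons must be sorted by start")
        gap <- start(ex)[-1L] - end(ex)[-length(ex)] - 1L
        if (any(gap < 1L))
            msg <- c(msg, "exons must be non-overlapping with introns of positive length")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TranscriptModel
#'
#' @param transcriptId,geneId,chrom,strand,exons see
#'   \linkS4class{TranscriptModel}.
#' @return a \linkS4class{TranscriptModel}.
#' @export
TranscriptModel <- function(transcriptId, geneId = transcriptId, chrom,
                            strand, exons) {
    new("TranscriptModel",
        transcriptId = as.character(transcriptId),
        geneId = as.character(geneId), chrom = as.character(chrom),
        strand = as.character(strand), exons = exons)
}

#' Simulation parameters for the heteroduplex-trapping library
#'
#' Defaults encode the study conditions the simulator reproduces:
#' PCR redundancy targets a mean of 6.6 reads per distinct captured fragment
#' (a library-level redundancy near 85\%), capture of loop-less fragments
#' leaks at 5\%, substitution errors at 1e-3 per base, and loop capture
#' requires at least 25 nt of single strand (the annealing length of the
#' random biotinylated 25-mer).
#'
#' @slot seed integer seed; every stochastic stage derives its stream from it.
#' @slot abundanceMeanlog,abundanceSdlog log-normal abundance model
#'   (copies per variant).
#' @slot pcrRedundancy target mean reads per distinct captured fragment
#'   (dimensionless, >= 1).
#' @slot captureNoise probability a loop-less fragment is captured anyway.
#' @slot readErrorRate per-base substitution probability.
#' @slot qualMean,qualSd Phred quality model for emitted reads.
#' @slot minLoop minimum single-strand loop length (nt) for capture.
#' @name SimulationParams-class
#' @aliases SimulationParams-class
#' @exportClass SimulationParams
setClass("SimulationParams",
    representation(
        seed            = "integer",
        abundanceMeanlog = "numeric",
        abundanceSdlog  = "numeric",
        pcrRedundancy   = "numeric",
        captureNoise    = "numeric",
        readErrorRate   = "numeric",
        qualMean        = "numeric",
        qualSd          = "numeric",
        minLoop         = "integer"
    ),
    prototype(
        seed = 1L, abundanceMeanlog = log(50), abundanceSdlog = 1,
        pcrRedundancy = 6.6, captureNoise = 0.05, readErrorRate = 0.001,
        qualMean = 30, qualSd = 3, minLoop = 25L
    )
)

setValidity("SimulationParams", function(object) {
    msg <- character()
    probs <- c(object@captureNoise, object@readErrorRate)
    if (any(probs < 0 | probs > 1))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (object@pcrRedundancy < 1)
        msg <- c(msg, "'pcrRedundancy' must be >= 1")
    if (object@abundanceSdlog < 0)
        msg <- c(msg, "'abundanceSdlog' must be >= 0")
    if (object@minLoop < 1L)
        msg <- c(msg, "'minLoop' must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct SimulationParams
#'
#' @param seed integer seed.
#' @param abundanceMeanlog,abundanceSdlog log-normal abundance model.
#' @param pcrRedundancy target mean reads per captured fragment.
#' @param captureNoise capture probability for loop-less fragments.
#' @param readErrorRate per-base substitution rate.
#' @param qualMean,qualSd Phred quality model.
#' @param minLoop minimum loop length (nt) for capture.
#' @return a \linkS4class{SimulationParams}.
#' @export
simParams <- function(seed = 1L, abundanceMeanlog = log(50),
                      abundanceSdlog = 1, pcrRedundancy = 6.6,
                      captureNoise = 0.05, readErrorRate = 0.001,
                      qualMean = 30, qualSd = 3, minLoop = 25L) {
    new("SimulationParams", seed = as.integer(seed),
        abundanceMeanlog = abundanceMeanlog, abundanceSdlog = abundanceSdlog,
        pcrRedundancy = pcrRedundancy, captureNoise = captureNoise,
        readErrorRate = readErrorRate, qualMean = qualMean, qualSd = qualSd,
        minLoop = as.integer(minLoop))
}

#' DuplexRecord: one simulated heteroduplex fragment
#'
#' A DpnII fragment of a heteroduplex formed by two splice variants of the
#' same gene, read in the transcript coordinates of \code{variantA}. Loop
#' intervals mark the positions of \code{variantA} that are absent from
#' \code{variantB} (single-stranded in the duplex) -- the enrichment target.
#'
#' @slot geneId gene of the two variants.
#' @slot variantA,variantB transcript ids of the two annealed variants;
#'   fragment and loop coordinates are in variantA's transcript space.
#' @slot fragment one \code{IRanges} interval (the fragment).
#' @slot loopIntervals \code{IRanges} of variant-discordant (single-strand)
#'   positions inside the fragment.
#' @slot weight pairing weight, proportional to the product of the two
#'   variant abundances.
#' @slot captured whether the fragment was bead-captured.
#' @name DuplexRecord-class
#' @aliases DuplexRecord-class
#' @exportClass DuplexRecord
setClass("DuplexRecord",
    representation(
        geneId        = "character",
        variantA      = "character",
        variantB      = "character",
        fragment      = "IRanges",
        loopIntervals = "IRanges",
        weight        = "numeric",
        captured      = "logical"
    ),
    prototype(weight = 1, captured = NA)
)

setValidity("DuplexRecord", function(object) {
    msg <- character()
    if (length(object@fragment) != 1L)
        msg <- c(msg, "'fragment' must be a single interval")
    if (identical(object@variantA, object@variantB))
        msg <- c(msg, "a heteroduplex needs two distinct variants")
    if (length(object@loopIntervals) &&
        (any(start(object@loopIntervals) < start(object@fragment)) ||
         any(end(object@loopIntervals) > end(object@fragment))))
        msg <- c(msg, "loop intervals must lie within the fragment")
    if (length(msg)) msg else TRUE
})

#' Quality-control parameters for windowed read trimming
#'
#' The trimming rule keeps the longest run of consecutive 20-nt windows in
#' which at least 15 bases reach Phred 20; reads shorter than
#' \code{minLength} after trimming are discarded.
#'
#' @slot window window width (nt).
#' @slot minGood minimum number of bases at or above \code{minQuality}
#'   per window.
#' @slot minQuality Phred threshold.
#' @slot minLength minimum surviving read length.
#' @name QCParams-class
#' @aliases QCParams-class
#' @exportClass QCParams
setClass("QCParams",
    representation(window = "integer", minGood = "integer",
                   minQuality = "integer", minLength = "integer"),
    prototype(window = 20L, minGood = 15L, minQuality = 20L, minLength = 50L)
)

setValidity("QCParams", function(object) {
    if (object@minGood > object@window)
        "'minGood' cannot exceed 'window'"
    else TRUE
})

#' Construct QCParams
#'
#' @param window,minGood,minQuality,minLength see \linkS4class{QCParams}.
#' @return a \linkS4class{QCParams}.
#' @export
qcParams <- function(window = 20L, minGood = 15L, minQuality = 20L,
                     minLength = 50L) {
    new("QCParams", window = as.integer(window), minGood = as.integer(minGood),
        minQuality = as.integer(minQuality), minLength = as.integer(minLength))
}

#' AlignedAsset: a consensus tag with its best spliced alignment
#'
#' Couples a consensus sequence (an "ASSET": alternative splicing
#' sequence-enriched tag) with its genomic alignment chain and the metrics
#' used for filtering: identity = 100 * matches / alignedLength and
#' coverage = 100 * alignedLength / queryLength.
#'
#' @slot assetId consensus identifier.
#' @slot chain alignment blocks as a \linkS4class{TranscriptModel}.
#' @slot matches matching bases.
#' @slot alignedLength aligned query bases (excluding query gaps).
#' @slot queryLength consensus length (nt).
#' @name AlignedAsset-class
#' @aliases AlignedAsset-class
#' @exportClass AlignedAsset
setClass("AlignedAsset",
    representation(
        assetId       = "character",
        chain         = "TranscriptModel",
        matches       = "integer",
        alignedLength = "integer",
        queryLength   = "integer"
    )
)

setValidity("AlignedAsset", function(object) {
    msg <- character()
    if (object@alignedLength < object@matches)
        msg <- c(msg, "'matches' cannot exceed 'alignedLength'")
    if (object@queryLength < object@alignedLength)
        msg <- c(msg, "'alignedLength' cannot exceed 'queryLength'")
    if (length(msg)) msg else TRUE
})

#' Construct an AlignedAsset
#'
#' @param assetId consensus identifier.
#' @param chain alignment chain (\linkS4class{TranscriptModel}).
#' @param matches,alignedLength,queryLength alignment metrics.
#' @return an \linkS4class{AlignedAsset}.
#' @export
AlignedAsset <- function(assetId, chain, matches, alignedLength, queryLength) {
    new("AlignedAsset", assetId = as.character(assetId), chain = chain,
        matches = as.integer(matches), alignedLength = as.integer(alignedLength),
        queryLength = as.integer(queryLength))
}

#' AssetCluster: assets grouped with reference transcripts by exonic overlap
#'
#' @slot clusterId cluster identifier.
#' @slot assetIds member asset ids.
#' @slot referenceIds member reference transcript ids.
#' @slot chrom,strand location of the cluster.
#' @slot span genomic span (\code{IRanges} of length 1).
#' @slot hasReference whether a curated reference transcript is a member.
#' @name AssetCluster-class
#' @aliases AssetCluster-class
#' @exportClass AssetCluster
setClass("AssetCluster",
    representation(
        clusterId    = "character",
        assetIds     = "character",
        referenceIds = "character",
        chrom        = "character",
        strand       = "character",
        span         = "IRanges",
        hasReference = "logical"
    )
)

setValidity("AssetCluster", function(object) {
    if (length(object@assetIds) < 1L)
        "a cluster must contain at least one asset"
    else TRUE
})
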