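#' @include AllClasses.R
NULL

#' Accessors for TranscriptModel and AlignedAsset
#'
#' @param x a \linkS4class{TranscriptModel} or \linkS4class{AlignedAsset}.
#' @return \code{transcriptId}, \code{geneId}, \code{chromName},
#'   \code{strandOf}: character scalars. \code{exonRanges},
#'   \code{intronRanges}: \code{IRanges}. \code{nExons}, \code{txLength}:
#'   integers. \code{assetId}: character. \code{identityPct},
#'   \code{coveragePct}: percentages.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))
#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))
#' @rdname accessors
#' @export
setGeneric("strandOf", function(x) standardGeneric("strandOf"))
#' @rdname accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname accessors
#' @export
setGeneric("intronRanges", function(x) standardGeneric("intronRanges"))
#' @rdname accessors
#' @export
setGeneric("nExons", function(x) standardGeneric("nExons"))
#' @rdname accessors
#' @export
setGeneric("txLength", function(x) standardGeneric("txLength"))
#' @rdname accessors
#' @export
setGeneric("assetId", function(x) standardGeneric("assetId"))
#' @rdname accessors
#' @export
setGeneric("identityPct", function(x) standardGeneric("identityPct"))
#' @rdname accessors
#' @export
setGeneric("coveragePct", function(x) standardGeneric("coveragePct"))

#' Spliced sequence of an exon chain
#'
#' Concatenates exon sequences in transcription order; minus-strand models
#' are reverse-complemented, so the result always reads 5' to 3' of the
#' transcript.
#'
#' @param x a \linkS4class{TranscriptModel}.
#' @param genome a named \link[Biostrings]{DNAStringSet}.
#' @return a \link[Biostrings]{DNAString}.
#' @export
setGeneric("splicedSequence", function(x, genome)
    standardGeneric("splicedSequence"))

#' Splice-site dinucleotides of every intron
#'
#' Per intron, the donor is the first two intronic bases at the
#' transcription-5' end and the acceptor the last two at the
#' transcription-3' end; on the minus strand both are reverse-complemented
#' (so the canonical pair always reads GT/AG). Introns shorter than 4 nt
#' are flagged invalid.
#'
#' @param x a \linkS4class{TranscriptModel}.
#' @param genome a named \link[Biostrings]{DNAStringSet}.
#' @return a data.frame with columns \code{donor}, \code{acceptor},
#'   \code{canonical}, \code{valid}, one row per intron.
#' @export
setGeneric("spliceDinucleotides", function(x, genome)
    standardGeneric("spliceDinucleotides"))
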