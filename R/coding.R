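#' @include transcript-model.R
NULL

.STOPS <- c("TAA", "TAG", "TGA")

#' Scan for the first in-frame stop codon
#'
#' Codon-by-codon scan of the spliced sequence from an annotated
#' translation initiation site (which must be ATG).
#'
#' @param variant a \linkS4class{TranscriptModel}.
#' @param genome named \code{DNAStringSet}.
#' @param startCodon 1-based transcript coordinate of the A of the start
#'   ATG (transcription orientation).
#' @return 1-based transcript coordinate of the first base of the first
#'   in-frame stop codon, or \code{NA} when the frame runs off the
#'   transcript without a stop.
#' @export
findStop <- function(variant, genome, startCodon = 1L) {
    seq <- as.character(splicedSequence(variant, genome))
    L <- nchar(seq)
    if (startCodon < 1L || startCodon + 2L > L)
        stop("start codon outside transcript")
    if (substr(seq, startCodon, startCodon + 2L) != "ATG")
        stop("annotated start is not ATG")
    at <- startCodon
    while (at + 2L <= L) {
        if (substr(seq, at, at + 2L) %in% .STOPS) return(at)
        at <- at + 3L
    }
    NA_integer_
}

#' Distance from a stop codon to the last exon-exon junction
#'
#' Positive when the stop ends upstream of the final junction (the
#' premature-termination geometry that licenses nonsense-mediated decay),
#' negative when downstream, zero when the stop ends exactly at the
#' junction. Undefined for single-exon transcripts.
#'
#' @param stopAt 1-based transcript coordinate of the stop codon's first
#'   base (from \code{\link{findStop}}).
#' @param variant a \linkS4class{TranscriptModel} with >= 2 exons.
#' @return distance in nt.
#' @export
ptcDistance <- function(stopAt, variant) {
    if (nExons(variant) < 2L)
        stop("PTC distance is undefined for single-exon transcripts")
    widths <- width(exonRanges(variant))
    if (strandOf(variant) == "-") widths <- rev(widths)
    lastJunction <- sum(widths[-length(widths)])
    stopEnd <- stopAt + 2L
    lastJunction - stopEnd
}

#' The 50-nt rule for nonsense-mediated decay candidacy
#'
#' @param distance nt from the stop codon's end to the last exon-exon
#'   junction (positive = upstream).
#' @param ruleNt boundary, default 50; the test is strict
#'   (\code{distance > ruleNt}).
#' @return logical flag.
#' @examples
#' nmdCandidate(96)  # TRUE
#' nmdCandidate(50)  # FALSE
#' @export
nmdCandidate <- function(distance, ruleNt = 50) {
    distance > ruleNt
}

#' Coding annotation of a splice variant
#'
#' Stop scan, PTC distance and NMD candidacy in one report row.
#'
#' @param variant a \linkS4class{TranscriptModel}.
#' @param genome named \code{DNAStringSet}.
#' @param startCodon 1-based transcript coordinate of the start ATG.
#' @param ruleNt NMD boundary, default 50.
#' @return one-row data.frame: transcript_id, start_codon, stop, has_stop,
#'   ptc_distance, nmd_candidate (distance fields NA for single-exon
#'   transcripts or stop-less frames).
#' @export
codingAnnotation <- function(variant, genome, startCodon = 1L, ruleNt = 50) {
    stopAt <- findStop(variant, genome, startCodon)
    multi <- nExons(variant) >= 2L
    dist <- if (!is.na(stopAt) && multi) ptcDistance(stopAt, variant)
            else NA_integer_
    data.frame(
        transcript_id = transcriptId(variant),
        start_codon = startCodon,
        stop = stopAt,
        has_stop = !is.na(stopAt),
        ptc_distance = dist,
        nmd_candidate = if (is.na(dist)) NA else nmdCandidate(dist, ruleNt))
}
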