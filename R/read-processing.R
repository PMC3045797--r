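#' @include AllClasses.R utils.R
#' @importFrom Biostrings pairwiseAlignment nmatch nmismatch quality
#'   BStringSet subseq
NULL

.phredInts <- function(qreads) {
    # integer Phred scores per read from a QualityScaledDNAStringSet
    lapply(as.character(quality(qreads)), function(q)
        as.integer(charToRaw(q)) - 33L)
}

.vectorArm <- function(piece, vectorSeq) {
    # does this read end occur in the vector, allowing 1 mismatch / 20 nt?
    length(Biostrings::matchPattern(piece, vectorSeq,
                                    max.mismatch = nchar(piece) %/% 20L,
                                    with.indels = FALSE)) > 0L
}

#' Trim cloning-vector sequence from read ends
#'
#' Removes the maximal read prefix and the maximal read suffix that occur
#' in the vector sequence, allowing one mismatch per 20 nt of matched
#' length (the two vector arms flanking the insert). A read that is
#' entirely vector becomes empty and is dropped downstream. Matches
#' shorter than \code{minArm} are ignored (too short to be credible
#' vector).
#'
#' @param read character scalar (read sequence).
#' @param vectorSeq character scalar (vector sequence).
#' @param minArm minimum vector match length (nt) acted on, default 12.
#' @return the trimmed read (possibly empty).
#' @export
trimVector <- function(read, vectorSeq, minArm = 12L) {
    read <- as.character(read); vectorSeq <- as.character(vectorSeq)
    vec <- Biostrings::DNAString(vectorSeq)
    nr <- nchar(read)
    pre <- 0L
    for (k in seq(min(nr, nchar(vectorSeq)), 1L)) {
        if (k < minArm) break
        if (.vectorArm(substr(read, 1L, k), vec)) { pre <- k; break }
    }
    rest <- substr(read, pre + 1L, nr)
    nr2 <- nchar(rest)
    suf <- 0L
    for (k in seq(min(nr2, nchar(vectorSeq)), 1L)) {
        if (k < minArm || nr2 == 0L) break
        if (.vectorArm(substr(rest, nr2 - k + 1L, nr2), vec)) {
            suf <- k; break
        }
    }
    substr(rest, 1L, nr2 - suf)
}

#' Windowed quality trimming
#'
#' Slides a window of \code{params@window} nt one base at a time; a window
#' is good when at least \code{params@minGood} of its bases reach Phred
#' \code{params@minQuality}. The longest run of consecutive good windows is
#' retained (from the first window's start to the last window's end); reads
#' shorter than \code{params@minLength} after trimming are discarded.
#'
#' @param seq character scalar (read sequence).
#' @param quals integer vector of Phred scores, one per base.
#' @param params a \linkS4class{QCParams}.
#' @return list with \code{seq}, \code{quals} and \code{kept}; when
#'   \code{kept} is FALSE the read is discarded.
#' @export
trimQuality <- function(seq, quals, params = qcParams()) {
    seq <- as.character(seq)
    L <- nchar(seq)
    stopifnot(length(quals) == L)
    w <- params@window
    drop <- list(seq = "", quals = integer(), kept = FALSE)
    if (L < w) return(drop)
    good <- as.integer(quals >= params@minQuality)
    cg <- c(0L, cumsum(good))
    counts <- cg[(w + 1L):(L + 1L)] - cg[1L:(L - w + 1L)]
    ok <- counts >= params@minGood
    if (!any(ok)) return(drop)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    from <- starts[best]
    to <- ends[best] + w - 1L
    if (to - from + 1L < params@minLength) return(drop)
    list(seq = substr(seq, from, to), quals = quals[from:to], kept = TRUE)
}

#' Apply vector and quality trimming to a read set
#'
#' @param qreads a \link[Biostrings]{QualityScaledDNAStringSet}.
#' @param params a \linkS4class{QCParams}.
#' @param vectorSeq optional vector sequence for end trimming.
#' @return a \link[Biostrings]{QualityScaledDNAStringSet} of surviving reads.
#' @export
qcReads <- function(qreads, params = qcParams(), vectorSeq = NULL) {
    seqs <- as.character(qreads)
    quals <- .phredInts(qreads)
    outSeq <- character(); outQual <- character(); outName <- character()
    for (i in seq_along(seqs)) {
        s <- seqs[i]; q <- quals[[i]]
        if (!is.null(vectorSeq)) {
            trimmed <- trimVector(s, vectorSeq)
            if (nchar(trimmed) == 0L) next
            at <- regexpr(trimmed, s, fixed = TRUE)
            q <- q[at:(at + nchar(trimmed) - 1L)]
            s <- trimmed
        }
        tq <- trimQuality(s, q, params)
        if (!tq$kept) next
        outSeq <- c(outSeq, tq$seq)
        outQual <- c(outQual, rawToChar(as.raw(tq$quals + 33L)))
        outName <- c(outName, names(qreads)[i])
    }
    rds <- DNAStringSet(outSeq)
    names(rds) <- outName
    QualityScaledDNAStringSet(rds, PhredQuality(outQual))
}

.readKmers <- function(seq, k = 21L, stride = 10L) {
    n <- nchar(seq)
    if (n < k) return(character())
    at <- unique(c(seq(1L, n - k + 1L, by = stride), n - k + 1L))
    substring(seq, at, at + k - 1L)
}

.majorityConsensus <- function(seqs, offsets) {
    width <- max(offsets + nchar(seqs) - 1L)
    tally <- matrix(0L, nrow = 4L, ncol = width,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
    for (i in seq_along(seqs)) {
        ch <- strsplit(seqs[i], "")[[1L]]
        cols <- offsets[i] + seq_along(ch) - 1L
        known <- ch %in% rownames(tally)
        # one base per column within a read, so plain indexed increment is safe
        idx <- cbind(match(ch[known], rownames(tally)), cols[known])
        tally[idx] <- tally[idx] + 1L
    }
    covered <- colSums(tally) > 0L
    # ties break toward the lexicographically smallest base (row order A<C<G<T)
    bases <- rownames(tally)[apply(tally[, covered, drop = FALSE], 2L,
                                   which.max)]
    paste(bases, collapse = "")
}

#' Greedy overlap clustering of reads into contigs and singlets
#'
#' A re-specified, dependency-free stand-in for black-box EST assembly:
#' reads are seeded longest-first; a read joins the cluster whose consensus
#' gives its best overlap of at least \code{minOverlap} nt at identity at
#' least \code{minIdentity} (overlap alignment, identity =
#' matches / aligned columns), and the consensus is recomputed by
#' per-column majority after overlap-anchored stacking. Deterministic given
#' the input set: ordering is by (length desc, name), and candidate
#' clusters are found through a shared-k-mer prefilter before alignment.
#'
#' @param qreads a \link[Biostrings]{QualityScaledDNAStringSet} (or named
#'   \code{DNAStringSet}).
#' @param minOverlap minimum overlap (nt), default 40.
#' @param minIdentity minimum overlap identity (fraction), default 0.95.
#' @return list of clusters, each a list with \code{cluster_id},
#'   \code{members} (read ids), \code{consensus}, \code{kind}
#'   ("contig" for >= 2 members, else "singlet").
#' @export
clusterReads <- function(qreads, minOverlap = 40L, minIdentity = 0.95) {
    if (length(qreads) == 0L) stop("no reads to cluster")
    seqs <- as.character(qreads)
    ids <- names(qreads)
    if (is.null(ids)) ids <- sprintf("r%06d", seq_along(seqs))
    o <- order(-nchar(seqs), ids)
    seqs <- seqs[o]; ids <- ids[o]
    subMat <- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = FALSE, type = "DNA")
    kmerIndex <- new.env(parent = emptyenv())
    clSeqs <- list(); clOffsets <- list(); clMembers <- list()
    clConsensus <- character()
    indexConsensus <- function(ci, cons) {
        for (km in .readKmers(cons)) {
            cur <- if (exists(km, envir = kmerIndex, inherits = FALSE))
                get(km, envir = kmerIndex, inherits = FALSE) else integer()
            assign(km, unique(c(cur, ci)), envir = kmerIndex)
        }
    }
    for (i in seq_along(seqs)) {
        s <- seqs[i]
        cands <- integer()
        for (km in .readKmers(s))
            if (exists(km, envir = kmerIndex, inherits = FALSE))
                cands <- c(cands, get(km, envir = kmerIndex, inherits = FALSE))
        cands <- sort(unique(cands))
        best <- NULL; bestKey <- c(-1, -1)
        for (ci in cands) {
            pa <- pairwiseAlignment(s, clConsensus[ci], type = "overlap",
                                    substitutionMatrix = subMat,
                                    gapOpening = 10, gapExtension = 4)
            ovl <- nmatch(pa) + nmismatch(pa)
            idy <- if (ovl > 0L) nmatch(pa) / ovl else 0
            if (ovl >= minOverlap && idy >= minIdentity &&
                (ovl > bestKey[1L] || (ovl == bestKey[1L] && idy > bestKey[2L]))) {
                best <- list(ci = ci, pa = pa)
                bestKey <- c(ovl, idy)
            }
        }
        if (is.null(best)) {
            ci <- length(clSeqs) + 1L
            clSeqs[[ci]] <- s
            clOffsets[[ci]] <- 1L
            clMembers[[ci]] <- ids[i]
            clConsensus[ci] <- s
            indexConsensus(ci, s)
        } else {
            ci <- best$ci
            offset <- start(Biostrings::subject(best$pa)) -
                start(Biostrings::pattern(best$pa)) + 1L
            if (offset < 1L) {
                # read extends left of the consensus; shift the stack right
                shiftBy <- 1L - offset
                clOffsets[[ci]] <- clOffsets[[ci]] + shiftBy
                offset <- 1L
            }
            clSeqs[[ci]] <- c(clSeqs[[ci]], s)
            clOffsets[[ci]] <- c(clOffsets[[ci]], offset)
            clMembers[[ci]] <- c(clMembers[[ci]], ids[i])
            clConsensus[ci] <- .majorityConsensus(clSeqs[[ci]],
                                                  clOffsets[[ci]])
            indexConsensus(ci, clConsensus[ci])
        }
    }
    lapply(seq_along(clSeqs), function(ci) list(
        cluster_id = sprintf("c%04d", ci),
        members = clMembers[[ci]],
        consensus = clConsensus[ci],
        kind = if (length(clMembers[[ci]]) >= 2L) "contig" else "singlet"))
}

#' Consensus sequences of a clustering as a DNAStringSet
#'
#' @param clusters result of \code{\link{clusterReads}}.
#' @return named \code{DNAStringSet} of consensus sequences.
#' @export
consensusSet <- function(clusters) {
    out <- DNAStringSet(vapply(clusters, `[[`, character(1), "consensus"))
    names(out) <- vapply(clusters, `[[`, character(1), "cluster_id")
    out
}

#' Library redundancy statistic
#'
#' 100 * (reads - consensus sequences) / reads, the fraction of sequencing
#' effort spent on duplicate molecules, reported to two decimals.
#'
#' @param nReads number of high-quality reads (> 0).
#' @param nConsensus number of consensus sequences (<= nReads).
#' @return percent, two decimals.
#' @examples
#' redundancy(946, 144)   # 84.78
#' redundancy(1102, 145)  # 86.84
#' @export
redundancy <- function(nReads, nConsensus) {
    if (nReads <= 0) stop("'nReads' must be positive")
    if (nConsensus > nReads) stop("'nConsensus' cannot exceed 'nReads'")
    roundHalfAway(100 * (nReads - nConsensus) / nReads, 2)
}

#' Library summary table
#'
#' One row per library: read, contig, singlet and consensus counts plus the
#' redundancy percentage.
#'
#' @param library library label.
#' @param nReads number of reads clustered.
#' @param clusters result of \code{\link{clusterReads}}.
#' @return one-row data.frame.
#' @export
librarySummary <- function(library, nReads, clusters) {
    kinds <- vapply(clusters, `[[`, character(1), "kind")
    nContig <- sum(kinds == "contig")
    nSinglet <- sum(kinds == "singlet")
    data.frame(library = library, n_reads = nReads, n_contigs = nContig,
               n_singlets = nSinglet, n_consensus = nContig + nSinglet,
               redundancy = redundancy(nReads, nContig + nSinglet))
}
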