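#' @include transcript-model.R
#' @importFrom Biostrings QualityScaledDNAStringSet PhredQuality
#'   matchPattern replaceLetterAt
#' @importFrom stats rlnorm rpois rnorm runif rbinom
NULL

.DNA <- c("A", "C", "G", "T")

.randomDNA <- function(n) paste(sample(.DNA, n, replace = TRUE), collapse = "")

.pokeSeq <- function(seq, at, what) {
    # overwrite `what` into `seq` starting at 1-based position `at`
    substr(seq, at, at + nchar(what) - 1L) <- what
    seq
}

#' Simulate a gene set with planted splice variants
#'
#' Generates a toy genome and, for each gene, a pair of splice variants
#' differing by exactly one alternative-splicing event, cycling through the
#' four classified types (exon skipping, intron retention, alternative 5'
#' and 3' splice sites). Every junction carries canonical GT/AG
#' dinucleotides (strand-aware), each transcript starts with ATG, and one
#' GATC site is planted mid-exon so that restriction fragments typically
#' span at least one splice junction on each side of a variant-discordant
#' loop. Genes alternate between the two strands.
#'
#' @param nGenes number of two-variant genes.
#' @param seed integer seed.
#' @param exonCount range (min, max) of exons per gene.
#' @param exonWidth,intronWidth ranges (min, max) in nt.
#' @param shiftRange range of alternative splice-site shifts (nt); the
#'   minimum default of 30 keeps every planted loop above the 25-nt capture
#'   threshold.
#' @param spacer intergenic spacer (nt).
#' @return a list with \code{genome} (\code{DNAStringSet}), \code{models}
#'   (list of \linkS4class{TranscriptModel}, two per gene) and \code{truth}
#'   (data.frame: gene, type, chrom, strand, start, end, size).
#' @export
simulateGeneSet <- function(nGenes = 50, seed = 1L,
                            exonCount = c(5L, 8L),
                            exonWidth = c(90L, 200L),
                            intronWidth = c(120L, 300L),
                            shiftRange = c(30L, 120L),
                            spacer = 300L) {
    set.seed(seed)
    types <- c("exon_skipping", "intron_retention", "alt_5ss", "alt_3ss")
    chromSeq <- character()
    offset <- 0L
    models <- list()
    truth <- list()
    for (g in seq_len(nGenes)) {
        gid <- sprintf("g%03d", g)
        strand <- if (g %% 2L == 1L) "+" else "-"
        type <- types[(g - 1L) %% 4L + 1L]
        nex <- sample(seq(exonCount[1], exonCount[2]), 1L)
        ew <- sample(seq(exonWidth[1], exonWidth[2]), nex, replace = TRUE)
        iw <- sample(seq(intronWidth[1], intronWidth[2]), nex - 1L,
                     replace = TRUE)
        starts <- offset + 1L + cumsum(c(0L, ew[-nex] + iw))
        exons <- IRanges(start = starts, width = ew)
        glen <- max(end(exons)) - offset
        seq <- .randomDNA(glen)

        pokeAbs <- function(at, what) seq <<- .pokeSeq(seq, at - offset, what)
        # canonical splice dinucleotides (strand-aware)
        introns <- IRanges(start = end(exons)[-nex] + 1L,
                           end = start(exons)[-1L] - 1L)
        for (i in seq_along(introns)) {
            if (strand == "+") {
                pokeAbs(start(introns)[i], "GT")
                pokeAbs(end(introns)[i] - 1L, "AG")
            } else {
                pokeAbs(start(introns)[i], "CT")   # revcomp acceptor AG
                pokeAbs(end(introns)[i] - 1L, "AC") # revcomp donor GT
            }
        }
        # pick the event locus first: retention genes must stay GATC-free
        # across the two exons being merged, or duplex fragments would be
        # cut inside the merged exon and the retention tag would come out
        # single-block (intronless) and be excluded from classification
        k <- if (type == "exon_skipping") sample(2:(nex - 1L), 1L)
             else sample(seq_len(nex - 1L), 1L)
        gatcFree <- if (type == "intron_retention") c(k, k + 1L) else integer()
        # one GATC mid-exon (plus natural background occurrences)
        for (i in setdiff(seq_len(nex), gatcFree))
            pokeAbs(start(exons)[i] + ew[i] %/% 2L, "GATC")
        for (i in gatcFree) {
            # scrub natural GATC from the merged exons (GATC -> GTTC)
            rel <- c(start(exons)[i], end(exons)[i]) - offset
            piece <- substr(seq, rel[1L], rel[2L])
            seq <- .pokeSeq(seq, rel[1L], gsub("GATC", "GTTC", piece,
                                               fixed = TRUE))
        }
        # translation start at the transcription 5' end
        if (strand == "+") pokeAbs(start(exons)[1L], "ATG")
        else pokeAbs(end(exons)[nex] - 2L, "CAT")

        exB <- exons
        if (type == "exon_skipping") {
            region <- exons[k]
            exB <- exons[-k]
        } else if (type == "intron_retention") {
            region <- introns[k]
            exB <- c(IRanges(start(exons)[seq_len(k - 1L)],
                             end(exons)[seq_len(k - 1L)]),
                     IRanges(start(exons)[k], end(exons)[k + 1L]))
            if (k + 2L <= nex)
                exB <- c(exB, exons[seq(k + 2L, nex)])
        } else {
            s <- start(introns)[k]; e <- end(introns)[k]
            maxShift <- min(shiftRange[2], width(introns)[k] - 8L)
            d <- sample(seq(shiftRange[1], maxShift), 1L)
            donorSide <- (type == "alt_5ss" & strand == "+") |
                         (type == "alt_3ss" & strand == "-")
            if (donorSide) {
                # variant exon extends rightward from the genomic-left exon
                end(exB)[k] <- end(exB)[k] + d
                region <- IRanges(s, s + d - 1L)
                if (strand == "+") pokeAbs(s + d, "GT") else pokeAbs(s + d, "CT")
            } else {
                start(exB)[k + 1L] <- start(exB)[k + 1L] - d
                region <- IRanges(e - d + 1L, e)
                if (strand == "+") pokeAbs(e - d - 1L, "AG")
                else pokeAbs(e - d - 1L, "AC")
            }
        }
        models[[length(models) + 1L]] <-
            TranscriptModel(paste0(gid, ".v1"), gid, "chr1", strand, exons)
        models[[length(models) + 1L]] <-
            TranscriptModel(paste0(gid, ".v2"), gid, "chr1", strand, exB)
        truth[[length(truth) + 1L]] <- data.frame(
            gene = gid, type = type, chrom = "chr1", strand = strand,
            start = start(region), end = end(region), size = width(region))
        chromSeq <- c(chromSeq, seq, .randomDNA(spacer))
        offset <- offset + glen + spacer
    }
    genome <- DNAStringSet(paste(chromSeq, collapse = ""))
    names(genome) <- "chr1"
    list(genome = genome, models = models, truth = do.call(rbind, truth))
}

#' Simulate per-variant transcript abundances
#'
#' Draws positive integer copy numbers per variant from the log-normal
#' abundance model, reproducibly under \code{params@seed}. Skewed balances
#' between the two variants of a gene arise naturally from the log-normal
#' spread.
#'
#' @param models list of \linkS4class{TranscriptModel}.
#' @param params a \linkS4class{SimulationParams}.
#' @return data.frame with columns \code{transcript_id}, \code{gene_id},
#'   \code{copies}.
#' @export
simulateAbundances <- function(models, params = simParams()) {
    set.seed(params@seed)
    n <- length(models)
    copies <- pmax(1L, as.integer(round(
        rlnorm(n, params@abundanceMeanlog, params@abundanceSdlog))))
    data.frame(
        transcript_id = vapply(models, transcriptId, character(1)),
        gene_id = vapply(models, geneId, character(1)),
        copies = copies)
}

#' DpnII digestion of a nucleotide sequence
#'
#' Cuts immediately 5' of every GATC occurrence; fragments are the
#' substrings between successive cut points (a leading empty fragment at a
#' position-1 site is dropped). Fragment offsets are 1-based positions in
#' the input, so the fragments concatenate back to the input.
#'
#' @param sequence a character scalar or \code{DNAString}.
#' @return data.frame with columns \code{offset} and \code{sequence}.
#' @export
dpniiDigest <- function(sequence) {
    sequence <- as.character(sequence)
    if (nchar(sequence) == 0L) stop("empty sequence")
    hits <- gregexpr("GATC", sequence, fixed = TRUE)[[1L]]
    cuts <- if (hits[1L] == -1L) integer() else as.integer(hits)
    bounds <- sort(unique(c(1L, cuts, nchar(sequence) + 1L)))
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L] - 1L
    keep <- ends >= starts
    data.frame(offset = starts[keep],
               sequence = substring(sequence, starts[keep], ends[keep]))
}

.genomicPositions <- function(model) {
    ex <- exonRanges(model)
    pos <- unlist(lapply(seq_along(ex),
                         function(i) seq(start(ex)[i], end(ex)[i])))
    if (strandOf(model) == "-") pos <- rev(pos)
    pos
}

.runsToRanges <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    IRanges(start = starts[r$values], end = ends[r$values])
}

#' Form heteroduplex fragments between the splice variants of one gene
#'
#' For every ordered variant pair (A, B), the two spliced sequences are
#' paired through their shared genomic positions. Positions of A absent
#' from B form single-stranded loops; terminal unpaired overhangs are
#' removed (the exonuclease step), and DpnII then cuts only at GATC sites
#' whose four bases are double-stranded (shared) -- single-stranded loops
#' are not a substrate. Each resulting fragment becomes a
#' \linkS4class{DuplexRecord} whose pairing weight is the product of the
#' two variant abundances; a fragment is loop-bearing iff it intersects a
#' loop interval.
#'
#' @param variants list of \linkS4class{TranscriptModel}, all of one gene
#'   (at least 2 for heteroduplexes).
#' @param genome named \code{DNAStringSet}.
#' @param abundances data.frame from \code{\link{simulateAbundances}}.
#' @param params a \linkS4class{SimulationParams}.
#' @return list of \linkS4class{DuplexRecord}.
#' @export
formHeteroduplexes <- function(variants, genome, abundances,
                               params = simParams()) {
    gids <- unique(vapply(variants, geneId, character(1)))
    if (length(gids) != 1L)
        stop("variants from different genes: ", paste(gids, collapse = ", "))
    if (length(variants) < 2L) return(list())
    copies <- setNames(abundances$copies, abundances$transcript_id)
    seqs <- lapply(variants, splicedSequence, genome = genome)
    poss <- lapply(variants, .genomicPositions)
    out <- list()
    idx <- seq_along(variants)
    for (a in idx) for (b in idx) {
        if (a == b) next
        shared <- poss[[a]] %in% poss[[b]]
        if (!any(shared)) next
        span <- range(which(shared))
        loops <- .runsToRanges(!shared)
        loops <- IRanges::restrict(loops, start = span[1L], end = span[2L])
        seqA <- as.character(seqs[[a]])
        gatc <- gregexpr("GATC", seqA, fixed = TRUE)[[1L]]
        gatc <- if (gatc[1L] == -1L) integer() else as.integer(gatc)
        dsCut <- gatc[gatc >= span[1L] & gatc + 3L <= span[2L]]
        dsCut <- dsCut[vapply(dsCut, function(p) all(shared[p:(p + 3L)]),
                              logical(1))]
        bounds <- sort(unique(c(span[1L], dsCut, span[2L] + 1L)))
        w <- unname(copies[transcriptId(variants[[a]])] *
                    copies[transcriptId(variants[[b]])])
        for (i in seq_len(length(bounds) - 1L)) {
            frag <- IRanges(bounds[i], bounds[i + 1L] - 1L)
            if (width(frag) == 0L) next
            out[[length(out) + 1L]] <- new("DuplexRecord",
                geneId = gids,
                variantA = transcriptId(variants[[a]]),
                variantB = transcriptId(variants[[b]]),
                fragment = frag,
                loopIntervals = IRanges::restrict(loops, start(frag), end(frag)),
                weight = w, captured = NA)
        }
    }
    out
}

.mutateRead <- function(seq, errorRate) {
    n <- nchar(seq)
    k <- rbinom(1L, n, errorRate)
    if (k == 0L) return(seq)
    at <- sample.int(n, k)
    chars <- strsplit(seq, "")[[1L]]
    for (p in at)
        chars[p] <- sample(setdiff(.DNA, chars[p]), 1L)
    paste(chars, collapse = "")
}

#' Capture loop-bearing fragments and emit reads with ground truth
#'
#' Fragments whose longest single-strand loop reaches \code{params@minLoop}
#' (the 25-mer annealing length) are captured with probability
#' 1 - captureNoise; loop-less fragments leak in with probability
#' captureNoise. Each captured fragment is amplified to
#' 1 + Poisson(pcrRedundancy - 1) reads; substitution errors and Phred
#' qualities are applied per read. Reads are emitted 5' to 3' of the
#' variantA transcript (one strand of the duplex per clone).
#'
#' @param duplexes list of \linkS4class{DuplexRecord}.
#' @param models list of all \linkS4class{TranscriptModel} (to resolve
#'   variantA sequences and genomic coordinates).
#' @param genome named \code{DNAStringSet}.
#' @param params a \linkS4class{SimulationParams}.
#' @return list with \code{reads} (a
#'   \link[Biostrings]{QualityScaledDNAStringSet}) and \code{truth}
#'   (data.frame: read_id, gene, variant_a, variant_b, chrom, start, end,
#'   loop_flag).
#' @export
captureAndEmit <- function(duplexes, models, genome, params = simParams()) {
    set.seed(params@seed + 1L)
    byId <- setNames(models, vapply(models, transcriptId, character(1)))
    seqCache <- new.env(parent = emptyenv())
    getSeq <- function(id) {
        if (!exists(id, envir = seqCache, inherits = FALSE))
            assign(id, as.character(splicedSequence(byId[[id]], genome)),
                   envir = seqCache)
        get(id, envir = seqCache, inherits = FALSE)
    }
    posCache <- new.env(parent = emptyenv())
    getPos <- function(id) {
        if (!exists(id, envir = posCache, inherits = FALSE))
            assign(id, .genomicPositions(byId[[id]]), envir = posCache)
        get(id, envir = posCache, inherits = FALSE)
    }
    reads <- character(); quals <- character(); truth <- list()
    rid <- 0L
    for (dx in duplexes) {
        maxLoop <- if (length(dx@loopIntervals)) max(width(dx@loopIntervals))
                   else 0L
        loopFlag <- maxLoop >= params@minLoop
        p <- if (loopFlag) 1 - params@captureNoise else params@captureNoise
        if (runif(1L) >= p) next
        ndup <- rpois(1L, params@pcrRedundancy - 1) + 1L
        fragSeq <- substring(getSeq(dx@variantA),
                             start(dx@fragment), end(dx@fragment))
        gpos <- getPos(dx@variantA)[start(dx@fragment):end(dx@fragment)]
        for (j in seq_len(ndup)) {
            rid <- rid + 1L
            seq <- .mutateRead(fragSeq, params@readErrorRate)
            q <- pmin(40L, pmax(2L, as.integer(round(
                rnorm(nchar(seq), params@qualMean, params@qualSd)))))
            reads <- c(reads, seq)
            quals <- c(quals, rawToChar(as.raw(q + 33L)))
            truth[[length(truth) + 1L]] <- data.frame(
                read_id = sprintf("r%06d", rid), gene = dx@geneId,
                variant_a = dx@variantA, variant_b = dx@variantB,
                chrom = chromName(byId[[dx@variantA]]),
                start = min(gpos), end = max(gpos), loop_flag = loopFlag)
        }
    }
    if (rid == 0L)
        return(list(reads = QualityScaledDNAStringSet(
                        DNAStringSet(), PhredQuality(character())),
                    truth = data.frame(read_id = character(),
                        gene = character(), variant_a = character(),
                        variant_b = character(), chrom = character(),
                        start = integer(), end = integer(),
                        loop_flag = logical())))
    truth <- do.call(rbind, truth)
    rds <- DNAStringSet(reads)
    names(rds) <- truth$read_id
    list(reads = QualityScaledDNAStringSet(rds, PhredQuality(quals)),
         truth = truth)
}

#' Run the full library simulation
#'
#' Abundance draw, heteroduplex formation per gene, loop capture and read
#' emission, in one call. Fully deterministic under \code{params@seed}.
#'
#' @param models list of \linkS4class{TranscriptModel}.
#' @param genome named \code{DNAStringSet}.
#' @param params a \linkS4class{SimulationParams}.
#' @return list with \code{reads}, \code{truth}, \code{abundances},
#'   \code{duplexes}.
#' @export
simulateLibrary <- function(models, genome, params = simParams()) {
    ab <- simulateAbundances(models, params)
    byGene <- split(models, vapply(models, geneId, character(1)))
    duplexes <- list()
    for (g in names(byGene))
        duplexes <- c(duplexes,
                      formHeteroduplexes(byGene[[g]], genome, ab, params))
    emitted <- captureAndEmit(duplexes, models, genome, params)
    c(emitted, list(abundances = ab, duplexes = duplexes))
}

#' Write simulated reads as FASTQ and the truth manifest as TSV
#'
#' @param sim result of \code{\link{simulateLibrary}} or
#'   \code{\link{captureAndEmit}}.
#' @param fastqPath,truthPath output paths.
#' @export
writeSimulatedReads <- function(sim, fastqPath, truthPath) {
    rds <- as(sim$reads, "DNAStringSet")
    S4Vectors::mcols(rds) <- NULL
    writeXStringSet(rds, fastqPath, format = "fastq",
                    qualities = Biostrings::BStringSet(
                        Biostrings::quality(sim$reads)))
    utils::write.table(sim$truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(NULL)
}

#' Read FASTQ reads with qualities
#'
#' @param path FASTQ file.
#' @return a \link[Biostrings]{QualityScaledDNAStringSet}.
#' @export
readFastqReads <- function(path) {
    # the reader parks qualities in a metadata column before promoting them;
    # the promotion warning is noise
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
}
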