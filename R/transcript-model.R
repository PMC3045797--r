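#' @include AllGenerics.R
#' @importFrom Biostrings DNAStringSet DNAString readDNAStringSet
#'   writeXStringSet reverseComplement extractAt xscat
#' @importFrom IRanges IRanges shift gaps
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom rtracklayer import export
NULL

#' @rdname accessors
setMethod("transcriptId", "TranscriptModel", function(x) x@transcriptId)
#' @rdname accessors
setMethod("geneId", "TranscriptModel", function(x) x@geneId)
#' @rdname accessors
setMethod("chromName", "TranscriptModel", function(x) x@chrom)
#' @rdname accessors
setMethod("strandOf", "TranscriptModel", function(x) x@strand)
#' @rdname accessors
setMethod("exonRanges", "TranscriptModel", function(x) x@exons)
#' @rdname accessors
setMethod("nExons", "TranscriptModel", function(x) length(x@exons))
#' @rdname accessors
setMethod("txLength", "TranscriptModel", function(x) sum(width(x@exons)))

#' @rdname accessors
setMethod("intronRanges", "TranscriptModel", function(x) {
    if (length(x@exons) < 2L)
        return(IRanges())
    ex <- x@exons
    IRanges(start = end(ex)[-length(ex)] + 1L, end = start(ex)[-1L] - 1L)
})

setMethod("show", "TranscriptModel", function(object) {
    cat(sprintf("TranscriptModel %s (gene %s): %s:%s, %d exon(s), %d nt\n",
                object@transcriptId, object@geneId, object@chrom,
                object@strand, length(object@exons), sum(width(object@exons))))
    ex <- object@exons
    cat("  exons: ",
        paste(sprintf("[%d, %d]", start(ex), end(ex)), collapse = " "), "\n")
})

.checkGenomeCovers <- function(model, genome) {
    chrom <- chromName(model)
    if (!chrom %in% names(genome))
        stop("chromosome '", chrom, "' not found in genome")
    if (max(end(exonRanges(model))) > length(genome[[chrom]]))
        stop("transcript '", transcriptId(model),
             "' extends past the end of ", chrom)
    invisible(TRUE)
}

#' @rdname splicedSequence
setMethod("splicedSequence", "TranscriptModel", function(x, genome) {
    .checkGenomeCovers(x, genome)
    seqs <- extractAt(genome[[chromName(x)]], exonRanges(x))
    out <- unlist(seqs)
    if (strandOf(x) == "-") out <- reverseComplement(out)
    out
})

#' @rdname spliceDinucleotides
setMethod("spliceDinucleotides", "TranscriptModel", function(x, genome) {
    .checkGenomeCovers(x, genome)
    introns <- intronRanges(x)
    n <- length(introns)
    if (n == 0L)
        return(data.frame(donor = character(), acceptor = character(),
                          canonical = logical(), valid = logical()))
    chr <- genome[[chromName(x)]]
    left  <- as.character(extractAt(chr, IRanges(start(introns), width = 2L)))
    right <- as.character(extractAt(chr, IRanges(end = end(introns), width = 2L)))
    # rows are reported in transcription order
    if (strandOf(x) == "+") {
        donor <- left; acceptor <- right
        valid <- width(introns) >= 4L
    } else {
        donor    <- rev(as.character(reverseComplement(DNAStringSet(right))))
        acceptor <- rev(as.character(reverseComplement(DNAStringSet(left))))
        valid <- rev(width(introns) >= 4L)
    }
    data.frame(donor = donor, acceptor = acceptor,
               canonical = valid & donor == "GT" & acceptor == "AG",
               valid = valid)
})

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return a named \link[Biostrings]{DNAStringSet}, uppercased.
#' @export
readGenome <- function(path) {
    g <- readDNAStringSet(path)
    names(g) <- sub("\\s.*$", "", names(g))
    Biostrings::DNAStringSet(toupper(g))
}

#' Write a genome to FASTA
#'
#' @param genome a named \link[Biostrings]{DNAStringSet}.
#' @param path output FASTA path.
#' @export
writeGenome <- function(genome, path) {
    writeXStringSet(genome, path)
    invisible(path)
}

.modelFromBedRow <- function(chrom, strand, name, blockStart, blockWidth) {
    ids <- strsplit(name, "|", fixed = TRUE)[[1L]]
    txid <- if (length(ids) == 2L) ids[2L] else name
    gid  <- if (length(ids) == 2L) ids[1L] else name
    TranscriptModel(txid, gid, chrom, strand,
                    IRanges(start = blockStart, width = blockWidth))
}

.rejectShortIntrons <- function(models) {
    ok <- vapply(models, function(m) {
        ir <- intronRanges(m)
        length(ir) == 0L || all(width(ir) >= 4L)
    }, logical(1))
    if (!all(ok))
        stop("transcripts with introns < 4 nt rejected on load: ",
             paste(vapply(models[!ok], transcriptId, character(1)),
                   collapse = ", "))
    models
}

#' Read transcript models from BED12 or GFF3
#'
#' BED12 blockStarts/blockSizes are converted to absolute exon intervals;
#' GFF3 exons are grouped by their transcript parent and sorted. BED names
#' of the form \code{"gene|transcript"} populate both identifiers; a plain
#' name is used for both. Transcripts whose introns are shorter than 4 nt
#' (too short to carry splice dinucleotides) are rejected.
#'
#' @param path input file.
#' @param format \code{"bed12"} or \code{"gff3"}.
#' @return a list of \linkS4class{TranscriptModel}.
#' @export
readTranscriptModels <- function(path, format = c("bed12", "gff3")) {
    format <- match.arg(format)
    if (format == "bed12") {
        gr <- rtracklayer::import(path, format = "bed")
        if (length(gr) == 0L) return(list())
        blocks <- mcols(gr)$blocks
        if (is.null(blocks))
            blocks <- IRanges::IRangesList(lapply(width(gr), function(w)
                IRanges(1L, w)))
        models <- lapply(seq_along(gr), function(i) {
            b <- blocks[[i]]
            if (length(b) == 0L)
                stop("zero-exon transcript in record ", i, " of ", path)
            .modelFromBedRow(as.character(GenomicRanges::seqnames(gr)[i]),
                             as.character(BiocGenerics::strand(gr)[i]),
                             mcols(gr)$name[i],
                             start(b) + start(gr)[i] - 1L, width(b))
        })
    } else {
        gr <- rtracklayer::import(path, format = "gff3")
        ex <- gr[tolower(as.character(mcols(gr)$type)) == "exon"]
        if (length(ex) == 0L)
            stop("no exon features found in ", path)
        parent <- as.character(S4Vectors::unstrsplit(mcols(ex)$Parent, ","))
        tx <- gr[tolower(as.character(mcols(gr)$type)) %in%
                     c("mrna", "transcript")]
        txGene <- setNames(
            as.character(S4Vectors::unstrsplit(mcols(tx)$Parent, ",")),
            mcols(tx)$ID)
        models <- lapply(split(seq_along(ex), parent), function(idx) {
            e <- ex[idx]
            o <- order(start(e))
            txid <- parent[idx][1L]
            gid <- txGene[txid]
            if (is.na(gid) || !nzchar(gid)) gid <- txid
            TranscriptModel(txid, gid,
                            as.character(GenomicRanges::seqnames(e)[1L]),
                            as.character(BiocGenerics::strand(e)[1L]),
                            IRanges(start(e)[o], end(e)[o]))
        })
        models <- unname(models)
    }
    .rejectShortIntrons(models)
}

#' Write transcript models to BED12 or GFF3
#'
#' Output is deterministic: records are sorted by (chrom, start,
#' transcriptId).
#'
#' @param models list of \linkS4class{TranscriptModel}.
#' @param path output file.
#' @param format \code{"bed12"} or \code{"gff3"}.
#' @export
writeTranscriptModels <- function(models, path, format = c("bed12", "gff3")) {
    format <- match.arg(format)
    o <- order(vapply(models, chromName, character(1)),
               vapply(models, function(m) start(exonRanges(m))[1L], integer(1)),
               vapply(models, transcriptId, character(1)))
    models <- models[o]
    if (format == "bed12") {
        gr <- GRanges(
            seqnames = vapply(models, chromName, character(1)),
            ranges = IRanges(
                start = vapply(models, function(m) start(exonRanges(m))[1L],
                               integer(1)),
                end = vapply(models, function(m) max(end(exonRanges(m))),
                             integer(1))),
            strand = vapply(models, strandOf, character(1)))
        mcols(gr)$name <- vapply(models, function(m)
            if (geneId(m) == transcriptId(m)) transcriptId(m)
            else paste0(geneId(m), "|", transcriptId(m)), character(1))
        mcols(gr)$blocks <- IRanges::IRangesList(lapply(models, function(m)
            shift(exonRanges(m), 1L - start(exonRanges(m))[1L])))
        rtracklayer::export(gr, path, format = "bed")
    } else {
        lines <- c("##gff-version 3")
        for (m in models) {
            ex <- exonRanges(m)
            span <- sprintf("%d\t%d", start(ex)[1L], max(end(ex)))
            lines <- c(lines,
                sprintf("%s\tspliceLoop\tgene\t%s\t.\t%s\t.\tID=%s",
                        chromName(m), span, strandOf(m), geneId(m)),
                sprintf("%s\tspliceLoop\tmRNA\t%s\t.\t%s\t.\tID=%s;Parent=%s",
                        chromName(m), span, strandOf(m), transcriptId(m),
                        geneId(m)),
                sprintf("%s\tspliceLoop\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                        chromName(m), start(ex), end(ex), strandOf(m),
                        transcriptId(m)))
        }
        writeLines(lines, path)
    }
    invisible(path)
}
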