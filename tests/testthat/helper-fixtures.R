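# in-code fixtures shared across test files

mkChain <- function(starts, ends, strand = "+", id = "tx", gene = id,
                    chrom = "chr1") {
    TranscriptModel(id, gene, chrom, strand,
                    IRanges::IRanges(start = starts, end = ends))
}

# a genome whose chr1 is the given string
mkGenome <- function(seq, chrom = "chr1") {
    g <- Biostrings::DNAStringSet(seq)
    names(g) <- chrom
    g
}

randomSeq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random valid exon chain with at most maxExons exons (introns >= 5 nt)
randomExons <- function(maxExons = 6L) {
    n <- sample.int(maxExons, 1L)
    widths <- sample(20:80, n, replace = TRUE)
    gaps <- if (n > 1L) sample(12:60, n - 1L, replace = TRUE) else integer()
    starts <- sample(1:50, 1L) + cumsum(c(0L, widths[-n] + gaps))
    IRanges::IRanges(start = starts, width = widths)
}

# perturb an exon chain with splice-like edits (skip, merge, boundary shift)
perturbExons <- function(ex, nOps = sample(0:3, 1L)) {
    for (i in seq_len(nOps)) {
        n <- length(ex)
        op <- sample(c("skip", "merge", "donor", "acceptor", "none"), 1L)
        if (op == "skip" && n >= 3L) {
            ex <- ex[-sample(2:(n - 1L), 1L)]
        } else if (op == "merge" && n >= 2L) {
            k <- sample.int(n - 1L, 1L)
            merged <- IRanges::IRanges(IRanges::start(ex)[k],
                                       IRanges::end(ex)[k + 1L])
            parts <- list(if (k > 1L) ex[seq_len(k - 1L)],
                          merged,
                          if (k + 2L <= n) ex[seq(k + 2L, n)])
            ex <- do.call(c, Filter(Negate(is.null), parts))
        } else if (op %in% c("donor", "acceptor") && n >= 2L) {
            k <- sample.int(n - 1L, 1L)
            gap <- IRanges::start(ex)[k + 1L] - IRanges::end(ex)[k] - 1L
            if (gap > 10L) {
                d <- sample.int(min(25L, gap - 6L), 1L)
                if (op == "donor")
                    IRanges::end(ex)[k] <- IRanges::end(ex)[k] + d
                else
                    IRanges::start(ex)[k + 1L] <-
                        IRanges::start(ex)[k + 1L] - d
            }
        }
    }
    ex
}

randomChainPair <- function(maxExons = 6L) {
    strand <- sample(c("+", "-"), 1L)
    exA <- randomExons(maxExons)
    exB <- perturbExons(exA)
    list(A = mkChain(IRanges::start(exA), IRanges::end(exA), strand, "A"),
         B = mkChain(IRanges::start(exB), IRanges::end(exB), strand, "B"))
}
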