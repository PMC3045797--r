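mkPsl <- function(matches, misMatches, qName, qSize, qStart, qEnd, tName,
                  tStart, blockSizes, tStarts, strand = "+") {
    paste(matches, misMatches, 0, 0, 0, 0, 0, 0, strand, qName, qSize,
          qStart, qEnd, tName, 1e6, tStart,
          tStarts[length(tStarts)] + blockSizes[length(blockSizes)],
          length(blockSizes),
          paste0(paste(blockSizes, collapse = ","), ","),
          paste0(paste(cumsum(c(qStart, blockSizes))[seq_along(blockSizes)],
                       collapse = ","), ","),
          paste0(paste(tStarts, collapse = ","), ","), sep = "\t")
}

test_that("PSL metrics follow the identity and coverage formulas", {
    psl <- tempfile(fileext = ".psl")
    writeLines(mkPsl(95, 5, "q1", 120, 0, 100, "chr1", 1000,
                     c(60, 40), c(1000, 1500)), psl)
    a <- readAlignments(psl, "psl")[[1]]
    expect_equal(identityPct(a), 95)
    expect_equal(coveragePct(a), 100 * 100 / 120, tolerance = 1e-9)
    expect_equal(nExons(a), 2)
    expect_equal(IRanges::start(exonRanges(a)), c(1001L, 1501L))
})

test_that("random PSL records reproduce brute-force field arithmetic", {
    set.seed(47)
    for (rep in 1:20) {
        nb <- sample(1:4, 1)
        bs <- sample(20:80, nb, replace = TRUE)
        gaps <- if (nb > 1) sample(30:100, nb - 1, replace = TRUE)
                else integer()
        ts <- 500 + cumsum(c(0, bs[-nb] + gaps))
        aligned <- sum(bs)
        mm <- sample(0:5, 1)
        qSize <- aligned + sample(0:40, 1)
        psl <- tempfile(fileext = ".psl")
        writeLines(mkPsl(aligned - mm, mm, "q", qSize, 0, aligned, "chr2",
                         ts[1], bs, ts), psl)
        a <- readAlignments(psl, "psl")[[1]]
        expect_equal(a@matches, aligned - mm)
        expect_equal(a@alignedLength, aligned)
        expect_equal(identityPct(a), 100 * (aligned - mm) / aligned)
        expect_equal(coveragePct(a), 100 * aligned / qSize)
        expect_equal(nExons(a), nb)
    }
})

test_that("BED12 alignments require and use the sidecar metrics", {
    bed <- tempfile(fileext = ".bed")
    writeLines(paste("chr1", 100, 300, "a1", 0, "+", 100, 300, "0",
                     2, "50,50,", "0,150,", sep = "\t"), bed)
    tsv <- tempfile(fileext = ".tsv")
    write.table(data.frame(name = "a1", matches = 98, aligned_length = 100,
                           query_length = 110),
                tsv, sep = "\t", row.names = FALSE, quote = FALSE)
    a <- readAlignments(bed, "bed12", metricsPath = tsv)[[1]]
    expect_equal(identityPct(a), 98)
    expect_error(readAlignments(bed, "bed12"), "sidecar")
    write.table(data.frame(name = "other", matches = 1, aligned_length = 1,
                           query_length = 1),
                tsv, sep = "\t", row.names = FALSE, quote = FALSE)
    expect_error(readAlignments(bed, "bed12", metricsPath = tsv),
                 "metrics missing for asset 'a1'")
})

mkAsset <- function(matches, alignedLength, queryLength, id = "a",
                    chrom = "chr1", start = 1L, nex = 1L) {
    starts <- start + (seq_len(nex) - 1L) * 200L
    AlignedAsset(id, mkChain(starts, starts + 49L, id = id, chrom = chrom),
                 matches, alignedLength, queryLength)
}

test_that("best hit maximizes (matches, identity, coverage) deterministically", {
    one <- mkAsset(90, 100, 100)
    expect_identical(bestHit(list(one)), one)
    h98 <- mkAsset(98, 100, 100, "x"); h95 <- mkAsset(95, 100, 100, "x")
    expect_equal(bestHit(list(h95, h98))@matches, 98L)
    # sort oracle on random hit sets
    set.seed(53)
    for (rep in 1:25) {
        hits <- lapply(1:5, function(i) mkAsset(
            sample(80:100, 1), 100, sample(100:140, 1), "q",
            chrom = sample(c("chr1", "chr2"), 1),
            start = sample(1:1000, 1)))
        key <- t(vapply(hits, function(a) c(a@matches, identityPct(a),
                                            coveragePct(a)), numeric(3)))
        chrom <- vapply(hits, function(a) a@chain@chrom, character(1))
        st <- vapply(hits, function(a) IRanges::start(a@chain@exons)[1],
                     integer(1))
        o <- order(-key[, 1], -key[, 2], -key[, 3], chrom, st)
        expect_identical(bestHit(hits), hits[[o[1]]])
    }
})

test_that("identity/coverage filter is inclusive, idempotent and order-free", {
    boundary <- mkAsset(93, 100, 100)   # identity 93.0
    lowCov <- mkAsset(55, 55, 100)      # coverage 55.0, identity 100
    below <- mkAsset(929, 1000, 1000)   # identity 92.9
    expect_length(filterAlignments(list(boundary)), 1)
    expect_length(filterAlignments(list(lowCov)), 1)
    expect_length(filterAlignments(list(below)), 0)
    # threshold oracle on a planted metric distribution
    set.seed(59)
    assets <- lapply(1:214, function(i) {
        al <- sample(50:100, 1)
        mkAsset(sample(ceiling(al / 2):al, 1), al, 100, sprintf("s%d", i))
    })
    kept <- filterAlignments(assets)
    want <- sum(vapply(assets, function(a)
        identityPct(a) >= 93 && coveragePct(a) >= 55, logical(1)))
    expect_length(kept, want)
    expect_identical(filterAlignments(kept), kept)
})

test_that("exon-count classification splits multi-exon from intronless", {
    expect_equal(classifyExonCount(mkAsset(50, 50, 50, nex = 2)),
                 "multi_exon")
    expect_equal(classifyExonCount(mkAsset(50, 50, 50, nex = 1)),
                 "intronless")
})

test_that("relative position profile rescales to transcript percentiles", {
    prof <- relativePositionProfile(
        data.frame(start = 500, end = 1000, length = 2000))
    expect_equal(prof$count[prof$percentile %in% 25:50], rep(1L, 26))
    expect_equal(sum(prof$count), 26)
    full <- relativePositionProfile(
        data.frame(start = 1, end = 2000, length = 2000))
    expect_equal(full$count, rep(1L, 101))
    expect_error(relativePositionProfile(
        data.frame(start = 0, end = 10, length = 100)), "outside")
    # uniformity oracle: single-base assets placed uniformly
    set.seed(61)
    pos <- sample(1:100, 10000, replace = TRUE)
    prof2 <- relativePositionProfile(
        data.frame(start = pos, end = pos, length = 100))
    counts <- prof2$count[prof2$percentile >= 1]
    expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("transcript-guided placement recovers exact chains", {
    gs <- simulateGeneSet(nGenes = 5, seed = 67)
    byId <- setNames(gs$models, vapply(gs$models, transcriptId, character(1)))
    set.seed(67)
    nMulti <- 0L; nTotal <- 0L
    for (rep in 1:20) {
        m <- gs$models[[sample(length(gs$models), 1)]]
        src <- as.character(splicedSequence(m, gs$genome))
        # pick a window guaranteed to straddle the first junction
        # (transcription order: the first exon is the genomic-last one on
        # the minus strand)
        ws <- IRanges::width(exonRanges(m))
        w1 <- if (strandOf(m) == "+") ws[1] else ws[length(ws)]
        st <- max(1, w1 - sample(30:60, 1))
        en <- min(nchar(src), w1 + sample(30:60, 1))
        cons <- Biostrings::DNAStringSet(substr(src, st, en))
        names(cons) <- "c1"
        placed <- alignToModels(cons, list(m), gs$genome)
        expect_length(placed$assets, 1)
        a <- placed$assets[[1]]
        expect_equal(identityPct(a), 100)
        expect_equal(coveragePct(a), 100)
        nTotal <- nTotal + 1L
        if (classifyExonCount(a) == "multi_exon") nMulti <- nMulti + 1L
    }
    expect_gte(nMulti / nTotal, 0.99)
})

test_that("projection maps transcript intervals through the exon chain", {
    m <- mkChain(c(1, 201, 401), c(100, 300, 500))
    sub <- projectToGenome(m, 51, 150)  # 50 nt of exon 1 + 50 nt of exon 2
    expect_equal(IRanges::start(exonRanges(sub)), c(51L, 201L))
    expect_equal(IRanges::end(exonRanges(sub)), c(100L, 250L))
    mi <- mkChain(c(1, 201), c(100, 300), "-")
    sub2 <- projectToGenome(mi, 1, 50)  # transcription start = genomic right
    expect_equal(IRanges::start(exonRanges(sub2)), 251L)
    expect_equal(IRanges::end(exonRanges(sub2)), 300L)
    expect_error(projectToGenome(m, 0, 10), "outside")
})
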