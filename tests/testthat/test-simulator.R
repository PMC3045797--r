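test_that("abundance draws follow the log-normal model reproducibly", {
    gs <- simulateGeneSet(nGenes = 4, seed = 5)
    # degenerate distribution: equal copies
    ab0 <- simulateAbundances(gs$models, simParams(seed = 2,
                                                   abundanceSdlog = 0))
    expect_true(all(ab0$copies == ab0$copies[1]))
    # determinism under a fixed seed
    p <- simParams(seed = 9)
    expect_identical(simulateAbundances(gs$models, p),
                     simulateAbundances(gs$models, p))
    # Monte-Carlo check of the stated spread (1000 genes, sdlog 1)
    many <- lapply(seq_len(1000), function(i)
        mkChain(1, 100, id = sprintf("t%d", i)))
    ab <- simulateAbundances(many, simParams(seed = 1, abundanceMeanlog = 5,
                                             abundanceSdlog = 1))
    se <- 1 / sqrt(2 * (length(many) - 1))
    expect_lt(abs(sd(log(ab$copies)) - 1), 3 * se + 0.02)
})

test_that("DpnII digestion cuts 5' of GATC and conserves the input", {
    expect_equal(dpniiDigest("TTGATCAA")$sequence, c("TT", "GATCAA"))
    expect_equal(dpniiDigest("AAAA")$sequence, "AAAA")
    expect_equal(dpniiDigest("GATCGATC")$sequence, c("GATC", "GATC"))
    set.seed(21)
    for (rep in 1:30) {
        s <- paste0(randomSeq(40), "GATC", randomSeq(sample(0:60, 1)),
                    if (runif(1) < 0.5) "GATC" else "", randomSeq(20))
        frags <- dpniiDigest(s)
        expect_equal(paste(frags$sequence, collapse = ""), s)
        expect_equal(frags$offset,
                     cumsum(c(1L, nchar(frags$sequence)))[seq_len(nrow(frags))])
    }
    expect_error(dpniiDigest(""), "empty")
})

test_that("heteroduplex loops are the variant-discordant positions", {
    genome <- mkGenome(randomSeq(2000))
    # identical chains (distinct ids): zero loop intervals
    a <- mkChain(c(1, 301), c(200, 500), id = "a", gene = "g")
    a2 <- mkChain(c(1, 301), c(200, 500), id = "a2", gene = "g")
    ab <- data.frame(transcript_id = c("a", "a2"), gene_id = "g",
                     copies = c(2L, 3L))
    dx <- formHeteroduplexes(list(a, a2), genome, ab)
    expect_true(all(vapply(dx, function(d) length(d@loopIntervals) == 0L,
                           logical(1))))
    expect_true(all(vapply(dx, function(d) d@weight == 6, logical(1))))

    # B skips a 60-nt exon of A: one loop of 60 in A coordinates
    A <- mkChain(c(1, 301, 601), c(200, 360, 800), id = "A", gene = "g")
    B <- mkChain(c(1, 601), c(200, 800), id = "B", gene = "g")
    ab2 <- data.frame(transcript_id = c("A", "B"), gene_id = "g",
                      copies = c(1L, 1L))
    dx2 <- formHeteroduplexes(list(A, B), genome, ab2)
    fromA <- Filter(function(d) d@variantA == "A", dx2)
    loops <- do.call(c, lapply(fromA, function(d) d@loopIntervals))
    expect_equal(sum(IRanges::width(loops)), 60L)
    # loop sits at transcript positions 201..260 of A
    expect_equal(min(IRanges::start(loops)), 201L)
    expect_equal(max(IRanges::end(loops)), 260L)

    expect_error(formHeteroduplexes(list(
        mkChain(1, 100, id = "x", gene = "g1"),
        mkChain(1, 100, id = "y", gene = "g2")), genome, ab), "different genes")
})

test_that("duplex fragments tile the paired span and loops are uncut", {
    # per-base genomic-position oracle over simulated variant pairs
    gs <- simulateGeneSet(nGenes = 8, seed = 31)
    ab <- simulateAbundances(gs$models, simParams(seed = 31))
    byGene <- split(gs$models, vapply(gs$models, geneId, character(1)))
    for (g in names(byGene)) {
        vs <- byGene[[g]]
        dx <- formHeteroduplexes(vs, gs$genome, ab, simParams(seed = 31))
        for (first in c(TRUE, FALSE)) {
            va <- if (first) vs[[1]] else vs[[2]]
            vb <- if (first) vs[[2]] else vs[[1]]
            sub <- Filter(function(d) d@variantA == transcriptId(va), dx)
            posA <- spliceLoop:::.genomicPositions(va)
            posB <- spliceLoop:::.genomicPositions(vb)
            shared <- posA %in% posB
            span <- range(which(shared))
            # fragments tile [first shared, last shared] without overlap
            frs <- do.call(c, lapply(sub, function(d) d@fragment))
            frs <- frs[order(IRanges::start(frs))]
            expect_equal(min(IRanges::start(frs)), span[1])
            expect_equal(max(IRanges::end(frs)), span[2])
            expect_equal(sum(IRanges::width(frs)), span[2] - span[1] + 1L)
            # loop union equals the discordant positions inside the span
            loops <- do.call(c, lapply(sub, function(d) d@loopIntervals))
            loopPos <- if (length(loops))
                sort(unique(unlist(Map(seq, IRanges::start(loops),
                                       IRanges::end(loops))))) else integer()
            expect_equal(loopPos,
                         intersect(which(!shared), seq(span[1], span[2])))
        }
    }
})

test_that("noise-free capture emits only loop fragments, error-free reads", {
    gs <- simulateGeneSet(nGenes = 6, seed = 13)
    p <- simParams(seed = 13, captureNoise = 0, readErrorRate = 0)
    sim <- simulateLibrary(gs$models, gs$genome, p)
    expect_gt(length(sim$reads), 0)
    expect_true(all(sim$truth$loop_flag))
    byId <- setNames(gs$models,
                     vapply(gs$models, transcriptId, character(1)))
    seqs <- as.character(sim$reads)
    for (i in seq_along(seqs)) {
        src <- as.character(splicedSequence(byId[[sim$truth$variant_a[i]]],
                                            gs$genome))
        expect_true(grepl(seqs[i], src, fixed = TRUE))
    }
})

test_that("library simulation is deterministic under the seed", {
    gs <- simulateGeneSet(nGenes = 5, seed = 3)
    p <- simParams(seed = 3)
    s1 <- simulateLibrary(gs$models, gs$genome, p)
    s2 <- simulateLibrary(gs$models, gs$genome, p)
    expect_identical(as.character(s1$reads), as.character(s2$reads))
    expect_identical(s1$truth, s2$truth)
})

test_that("clustering redundancy rises monotonically with PCR redundancy", {
    gs <- simulateGeneSet(nGenes = 10, seed = 17)
    red <- vapply(c(2, 6, 12), function(pcr) {
        sim <- simulateLibrary(gs$models, gs$genome,
                               simParams(seed = 17, pcrRedundancy = pcr))
        cl <- clusterReads(sim$reads)
        redundancy(length(sim$reads), length(cl))
    }, numeric(1))
    expect_true(all(diff(red) > 0))
})

test_that("reads and genome round-trip through FASTQ and FASTA", {
    gs <- simulateGeneSet(nGenes = 3, seed = 37)
    sim <- simulateLibrary(gs$models, gs$genome, simParams(seed = 37))
    fq <- tempfile(fileext = ".fastq")
    tsv <- tempfile(fileext = ".tsv")
    writeSimulatedReads(sim, fq, tsv)
    back <- readFastqReads(fq)
    expect_equal(as.character(back), as.character(sim$reads),
                 ignore_attr = TRUE)
    expect_equal(as.character(Biostrings::quality(back)),
                 as.character(Biostrings::quality(sim$reads)),
                 ignore_attr = TRUE)
    manifest <- read.delim(tsv)
    expect_equal(manifest$read_id, sim$truth$read_id)
    fa <- tempfile(fileext = ".fa")
    writeGenome(gs$genome, fa)
    g2 <- readGenome(fa)
    expect_equal(as.character(g2), as.character(gs$genome))
})
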