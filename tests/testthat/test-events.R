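test_that("toy chain pairs classify to the defined event types", {
    # exon skipping: B carries a 20-nt exon inside A's intron
    A <- mkChain(c(1, 201), c(100, 300), id = "A")
    B <- mkChain(c(1, 141, 201), c(100, 160, 300), id = "B")
    ev <- eventsToDf(classifyEvents(A, B))
    expect_equal(ev, dfNoRownames(data.frame(
        type = "exon_skipping", start = 141L, end = 160L, size = 20L)))

    # intron retention: single-exon A spans B's intron
    A2 <- mkChain(1, 300, id = "A2")
    B2 <- mkChain(c(1, 201), c(100, 300), id = "B2")
    ev2 <- eventsToDf(classifyEvents(A2, B2))
    expect_equal(ev2, dfNoRownames(data.frame(
        type = "intron_retention", start = 101L, end = 200L, size = 100L)))

    # alternative 5' splice site elongating an exon by 117 nt (plus strand,
    # introns sharing the acceptor, donors 117 nt apart)
    A3 <- mkChain(c(1, 501), c(217, 700), id = "A3")
    B3 <- mkChain(c(1, 501), c(100, 700), id = "B3")
    ev3 <- eventsToDf(classifyEvents(A3, B3))
    expect_equal(ev3$type, "alt_5ss")
    expect_equal(ev3$size, 117L)
    expect_equal(c(ev3$start, ev3$end), c(101L, 217L))
})

test_that("classification is symmetric and stays inside the window", {
    set.seed(71)
    for (rep in 1:50) {
        p <- randomChainPair()
        win <- oracleWindow(p$A, p$B)
        if (is.null(win)) next
        evAB <- eventsToDf(classifyEvents(p$A, p$B))
        evBA <- eventsToDf(classifyEvents(p$B, p$A))
        expect_equal(evAB, evBA)
        if (nrow(evAB)) {
            expect_true(all(evAB$start >= win[1] & evAB$end <= win[2]))
        }
    }
})

test_that("classifier agrees with the brute-force boundary enumeration", {
    set.seed(73)
    for (rep in 1:200) {
        p <- randomChainPair()
        want <- tryCatch(dfNoRownames(oracleEvents(p$A, p$B)),
                         error = function(e) NULL)
        if (is.null(oracleWindow(p$A, p$B))) {
            expect_error(classifyEvents(p$A, p$B), "overlap")
        } else {
            got <- eventsToDf(classifyEvents(p$A, p$B))
            expect_equal(got, want)
        }
    }
})

test_that("mirroring a case to the minus strand preserves event labels", {
    set.seed(79)
    for (rep in 1:30) {
        strandKeep <- TRUE
        exA <- randomExons(5); exB <- perturbExons(exA)
        A <- mkChain(IRanges::start(exA), IRanges::end(exA), "+", "A")
        B <- mkChain(IRanges::start(exB), IRanges::end(exB), "+", "B")
        if (is.null(oracleWindow(A, B))) next
        plus <- eventsToDf(classifyEvents(A, B))
        # reflect all coordinates around M so the minus-strand gene reads
        # identically in transcription order
        M <- max(IRanges::end(exA), IRanges::end(exB)) + 10L
        refl <- function(ex) IRanges::IRanges(rev(M - IRanges::end(ex)),
                                              rev(M - IRanges::start(ex)))
        Am <- mkChain(IRanges::start(refl(exA)), IRanges::end(refl(exA)),
                      "-", "A")
        Bm <- mkChain(IRanges::start(refl(exB)), IRanges::end(refl(exB)),
                      "-", "B")
        minus <- eventsToDf(classifyEvents(Am, Bm))
        minusBack <- minus
        minusBack$start <- M - minus$end
        minusBack$end <- M - minus$start
        minusBack <- minusBack[order(minusBack$type, minusBack$start,
                                     minusBack$end), , drop = FALSE]
        rownames(minusBack) <- NULL
        expect_equal(plus, minusBack)
    }
})

test_that("reference clustering matches connected components by overlap", {
    # one asset overlapping one reference exon: a single 2-member cluster
    ref <- mkChain(c(1, 201), c(100, 300), id = "ref")
    asset <- AlignedAsset("as1", mkChain(50, 90, id = "as1"), 41, 41, 41)
    cl <- clusterWithReferences(list(asset), list(ref))
    expect_length(cl, 1)
    expect_equal(cl[[1]]@assetIds, "as1")
    expect_equal(cl[[1]]@referenceIds, "ref")
    expect_true(cl[[1]]@hasReference)

    # opposite strand: separate clusters
    assetM <- AlignedAsset("as2", mkChain(50, 90, "-", id = "as2"),
                           41, 41, 41)
    cl2 <- clusterWithReferences(list(assetM), list(ref))
    expect_length(cl2, 1)
    expect_length(cl2[[1]]@referenceIds, 0)
    expect_false(cl2[[1]]@hasReference)

    # graph oracle on random interval sets
    set.seed(83)
    for (rep in 1:15) {
        chains <- lapply(1:8, function(i) {
            st <- sample(1:600, 1)
            mkChain(st, st + sample(30:150, 1),
                    sample(c("+", "-"), 1, prob = c(.8, .2)),
                    sprintf("m%d", i))
        })
        assets <- lapply(chains[1:4], function(ch)
            AlignedAsset(transcriptId(ch), ch, 10, 10, 10))
        refs <- chains[5:8]
        comp <- oracleComponents(chains)
        got <- clusterWithReferences(assets, refs)
        # same partition restricted to components containing an asset
        gotSets <- lapply(got, function(cl)
            sort(c(cl@assetIds, cl@referenceIds)))
        wantSets <- Filter(function(s) any(s %in% sprintf("m%d", 1:4)),
                           lapply(split(seq_along(chains), comp),
                                  function(ix) sort(sprintf("m%d", ix))))
        expect_setequal(gotSets, unname(wantSets))
    }
})

test_that("comparison window spans the outermost exonic overlaps", {
    A <- mkChain(c(1, 201), c(100, 300), id = "A")
    expect_equal(comparisonWindow(A, A), IRanges::IRanges(1, 300))
    # asset covering exons 2-4 of a 6-exon reference
    ref <- mkChain(seq(1, 1001, by = 200), seq(100, 1100, by = 200),
                   id = "r")
    asset <- mkChain(c(250, 401, 601), c(300, 500, 650), id = "a")
    w <- comparisonWindow(asset, ref)
    expect_equal(IRanges::start(w), 250L)
    expect_equal(IRanges::end(w), 650L)
    # all-pairs intersection oracle
    set.seed(89)
    for (rep in 1:30) {
        p <- randomChainPair()
        want <- oracleWindow(p$A, p$B)
        if (is.null(want)) {
            expect_error(comparisonWindow(p$A, p$B), "overlap")
        } else {
            w <- comparisonWindow(p$A, p$B)
            expect_equal(c(IRanges::start(w), IRanges::end(w)), want)
        }
    }
    expect_error(comparisonWindow(A, mkChain(1000, 1100, id = "far")),
                 "overlap")
    expect_error(comparisonWindow(A, mkChain(1, 100, "-", id = "neg")),
                 "strand")
})

test_that("event summaries preserve totals and one-decimal percentages", {
    s <- summarizeEvents(c(alt_5ss = 62, alt_3ss = 55, exon_skipping = 13,
                           intron_retention = 8))
    expect_equal(s$total, 138L)
    byType <- setNames(s$byType$percent, s$byType$type)
    expect_equal(byType[["alt_5ss"]], 44.9)
    expect_equal(byType[["alt_3ss"]], 39.9)
    expect_equal(byType[["exon_skipping"]], 9.4)
    expect_equal(byType[["intron_retention"]], 5.8)
    empty <- summarizeEvents(classifyEvents(mkChain(1, 100, id = "x"),
                                            mkChain(1, 100, id = "y")))
    expect_equal(empty$total, 0L)
    expect_true(all(empty$byType$percent == 0))
})

test_that("intronless overlap fraction is an interval-intersection count", {
    mkIntronless <- function(i, st) AlignedAsset(
        sprintf("il%d", i), mkChain(st, st + 49, id = sprintf("il%d", i)),
        50, 50, 50)
    # 63 of 96 spans overlapping one event region
    assets <- lapply(1:96, function(i)
        mkIntronless(i, if (i <= 63) 1000 + i else 5000 + i * 100))
    events <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1200))
    expect_equal(flagIntronlessOverlap(assets, events), 65.6)
    none <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2))
    expect_equal(flagIntronlessOverlap(assets, none), 0)
    # interval oracle under random placement
    set.seed(97)
    ev <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        c(100, 900, 2000), c(300, 1000, 2500)))
    sts <- sample(1:3000, 40)
    rnd <- lapply(seq_along(sts), function(i) mkIntronless(i, sts[i]))
    want <- sum(vapply(sts, function(s)
        any(s + 49 >= GenomicRanges::start(ev) &
            s <= GenomicRanges::end(ev)), logical(1)))
    expect_equal(flagIntronlessOverlap(rnd, ev), percentOf(want, 40))
})
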