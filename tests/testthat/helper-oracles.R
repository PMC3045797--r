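# independent brute-force oracles, kept free of package internals

# all-pairs exonic-intersection window
oracleWindow <- function(A, B) {
    exA <- exonRanges(A); exB <- exonRanges(B)
    lo <- Inf; hi <- -Inf
    for (i in seq_along(exA)) for (j in seq_along(exB)) {
        s <- max(IRanges::start(exA)[i], IRanges::start(exB)[j])
        e <- min(IRanges::end(exA)[i], IRanges::end(exB)[j])
        if (s <= e) { lo <- min(lo, s); hi <- max(hi, e) }
    }
    if (!is.finite(lo)) NULL else c(lo, hi)
}

.oracleIntrons <- function(ex) {
    n <- nrow(ex)
    if (n < 2L) return(data.frame(start = integer(), end = integer()))
    data.frame(start = ex$end[-n] + 1L, end = ex$start[-1L] - 1L)
}

# brute-force event enumeration: every intron/exon containment and boundary
# relation is checked explicitly from plain data frames
oracleEvents <- function(A, B) {
    empty <- data.frame(type = character(), start = integer(),
                        end = integer(), size = integer())
    win <- oracleWindow(A, B)
    if (is.null(win)) return(empty)
    strand <- strandOf(A)
    exA <- as.data.frame(exonRanges(A))[, c("start", "end")]
    exB <- as.data.frame(exonRanges(B))[, c("start", "end")]
    iA <- .oracleIntrons(exA); iB <- .oracleIntrons(exB)
    keepA <- which(iA$start >= win[1] & iA$end <= win[2])
    keepB <- which(iB$start >= win[1] & iB$end <= win[2])
    rows <- list()
    suppressed <- character()  # "ai/bi" intron pairs explained by skipping

    scanSkip <- function(host, hostKeep, exOther, iOther, hostIsA) {
        for (hi in hostKeep) {
            I <- host[hi, ]
            ins <- which(exOther$start > I$start & exOther$end < I$end)
            if (length(ins) == 0L) next
            upIv <- c(I$start, exOther$start[min(ins)] - 1L)
            dnIv <- c(exOther$end[max(ins)] + 1L, I$end)
            oi_up <- which(iOther$start == upIv[1] & iOther$end == upIv[2])
            oi_dn <- which(iOther$start == dnIv[1] & iOther$end == dnIv[2])
            if (length(oi_up) != 1L || length(oi_dn) != 1L) next
            rows[[length(rows) + 1L]] <<- data.frame(
                type = "exon_skipping",
                start = exOther$start[min(ins)], end = exOther$end[max(ins)],
                size = sum(exOther$end[ins] - exOther$start[ins] + 1L))
            pair <- if (hostIsA) paste0(hi, "/", c(oi_up, oi_dn))
                    else paste0(c(oi_up, oi_dn), "/", hi)
            suppressed <<- c(suppressed, pair)
        }
    }
    scanSkip(iA, keepA, exB, iB, TRUE)
    scanSkip(iB, keepB, exA, iA, FALSE)

    scanRet <- function(host, hostKeep, exOther) {
        for (hi in hostKeep) {
            I <- host[hi, ]
            if (any(exOther$start < I$start & I$end < exOther$end))
                rows[[length(rows) + 1L]] <<- data.frame(
                    type = "intron_retention", start = I$start, end = I$end,
                    size = I$end - I$start + 1L)
        }
    }
    scanRet(iA, keepA, exB)
    scanRet(iB, keepB, exA)

    for (ai in keepA) for (bi in keepB) {
        if (paste0(ai, "/", bi) %in% suppressed) next
        a <- iA[ai, ]; b <- iB[bi, ]
        if (a$start == b$start && a$end == b$end) next
        if (strand == "+") {
            dA <- a$start; aA <- a$end; dB <- b$start; aB <- b$end
        } else {
            dA <- a$end; aA <- a$start; dB <- b$end; aB <- b$start
        }
        if (aA == aB && dA != dB) {
            lo <- min(dA, dB); hi <- max(dA, dB)
            coords <- if (strand == "+") c(lo, hi - 1L) else c(lo + 1L, hi)
            rows[[length(rows) + 1L]] <- data.frame(
                type = "alt_5ss", start = coords[1], end = coords[2],
                size = hi - lo)
        } else if (dA == dB && aA != aB) {
            lo <- min(aA, aB); hi <- max(aA, aB)
            coords <- if (strand == "+") c(lo + 1L, hi) else c(lo, hi - 1L)
            rows[[length(rows) + 1L]] <- data.frame(
                type = "alt_3ss", start = coords[1], end = coords[2],
                size = hi - lo)
        }
    }
    if (length(rows) == 0L) return(empty)
    out <- do.call(rbind, rows)
    out <- out[!duplicated(out[, c("type", "start", "end")]), ]
    out[order(out$type, out$start, out$end), , drop = FALSE]
}

# canonical form of a classifyEvents GRanges for comparison
eventsToDf <- function(gr) {
    if (length(gr) == 0L)
        return(data.frame(type = character(), start = integer(),
                          end = integer(), size = integer()))
    df <- data.frame(type = S4Vectors::mcols(gr)$type,
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     size = S4Vectors::mcols(gr)$size)
    df <- df[order(df$type, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
    df
}

dfNoRownames <- function(df) { rownames(df) <- NULL; df }

# connected components by pairwise exonic overlap (same chrom & strand)
oracleComponents <- function(chains) {
    n <- length(chains)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        a <- chains[[i]]; b <- chains[[j]]
        if (chromName(a) != chromName(b) || strandOf(a) != strandOf(b)) next
        exA <- exonRanges(a); exB <- exonRanges(b)
        for (p in seq_along(exA)) for (q in seq_along(exB)) {
            if (max(IRanges::start(exA)[p], IRanges::start(exB)[q]) <=
                min(IRanges::end(exA)[p], IRanges::end(exB)[q])) {
                adj[i, j] <- TRUE
            }
        }
    }
    comp <- rep(NA_integer_, n); cid <- 0L
    for (s in seq_len(n)) {
        if (!is.na(comp[s])) next
        cid <- cid + 1L
        queue <- s
        while (length(queue)) {
            v <- queue[1L]; queue <- queue[-1L]
            if (!is.na(comp[v])) next
            comp[v] <- cid
            queue <- c(queue, which(adj[v, ] & is.na(comp)))
        }
    }
    comp
}

# brute-force quality trimming: test every substring for the window rule
oracleTrimQuality <- function(quals, w, minGood, minQ, minLen) {
    L <- length(quals)
    best <- c(0L, 0L)  # from, to
    for (a in seq_len(L)) for (b in seq(a, L)) {
        if (b - a + 1L < w) next
        good <- TRUE
        for (st in seq(a, b - w + 1L)) {
            if (sum(quals[st:(st + w - 1L)] >= minQ) < minGood) {
                good <- FALSE; break
            }
        }
        if (good && (b - a + 1L) > (best[2L] - best[1L] + 1L))
            best <- c(a, b)
    }
    if (best[1L] == 0L || best[2L] - best[1L] + 1L < minLen)
        return(NULL)
    best
}
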