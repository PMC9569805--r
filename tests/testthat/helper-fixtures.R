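# in-code fixtures and independent oracles used across the suite

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
    library(S4Vectors)
})

# build TranscriptModels from a list: tx_id -> list(gene, scf, strand, exons)
# where exons is a 2-column matrix or a vector c(s1,e1, s2,e2, ...)
makeTx <- function(spec) {
    grl <- GRangesList(lapply(spec, function(x) {
        m <- x$exons
        if (!is.matrix(m)) m <- matrix(m, ncol = 2, byrow = TRUE)
        GRanges(x$scf, IRanges(m[, 1], m[, 2]), strand = x$strand)
    }))
    names(grl) <- names(spec)
    TranscriptModels(grl,
        geneIds = vapply(spec, `[[`, character(1), "gene"),
        smrtSupported = vapply(spec, function(x)
            if (is.null(x$smrt)) TRUE else x$smrt, logical(1)))
}

# a two-isoform cassette-exon gene plus its skipping isoform
seGene <- function(scf = "s1", strand = "+") {
    makeTx(list(
        tx1 = list(gene = "g1", scf = scf, strand = strand,
                   exons = c(101, 200, 301, 400, 501, 600)),
        tx2 = list(gene = "g1", scf = scf, strand = strand,
                   exons = c(101, 200, 501, 600))))
}

# a three-exon gene with an intron-retaining isoform
riGene <- function(scf = "s1", strand = "+") {
    makeTx(list(
        tx1 = list(gene = "g1", scf = scf, strand = strand,
                   exons = c(101, 400, 501, 600)),        # retains intron 1
        tx2 = list(gene = "g1", scf = scf, strand = strand,
                   exons = c(101, 200, 301, 400, 501, 600))))
}

# per-base bitmap oracle for reciprocal overlap fractions: repeats are
# merged first, and only merged blocks touching the transcript count
oracleOverlap <- function(exonMat, repMat) {
    lim <- max(exonMat[, 2], repMat[, 2]) + 10L
    exB <- logical(lim); allRep <- logical(lim)
    for (i in seq_len(nrow(exonMat)))
        exB[exonMat[i, 1]:exonMat[i, 2]] <- TRUE
    for (i in seq_len(nrow(repMat)))
        allRep[repMat[i, 1]:repMat[i, 2]] <- TRUE
    runs <- rle(allRep)
    stops <- cumsum(runs$lengths)
    starts <- stops - runs$lengths + 1L
    repB <- logical(lim)
    for (k in which(runs$values)) {
        block <- starts[k]:stops[k]
        if (any(exB[block])) repB[block] <- TRUE
    }
    if (!any(repB)) return(c(0, 0))
    ov <- sum(exB & repB)
    c(ov / sum(repB), ov / sum(exB))
}

# exact two-sided signed-rank p-value by enumeration over all sign vectors
oracleSignedRankExact <- function(x, y) {
    d <- y - x
    stopifnot(all(d != 0), !any(duplicated(abs(d))))
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.vector(signs %*% r)
    pLe <- mean(Wall <= W); pGe <- mean(Wall >= W)
    min(1, 2 * min(pLe, pGe))
}

# exact two-sided Mann-Whitney p-value by enumeration over group labelings
oracleMannWhitneyExact <- function(x, y) {
    stopifnot(!any(duplicated(c(x, y))))
    n <- length(x); m <- length(y)
    pool <- c(x, y)
    U <- sum(rank(pool)[seq_len(n)]) - n * (n + 1) / 2
    combs <- utils::combn(n + m, n)
    Uall <- apply(combs, 2, function(idx)
        sum(rank(pool)[idx]) - n * (n + 1) / 2)
    pLe <- mean(Uall <= U); pGe <- mean(Uall >= U)
    min(1, 2 * min(pLe, pGe))
}

# straightforward position-by-position PWM scan (no positional constraint)
oracleScanScores <- function(pwm, sequence, pseudocount = 0.01) {
    s <- strsplit(sequence, "")[[1]]
    w <- ncol(pwm)
    vapply(seq_len(length(s) - w + 1L), function(at) {
        sum(vapply(seq_len(w), function(j)
            log2((pwm[s[at + j - 1L], j] + pseudocount) / 0.25), numeric(1)))
    }, numeric(1))
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
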