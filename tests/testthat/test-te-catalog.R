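test_that("overlap fractions match interval arithmetic and a bitmap oracle", {
    ex <- GRanges("s1", IRanges(1, 100))
    expect_equal(overlapFractions(ex, GRanges("s1", IRanges(1, 95))),
                 c(repeat_fraction = 1.0, self_fraction = 0.95))
    expect_equal(overlapFractions(ex, GRanges("s1", IRanges(1, 50))),
                 c(repeat_fraction = 1.0, self_fraction = 0.5))
    # random 20-interval cases against a per-base bitmap
    set.seed(42)
    for (rep in 1:20) {
        s <- sort(sample(1:12, 5)) * 500
        exm <- cbind(s, s + sample(50:120, 5))
        r <- sample(1:6000, 20)
        rpm <- cbind(r, r + sample(10:200, 20))
        got <- overlapFractions(GRanges("s1", IRanges(exm[, 1], exm[, 2])),
                                GRanges("s1", IRanges(rpm[, 1], rpm[, 2])))
        expect_equal(unname(got), oracleOverlap(exm, rpm), tolerance = 1e-12)
    }
    expect_error(overlapFractions(GRanges(), GRanges("s1", IRanges(1, 5))),
                 "zero-length")
})

test_that("the >90/>90 rule classifies the three planted regimes", {
    expect_identical(classifyTeTranscript(c(0.95, 0.95)),
                     "expressed_transposon")
    expect_identical(classifyTeTranscript(c(0.95, 0.50)), "te_associated")
    expect_identical(classifyTeTranscript(c(0.50, 0.95)), "none")
    # boundary is strict: exactly 0.9 does not qualify
    expect_identical(classifyTeTranscript(c(0.9, 0.95)), "none")
    expect_identical(classifyTeTranscript(c(0.95, 0.9)), "te_associated")
})

test_that("classification is monotone in both overlap fractions", {
    rank <- c(none = 0, te_associated = 1, expressed_transposon = 2)
    fr <- seq(0, 1, by = 0.1)
    for (r1 in fr) for (s1 in fr) {
        base <- rank[[classifyTeTranscript(c(r1, s1))]]
        expect_gte(rank[[classifyTeTranscript(c(min(r1 + 0.2, 1), s1))]], base)
        expect_gte(rank[[classifyTeTranscript(c(r1, min(s1 + 0.2, 1)))]], base)
    }
})

test_that("N runs in the 20-bp flanks remove a transposon, clipped at edges", {
    genome <- DNAStringSet(c(s1 = paste0(
        strrep("A", 80), "N",                 # N at position 81
        strrep("C", 19), strrep("G", 100),    # transcript at 101..200
        strrep("T", 100))))
    models <- makeTx(list(
        x.1 = list(gene = "g1", scf = "s1", strand = "+", exons = c(101, 200)),
        y.1 = list(gene = "g2", scf = "s1", strand = "+", exons = c(96, 200)),
        z.1 = list(gene = "g3", scf = "s1", strand = "+", exons = c(1, 60))))
    # x: nearest N is 20 bp upstream -> inside the window -> removed
    expect_identical(filterNFlanked("x.1", models, genome), character(0))
    # y: nearest N is 15bp up of 96? N at 81, window 76..95 covers it
    expect_identical(filterNFlanked("y.1", models, genome), character(0))
    # z: starts at the scaffold edge, downstream flank is clean -> kept
    expect_identical(filterNFlanked("z.1", models, genome), "z.1")
    # N beyond the window is ignored
    genome2 <- DNAStringSet(c(s1 = paste0(strrep("A", 75), "N",
                                          strrep("C", 300))))
    models2 <- makeTx(list(w.1 = list(gene = "g1", scf = "s1", strand = "+",
                                      exons = c(101, 200))))
    expect_identical(filterNFlanked("w.1", models2, genome2), "w.1")
})

test_that("family composition reproduces printed two-decimal percentages", {
    counts <- c("unclassified LTR" = 2, "DNA/TcMar" = 8, "LINE/L2" = 13,
                "unclassified SINE" = 41)
    out <- familyComposition(counts)
    expect_equal(out$ratio_pct[match(names(counts), out$family)],
                 c(3.13, 12.50, 20.31, 64.06))
    expect_lt(abs(sum(out$ratio_pct) - 100), 0.02)
    # a single family is 100.00
    expect_equal(familyComposition(c(SINE = 7))$ratio_pct, 100)
    # permuting the counts permutes the ratios
    out2 <- familyComposition(counts[c(3, 1, 4, 2)])
    expect_equal(out2$ratio_pct[match(out$family, out2$family)],
                 out$ratio_pct)
})

test_that("motif scanning honors score and positional constraints", {
    m <- motifModel("m", (function(p) p)(matrix(
        rep(0.25, 4 * 8), 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))),
        maxStart = 50L)
    # informative motif with known consensus
    pwm <- matrix(0.05, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
    cons <- c("T", "G", "A", "C", "C", "A", "T", "G")
    for (j in 1:8) pwm[cons[j], j] <- 0.85
    m <- motifModel("m", pwm, maxStart = 50L)
    consensus <- paste(cons, collapse = "")
    expect_identical(motifConsensus(m), consensus)

    set.seed(7)
    bg <- function(n) randomSeq(n)
    hit <- scanMotif(m, paste0(bg(29), consensus, bg(40)))
    expect_identical(hit$start, 30L)
    # the same motif starting at 60 violates the positional constraint
    expect_null(scanMotif(m, paste0(bg(59), consensus, bg(20))))
    # consensus scores maximum over all sequences
    lodMax <- sum(apply(log2((pwm + 0.01) / 0.25), 2, max))
    expect_equal(hit$score, lodMax, tolerance = 1e-12)
    # exhaustive equivalence with a brute-force position scan
    for (rep in 1:5) {
        s <- randomSeq(50)
        sc <- oracleScanScores(pwm, s)
        got <- scanMotif(motifModel("m", pwm, maxStart = 50L,
                                    scoreThreshold = -Inf), s)
        expect_identical(got$start, which.max(sc))
        expect_equal(got$score, max(sc), tolerance = 1e-12)
    }
    # N positions are skipped, not scored
    withN <- paste0(strrep("N", 10), consensus, bg(20))
    expect_identical(scanMotif(m, withN)$start, 11L)
})

test_that("motif co-occurrence grouping is plain set logic", {
    expect_identical(
        classifyMotifCombination(c(TRUE, TRUE, FALSE, FALSE),
                                 c(TRUE, FALSE, TRUE, FALSE)),
        c("both", "only_motif1", "only_motif5", "none"))
    # list-of-hits interface
    expect_identical(
        classifyMotifCombination(list(list(start = 10), NULL),
                                 list(list(start = 5), NULL)),
        c("both", "none"))
})
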