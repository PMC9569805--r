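mk2 <- function() makeTx(list(
    a.1 = list(gene = "gA", scf = "s1", strand = "+",
               exons = c(10001, 10100, 10301, 10400)),
    a.2 = list(gene = "gA", scf = "s1", strand = "+", exons = c(10001, 10400)),
    b.1 = list(gene = "gB", scf = "s1", strand = "-",
               exons = c(20001, 20100, 20301, 20400))))

test_that("the expression floor keeps a transcript iff max TPM reaches it", {
    models <- mk2()
    tpm <- rbind(a.1 = c(0.8, 0.6, 0.2),
                 a.2 = c(0, 0, 5.0),
                 b.1 = c(2, 2, 2))
    colnames(tpm) <- paste0("T", 2:4)
    res <- filterLowExpression(models, tpm, floor = 1)
    expect_setequal(txIds(res$models), c("a.2", "b.1"))   # 0.8 max removed
    expect_identical(res$report$n_removed, 1L)
    expect_identical(res$report$n_input,
                     res$report$n_removed + res$report$n_surviving)
    # a transcript expressed in a single sample survives under the max rule
    expect_true("a.2" %in% txIds(res$models))
    # floor 0 is the identity filter
    expect_identical(txIds(filterLowExpression(models, tpm, 0)$models),
                     txIds(models))
    # transcripts missing from the matrix count as zero
    res2 <- filterLowExpression(models, tpm[c("a.1", "b.1"), ], floor = 1)
    expect_false("a.2" %in% txIds(res2$models))
})

test_that("pooled intron-length quantile uses the nearest-rank definition", {
    spec <- lapply(seq_len(50), function(i) {
        # intron of length i*2 between two 50-bp exons
        s <- 1000 * i
        list(gene = paste0("g", i), scf = "s1", strand = "+",
             exons = c(s, s + 49, s + 50 + 2 * i, s + 99 + 2 * i))
    })
    names(spec) <- paste0("t", seq_len(50), ".1")
    models <- makeTx(spec)   # intron lengths 2,4,...,100
    expect_identical(intronLengthPercentile(models, 0.95), 96L)
    expect_identical(intronLengthPercentile(models, 0.5), 50L)
    single <- makeTx(list(x.1 = list(gene = "gX", scf = "s1", strand = "+",
                                     exons = c(1, 100))))
    expect_error(intronLengthPercentile(single), "no introns")
})

test_that("fragmented transcripts are removed unless long-read supported", {
    models <- makeTx(list(
        edge.1 = list(gene = "g1", scf = "s1", strand = "+",
                      exons = c(2001, 2100, 2301, 2400), smrt = FALSE),
        edge.2 = list(gene = "g2", scf = "s1", strand = "+",
                      exons = c(2001, 2100, 2301, 2400), smrt = TRUE),
        mid.1 = list(gene = "g3", scf = "s1", strand = "+",
                     exons = c(50001, 50100, 50301, 50400), smrt = FALSE)))
    slen <- c(s1 = 100000L)
    res <- filterFragmented(models, slen, threshold = 7875)
    # distance 2000 < 7875 and no support -> removed; support -> kept
    expect_setequal(txIds(res$models), c("edge.2", "mid.1"))
    # distance above the threshold is kept regardless of support
    expect_true("mid.1" %in% txIds(res$models))
    expect_error(filterFragmented(models, c(s1 = 2350L), 100),
                 "beyond")
})

test_that("precursor singletons are removed only beside multi-exon isoforms", {
    models <- makeTx(list(
        a.1 = list(gene = "gA", scf = "s1", strand = "+",
                   exons = c(101, 200, 301, 400)),
        a.2 = list(gene = "gA", scf = "s1", strand = "+", exons = c(101, 400)),
        b.1 = list(gene = "gB", scf = "s1", strand = "+", exons = c(1001, 1400)),
        c.1 = list(gene = "gC", scf = "s1", strand = "+",
                   exons = c(2001, 2100, 2301, 2400)),
        c.2 = list(gene = "gC", scf = "s1", strand = "+",
                   exons = c(2001, 2100, 2351, 2400))))
    res <- filterPrecursorSingletons(models)
    expect_setequal(txIds(res$models), c("a.1", "b.1", "c.1", "c.2"))
    # single-exon-only gene untouched; all-multi-exon gene unchanged
    expect_true("b.1" %in% txIds(res$models))
})

test_that("curation filters are idempotent", {
    models <- mk2()
    tpm <- rbind(a.1 = c(5, 5, 5), a.2 = c(2, 0, 0), b.1 = c(0.5, 0.2, 0))
    colnames(tpm) <- paste0("T", 2:4)
    f1 <- filterLowExpression(models, tpm, 1)
    f1b <- filterLowExpression(f1$models, tpm, 1)
    expect_identical(txIds(f1b$models), txIds(f1$models))
    expect_identical(f1b$report$n_removed, 0L)
    p1 <- filterPrecursorSingletons(models)
    p2 <- filterPrecursorSingletons(p1$models)
    expect_identical(txIds(p2$models), txIds(p1$models))
})

test_that("coding consensus and gene class follow the two-predictor rule", {
    expect_identical(classifyCodingConsensus("noncoding", "noncoding"),
                     "lncRNA")
    expect_identical(classifyCodingConsensus("coding", "coding"), "mRNA")
    expect_identical(classifyCodingConsensus("coding", "noncoding"), "TUCP")
    expect_identical(classifyCodingConsensus("noncoding", "coding"), "TUCP")
    expect_error(classifyCodingConsensus("maybe", "coding"), "label")

    expect_identical(assignGeneClass(c("lncRNA", "lncRNA")), "lncRNA")
    expect_identical(assignGeneClass(c("mRNA", "TUCP")), "misc")
    expect_identical(assignGeneClass("mRNA"), "mRNA")
    expect_error(assignGeneClass(character()), "empty")
})

test_that("the full curation pipeline reports per-rule attrition", {
    cfg <- simulationConfig(seed = 12, eventMix = c(RI = 3L), nGenes = 11L)
    sim <- simulateTranscriptome(cfg)
    slen <- setNames(nchar(sim$genome), names(sim$genome))
    res <- curateTranscripts(sim$models, sim$tpm, slen, edgeThreshold = 100)
    expect_identical(res$report$rule, c("low_tpm", "fragmented", "precursor"))
    expect_identical(sum(res$report$n_removed),
                     length(sim$models) - length(res$models))
})
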