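test_that("genome generation honors the length contract and the seed", {
    cfg <- simulationConfig(seed = 1, nScaffolds = 2L, scaffoldLength = 50000L)
    g <- simulateGenome(cfg)
    expect_length(g, 2)
    expect_identical(unname(nchar(g)), c(50000L, 50000L))
    expect_true(all(strsplit(as.character(g[[1]]), "")[[1]] %in%
                    c("A", "C", "G", "T")))
    g2 <- simulateGenome(cfg)
    expect_identical(as.character(g), as.character(g2))
    g3 <- simulateGenome(simulationConfig(seed = 2, nScaffolds = 2L,
                                          scaffoldLength = 50000L))
    expect_false(identical(as.character(g[[1]]), as.character(g3[[1]])))
    expect_error(simulationConfig(scaffoldLength = 500L), "scaffoldLength")
})

test_that("full simulation is deterministic under a fixed seed", {
    cfg <- simulationConfig(seed = 5)
    a <- simulateTranscriptome(cfg)
    b <- simulateTranscriptome(cfg)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(a$tpm, b$tpm)
    expect_identical(a$truth$events, b$truth$events)
    expect_identical(ranges(unlist(exonsByTx(a$models))),
                     ranges(unlist(exonsByTx(b$models))))
})

test_that("planted gene models realize their events with GT..AG sites", {
    cfg <- simulationConfig(seed = 3, eventMix = c(RI = 5L), nGenes = 13L)
    sim <- simulateTranscriptome(cfg)
    tr <- sim$truth$events
    expect_identical(nrow(tr), 5L)
    # each RI gene: one intron-retaining and one spliced isoform
    nEx <- lengths(exonsByTx(sim$models))
    for (i in seq_len(nrow(tr)))
        expect_lt(nEx[[tr$tx_form1[i]]], nEx[[tr$tx_form2[i]]])
    # all annotated introns carry canonical dinucleotides, strand-aware
    introns <- intronsByTx(sim$models)
    for (t in txIds(sim$models)) {
        gr <- introns[[t]]
        if (!length(gr)) next
        seqs <- extractSequences(gr, sim$genome)
        expect_true(all(substr(seqs, 1, 2) == "GT"))
        expect_true(all(substr(seqs, nchar(seqs) - 1, nchar(seqs)) == "AG"))
    }
})

test_that("an empty event mix yields single-isoform genes only", {
    cfg <- simulationConfig(seed = 4, eventMix = integer(), nGenes = 8L)
    sim <- simulateTranscriptome(cfg)
    expect_identical(length(sim$models), 8L)
    expect_identical(nrow(sim$truth$events), 0L)
    expect_identical(length(enumerateEvents(sim$models)), 0L)
})

test_that("annotation round-trips through GTF with identical exon sets", {
    cfg <- simulationConfig(seed = 6, eventMix = c(SE = 2L, RI = 2L),
                            nGenes = 12L)
    sim <- simulateTranscriptome(cfg)
    path <- withr::local_tempfile(fileext = ".gtf")
    writeGtf(sim$models, path)
    back <- readGtf(path)
    for (t in txIds(sim$models))
        expect_identical(ranges(exonsByTx(back)[[t]]),
                         ranges(exonsByTx(sim$models)[[t]]))
})

test_that("noiseless expression reproduces the planted Psi step exactly", {
    cfg <- simulationConfig(seed = 7, eventMix = c(RI = 4L), nGenes = 12L,
                            noiseSd = 0, nOver = 2L, plantedDeltaPsi = 0.2)
    sim <- simulateTranscriptome(cfg)
    ev <- enumerateEvents(sim$models)
    psi <- psiExperiment(ev, sim$tpm)
    key <- paste(eventTable(ev)$gene_id, eventTable(ev)$type, sep = ":")
    expect_equal(unname(psiValues(psi)), unname(sim$psiTrajectory[key, ]),
                 tolerance = 1e-12)
    # over events step by exactly the planted delta at the transition
    tr <- sim$psiTrajectory[sim$truth$events$event_key[sim$truth$events$over], ]
    expect_equal(unname(tr[, cfg@activationIndex] -
                        tr[, cfg@activationIndex - 1L]),
                 rep(0.2, 2), tolerance = 1e-12)
})

test_that("events planted below the TPM floor have undefined Psi", {
    cfg <- simulationConfig(seed = 8, eventMix = c(RI = 2L), nGenes = 10L,
                            noiseSd = 0)
    g <- simulateGenome(cfg)
    gm <- simulateGeneModels(cfg, g)
    lowKey <- gm$truth$events$event_key[1]
    expr <- simulateExpression(cfg, gm$truth, lowExpressionEvents = lowKey)
    ev <- enumerateEvents(gm$models)
    psi <- psiExperiment(ev, expr$tpm)
    key <- paste(eventTable(ev)$gene_id, eventTable(ev)$type, sep = ":")
    expect_true(all(is.na(psiValues(psi)[key == lowKey, ])))
    expect_true(all(!is.na(psiValues(psi)[key != lowKey, ])))
})

test_that("noisy delta-Psi estimates concentrate on the planted value", {
    cfg <- simulationConfig(seed = 9, eventMix = c(RI = 200L), nGenes = 208L,
                            nScaffolds = 3L, scaffoldLength = 800000L,
                            noiseSd = 0.1, nOver = 200L,
                            plantedDeltaPsi = 0.2)
    g <- simulateGenome(cfg)
    gm <- simulateGeneModels(cfg, g)
    expr <- simulateExpression(cfg, gm$truth)
    ev <- gm$truth$events
    i <- cfg@activationIndex
    psiOf <- function(tx1, tx2, col)
        expr$tpm[tx1, col] / (expr$tpm[tx1, col] + expr$tpm[tx2, col])
    d <- psiOf(ev$tx_form1, ev$tx_form2, i) -
         psiOf(ev$tx_form1, ev$tx_form2, i - 1L)
    expect_lt(abs(mean(d) - 0.2), 0.02)
})

test_that("planted motif offsets respect their positional constraints", {
    cfg <- simulationConfig(seed = 10, nGenes = 36L,
        motifPlant = data.frame(motif_id = c("motif1+motif5", "motif1"),
                                offset_min = c(10, 20), offset_max = c(25, 45),
                                count = c(1L, 1L), stringsAsFactors = FALSE))
    sim <- simulateTranscriptome(cfg)
    sc <- scanMotifCatalog(sim$models, sim$genome)
    hosts <- sim$truth$motifHosts
    expect_length(hosts, 2)
    got <- sc[match(names(hosts), sc$transcript_id), ]
    both <- names(hosts)[lengths(hosts) == 2]
    expect_identical(got$group[match(both, got$transcript_id)], "both")
    expect_true(all(got$motif1_start < 50, na.rm = TRUE))
    expect_true(all(got$motif5_start < 40, na.rm = TRUE))
})
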