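#' Run the full analysis pipeline on a simulated dataset
#'
#' Orchestrates every stage end to end: simulate -> curate -> transposon
#' scan -> event enumeration -> Psi -> adjacent-pair comparisons ->
#' over/normal classification -> intron features -> PCA. All randomness
#' flows from the config seed, so a rerun with the same config reproduces
#' the report exactly. With \code{outDir} set, inputs and stage outputs are
#' written as FASTA/GTF/BED/TSV/JSON.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param outDir Optional output directory.
#' @param tpmFloor Expression floor used for curation and Psi (default 1).
#' @param overThreshold Over/normal delta-Psi threshold (default 0.07).
#' @param smrtOnly Restrict event detection to long-read-supported
#'   transcripts (default TRUE, as in the splicing analysis proper).
#' @param runIntronFeatures Compute the intron feature table (default
#'   TRUE; needs enough constitutive introns to train splice models).
#' @return A list with the stage outputs (\code{sim}, \code{curated},
#'   \code{teTable}, \code{events}, \code{psi}, \code{adjacent},
#'   \code{overNormal}, \code{intronFeatures}, \code{pca}) and
#'   \code{report}, a data.frame of per-stage record counts, thresholds and
#'   wall times, carrying the seed.
#' @export
runPipeline <- function(config = simulationConfig(), outDir = NULL,
                        tpmFloor = 1, overThreshold = 0.07, smrtOnly = TRUE,
                        runIntronFeatures = TRUE) {
    report <- list()
    note <- function(stage, n_in, n_out, threshold = NA_real_, t0) {
        report[[length(report) + 1L]] <<- data.frame(
            stage = stage, n_input = n_in, n_output = n_out,
            threshold = threshold,
            seconds = round(as.numeric(Sys.time()) - t0, 2),
            stringsAsFactors = FALSE)
    }
    t0 <- as.numeric(Sys.time())
    sim <- simulateTranscriptome(config)
    note("simulate", config@nGenes, length(sim$models), config@seed, t0)

    t0 <- as.numeric(Sys.time())
    slen <- setNames(Biostrings::nchar(sim$genome), names(sim$genome))
    cur <- curateTranscripts(sim$models, sim$tpm, slen, tpmFloor = tpmFloor)
    note("curate", length(sim$models), length(cur$models), tpmFloor, t0)

    t0 <- as.numeric(Sys.time())
    teTable <- classifyTeTranscripts(cur$models, sim$repeats)
    teIds <- teTable$transcript_id[teTable$label == "expressed_transposon"]
    teIds <- filterNFlanked(teIds, cur$models, sim$genome)
    note("te_scan", length(cur$models), length(teIds), 0.9, t0)

    t0 <- as.numeric(Sys.time())
    events <- enumerateEvents(cur$models, smrtOnly = smrtOnly)
    note("events", length(cur$models), length(events), NA, t0)

    t0 <- as.numeric(Sys.time())
    psi <- psiExperiment(events, sim$tpm, floor = tpmFloor)
    note("psi", length(events), sum(!is.na(psiValues(psi))), tpmFloor, t0)

    t0 <- as.numeric(Sys.time())
    adj <- compareAdjacent(psi)
    samples <- colnames(psi)
    pair <- c(samples[config@activationIndex - 1L],
              samples[config@activationIndex])
    ovn <- classifyOverNormal(psi, pair[1], pair[2],
                              threshold = overThreshold)
    note("classify", length(events), sum(ovn$status == "over"),
         overThreshold, t0)

    intronFeat <- NULL
    if (runIntronFeatures) {
        t0 <- as.numeric(Sys.time())
        introns <- extractIntrons(cur$models, events, ovn)
        intronFeat <- tryCatch(
            intronFeatureTable(introns, cur$models, sim$genome),
            error = function(e) {
                warning("intron features skipped: ", conditionMessage(e))
                NULL
            })
        note("introns", length(introns),
             if (is.null(intronFeat)) 0L else nrow(intronFeat), NA, t0)
    }

    t0 <- as.numeric(Sys.time())
    pca <- runPca(sim$tpm, nComponents = 4)
    note("pca", nrow(sim$tpm), ncol(pca$scores), NA, t0)

    report <- do.call(rbind, report)
    report$seed <- config@seed
    out <- list(sim = sim, curated = cur, teTable = teTable,
                expressedTransposons = teIds, events = events, psi = psi,
                adjacent = adj, overNormal = ovn,
                intronFeatures = intronFeat, pca = pca, report = report)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeSimulation(sim, file.path(outDir, "sim"), config)
        writeGtf(cur$models, file.path(outDir, "curated.gtf"))
        utils::write.table(as.data.frame(eventTable(events)[,
            c("event_id", "gene_id", "type", "seqnames", "strand",
              "form1", "form2")]),
            file.path(outDir, "events.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        utils::write.table(adj, file.path(outDir, "comparisons.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(ovn, file.path(outDir, "over_normal.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(report, file.path(outDir, "report.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
}
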