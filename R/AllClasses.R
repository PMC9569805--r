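#' @include AllGenerics.R
NULL

#' Container for exon-structured transcript models
#'
#' Holds one exon set per transcript (a named \linkS4class{GRangesList}) plus
#' per-transcript metadata: the owning gene, whether the structure is
#' corroborated by long-read (SMRT) sequencing, and an optional coding-class
#' label (\code{mRNA}, \code{lncRNA}, \code{TUCP}).
#'
#' All transcripts of a gene must share scaffold and strand; exons within a
#' transcript are sorted, non-overlapping, and strictly positive-width.
#' Coordinates follow the IRanges convention (1-based, closed).
#'
#' @slot exons A named \code{GRangesList}, one element per transcript.
#' @slot txData A \code{DataFrame} with rownames matching \code{names(exons)}
#'   and columns \code{gene_id}, \code{smrt_supported}, \code{class_label}.
#'
#' @export
setClass("TranscriptModels",
    slots = c(exons = "GRangesList", txData = "DataFrame"))

setValidity("TranscriptModels", function(object) {
    ex <- object@exons
    td <- object@txData
    if (is.null(names(ex)) || anyDuplicated(names(ex)))
        return("exons must be uniquely named by transcript id")
    if (!identical(names(ex), rownames(td)))
        return("txData rownames must match exon list names")
    need <- c("gene_id", "smrt_supported", "class_label")
    if (!all(need %in% colnames(td)))
        return(paste("txData must have columns:", paste(need, collapse = ", ")))
    u <- unlist(ex, use.names = FALSE)
    if (length(u) && any(width(u) < 1))
        return("all exons must have width >= 1")
    nseq <- lengths(unique(GenomicRanges::seqnames(ex)))
    nstr <- lengths(unique(strand(ex)))
    if (any(nseq > 1) || any(nstr > 1))
        return("each transcript must lie on a single scaffold and strand")
    ust <- S4Vectors::runValue(strand(ex))
    if (any(unlist(ust) == "*"))
        return("transcript strand must be + or -")
    # sorted, disjoint exons within each transcript
    st <- IRanges::start(ex); en <- IRanges::end(ex)
    bad <- vapply(seq_along(ex), function(i) {
        s <- st[[i]]; e <- en[[i]]
        length(s) > 1 && any(s[-1] <= e[-length(e)])
    }, logical(1))
    if (any(bad))
        return("exons within a transcript must be sorted and non-overlapping")
    # one scaffold+strand per gene
    sc1 <- vapply(seq_along(ex),
        function(i) as.character(GenomicRanges::seqnames(ex[[i]])[1]), character(1))
    sr1 <- vapply(seq_along(ex),
        function(i) as.character(strand(ex[[i]])[1]), character(1))
    key <- paste(sc1, sr1)
    if (any(vapply(split(key, td$gene_id), function(k) length(unique(k)) > 1,
                   logical(1))))
        return("all transcripts of a gene must share scaffold and strand")
    TRUE
})

#' Construct a TranscriptModels object
#'
#' @param exons Named \code{GRangesList} of exons, one element per transcript,
#'   each sorted in genomic order.
#' @param geneIds Character vector of gene ids, parallel to \code{exons}.
#' @param smrtSupported Logical vector (recycled), long-read support flags.
#' @param classLabels Optional character vector of coding-class labels.
#'
#' @return A \linkS4class{TranscriptModels} object.
#' @export
TranscriptModels <- function(exons, geneIds,
                             smrtSupported = FALSE, classLabels = NA_character_) {
    n <- length(exons)
    td <- S4Vectors::DataFrame(
        gene_id = rep_len(as.character(geneIds), n),
        smrt_supported = rep_len(as.logical(smrtSupported), n),
        class_label = rep_len(as.character(classLabels), n),
        row.names = names(exons))
    new("TranscriptModels", exons = exons, txData = td)
}

#' One local alternative-splicing event per row
#'
#' Each event has a type in \{A3, A5, AF, AL, MX, RI, SE\}, two splicing-form
#' signatures (junction/boundary coordinate tuples anchored to shared flanks)
#' and the disjoint transcript sets F1/F2 compatible with form 1 and form 2.
#' For RI events form 1 is the intron-retaining form and the retained intron's
#' coordinates are carried in \code{ri_start}/\code{ri_end}.
#'
#' @slot events A \code{DataFrame} with columns \code{event_id},
#'   \code{gene_id}, \code{type}, \code{seqnames}, \code{strand},
#'   \code{form1}, \code{form2}, \code{F1}, \code{F2} (CharacterList),
#'   \code{ri_start}, \code{ri_end}.
#'
#' @export
setClass("SpliceEventSet", slots = c(events = "DataFrame"))

setValidity("SpliceEventSet", function(object) {
    ev <- object@events
    need <- c("event_id", "gene_id", "type", "seqnames", "strand",
              "form1", "form2", "F1", "F2", "ri_start", "ri_end")
    if (!all(need %in% colnames(ev)))
        return(paste("events must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(ev$event_id))
        return("event ids must be unique")
    if (length(ev$type) && !all(ev$type %in% EVENT_TYPES))
        return("event types must be in {A3,A5,AF,AL,MX,RI,SE}")
    both <- mapply(function(a, b) length(intersect(a, b)) > 0, ev$F1, ev$F2)
    if (length(both) && any(both))
        return("F1 and F2 must be disjoint")
    TRUE
})

#' @export
EVENT_TYPES <- c("A3", "A5", "AF", "AL", "MX", "RI", "SE")

#' Psi (percent-spliced-in) values as a SummarizedExperiment
#'
#' Rows are splicing events, columns are samples. Assay \code{psi} holds
#' \eqn{\Psi \in [0,1]} or \code{NA} where the event's total expression does
#' not exceed the TPM floor; assay \code{total} holds the per-cell total TPM
#' over F1 and F2 transcripts.
#'
#' @export
setClass("PsiExperiment", contains = "SummarizedExperiment")

setValidity("PsiExperiment", function(object) {
    if (!all(c("psi", "total") %in% SummarizedExperiment::assayNames(object)))
        return("assays 'psi' and 'total' are required")
    p <- SummarizedExperiment::assay(object, "psi")
    if (any(p < 0 | p > 1, na.rm = TRUE))
        return("defined psi values must lie in [0,1]")
    TRUE
})

#' Configuration of the synthetic-data generator
#'
#' Defines the study conditions emulated by the simulator: a multi-scaffold
#' genome, two-isoform gene models realizing a chosen mix of the seven
#' alternative-splicing event types, an ordered time series of samples with a
#' designated activation transition (mirroring the T6 to T7, 256-cell to dome
#' step at zygotic genome activation), a planted Psi step for "over"
#' retained-intron events, log-normal expression noise, and optional planted
#' repeat intervals and sequence motifs.
#'
#' @slot seed Integer; every random draw flows from it.
#' @slot nScaffolds,scaffoldLength Genome geometry (bp).
#' @slot nGenes Total genes; genes beyond the event mix are single-isoform.
#' @slot eventMix Named integer vector over \{A3,A5,AF,AL,MX,RI,SE\}.
#' @slot nSamples Ordered time points (default 19, labelled T2..T20).
#' @slot activationIndex 1-based index of the first post-activation sample
#'   (default 6, i.e. the T7 column).
#' @slot plantedDeltaPsi Psi step applied to designated over RI events at the
#'   activation transition.
#' @slot nOver Number of RI events planted as "over" (the rest are null).
#' @slot noiseSd Log-scale standard deviation of multiplicative TPM noise.
#' @slot baseTpm Per-event total TPM before noise.
#' @slot repeatPlant data.frame(family, count, length) of repeat intervals.
#' @slot motifPlant data.frame(motif_id, offset_min, offset_max, count) of
#'   motif plantings at constrained transcript offsets.
#'
#' @export
setClass("SimulationConfig",
    slots = c(seed = "integer", nScaffolds = "integer",
              scaffoldLength = "integer", nGenes = "integer",
              eventMix = "integer", nSamples = "integer",
              activationIndex = "integer", plantedDeltaPsi = "numeric",
              nOver = "integer", noiseSd = "numeric", baseTpm = "numeric",
              repeatPlant = "data.frame", motifPlant = "data.frame"))

setValidity("SimulationConfig", function(object) {
    if (object@scaffoldLength < 10000L)
        return("scaffoldLength must be >= 10000")
    if (object@nScaffolds < 1L || object@nGenes < 0L)
        return("nScaffolds must be positive and nGenes non-negative")
    if (length(object@eventMix) &&
        (is.null(names(object@eventMix)) ||
         !all(names(object@eventMix) %in% EVENT_TYPES)))
        return("eventMix names must be event types (A3,A5,AF,AL,MX,RI,SE)")
    if (any(object@eventMix < 0L))
        return("eventMix counts must be >= 0")
    if (object@activationIndex < 2L || object@activationIndex > object@nSamples)
        return("activationIndex must fall within the sample series (>= 2)")
    if (object@plantedDeltaPsi < 0 || object@plantedDeltaPsi > 1)
        return("plantedDeltaPsi must lie in [0,1]")
    if (object@noiseSd < 0)
        return("noiseSd must be non-negative")
    TRUE
})

#' @rdname SimulationConfig-class
#'
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param nScaffolds,scaffoldLength,nGenes,eventMix,nSamples,activationIndex
#'   See slot documentation.
#' @param plantedDeltaPsi,nOver,noiseSd,baseTpm,repeatPlant,motifPlant
#'   See slot documentation.
#'
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             nScaffolds = 2L,
                             scaffoldLength = 500000L,
                             eventMix = c(A3 = 3L, A5 = 3L, AF = 3L, AL = 3L,
                                          MX = 3L, RI = 6L, SE = 3L),
                             nGenes = sum(eventMix) + 8L,
                             nSamples = 19L,
                             activationIndex = 6L,
                             plantedDeltaPsi = 0.2,
                             nOver = NA_integer_,
                             noiseSd = 0.05,
                             baseTpm = 20,
                             repeatPlant = data.frame(
                                 family = character(), count = integer(),
                                 length = integer()),
                             motifPlant = data.frame(
                                 motif_id = character(), offset_min = integer(),
                                 offset_max = integer(), count = integer())) {
    em <- setNames(as.integer(eventMix), names(eventMix))
    if (is.na(nOver)) {
        nri <- if ("RI" %in% names(em)) em[["RI"]] else 0L
        nOver <- as.integer(ceiling(nri / 2))
    }
    new("SimulationConfig", seed = as.integer(seed),
        nScaffolds = as.integer(nScaffolds),
        scaffoldLength = as.integer(scaffoldLength),
        nGenes = as.integer(nGenes), eventMix = em,
        nSamples = as.integer(nSamples),
        activationIndex = as.integer(activationIndex),
        plantedDeltaPsi = plantedDeltaPsi, nOver = as.integer(nOver),
        noiseSd = noiseSd, baseTpm = baseTpm,
        repeatPlant = repeatPlant, motifPlant = motifPlant)
}

# ---- accessors ----

#' @describeIn TranscriptModels-class Transcript identifiers.
#' @param x A TranscriptModels object.
#' @export
setMethod("txIds", "TranscriptModels", function(x) names(x@exons))

#' @describeIn TranscriptModels-class Gene id of each transcript (named).
#' @export
setMethod("geneIds", "TranscriptModels",
    function(x) setNames(x@txData$gene_id, rownames(x@txData)))

#' @describeIn TranscriptModels-class Exons as a named GRangesList.
#' @export
setMethod("exonsByTx", "TranscriptModels", function(x) x@exons)

#' @describeIn TranscriptModels-class Introns (gaps between consecutive
#'   exons) as a named GRangesList, possibly empty per transcript.
#' @export
setMethod("intronsByTx", "TranscriptModels", function(x) {
    sp <- unlist(range(x@exons))
    GenomicRanges::psetdiff(sp, x@exons)
})

#' @describeIn TranscriptModels-class Long-read support flags (named).
#' @export
setMethod("smrtSupported", "TranscriptModels",
    function(x) setNames(x@txData$smrt_supported, rownames(x@txData)))

#' @describeIn TranscriptModels-class Coding-class labels (named).
#' @export
setMethod("classLabels", "TranscriptModels",
    function(x) setNames(x@txData$class_label, rownames(x@txData)))

#' @describeIn TranscriptModels-class Replace coding-class labels.
#' @param value Character vector, named by transcript id or parallel to
#'   \code{txIds(x)}.
#' @export
setReplaceMethod("classLabels", "TranscriptModels", function(x, value) {
    if (!is.null(names(value))) {
        x@txData$class_label[match(names(value), rownames(x@txData))] <-
            as.character(value)
    } else {
        x@txData$class_label <- rep_len(as.character(value), length(x@exons))
    }
    x
})

#' @describeIn TranscriptModels-class Number of transcripts.
#' @export
setMethod("length", "TranscriptModels", function(x) length(x@exons))

#' Subset transcript models by transcript id or index
#'
#' @param x A TranscriptModels object.
#' @param i Transcript ids (character) or indices.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "TranscriptModels", function(x, i, j, ..., drop = FALSE) {
    initialize(x, exons = x@exons[i], txData = x@txData[i, , drop = FALSE])
})

setMethod("show", "TranscriptModels", function(object) {
    cat("TranscriptModels with", length(object), "transcripts in",
        length(unique(object@txData$gene_id)), "genes\n")
    cat("  smrt-supported:", sum(object@txData$smrt_supported), "\n")
    cl <- object@txData$class_label
    if (any(!is.na(cl))) {
        tab <- table(cl, useNA = "no")
        cat("  classes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    }
})

#' Genomic span of each transcript
#'
#' @param x A TranscriptModels object.
#' @return A GRanges, one range per transcript.
#' @export
txSpans <- function(x) {
    sp <- unlist(range(exonsByTx(x)))
    names(sp) <- txIds(x)
    sp
}

#' @describeIn SpliceEventSet-class Event identifiers.
#' @param x A SpliceEventSet.
#' @export
setMethod("eventIds", "SpliceEventSet", function(x) x@events$event_id)

#' @describeIn SpliceEventSet-class Event types, named by event id.
#' @export
setMethod("eventTypes", "SpliceEventSet",
    function(x) setNames(x@events$type, x@events$event_id))

#' @describeIn SpliceEventSet-class Number of events.
#' @export
setMethod("length", "SpliceEventSet", function(x) nrow(x@events))

#' @describeIn SpliceEventSet-class Subset events.
#' @param i Event ids (character) or indices.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "SpliceEventSet", function(x, i, j, ..., drop = FALSE) {
    ev <- x@events
    if (is.character(i)) i <- match(i, ev$event_id)
    initialize(x, events = ev[i, , drop = FALSE])
})

#' Event table as a DataFrame
#' @param x A SpliceEventSet.
#' @export
eventTable <- function(x) x@events

setMethod("show", "SpliceEventSet", function(object) {
    cat("SpliceEventSet with", length(object), "events\n")
    if (length(object)) {
        tab <- table(factor(object@events$type, levels = EVENT_TYPES))
        cat(" ", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    }
})

#' @describeIn PsiExperiment-class The event-by-sample Psi matrix.
#' @param x A PsiExperiment.
#' @export
setMethod("psiValues", "PsiExperiment",
    function(x) SummarizedExperiment::assay(x, "psi"))

#' @describeIn PsiExperiment-class Total F1+F2 TPM per event and sample.
#' @export
setMethod("totalTpm", "PsiExperiment",
    function(x) SummarizedExperiment::assay(x, "total"))

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig: seed", object@seed, "|",
        object@nScaffolds, "scaffold(s) x", object@scaffoldLength, "bp |",
        object@nGenes, "genes |", object@nSamples, "samples\n")
    if (length(object@eventMix))
        cat("  eventMix:",
            paste(names(object@eventMix), object@eventMix, sep = "=",
                  collapse = " "), "\n")
    cat("  activation at sample", object@activationIndex,
        "| planted dPsi", object@plantedDeltaPsi,
        "| over RI", object@nOver,
        "| noiseSd", object@noiseSd, "\n")
})
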