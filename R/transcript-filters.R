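#' Transcript curation: expression floor, fragmented-transcript and
#' precursor rules, coding-consensus classification
#'
#' These functions implement the curation applied to a merged short-read +
#' long-read transcriptome assembly before splicing analysis: transcripts
#' below an expression floor are dropped; transcripts close to a scaffold
#' edge without long-read support are treated as assembly fragments; and
#' single-exon transcripts inside genes that also have multi-exon isoforms
#' are treated as unspliced precursors. Each filter returns the surviving
#' models plus a report row so attrition per rule is auditable.
#'
#' @name transcript-filters
NULL

filterReport <- function(rule, removed, input) {
    data.frame(rule = rule, n_input = input, n_removed = length(removed),
               n_surviving = input - length(removed),
               removed_ids = paste(removed, collapse = ","),
               stringsAsFactors = FALSE)
}

#' Drop transcripts below the TPM floor
#'
#' A transcript is retained iff its TPM statistic across samples reaches the
#' floor (default 1 TPM). The statistic is \code{max} by default: a
#' transcript expressed in a single stage (e.g. an activation-restricted
#' transposon) survives; per-sample or mean variants are available via
#' \code{mode}.
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @param tpm Transcript-by-sample TPM matrix; transcripts absent from the
#'   matrix are treated as zero everywhere.
#' @param floor Expression floor in TPM (default 1).
#' @param mode One of \code{"max"} (default), \code{"mean"}, \code{"all"}
#'   (every sample must reach the floor).
#' @return \code{list(models, report)}.
#' @export
filterLowExpression <- function(models, tpm, floor = 1, mode = c("max", "mean", "all")) {
    mode <- match.arg(mode)
    ids <- txIds(models)
    vals <- matrix(0, nrow = length(ids), ncol = ncol(tpm),
                   dimnames = list(ids, colnames(tpm)))
    hit <- intersect(ids, rownames(tpm))
    vals[hit, ] <- tpm[hit, , drop = FALSE]
    stat <- switch(mode,
        max = apply(vals, 1, max),
        mean = rowMeans(vals),
        all = apply(vals, 1, min))
    keep <- stat >= floor
    list(models = models[ids[keep]],
         report = filterReport("low_tpm", ids[!keep], length(ids)))
}

#' Pooled intron-length quantile
#'
#' Nearest-rank (type-1) quantile of all intron lengths pooled over
#' transcripts; used to derive the scaffold-edge distance threshold for the
#' fragmented-transcript rule (the study's value at q = 0.95 was 7875 bp).
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @param q Quantile in (0, 1), default 0.95.
#' @return Integer length in bp.
#' @export
intronLengthPercentile <- function(models, q = 0.95) {
    stopifnot(q > 0, q < 1)
    lens <- unlist(width(intronsByTx(models)), use.names = FALSE)
    if (!length(lens)) stop("no introns in the supplied models")
    as.integer(quantile(lens, probs = q, type = 1))
}

#' Remove fragmented transcripts near scaffold edges
#'
#' A transcript is removed iff its genomic span lies closer than
#' \code{threshold} to either scaffold edge AND it is not supported by
#' long-read (SMRT) data. Edge distance is strand-ignorant: fragmentation is
#' a physical scaffold-boundary artifact.
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @param scaffoldLengths Named integer vector of scaffold lengths.
#' @param threshold Edge distance in bp (e.g. from
#'   \code{\link{intronLengthPercentile}}).
#' @return \code{list(models, report)}.
#' @export
filterFragmented <- function(models, scaffoldLengths, threshold) {
    ids <- txIds(models)
    sp <- txSpans(models)
    scf <- as.character(seqnames(sp))
    if (!all(scf %in% names(scaffoldLengths)))
        stop("scaffold lengths missing for: ",
             paste(setdiff(scf, names(scaffoldLengths)), collapse = ", "))
    slen <- scaffoldLengths[scf]
    if (any(end(sp) > slen))
        stop("transcript extends beyond its scaffold")
    edge <- pmin(start(sp) - 1L, slen - end(sp))
    remove <- edge < threshold & !unname(smrtSupported(models))
    list(models = models[ids[!remove]],
         report = filterReport("fragmented", ids[remove], length(ids)))
}

#' Remove precursor single-exon transcripts
#'
#' Within each gene that contains at least one multi-exon transcript, all
#' single-exon transcripts are removed (they are almost certainly unspliced
#' precursors). Genes consisting only of single-exon transcripts are left
#' untouched.
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @return \code{list(models, report)}.
#' @export
filterPrecursorSingletons <- function(models) {
    ids <- txIds(models)
    nEx <- lengths(exonsByTx(models))
    gid <- unname(geneIds(models))
    multiGene <- unique(gid[nEx > 1])
    remove <- nEx == 1 & gid %in% multiGene
    list(models = models[ids[!remove]],
         report = filterReport("precursor", ids[remove], length(ids)))
}

#' Consensus coding classification from two predictors
#'
#' Both predictors non-coding: \code{lncRNA}; both coding: \code{mRNA};
#' discordant: \code{TUCP} (transcript of uncertain coding potential).
#'
#' @param labelA,labelB Character vectors over \{"coding", "noncoding"\}
#'   (vectorized, recycled).
#' @return Character vector over \{"lncRNA", "mRNA", "TUCP"\}.
#' @export
classifyCodingConsensus <- function(labelA, labelB) {
    ok <- c("coding", "noncoding")
    if (!all(labelA %in% ok) || !all(labelB %in% ok))
        stop("coding labels must be 'coding' or 'noncoding'")
    n <- max(length(labelA), length(labelB))
    labelA <- rep_len(labelA, n); labelB <- rep_len(labelB, n)
    ifelse(labelA == "noncoding" & labelB == "noncoding", "lncRNA",
        ifelse(labelA == "coding" & labelB == "coding", "mRNA", "TUCP"))
}

#' Gene-level class from transcript classes
#'
#' A gene whose transcripts all share one class gets that class; mixed-class
#' genes are labelled \code{"misc"}.
#'
#' @param txClasses Character vector of transcript classes (one gene).
#' @return A single class label.
#' @export
assignGeneClass <- function(txClasses) {
    if (!length(txClasses)) stop("empty transcript class list")
    u <- unique(txClasses)
    if (length(u) == 1) u else "misc"
}

#' Run the curation filters in pipeline order
#'
#' TPM floor, then fragmented-transcript rule, then precursor rule. When
#' \code{edgeThreshold} is NA it is derived from the input models as the
#' \code{q} intron-length quantile.
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @param tpm TPM matrix.
#' @param scaffoldLengths Named integer vector.
#' @param tpmFloor Expression floor (default 1 TPM).
#' @param q Intron-length quantile for the edge threshold (default 0.95).
#' @param edgeThreshold Override for the edge distance threshold in bp.
#' @return \code{list(models, report)} with one report row per rule.
#' @export
curateTranscripts <- function(models, tpm, scaffoldLengths, tpmFloor = 1,
                              q = 0.95, edgeThreshold = NA) {
    if (is.na(edgeThreshold))
        edgeThreshold <- intronLengthPercentile(models, q)
    s1 <- filterLowExpression(models, tpm, tpmFloor)
    s2 <- filterFragmented(s1$models, scaffoldLengths, edgeThreshold)
    s3 <- filterPrecursorSingletons(s2$models)
    report <- rbind(s1$report, s2$report, s3$report)
    report$threshold <- c(tpmFloor, edgeThreshold, NA)
    list(models = s3$models, report = report)
}
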