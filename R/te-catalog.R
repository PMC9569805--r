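#' A position weight matrix with a positional start constraint
#'
#' Models a FIMO-style motif scan restricted to the 5' region of the
#' transcript sense sequence (the head-to-body architecture of the SINE-like
#' elements studied): a hit counts only when the best-scoring start position
#' is below \code{maxStart}.
#'
#' @slot motifId Character id.
#' @slot pwm 4-row probability matrix (rows A, C, G, T); columns sum to 1.
#' @slot maxStart Hits must start at a 1-based position <= maxStart.
#' @slot scoreThreshold Log-odds (bits) threshold; \code{NA} means 60\% of
#'   the consensus score.
#'
#' @export
setClass("MotifModel",
    slots = c(motifId = "character", pwm = "matrix", maxStart = "integer",
              scoreThreshold = "numeric"))

setValidity("MotifModel", function(object) {
    p <- object@pwm
    if (nrow(p) != 4 || !identical(rownames(p), BASES))
        return("pwm must have rows A, C, G, T")
    if (any(abs(colSums(p) - 1) > 1e-6))
        return("pwm columns must sum to 1")
    if (object@maxStart < 0) return("maxStart must be >= 0")
    TRUE
})

#' @rdname MotifModel-class
#' @param motifId,pwm,maxStart,scoreThreshold See slots.
#' @export
motifModel <- function(motifId, pwm, maxStart, scoreThreshold = NA_real_) {
    new("MotifModel", motifId = motifId, pwm = pwm,
        maxStart = as.integer(maxStart), scoreThreshold = scoreThreshold)
}

setMethod("show", "MotifModel", function(object) {
    cat("MotifModel", object@motifId, "| width", ncol(object@pwm),
        "| maxStart", object@maxStart, "| consensus",
        motifConsensus(object), "\n")
})

#' Consensus sequence of a motif (argmax base per column)
#' @param model A \linkS4class{MotifModel}.
#' @export
motifConsensus <- function(model) {
    paste(BASES[apply(model@pwm, 2, which.max)], collapse = "")
}

pwmFromConsensus <- function(cons, major = 0.85) {
    v <- strsplit(cons, "")[[1]]
    p <- matrix((1 - major) / 3, nrow = 4, ncol = length(v),
                dimnames = list(BASES, NULL))
    for (j in seq_along(v)) p[v[j], j] <- major
    p
}

#' The two positionally constrained head motifs
#'
#' Stand-ins for the two 5'-region motifs of the activation-expressed
#' SINE-like family: motif 1 must start before position 50 of the transcript,
#' motif 5 before position 40. The matrices are synthetic (the originals are
#' published only as sequence logos); widths and constraints match the
#' analysis design.
#'
#' @return A list of two \linkS4class{MotifModel} objects.
#' @export
defaultMotifModels <- function() {
    list(motifModel("motif1", pwmFromConsensus("TGGCCGAGTGGT"), 50L),
         motifModel("motif5", pwmFromConsensus("GGTTCGATTC"), 40L))
}

#' Reciprocal overlap fractions between a transcript and repeat intervals
#'
#' Repeat intervals intersecting the transcript are merged before the
#' computation. The repeat fraction is (covered repeat bases) / (total bases
#' of intersecting repeats); the self fraction is (covered transcript bases)
#' / (transcript bases). By default transcript bases are exonic (spliced)
#' bases; \code{on = "span"} uses the genomic span instead.
#'
#' @param exons GRanges of one transcript's exons.
#' @param repeats GRanges of repeat intervals (same scaffold comparisons
#'   only; other scaffolds are ignored).
#' @param on \code{"exonic"} (default) or \code{"span"}.
#' @return \code{c(repeat_fraction, self_fraction)}.
#' @export
overlapFractions <- function(exons, repeats, on = c("exonic", "span")) {
    on <- match.arg(on)
    target <- if (on == "span") range(granges(exons)) else granges(exons)
    target <- GenomicRanges::reduce(target, ignore.strand = TRUE)
    tlen <- sum(width(target))
    if (tlen == 0) stop("zero-length transcript")
    rep0 <- GenomicRanges::reduce(granges(repeats), ignore.strand = TRUE)
    hit <- rep0[IRanges::overlapsAny(rep0, target, ignore.strand = TRUE)]
    if (!length(hit)) return(c(repeat_fraction = 0, self_fraction = 0))
    ov <- sum(width(GenomicRanges::intersect(hit, target,
                                             ignore.strand = TRUE)))
    c(repeat_fraction = ov / sum(width(hit)), self_fraction = ov / tlen)
}

#' Classify one transcript against the >90\%/>90\% reciprocal-overlap rule
#'
#' Both fractions above 0.9: an expressed transposon. Repeat fraction above
#' 0.9 but self fraction not: a TE-associated transcript. Otherwise: none.
#' Thresholds are strict inequalities ("more than 90 percent").
#'
#' @param fractions \code{c(repeat_fraction, self_fraction)} from
#'   \code{\link{overlapFractions}}.
#' @return One of \code{"expressed_transposon"}, \code{"te_associated"},
#'   \code{"none"}.
#' @export
classifyTeTranscript <- function(fractions) {
    rf <- fractions[[1]]; sf <- fractions[[2]]
    if (rf > 0.9 && sf > 0.9) "expressed_transposon"
    else if (rf > 0.9) "te_associated"
    else "none"
}

#' Classify all transcripts against a repeat annotation
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @param repeats GRanges with a \code{family} column.
#' @param on Overlap denominator, see \code{\link{overlapFractions}}.
#' @return data.frame(transcript_id, label, repeat_fraction, self_fraction,
#'   family): \code{family} is the repeat family covering most transcript
#'   bases (NA when no overlap).
#' @export
classifyTeTranscripts <- function(models, repeats, on = "exonic") {
    ex <- exonsByTx(models)
    out <- lapply(seq_along(ex), function(i) {
        g <- ex[[i]]
        scf <- as.character(seqnames(g)[1])
        reps <- repeats[as.character(seqnames(repeats)) == scf]
        fr <- overlapFractions(g, reps, on = on)
        fam <- NA_character_
        if (length(reps)) {
            ov <- GenomicRanges::findOverlaps(reps, granges(g),
                                              ignore.strand = TRUE)
            if (length(ov)) {
                w <- width(GenomicRanges::pintersect(
                    granges(reps)[S4Vectors::queryHits(ov)],
                    granges(g)[S4Vectors::subjectHits(ov)]))
                cw <- tapply(w, reps$family[S4Vectors::queryHits(ov)], sum)
                fam <- names(cw)[which.max(cw)]
            }
        }
        data.frame(transcript_id = names(ex)[i],
                   label = classifyTeTranscript(fr),
                   repeat_fraction = fr[[1]], self_fraction = fr[[2]],
                   family = fam, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Drop transposons with N runs in their 20-bp flanks
#'
#' A transposon-classified transcript is removed iff any N base occurs in
#' the genomic windows 20 bp upstream and downstream of its span; windows
#' are clipped at scaffold edges.
#'
#' @param transposonIds Transcript ids classified as expressed transposons.
#' @param models A \linkS4class{TranscriptModels}.
#' @param genome Named \code{DNAStringSet}.
#' @param window Flank width in bp (default 20).
#' @return The surviving transcript ids.
#' @export
filterNFlanked <- function(transposonIds, models, genome, window = 20L) {
    sp <- txSpans(models)[transposonIds]
    keep <- vapply(seq_along(sp), function(i) {
        scf <- as.character(seqnames(sp)[i])
        len <- Biostrings::nchar(genome[[scf]])
        up <- IRanges(max(1L, start(sp)[i] - window),
                      max(1L, start(sp)[i] - 1L))
        dn <- IRanges(min(len, end(sp)[i] + 1L),
                      min(len, end(sp)[i] + window))
        flank <- paste(as.character(Biostrings::extractAt(
            genome[[scf]], c(up, dn))), collapse = "")
        !grepl("N", flank, fixed = TRUE)
    }, logical(1))
    transposonIds[keep]
}

#' Percentage with two-decimal rendering
#'
#' @param count Numerator(s).
#' @param total Denominator.
#' @return Numeric percentage rounded half-up to 2 decimals (the rendering
#'   convention of printed composition tables, where 2/64 is 3.13).
#' @export
percentRatio <- function(count, total)
    floor(100 * count / total * 100 + 0.5) / 100

#' Family composition of expressed transposons
#'
#' One row per repeat family: count among expressed transposons and its
#' percentage of all expressed transposons (two decimals), plus, when a
#' genome-side repeat annotation is given, the family's interval count and
#' its percentage of total repeat bases.
#'
#' @param classifications Output of \code{\link{classifyTeTranscripts}} (or
#'   any data.frame with \code{label} and \code{family}), or a named count
#'   vector (family -> expressed-transposon count).
#' @param genomeRepeats Optional GRanges with a \code{family} column.
#' @return data.frame(family, count, ratio_pct[, genome_count,
#'   genome_fraction_pct]).
#' @export
familyComposition <- function(classifications, genomeRepeats = NULL) {
    counts <- if (is.numeric(classifications)) classifications else {
        te <- classifications[classifications$label == "expressed_transposon", ]
        table(te$family)
    }
    counts <- counts[order(names(counts))]
    if (!sum(counts)) stop("no expressed transposons")
    out <- data.frame(family = names(counts), count = as.integer(counts),
                      ratio_pct = percentRatio(as.integer(counts),
                                               sum(counts)),
                      stringsAsFactors = FALSE)
    if (!is.null(genomeRepeats)) {
        gb <- tapply(width(genomeRepeats), genomeRepeats$family, sum)
        gc <- table(genomeRepeats$family)
        out$genome_count <- as.integer(gc[out$family])
        out$genome_fraction_pct <- percentRatio(as.numeric(gb[out$family]),
                                                sum(width(genomeRepeats)))
    }
    out
}

#' Scan a transcript sense sequence with a positionally constrained PWM
#'
#' Every start position is scored as the sum over motif columns of
#' log2((p + pseudocount) / background) with uniform background 0.25;
#' positions whose window contains an N are skipped. A hit is reported only
#' when the best score reaches the threshold AND the best start is below the
#' motif's \code{maxStart}.
#'
#' @param model A \linkS4class{MotifModel}.
#' @param sequence Character or \code{DNAString} sense sequence.
#' @param pseudocount Added to PWM probabilities before the log (default
#'   0.01).
#' @return \code{list(start, score)} for a hit, or \code{NULL}.
#' @export
scanMotif <- function(model, sequence, pseudocount = 0.01) {
    s <- strsplit(toupper(as.character(sequence)), "")[[1]]
    w <- ncol(model@pwm)
    if (length(s) < w) stop("sequence shorter than motif width")
    lod <- log2((model@pwm + pseudocount) / 0.25)
    best <- -Inf; bestAt <- NA_integer_
    for (at in seq_len(length(s) - w + 1L)) {
        win <- match(s[at:(at + w - 1L)], BASES)
        if (anyNA(win)) next
        sc <- sum(lod[cbind(win, seq_len(w))])
        if (sc > best) { best <- sc; bestAt <- at }
    }
    thr <- model@scoreThreshold
    if (is.na(thr))
        thr <- 0.6 * sum(apply(lod, 2, max))
    if (is.finite(best) && best >= thr && bestAt < model@maxStart)
        list(start = bestAt, score = best)
    else NULL
}

#' Group transcripts by motif co-occurrence
#'
#' @param hits1,hits5 Logical vectors (or lists of hits/NULLs) per
#'   transcript for motif 1 and motif 5, same length and order.
#' @return Character vector over \{"both", "only_motif1", "only_motif5",
#'   "none"\}.
#' @export
classifyMotifCombination <- function(hits1, hits5) {
    h1 <- if (is.list(hits1)) !vapply(hits1, is.null, logical(1)) else hits1
    h5 <- if (is.list(hits5)) !vapply(hits5, is.null, logical(1)) else hits5
    ifelse(h1 & h5, "both",
        ifelse(h1, "only_motif1", ifelse(h5, "only_motif5", "none")))
}

#' Scan all transcripts for the head motifs and group them
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @param genome Named \code{DNAStringSet}.
#' @param motifs List of two \linkS4class{MotifModel}s (motif1, motif5).
#' @return data.frame(transcript_id, motif1_start, motif5_start, group).
#' @export
scanMotifCatalog <- function(models, genome, motifs = defaultMotifModels()) {
    seqs <- txSequences(models, genome)
    one <- function(m) lapply(seq_along(seqs), function(i) {
        if (Biostrings::nchar(seqs[i]) < ncol(m@pwm)) NULL
        else scanMotif(m, seqs[[i]])
    })
    h1 <- one(motifs[[1]]); h5 <- one(motifs[[2]])
    getStart <- function(h) vapply(h, function(x)
        if (is.null(x)) NA_integer_ else x$start, integer(1))
    data.frame(transcript_id = names(seqs),
               motif1_start = getStart(h1), motif5_start = getStart(h5),
               group = classifyMotifCombination(h1, h5),
               stringsAsFactors = FALSE)
}
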