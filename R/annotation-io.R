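#' Read transcript models from a GTF file
#'
#' Parses a GTF2.2 file (exon features only; other feature types are ignored),
#' groups exons by \code{transcript_id} and transcripts by \code{gene_id},
#' and returns a \linkS4class{TranscriptModels} object. The custom
#' \code{smrt_supported} attribute, when present, is interpreted as a logical
#' long-read support flag (absent means \code{FALSE}); a \code{class_label}
#' attribute is carried through the same way. GTF's 1-based closed coordinates
#' map directly onto the internal IRanges convention.
#'
#' @param path Path to a GTF file.
#' @return A \linkS4class{TranscriptModels} object.
#' @export
readGtf <- function(path) {
    if (!file.exists(path)) stop("GTF file not found: ", path)
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0) stop("no exon features in ", path)
    if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
        stop("GTF parse error: exon feature without transcript_id in ", path)
    if (is.null(gr$gene_id) || anyNA(gr$gene_id))
        stop("GTF parse error: exon feature without gene_id in ", path)
    ord <- order(gr$transcript_id, start(gr))
    gr <- gr[ord]
    smrt <- if (!is.null(gr$smrt_supported)) {
        v <- toupper(as.character(gr$smrt_supported))
        v %in% c("TRUE", "1", "YES")
    } else rep(FALSE, length(gr))
    clab <- if (!is.null(gr$class_label)) as.character(gr$class_label)
            else rep(NA_character_, length(gr))
    keep <- !duplicated(gr$transcript_id)
    exons <- GenomicRanges::split(granges(gr), gr$transcript_id)
    TranscriptModels(exons,
        geneIds = gr$gene_id[keep][match(names(exons), gr$transcript_id[keep])],
        smrtSupported = smrt[keep][match(names(exons), gr$transcript_id[keep])],
        classLabels = clab[keep][match(names(exons), gr$transcript_id[keep])])
}

#' Write transcript models to GTF
#'
#' Emits one \code{exon} feature per exon with \code{gene_id},
#' \code{transcript_id}, the \code{smrt_supported} flag and, when set, the
#' \code{class_label} attribute. Round-trips losslessly through
#' \code{\link{readGtf}}.
#'
#' @param models A \linkS4class{TranscriptModels} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGtf <- function(models, path) {
    ex <- exonsByTx(models)
    gr <- unlist(ex, use.names = FALSE)
    n <- lengths(ex)
    gr$type <- "exon"
    gr$source <- "SpliceDynamics"
    gr$transcript_id <- rep(names(ex), n)
    gr$gene_id <- rep(unname(geneIds(models)), n)
    gr$smrt_supported <- rep(ifelse(unname(smrtSupported(models)),
                                    "TRUE", "FALSE"), n)
    cl <- unname(classLabels(models))
    if (any(!is.na(cl))) gr$class_label <- rep(cl, n)
    rtracklayer::export(gr, path, format = "gtf")
    invisible(path)
}

#' Read a genome FASTA
#'
#' Sequences are uppercased (soft-masked lowercase bases lose the mask);
#' \code{N} bases are preserved, which downstream N-flank filtering relies on.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A \code{DNAStringSet} named by scaffold.
#' @export
readGenome <- function(path) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    seqs <- Biostrings::readDNAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    Biostrings::DNAStringSet(toupper(seqs))
}

#' Write a genome FASTA
#' @param genome A named \code{DNAStringSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGenome <- function(genome, path) {
    Biostrings::writeXStringSet(genome, path, width = 80L)
    invisible(path)
}

#' Read repeat-element intervals from BED6
#'
#' The BED \code{name} column carries the repeat family label (e.g.
#' \code{"LINE/L2"}, \code{"unclassified SINE"}). BED's 0-based half-open
#' coordinates are converted to the internal 1-based closed convention.
#'
#' @param path Path to a BED6 file.
#' @return A \code{GRanges} with metadata columns \code{family} and
#'   \code{class} (the part of the family label before any \code{"/"}).
#' @export
readRepeats <- function(path) {
    if (!file.exists(path)) stop("BED file not found: ", path)
    gr <- rtracklayer::import(path, format = "BED")
    if (any(width(gr) < 1)) stop("repeat interval with start >= end in ", path)
    fam <- if (is.null(gr$name)) rep(NA_character_, length(gr)) else gr$name
    mcols(gr) <- S4Vectors::DataFrame(family = fam,
                                      class = sub("/.*$", "", fam))
    gr
}

#' Write repeat intervals to BED6
#' @param repeats A \code{GRanges} with a \code{family} metadata column.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeRepeats <- function(repeats, path) {
    out <- granges(repeats)
    out$name <- repeats$family
    out$score <- 0L
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Read a transcript-by-sample TPM matrix from TSV
#'
#' First column (any name) holds transcript ids; remaining columns are
#' samples. Values must be non-negative and transcript ids unique.
#'
#' @param path Path to a TSV file with a header row.
#' @return A numeric matrix, rownames = transcript ids.
#' @export
readTpm <- function(path) {
    if (!file.exists(path)) stop("TPM file not found: ", path)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) stop("duplicate transcript ids in TPM table")
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (anyDuplicated(colnames(m))) stop("duplicate sample ids in TPM table")
    if (any(m < 0, na.rm = TRUE)) stop("negative TPM values are not allowed")
    m
}

#' Write a TPM matrix to TSV
#' @param tpm Numeric matrix with transcript rownames and sample colnames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeTpm <- function(tpm, path) {
    df <- data.frame(transcript_id = rownames(tpm), tpm,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read per-transcript coding-potential labels
#'
#' @param path TSV with columns \code{transcript_id}, \code{predictor_a},
#'   \code{predictor_b}; labels must be \code{coding} or \code{noncoding}.
#' @return A data.frame.
#' @export
readCodingLabels <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("transcript_id", "predictor_a", "predictor_b")
    if (!all(need %in% colnames(df)))
        stop("coding-label table needs columns: ", paste(need, collapse = ", "))
    df
}

#' Extract the spliced (exonic) sequence of each transcript
#'
#' Exon sequences are concatenated in transcript order; minus-strand
#' transcripts are reverse-complemented, so the result is the sense (mature
#' RNA, written as DNA) sequence.
#'
#' @param models A \linkS4class{TranscriptModels} object.
#' @param genome A named \code{DNAStringSet}.
#' @return A \code{DNAStringSet} named by transcript id.
#' @export
txSequences <- function(models, genome) {
    ex <- exonsByTx(models)
    seqs <- Biostrings::DNAStringSet(vapply(seq_along(ex), function(i) {
        g <- ex[[i]]
        sc <- as.character(GenomicRanges::seqnames(g)[1])
        parts <- Biostrings::extractAt(genome[[sc]], ranges(g))
        s <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
        if (as.character(strand(g)[1]) == "-")
            s <- Biostrings::reverseComplement(s)
        as.character(s)
    }, character(1)))
    names(seqs) <- names(ex)
    seqs
}

#' Extract strand-aware genomic subsequences
#'
#' @param gr A \code{GRanges}.
#' @param genome A named \code{DNAStringSet}.
#' @return A \code{DNAStringSet} parallel to \code{gr}; minus-strand ranges
#'   are reverse-complemented.
#' @export
extractSequences <- function(gr, genome) {
    out <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
        sc <- as.character(GenomicRanges::seqnames(gr)[i])
        s <- Biostrings::extractAt(genome[[sc]], ranges(gr)[i])[[1]]
        if (as.character(strand(gr)[i]) == "-")
            s <- Biostrings::reverseComplement(s)
        as.character(s)
    }, character(1)))
    names(out) <- names(gr)
    out
}
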