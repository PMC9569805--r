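#' Local alternative-splicing event enumeration from isoform structures
#'
#' Events are found by exhaustive pairwise comparison of the isoforms of a
#' gene, expressed in junction (intron) algebra, then deduplicated by their
#' genomic coordinate signature so an event discovered from several isoform
#' pairs counts once. Only simple binary events are produced; nested or
#' combined events are not merged into complexes. The seven types:
#'
#' \itemize{
#'   \item RI: one form has intron (s, e), the other an exon spanning it.
#'     Form 1 is the intron-retaining form.
#'   \item SE: an internal exon with its two flanking junctions in one form
#'     vs the single skipping junction in the other. Form 1 = inclusion.
#'   \item A5/A3: two junctions sharing one boundary and differing at the
#'     donor (A5) or acceptor (A3) side, with overlapping flanking exons.
#'     Form 1 = the longer-exon (shorter-intron, proximal splice site) form.
#'   \item MX: two mutually exclusive internal exons sharing both outer
#'     junction anchors. Form 1 = the 5'-most exon form.
#'   \item AF/AL: distinct, non-overlapping first/last exons spliced into a
#'     shared exon. Form 1 = the distal (outermost) terminal exon form.
#' }
#'
#' Donor/acceptor semantics are resolved through the strand; signatures are
#' stored in genomic coordinates.
#'
#' @name as-events
NULL

txIntronMatrix <- function(exonMat) {
    n <- nrow(exonMat)
    if (n < 2) return(matrix(integer(), ncol = 2))
    cbind(exonMat[-n, 2] + 1L, exonMat[-1, 1] - 1L)
}

hasIntron <- function(introns, s, e) {
    nrow(introns) > 0 && any(introns[, 1] == s & introns[, 2] == e)
}

hasExonCovering <- function(exonMat, s, e) {
    any(exonMat[, 1] <= s & exonMat[, 2] >= e)
}

encodeIntrons <- function(m) paste(sprintf("%d-%d", m[, 1], m[, 2]),
                                   collapse = ";")

decodeIntrons <- function(s) {
    if (startsWith(s, "RET:"))
        return(list(ret = as.integer(strsplit(sub("RET:", "", s),
                                              "-")[[1]])))
    parts <- strsplit(strsplit(s, ";")[[1]], "-")
    list(introns = matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE))
}

matchesForm <- function(form, exonMat, intronMat) {
    dec <- decodeIntrons(form)
    if (!is.null(dec$ret))
        hasExonCovering(exonMat, dec$ret[1] - 1L, dec$ret[2] + 1L)
    else all(apply(dec$introns, 1, function(r)
        hasIntron(intronMat, r[1], r[2])))
}

# candidate events from one gene; returns list of rows (no F1/F2 yet)
geneCandidates <- function(exl, inl, strandChr) {
    plus <- strandChr == "+"
    txn <- names(exl)
    out <- list()
    add <- function(type, sig, form1, form2, ri = c(NA_integer_, NA_integer_)) {
        out[[paste(type, sig)]] <<- list(type = type, sig = sig,
                                         form1 = form1, form2 = form2,
                                         ri = ri)
    }
    n <- length(exl)
    for (p in seq_len(n)) for (q in seq_len(n)) {
        if (p == q) next
        ip <- inl[[p]]; iq <- inl[[q]]; ep <- exl[[p]]
        # RI: q's intron retained inside an exon of p
        if (nrow(iq)) for (r in seq_len(nrow(iq))) {
            s <- iq[r, 1]; e <- iq[r, 2]
            if (hasExonCovering(ep, s - 1L, e + 1L))
                add("RI", paste(s, e), sprintf("RET:%d-%d", s, e),
                    sprintf("%d-%d", s, e), c(s, e))
        }
        # SE: internal exon of p skipped by a single junction in q
        if (nrow(ep) >= 3) for (k in 2:(nrow(ep) - 1)) {
            dl <- ip[k - 1, 1]; ar <- ip[k, 2]
            xs <- ep[k, 1]; xe <- ep[k, 2]
            if (hasIntron(iq, dl, ar))
                add("SE", paste(dl, xs, xe, ar),
                    sprintf("%d-%d;%d-%d", dl, xs - 1L, xe + 1L, ar),
                    sprintf("%d-%d", dl, ar))
        }
        if (p < q) {
            eq <- exl[[q]]
            # shared-boundary junction pairs -> A5/A3/AF/AL
            if (nrow(ip) && nrow(iq))
            for (r1 in seq_len(nrow(ip))) for (r2 in seq_len(nrow(iq))) {
                s1 <- ip[r1, 1]; e1 <- ip[r1, 2]
                s2 <- iq[r2, 1]; e2 <- iq[r2, 2]
                if (s1 == s2 && e1 == e2) next
                if (e1 == e2 && s1 != s2) {
                    # variation at the genomic-left (intron start) boundary
                    xa <- ep[ep[, 2] == s1 - 1L, , drop = FALSE]
                    xb <- eq[eq[, 2] == s2 - 1L, , drop = FALSE]
                    if (!nrow(xa) || !nrow(xb)) next
                    overlap <- xa[1, 1] <= xb[1, 2] && xb[1, 1] <= xa[1, 2]
                    if (overlap) {
                        type <- if (plus) "A5" else "A3"
                        lo <- min(s1, s2); hi <- max(s1, s2)
                        add(type, paste(lo, hi, e1),
                            sprintf("%d-%d", hi, e1),   # shorter intron
                            sprintf("%d-%d", lo, e1))
                    } else if (identical(xa[1, ], ep[1, ]) &&
                               identical(xb[1, ], eq[1, ])) {
                        type <- if (plus) "AF" else "AL"
                        lo <- min(s1, s2); hi <- max(s1, s2)
                        add(type, paste(lo, hi, e1),
                            sprintf("%d-%d", lo, e1),   # distal terminal exon
                            sprintf("%d-%d", hi, e1))
                    }
                } else if (s1 == s2 && e1 != e2) {
                    # variation at the genomic-right (intron end) boundary
                    xa <- ep[ep[, 1] == e1 + 1L, , drop = FALSE]
                    xb <- eq[eq[, 1] == e2 + 1L, , drop = FALSE]
                    if (!nrow(xa) || !nrow(xb)) next
                    overlap <- xa[1, 1] <= xb[1, 2] && xb[1, 1] <= xa[1, 2]
                    if (overlap) {
                        type <- if (plus) "A3" else "A5"
                        lo <- min(e1, e2); hi <- max(e1, e2)
                        add(type, paste(s1, lo, hi),
                            sprintf("%d-%d", s1, lo),   # shorter intron
                            sprintf("%d-%d", s1, hi))
                    } else if (identical(xa[1, ], ep[nrow(ep), ]) &&
                               identical(xb[1, ], eq[nrow(eq), ])) {
                        type <- if (plus) "AL" else "AF"
                        lo <- min(e1, e2); hi <- max(e1, e2)
                        add(type, paste(s1, lo, hi),
                            sprintf("%d-%d", s1, hi),   # distal terminal exon
                            sprintf("%d-%d", s1, lo))
                    }
                }
            }
            # MX: internal exons sharing both outer junction anchors
            if (nrow(ep) >= 3 && nrow(eq) >= 3)
            for (k in 2:(nrow(ep) - 1)) for (l in 2:(nrow(eq) - 1)) {
                x1 <- ep[k, ]; x2 <- eq[l, ]
                if (x1[1] <= x2[2] && x2[1] <= x1[2]) next  # must be disjoint
                if (ip[k - 1, 1] != iq[l - 1, 1]) next      # shared donor anchor
                if (ip[k, 2] != iq[l, 2]) next              # shared acceptor anchor
                d <- ip[k - 1, 1]; a <- ip[k, 2]
                first <- if (x1[1] < x2[1]) x1 else x2
                secnd <- if (x1[1] < x2[1]) x2 else x1
                # form 1 = 5'-most exon in transcript orientation
                f1x <- if (plus) first else secnd
                f2x <- if (plus) secnd else first
                add("MX", paste(d, first[1], first[2], secnd[1], secnd[2], a),
                    sprintf("%d-%d;%d-%d", d, f1x[1] - 1L, f1x[2] + 1L, a),
                    sprintf("%d-%d;%d-%d", d, f2x[1] - 1L, f2x[2] + 1L, a))
            }
        }
    }
    out
}

#' Enumerate alternative-splicing events from transcript models
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @param smrtOnly When TRUE, only long-read-supported transcripts
#'   participate (the setting used for the splicing analysis proper).
#' @return A \linkS4class{SpliceEventSet}. Event ids are
#'   \code{gene;type;signature} and stable across runs and input orderings.
#' @export
enumerateEvents <- function(models, smrtOnly = FALSE) {
    if (smrtOnly) models <- models[txIds(models)[unname(smrtSupported(models))]]
    ex <- exonsByTx(models)
    gid <- unname(geneIds(models))
    sL <- as.list(start(ex)); eL <- as.list(end(ex))
    idx1 <- cumsum(lengths(ex)) - lengths(ex) + 1L
    scf1 <- as.character(unlist(seqnames(ex), use.names = FALSE))[idx1]
    str1 <- as.character(unlist(strand(ex), use.names = FALSE))[idx1]
    rows <- list()
    for (g in unique(gid)) {
        idx <- which(gid == g)
        if (length(idx) < 2) next
        exl <- lapply(idx, function(i) {
            m <- cbind(sL[[i]], eL[[i]])
            m[order(m[, 1]), , drop = FALSE]
        })
        names(exl) <- names(ex)[idx]
        inl <- lapply(exl, txIntronMatrix)
        scf <- scf1[idx[1]]
        str <- str1[idx[1]]
        cand <- geneCandidates(exl, inl, str)
        for (cd in cand) {
            f1 <- names(exl)[vapply(seq_along(exl), function(i)
                matchesForm(cd$form1, exl[[i]], inl[[i]]), logical(1))]
            f2 <- names(exl)[vapply(seq_along(exl), function(i)
                matchesForm(cd$form2, exl[[i]], inl[[i]]), logical(1))]
            if (length(intersect(f1, f2)))
                stop("internal consistency error: transcript matches both ",
                     "forms of ", g, " ", cd$type, " ", cd$sig)
            rows[[length(rows) + 1L]] <- list(
                event_id = paste(g, cd$type, gsub(" ", ":", cd$sig),
                                 sep = ";"),
                gene_id = g, type = cd$type, seqnames = scf, strand = str,
                form1 = cd$form1, form2 = cd$form2,
                F1 = sort(f1), F2 = sort(f2),
                ri_start = cd$ri[1], ri_end = cd$ri[2])
        }
    }
    col <- function(f, how) vapply(rows, `[[`, how, f)
    ev <- if (length(rows)) S4Vectors::DataFrame(
            event_id = col("event_id", character(1)),
            gene_id = col("gene_id", character(1)),
            type = col("type", character(1)),
            seqnames = col("seqnames", character(1)),
            strand = col("strand", character(1)),
            form1 = col("form1", character(1)),
            form2 = col("form2", character(1)),
            F1 = IRanges::CharacterList(lapply(rows, `[[`, "F1")),
            F2 = IRanges::CharacterList(lapply(rows, `[[`, "F2")),
            ri_start = col("ri_start", integer(1)),
            ri_end = col("ri_end", integer(1)))
        else
        S4Vectors::DataFrame(event_id = character(), gene_id = character(),
            type = character(), seqnames = character(), strand = character(),
            form1 = character(), form2 = character(),
            F1 = IRanges::CharacterList(), F2 = IRanges::CharacterList(),
            ri_start = integer(), ri_end = integer())
    ev <- ev[order(ev$event_id), , drop = FALSE]
    new("SpliceEventSet", events = ev)
}

#' Re-derive the F1/F2 transcript sets of one event
#'
#' A transcript joins F1 (resp. F2) iff its structure contains the full
#' form-1 (resp. form-2) signature: all form junctions for junction-defined
#' forms, or an exon covering the retained intron for the RI form 1.
#'
#' @param event One-row subset of a \linkS4class{SpliceEventSet} (or its
#'   \code{eventTable} row).
#' @param models \linkS4class{TranscriptModels} of the event's gene.
#' @return \code{list(F1, F2)} of transcript ids.
#' @export
assignTranscripts <- function(event, models) {
    if (is(event, "SpliceEventSet")) event <- eventTable(event)
    stopifnot(nrow(event) == 1)
    ids <- txIds(models)[unname(geneIds(models)) == event$gene_id]
    ex <- exonsByTx(models)[ids]
    exl <- lapply(seq_along(ex), function(i) cbind(start(ex[[i]]), end(ex[[i]])))
    names(exl) <- ids
    inl <- lapply(exl, txIntronMatrix)
    f1 <- ids[vapply(ids, function(t)
        matchesForm(event$form1, exl[[t]], inl[[t]]), logical(1))]
    f2 <- ids[vapply(ids, function(t)
        matchesForm(event$form2, exl[[t]], inl[[t]]), logical(1))]
    if (length(intersect(f1, f2)))
        stop("internal consistency error: transcript matches both forms")
    list(F1 = sort(f1), F2 = sort(f2))
}

#' Event-type composition per stage
#'
#' An event counts as expressed in a stage iff its Psi is defined in at
#' least one sample of that stage; ratios are normalized within stage.
#'
#' @param psi A \linkS4class{PsiExperiment}.
#' @param stageOf Named character: sample id -> stage label.
#' @return data.frame(stage, type, count, ratio).
#' @export
eventComposition <- function(psi, stageOf) {
    p <- psiValues(psi)
    types <- SummarizedExperiment::rowData(psi)$type
    stages <- unique(stageOf[colnames(p)])
    out <- list()
    for (st in stages) {
        cols <- names(stageOf)[stageOf == st]
        expressed <- rowSums(!is.na(p[, cols, drop = FALSE])) > 0
        tab <- table(factor(types[expressed], levels = EVENT_TYPES))
        tot <- sum(tab)
        out[[st]] <- data.frame(stage = st, type = names(tab),
                                count = as.integer(tab),
                                ratio = if (tot) as.integer(tab) / tot else 0,
                                stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}
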