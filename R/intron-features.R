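#' Position log-odds model of a splice site
#'
#' First-order (independent-position) maximum-entropy scoring: a position
#' frequency matrix learned from training sites with a pseudocount, scored
#' as summed log2 odds against the window-wide background composition.
#' Donor windows are 3 exonic + 6 intronic bases (9-mer, intronic positions
#' 1-2 are the GT); acceptor windows are 20 intronic + 3 exonic bases
#' (23-mer, intronic positions 19-20 are the AG).
#'
#' @slot siteKind \code{"donor"} or \code{"acceptor"}.
#' @slot freq 4-row probability matrix (rows A, C, G, T), columns sum to 1.
#' @slot background Length-4 base composition of the training windows.
#'
#' @export
setClass("SpliceSiteModel",
    slots = c(siteKind = "character", freq = "matrix",
              background = "numeric"))

setValidity("SpliceSiteModel", function(object) {
    if (!object@siteKind %in% c("donor", "acceptor"))
        return("siteKind must be 'donor' or 'acceptor'")
    w <- if (object@siteKind == "donor") 9L else 23L
    if (ncol(object@freq) != w)
        return(paste("freq must have", w, "columns for", object@siteKind))
    if (any(abs(colSums(object@freq) - 1) > 1e-6))
        return("freq columns must sum to 1")
    TRUE
})

setMethod("show", "SpliceSiteModel", function(object) {
    cons <- paste(BASES[apply(object@freq, 2, which.max)], collapse = "")
    cat("SpliceSiteModel (", object@siteKind, "), consensus ", cons, "\n",
        sep = "")
})

spliceWindowRanges <- function(introns, kind) {
    plus <- as.character(strand(introns)) == "+"
    s <- start(introns); e <- end(introns)
    if (kind == "donor") {
        st <- ifelse(plus, s - 3L, e - 5L)
        en <- ifelse(plus, s + 5L, e + 3L)
    } else {
        st <- ifelse(plus, e - 19L, s - 3L)
        en <- ifelse(plus, e + 3L, s + 19L)
    }
    GRanges(seqnames(introns), IRanges(st, en), strand = strand(introns))
}

#' Train a splice-site model from constitutive introns
#'
#' @param introns GRanges of training introns (strand required); their
#'   donor or acceptor windows are extracted strand-aware from the genome.
#' @param genome Named \code{DNAStringSet}.
#' @param siteKind \code{"donor"} or \code{"acceptor"}.
#' @param pseudocount Added per base per position before normalizing
#'   (default 1).
#' @param minSites Minimum number of training sites (default 50).
#' @return A \linkS4class{SpliceSiteModel}.
#' @export
trainSpliceModel <- function(introns, genome, siteKind = c("donor", "acceptor"),
                             pseudocount = 1, minSites = 50L) {
    siteKind <- match.arg(siteKind)
    if (length(introns) < minSites)
        stop("need at least ", minSites, " training sites, have ",
             length(introns))
    win <- spliceWindowRanges(introns, siteKind)
    seqs <- extractSequences(win, genome)
    spliceModelFromSites(as.character(seqs), siteKind, pseudocount)
}

#' Build a splice-site model from window sequences directly
#'
#' @param sites Character vector of equal-length window sequences.
#' @param siteKind \code{"donor"} or \code{"acceptor"}.
#' @param pseudocount Added per base per position (default 1).
#' @return A \linkS4class{SpliceSiteModel}.
#' @export
spliceModelFromSites <- function(sites, siteKind, pseudocount = 1) {
    mat <- do.call(rbind, strsplit(toupper(sites), ""))
    counts <- vapply(seq_len(ncol(mat)), function(j) {
        tab <- table(factor(mat[, j], levels = BASES))
        as.numeric(tab)
    }, numeric(4))
    rownames(counts) <- BASES
    counts <- counts + pseudocount
    freq <- sweep(counts, 2, colSums(counts), "/")
    bgc <- table(factor(as.vector(mat), levels = BASES)) + pseudocount
    bg <- as.numeric(bgc) / sum(bgc)
    names(bg) <- BASES
    new("SpliceSiteModel", siteKind = siteKind, freq = freq, background = bg)
}

#' Score a splice-site window
#'
#' Summed log2(freq / background) over positions; higher = stronger site.
#' Positions with non-ACGT bases contribute 0.
#'
#' @param model A \linkS4class{SpliceSiteModel}.
#' @param sequence Window sequence, length must equal the model window.
#' @return Log-odds score in bits.
#' @export
scoreSpliceSite <- function(model, sequence) {
    s <- strsplit(toupper(as.character(sequence)), "")[[1]]
    if (length(s) != ncol(model@freq))
        stop("sequence length ", length(s), " != model window ",
             ncol(model@freq))
    ri <- match(s, BASES)
    ok <- !is.na(ri)
    sum(log2(model@freq[cbind(ri[ok], which(ok))] /
             model@background[ri[ok]]))
}

#' The branch-point PWM (consensus NNNYNAN)
#'
#' Position 4 is pyrimidine-weighted, position 6 adenine-dominant, other
#' positions uninformative; Y = pyrimidine, N = any base.
#'
#' @return A 4 x 7 probability matrix (rows A, C, G, T).
#' @export
bpsPwm <- function() {
    p <- matrix(0.25, 4, 7, dimnames = list(BASES, NULL))
    p[, 4] <- c(A = 0.05, C = 0.45, G = 0.05, T = 0.45)
    p[, 6] <- c(A = 0.85, C = 0.05, G = 0.05, T = 0.05)
    p
}

#' Scan for the branch-point sequence upstream of the 3' splice site
#'
#' Slides the 7-mer NNNYNAN PWM over the configured window upstream of the
#' intron's 3' end and returns the best log2-odds score (uniform
#' background) and its offset. Offsets are relative to the 3' splice site:
#' a motif starting at the intron's k-th base from its 3' end has position
#' \code{-(k)}; e.g. a hit at -25 ends 18 bases before the intron end.
#'
#' @param intronSeq Intron sequence in transcript (5'->3') orientation.
#' @param window \code{c(min, max)} distance in bp from the motif 3' end to
#'   the splice site (default 18 to 44).
#' @param pwm Branch-point PWM (default \code{\link{bpsPwm}()}).
#' @return \code{list(score, position)}; score NA when the intron is too
#'   short for the window.
#' @export
scoreBps <- function(intronSeq, window = c(18L, 44L), pwm = bpsPwm()) {
    s <- strsplit(toupper(as.character(intronSeq)), "")[[1]]
    L <- length(s)
    w <- ncol(pwm)
    pMin <- max(1L, L - window[2] - w + 1L)
    pMax <- L - window[1] - w + 1L
    if (pMax < pMin)
        return(list(score = NA_real_, position = NA_integer_))
    lod <- log2(pwm / 0.25)
    best <- -Inf; bestAt <- NA_integer_
    for (p in pMin:pMax) {
        winS <- match(s[p:(p + w - 1L)], BASES)
        if (anyNA(winS)) next
        sc <- sum(lod[cbind(winS, seq_len(w))])
        if (sc > best) { best <- sc; bestAt <- p }
    }
    if (!is.finite(best))
        return(list(score = NA_real_, position = NA_integer_))
    list(score = best, position = bestAt - (L + 1L))
}

#' GC content of a sequence
#'
#' (G+C) / (A+C+G+T); N bases are excluded from the denominator.
#'
#' @param sequence Character or \code{DNAString}.
#' @return Fraction in [0,1].
#' @export
gcContent <- function(sequence) {
    s <- strsplit(toupper(as.character(sequence)), "")[[1]]
    n <- sum(s %in% BASES)
    if (n == 0) stop("no A/C/G/T bases in sequence")
    sum(s %in% c("G", "C")) / n
}

#' Relative position of an intron within its gene
#'
#' Strand-aware distance from the gene's transcription start site to the
#' intron's 5' end, divided by the reference span length (the gene's
#' longest transcript).
#'
#' @param intron GRanges of one intron.
#' @param geneSpan GRanges of the reference gene span (same strand).
#' @return Fraction in [0,1].
#' @export
relativePosition <- function(intron, geneSpan) {
    plus <- as.character(strand(geneSpan)) == "+"
    d <- if (plus) start(intron) - start(geneSpan)
         else end(geneSpan) - end(intron)
    if (d < 0 || d >= width(geneSpan))
        stop("intron outside the gene span")
    d / width(geneSpan)
}

#' Extract alternative and constitutive introns, categorized over/normal
#'
#' Alternative introns are the retained introns of classified RI events;
#' constitutive introns occur in every isoform of their gene and are not
#' engaged in any event. Both are crossed with the host gene's over/normal
#' status: a gene hosting at least one over RI event is an "over" gene,
#' a gene whose classified RI events are all normal is a "normal" gene;
#' genes without classified RI events contribute no introns.
#'
#' @param models A \linkS4class{TranscriptModels}.
#' @param events A \linkS4class{SpliceEventSet}.
#' @param overNormal Output of \code{\link{classifyOverNormal}} for the RI
#'   events.
#' @return GRanges of introns with metadata \code{gene_id},
#'   \code{intron_class} (alternative/constitutive) and \code{category}
#'   (alt_over, alt_normal, cons_over, cons_normal).
#' @export
extractIntrons <- function(models, events, overNormal) {
    ev <- eventTable(events)
    on <- overNormal[overNormal$status %in% c("over", "normal"), ]
    geneStatus <- tapply(on$status, on$gene_id,
                         function(s) if (any(s == "over")) "over" else "normal")
    introns <- intronsByTx(models)
    gid <- unname(geneIds(models))
    out <- GRanges()
    for (g in names(geneStatus)) {
        st <- geneStatus[[g]]
        idx <- which(gid == g)
        # alternative introns: retained introns of this gene's classified RI
        evg <- ev[ev$gene_id == g & ev$type == "RI" &
                  ev$event_id %in% on$event_id, , drop = FALSE]
        altKey <- character()
        if (nrow(evg)) {
            alt <- GRanges(evg$seqnames, IRanges(evg$ri_start, evg$ri_end),
                           strand = evg$strand)
            evStatus <- on$status[match(evg$event_id, on$event_id)]
            alt$gene_id <- g
            alt$intron_class <- "alternative"
            alt$category <- paste0("alt_", evStatus)
            altKey <- paste(start(alt), end(alt))
            out <- c(out, alt)
        }
        # constitutive introns: in every isoform, not in any event signature
        inl <- lapply(idx, function(i) {
            m <- introns[[i]]
            paste(start(m), end(m))
        })
        shared <- Reduce(intersect, inl)
        evIntrons <- unlist(lapply(ev$event_id[ev$gene_id == g], function(e) {
            row <- ev[ev$event_id == e, ]
            keys <- character()
            for (f in c(row$form1, row$form2)) {
                dec <- decodeIntrons(f)
                if (!is.null(dec$ret)) keys <- c(keys,
                    paste(dec$ret[1], dec$ret[2]))
                else keys <- c(keys, paste(dec$introns[, 1], dec$introns[, 2]))
            }
            keys
        }))
        shared <- setdiff(shared, c(evIntrons, altKey))
        if (length(shared)) {
            co <- do.call(rbind, strsplit(shared, " "))
            g1 <- introns[[idx[1]]]
            cons <- GRanges(seqnames(g1)[1],
                            IRanges(as.integer(co[, 1]), as.integer(co[, 2])),
                            strand = strand(g1)[1])
            cons$gene_id <- g
            cons$intron_class <- "constitutive"
            cons$category <- paste0("cons_", st)
            out <- c(out, cons)
        }
    }
    sort(out)
}

geneReferenceSpans <- function(models) {
    sp <- txSpans(models)
    gid <- unname(geneIds(models))
    keep <- unlist(lapply(split(seq_along(sp), gid),
                          function(i) i[which.max(width(sp)[i])]))
    out <- sp[keep]
    names(out) <- names(split(seq_along(sp), gid))
    out
}

#' Compute the feature table for categorized introns
#'
#' Length, GC content, relative position from the TSS, donor/acceptor
#' splice-site strengths (against models trained on the constitutive
#' introns unless supplied) and branch-point score/position.
#'
#' @param introns Categorized introns from \code{\link{extractIntrons}}.
#' @param models The \linkS4class{TranscriptModels}.
#' @param genome Named \code{DNAStringSet}.
#' @param donorModel,acceptorModel Optional pre-trained
#'   \linkS4class{SpliceSiteModel}s.
#' @param bpsWindow Branch-point search window (default c(18, 44)).
#' @param trainMinSites Minimum constitutive introns for splice-model
#'   training (default 50).
#' @return data.frame(intron_id, gene_id, category, length, gc,
#'   relative_position, ss5_score, ss3_score, bps_score, bps_position).
#' @export
intronFeatureTable <- function(introns, models, genome,
                               donorModel = NULL, acceptorModel = NULL,
                               bpsWindow = c(18L, 44L), trainMinSites = 50L) {
    cons <- introns[introns$intron_class == "constitutive"]
    if (is.null(donorModel))
        donorModel <- trainSpliceModel(cons, genome, "donor",
                                       minSites = trainMinSites)
    if (is.null(acceptorModel))
        acceptorModel <- trainSpliceModel(cons, genome, "acceptor",
                                          minSites = trainMinSites)
    spans <- geneReferenceSpans(models)
    seqs <- extractSequences(introns, genome)
    dWin <- extractSequences(spliceWindowRanges(introns, "donor"), genome)
    aWin <- extractSequences(spliceWindowRanges(introns, "acceptor"), genome)
    n <- length(introns)
    out <- data.frame(
        intron_id = paste0(seqnames(introns), ":", start(introns), "-",
                           end(introns), ":", strand(introns)),
        gene_id = introns$gene_id, category = introns$category,
        length = width(introns), gc = NA_real_,
        relative_position = NA_real_, ss5_score = NA_real_,
        ss3_score = NA_real_, bps_score = NA_real_,
        bps_position = NA_integer_, stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
        out$gc[i] <- gcContent(seqs[[i]])
        out$relative_position[i] <-
            relativePosition(introns[i], spans[introns$gene_id[i]])
        out$ss5_score[i] <- scoreSpliceSite(donorModel, dWin[[i]])
        out$ss3_score[i] <- scoreSpliceSite(acceptorModel, aWin[[i]])
        b <- scoreBps(seqs[[i]], window = bpsWindow)
        out$bps_score[i] <- b$score
        out$bps_position[i] <- b$position
    }
    out
}

#' Compare intron feature distributions between categories
#'
#' Two-sided Mann-Whitney U test per feature and category pair, with the
#' direction of the first group's median relative to the second.
#'
#' @param records Feature table from \code{\link{intronFeatureTable}} (any
#'   data.frame with a \code{category} column and numeric feature columns).
#' @param features Feature column names to compare.
#' @param pairs List of c(group_a, group_b) category pairs; default: the
#'   four contrasts of the over/normal x alternative/constitutive design.
#' @return data.frame(feature, group_a, group_b, n_a, n_b, p, direction)
#'   with direction in \{"higher", "lower", "equal"\} (median of group_a
#'   vs group_b); comparisons with an empty group are skipped.
#' @export
compareFeatureDistributions <- function(records,
        features = c("length", "gc", "relative_position", "ss5_score",
                     "ss3_score", "bps_score"),
        pairs = list(c("alt_over", "cons_over"),
                     c("alt_normal", "cons_normal"),
                     c("alt_over", "alt_normal"),
                     c("cons_over", "cons_normal"))) {
    out <- list()
    for (pr in pairs) {
        a <- records[records$category == pr[1], , drop = FALSE]
        b <- records[records$category == pr[2], , drop = FALSE]
        if (nrow(a) < 2 || nrow(b) < 2) next
        for (f in features) {
            xa <- a[[f]][!is.na(a[[f]])]; xb <- b[[f]][!is.na(b[[f]])]
            if (length(xa) < 2 || length(xb) < 2) next
            p <- wilcox.test(xa, xb, exact = FALSE)$p.value
            md <- median(xa) - median(xb)
            out[[length(out) + 1L]] <- data.frame(
                feature = f, group_a = pr[1], group_b = pr[2],
                n_a = length(xa), n_b = length(xb), p = p,
                direction = if (md > 0) "higher" else if (md < 0) "lower"
                            else "equal",
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}
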