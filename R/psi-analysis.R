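#' Percent spliced-in for one event
#'
#' \eqn{\Psi = \sum_{k \in F1} TPM_k / \sum_{j \in F1 \cup F2} TPM_j},
#' undefined (NA) unless the total expression of the participating
#' transcripts exceeds the floor (default 1 TPM). Undefined Psi propagates
#' as missing, never as 0 — 0 is a meaningful value (all expression on
#' form 2).
#'
#' @param f1Tpm,f2Tpm TPM values of the form-1 / form-2 transcripts.
#' @param floor Minimum total TPM, exclusive (default 1).
#' @return Psi in [0,1], or NA.
#' @export
computePsi <- function(f1Tpm, f2Tpm, floor = 1) {
    if (any(c(f1Tpm, f2Tpm) < 0)) stop("negative TPM")
    tot <- sum(f1Tpm) + sum(f2Tpm)
    if (tot <= floor) return(NA_real_)
    sum(f1Tpm) / tot
}

#' Psi matrix over events and samples
#'
#' Builds a \linkS4class{PsiExperiment} from an event set and a TPM matrix.
#' Transcripts absent from the matrix contribute 0 TPM.
#'
#' @param events A \linkS4class{SpliceEventSet}.
#' @param tpm Transcript-by-sample TPM matrix.
#' @param floor Minimum total TPM, exclusive (default 1).
#' @return A \linkS4class{PsiExperiment} with assays \code{psi} and
#'   \code{total}; event metadata in \code{rowData}.
#' @export
psiExperiment <- function(events, tpm, floor = 1) {
    ev <- eventTable(events)
    ns <- ncol(tpm)
    rowTpm <- function(ids) {
        hit <- intersect(ids, rownames(tpm))
        if (!length(hit)) return(rep(0, ns))
        colSums(tpm[hit, , drop = FALSE])
    }
    psi <- matrix(NA_real_, nrow(ev), ns,
                  dimnames = list(ev$event_id, colnames(tpm)))
    tot <- psi
    for (i in seq_len(nrow(ev))) {
        a <- rowTpm(ev$F1[[i]]); b <- rowTpm(ev$F2[[i]])
        tot[i, ] <- a + b
        ok <- tot[i, ] > floor
        psi[i, ok] <- a[ok] / tot[i, ok]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(psi = psi, total = tot),
        rowData = ev[, c("event_id", "gene_id", "type", "seqnames",
                         "strand", "ri_start", "ri_end")])
    new("PsiExperiment", se)
}

#' Psi difference between two conditions
#'
#' @param psiA,psiB Psi values (vectors recycled); NA on either side gives
#'   NA.
#' @return \code{psiB - psiA}.
#' @export
deltaPsi <- function(psiA, psiB) psiB - psiA

#' Wilcoxon signed-rank test with a Pratt zero policy
#'
#' Two-sided paired test. With the default Pratt policy, zero differences
#' are kept in the ranking of |d| and dropped from the signs — many Psi
#' pairs tie exactly, and dropping them (the classical Wilcoxon policy,
#' available as \code{zeroMethod = "wilcoxon"}) silently shrinks n. The
#' exact distribution (base \code{psignrank}) is used when there are no
#' ties and no zeros and n <= 50; otherwise a normal approximation with tie
#' and zero corrections.
#'
#' @param x,y Paired numeric vectors.
#' @param zeroMethod \code{"pratt"} (default) or \code{"wilcoxon"}.
#' @param exact Force (TRUE) or forbid (FALSE) the exact distribution;
#'   NULL decides automatically.
#' @param correct Continuity correction in the normal approximation
#'   (default FALSE).
#' @return \code{list(statistic, p.value, n, method)}; \code{statistic} is
#'   the positive-rank sum W+.
#' @export
wilcoxonSignedRank <- function(x, y, zeroMethod = c("pratt", "wilcoxon"),
                               exact = NULL, correct = FALSE) {
    zeroMethod <- match.arg(zeroMethod)
    stopifnot(length(x) == length(y))
    keep <- !(is.na(x) | is.na(y))
    d <- (y - x)[keep]
    if (!length(d))
        return(list(statistic = NA_real_, p.value = NA_real_, n = 0L,
                    method = "empty"))
    if (all(d == 0))
        return(list(statistic = 0, p.value = 1, n = length(d),
                    method = "degenerate"))
    if (zeroMethod == "wilcoxon") d <- d[d != 0]
    n <- length(d)
    z <- sum(d == 0)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    ties <- any(duplicated(abs(d)))
    useExact <- if (is.null(exact)) (n <= 50 && !ties && z == 0)
                else exact
    if (useExact && !ties && z == 0) {
        p <- min(1, 2 * min(stats::psignrank(W, n),
                            1 - stats::psignrank(W - 1, n)))
        return(list(statistic = W, p.value = p, n = n, method = "exact"))
    }
    mn <- n * (n + 1) / 4 - z * (z + 1) / 4
    sig2 <- (n * (n + 1) * (2 * n + 1) - z * (z + 1) * (2 * z + 1)) / 24
    tab <- table(r)
    sig2 <- sig2 - sum(tab^3 - tab) / 48
    if (sig2 <= 0)
        return(list(statistic = W, p.value = 1, n = n,
                    method = "degenerate"))
    dev <- W - mn
    if (correct) dev <- dev - sign(dev) * 0.5
    p <- min(1, 2 * pnorm(-abs(dev) / sqrt(sig2)))
    list(statistic = W, p.value = p, n = n, method = "normal")
}

#' Compare Psi distributions across adjacent time points
#'
#' For each adjacent pair of ordered samples and each event type, events
#' defined at both samples are paired and tested two-sided with
#' \code{\link{wilcoxonSignedRank}}. Pairs with fewer than \code{minPairs}
#' events are flagged underpowered but kept. A Benjamini-Hochberg column
#' over all rows is emitted alongside the raw p-values.
#'
#' @param psi A \linkS4class{PsiExperiment}.
#' @param adjacency Ordered sample ids (default: column order).
#' @param types Event types to test (default: those present).
#' @param minPairs Underpowered flag threshold (default 6).
#' @return data.frame(sample_a, sample_b, type, n, statistic, p, p_bh,
#'   underpowered, test).
#' @export
compareAdjacent <- function(psi, adjacency = colnames(psi), types = NULL,
                            minPairs = 6L) {
    p <- psiValues(psi)
    evType <- SummarizedExperiment::rowData(psi)$type
    if (is.null(types)) types <- sort(unique(evType))
    if (length(adjacency) < 2) stop("need at least two ordered samples")
    out <- list()
    for (i in seq_len(length(adjacency) - 1L)) {
        a <- adjacency[i]; b <- adjacency[i + 1L]
        for (ty in types) {
            xa <- p[evType == ty, a]; xb <- p[evType == ty, b]
            ok <- !(is.na(xa) | is.na(xb))
            w <- wilcoxonSignedRank(xa[ok], xb[ok])
            out[[length(out) + 1L]] <- data.frame(
                sample_a = a, sample_b = b, type = ty, n = sum(ok),
                statistic = w$statistic, p = w$p.value,
                underpowered = sum(ok) < minPairs,
                test = "wilcoxon_signed_rank", stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    res$p_bh <- p.adjust(res$p, method = "BH")
    res
}

#' Compare Psi distributions between tissue pairs
#'
#' Psi per tissue is the mean over that tissue's replicate columns (the two
#' late sampling dates) where defined. All unordered tissue pairs are
#' tested per event type with the paired signed-rank test over events
#' defined in both tissues.
#'
#' @param psi A \linkS4class{PsiExperiment} whose columns are tissue
#'   replicates.
#' @param tissueOf Named character: column id -> tissue label.
#' @param types Event types to test (default: those present).
#' @param minPairs Underpowered flag threshold (default 6).
#' @return data.frame(tissue_a, tissue_b, type, n, statistic, p, p_bh,
#'   underpowered, test).
#' @export
compareTissuePairs <- function(psi, tissueOf, types = NULL, minPairs = 6L) {
    p <- psiValues(psi)
    evType <- SummarizedExperiment::rowData(psi)$type
    if (is.null(types)) types <- sort(unique(evType))
    tissues <- unique(unname(tissueOf[colnames(p)]))
    byTissue <- vapply(tissues, function(tt) {
        cols <- names(tissueOf)[tissueOf == tt]
        rowMeans(p[, cols, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(p)))
    byTissue[is.nan(byTissue)] <- NA_real_
    out <- list()
    if (length(tissues) >= 2)
    for (i in seq_len(length(tissues) - 1L))
        for (j in seq(i + 1L, length(tissues))) {
            for (ty in types) {
                xa <- byTissue[evType == ty, i]
                xb <- byTissue[evType == ty, j]
                ok <- !(is.na(xa) | is.na(xb))
                w <- wilcoxonSignedRank(xa[ok], xb[ok])
                out[[length(out) + 1L]] <- data.frame(
                    tissue_a = tissues[i], tissue_b = tissues[j], type = ty,
                    n = sum(ok), statistic = w$statistic, p = w$p.value,
                    underpowered = sum(ok) < minPairs,
                    test = "wilcoxon_signed_rank", stringsAsFactors = FALSE)
            }
        }
    res <- do.call(rbind, out)
    res$p_bh <- p.adjust(res$p, method = "BH")
    res
}

#' Classify events as "over" or "normal" at a transition
#'
#' An event whose Psi difference across the transition exceeds the
#' threshold (strictly; default 0.07) is "over" — it sheds proportionally
#' more of its expression onto the form-1 (for RI: intron-retaining)
#' transcripts after the transition. Events with undefined delta are
#' excluded with a reason.
#'
#' @param psi A \linkS4class{PsiExperiment}.
#' @param sampleA,sampleB The transition pair (e.g. the samples flanking
#'   zygotic genome activation).
#' @param threshold Over threshold on delta Psi (default 0.07).
#' @param types Event types to classify (default \code{"RI"}; use
#'   \code{NULL} for all).
#' @return data.frame(event_id, gene_id, type, delta_psi, status); status
#'   in \{"over", "normal", "excluded:undefined"\}.
#' @export
classifyOverNormal <- function(psi, sampleA, sampleB, threshold = 0.07,
                               types = "RI") {
    p <- psiValues(psi)
    rd <- SummarizedExperiment::rowData(psi)
    keep <- if (is.null(types)) rep(TRUE, nrow(p)) else rd$type %in% types
    d <- deltaPsi(p[keep, sampleA], p[keep, sampleB])
    status <- ifelse(is.na(d), "excluded:undefined",
                     ifelse(d > threshold, "over", "normal"))
    data.frame(event_id = rownames(p)[keep], gene_id = rd$gene_id[keep],
               type = rd$type[keep], delta_psi = unname(d), status = status,
               stringsAsFactors = FALSE)
}

#' Count over RI events per gene
#'
#' @param overNormal Output of \code{\link{classifyOverNormal}}.
#' @return data.frame(gene_id, n_over): genes with at least one over event.
#' @export
overGeneCounts <- function(overNormal) {
    ov <- overNormal[overNormal$status == "over", ]
    tab <- table(ov$gene_id)
    data.frame(gene_id = names(tab), n_over = as.integer(tab),
               stringsAsFactors = FALSE)
}
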