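#' PCA of expression with per-transcript variable contributions
#'
#' Samples are observations, transcripts are variables. Expression is
#' log2(TPM+1)-transformed and mean-centered (not unit-scaled) before
#' \code{prcomp}. Each PC is oriented so that its largest-|loading|
#' transcript has a positive loading, making outputs reproducible across
#' linear-algebra backends.
#'
#' @param tpm Transcript-by-sample TPM matrix.
#' @param nComponents Number of PCs to keep (default
#'   \code{min(dim) - 1}).
#' @param logTransform Apply log2(TPM+1) first (default TRUE).
#' @param scale. Unit-scale variables (default FALSE; constant transcripts
#'   are dropped with a warning when scaling).
#' @return A list of class \code{"PcaResult"}: \code{scores} (sample x PC),
#'   \code{loadings} (transcript x PC), \code{variance_explained}
#'   (percent per PC, non-increasing), \code{contributions} (transcript x
#'   PC, percent, columns sum to 100).
#' @export
runPca <- function(tpm, nComponents = NULL, logTransform = TRUE,
                   scale. = FALSE) {
    if (nrow(tpm) < 2 || ncol(tpm) < 2)
        stop("need at least 2 transcripts and 2 samples")
    x <- t(if (logTransform) log2(tpm + 1) else tpm)
    if (scale.) {
        v <- apply(x, 2, stats::var)
        if (any(v == 0)) {
            warning("dropping ", sum(v == 0), " constant transcript(s)")
            x <- x[, v > 0, drop = FALSE]
        }
    }
    pc <- prcomp(x, center = TRUE, scale. = scale.)
    k <- min(if (is.null(nComponents)) ncol(pc$rotation) else nComponents,
             ncol(pc$rotation))
    rot <- pc$rotation[, seq_len(k), drop = FALSE]
    sco <- pc$x[, seq_len(k), drop = FALSE]
    flip <- vapply(seq_len(k), function(j)
        sign(rot[which.max(abs(rot[, j])), j]), numeric(1))
    flip[flip == 0] <- 1
    rot <- sweep(rot, 2, flip, "*")
    sco <- sweep(sco, 2, flip, "*")
    ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
    res <- list(scores = sco, loadings = rot,
                variance_explained = ve[seq_len(k)],
                contributions = variableContributions(rot))
    class(res) <- "PcaResult"
    res
}

#' Variable contributions from loadings
#'
#' contribution(t, k) = 100 * loading(t, k)^2 / sum_t loading(t, k)^2;
#' each PC's contributions sum to 100 and are invariant to PC sign flips.
#'
#' @param loadings Transcript-by-PC loading matrix (or a PcaResult).
#' @return Matrix of percent contributions, same shape.
#' @export
variableContributions <- function(loadings) {
    if (inherits(loadings, "PcaResult")) loadings <- loadings$loadings
    norms <- colSums(loadings^2)
    if (any(norms == 0)) stop("zero-norm principal component")
    sweep(100 * loadings^2, 2, norms, "/")
}

#' Assign each transcript to its highest-contribution PC
#'
#' The PC-k-related transcript set is the set of transcripts whose maximum
#' contribution over the considered PCs falls on PC k. Ties break to the
#' lowest PC index. The sets partition the transcripts.
#'
#' @param result A PcaResult (or contribution matrix).
#' @param pcs Indices of the PCs considered (default: all in the result).
#' @return Named integer vector: transcript -> assigned PC index.
#' @export
pcRelatedTranscripts <- function(result, pcs = NULL) {
    con <- if (inherits(result, "PcaResult")) result$contributions
           else result
    if (is.null(pcs)) pcs <- seq_len(ncol(con))
    sub <- con[, pcs, drop = FALSE]
    idx <- apply(sub, 1, which.max)   # which.max breaks ties low
    setNames(pcs[idx], rownames(con))
}

#' @export
print.PcaResult <- function(x, ...) {
    cat("PcaResult:", nrow(x$scores), "samples x", ncol(x$scores), "PCs;",
        nrow(x$loadings), "transcripts\n")
    cat("  variance explained (%):",
        paste(sprintf("%.1f", utils::head(x$variance_explained, 5)),
              collapse = " "), "\n")
    invisible(x)
}
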