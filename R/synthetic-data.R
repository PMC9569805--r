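#' @importFrom GenomicRanges GRanges GRangesList granges mcols mcols<- seqnames
#' @importFrom IRanges IRanges ranges
#' @importFrom S4Vectors DataFrame
#' @importFrom stats rnorm runif setNames prcomp p.adjust pnorm wilcox.test
NULL

BASES <- c("A", "C", "G", "T")

randDna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# write `s` into scaffold string at `at` (1-based); revcomp first on minus
plantString <- function(chars, scf, at, s, minus = FALSE) {
    if (minus)
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    substr(chars[[scf]], at, at + nchar(s) - 1L) <- s
    chars
}

# batched genome editing: edits are collected as (scf, at, seq) and applied
# per scaffold on a character vector, which R updates in place
newEditLog <- function() {
    e <- new.env(parent = emptyenv())
    e$edits <- list()
    e$n <- 0L
    e
}

logEdit <- function(log, scf, at, s, minus = FALSE) {
    if (minus)
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    log$n <- log$n + 1L
    log$edits[[log$n]] <- list(scf = scf, at = at, s = s)
    invisible(log)
}

applyEdits <- function(genome, log) {
    edits <- log$edits
    if (!length(edits)) return(genome)
    scfs <- vapply(edits, `[[`, character(1), "scf")
    out <- as.character(genome)
    names(out) <- names(genome)
    for (scf in unique(scfs)) {
        v <- strsplit(out[[scf]], "")[[1]]
        for (e in edits[scfs == scf]) {
            w <- nchar(e$s)
            v[e$at:(e$at + w - 1L)] <- strsplit(e$s, "")[[1]]
        }
        out[[scf]] <- paste(v, collapse = "")
    }
    res <- Biostrings::DNAStringSet(out)
    names(res) <- names(genome)
    res
}

mutateSeq <- function(s, p, fixed = integer()) {
    v <- strsplit(s, "")[[1]]
    hit <- runif(length(v)) < p
    hit[fixed] <- FALSE
    v[hit] <- sample(BASES, sum(hit), replace = TRUE)
    paste(v, collapse = "")
}

#' Simulate a multi-scaffold genome
#'
#' Uniform random DNA over \{A,C,G,T\}; deterministic under the config seed.
#' Splice sites, branch points and motifs are written in later by
#' \code{\link{simulateGeneModels}} and \code{\link{plantRepeatsAndMotifs}}.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return A named \code{DNAStringSet} (\code{scf1}, \code{scf2}, ...).
#' @export
simulateGenome <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    set.seed(config@seed)
    seqs <- vapply(seq_len(config@nScaffolds),
                   function(i) randDna(config@scaffoldLength), character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- paste0("scf", seq_len(config@nScaffolds))
    out
}

# ---- event templates -------------------------------------------------------
# Templates are built in transcript-forward coordinates starting at 1; the
# caller mirrors them for minus-strand genes. Each returns a list of two exon
# matrices (col1 start, col2 end), which isoform follows form 1 under the
# package's orientation convention, and (for RI) the retained intron.

rint <- function(lo, hi) sample(seq(lo, hi), 1L)

buildEventTemplate <- function(type) {
    tmpl <- buildEventCore(type)
    # give every gene a constitutive intron by adding a shared terminal
    # exon on the side where the isoforms share their outermost exon
    if (type != "RI") tmpl <- addSharedFlank(tmpl, upstream = type == "AL")
    tmpl
}

addSharedFlank <- function(tmpl, upstream = FALSE) {
    iC <- rint(150, 700); eC <- rint(90, 220)
    if (upstream) {
        shift <- eC + iC
        tmpl$txs <- lapply(tmpl$txs, function(m)
            rbind(c(1, eC), m + shift))
        if (!is.null(tmpl$ri)) tmpl$ri <- tmpl$ri + shift
    } else {
        hi <- max(vapply(tmpl$txs, function(m) max(m[, 2]), numeric(1)))
        tmpl$txs <- lapply(tmpl$txs, function(m)
            rbind(m, c(hi + iC + 1, hi + iC + eC)))
    }
    tmpl
}

buildEventCore <- function(type) {
    e1 <- rint(90, 220); e2 <- rint(90, 220); e3 <- rint(90, 220)
    i1 <- rint(150, 700); i2 <- rint(150, 700)
    ext <- rint(30, 80); gap <- rint(40, 120)
    ex <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
    switch(type,
    SE = {   # A includes cassette exon, B skips it; form 1 = inclusion
        a <- ex(1, e1, e1 + i1 + 1, e1 + i1 + e2,
                e1 + i1 + e2 + i2 + 1, e1 + i1 + e2 + i2 + e3)
        b <- a[c(1, 3), , drop = FALSE]
        list(txs = list(A = a, B = b), form1 = "A", ri = NULL)
    },
    RI = {   # A retains intron 1 (form 1); intron 2 is constitutive
        b <- ex(1, e1, e1 + i1 + 1, e1 + i1 + e2,
                e1 + i1 + e2 + i2 + 1, e1 + i1 + e2 + i2 + e3)
        a <- ex(1, e1 + i1 + e2,
                e1 + i1 + e2 + i2 + 1, e1 + i1 + e2 + i2 + e3)
        list(txs = list(A = a, B = b), form1 = "A",
             ri = c(e1 + 1, e1 + i1))
    },
    A5 = {   # alternative donor; form 1 = longer exon (shorter intron) = A
        a <- ex(1, e1 + ext, e1 + i1 + 1, e1 + i1 + e2)
        b <- ex(1, e1, e1 + i1 + 1, e1 + i1 + e2)
        list(txs = list(A = a, B = b), form1 = "A", ri = NULL)
    },
    A3 = {   # alternative acceptor; form 1 = longer exon (shorter intron) = A
        a <- ex(1, e1, e1 + i1 - ext + 1, e1 + i1 + e2)
        b <- ex(1, e1, e1 + i1 + 1, e1 + i1 + e2)
        list(txs = list(A = a, B = b), form1 = "A", ri = NULL)
    },
    MX = {   # mutually exclusive internal exons; form 1 = 5'-most exon = A
        x1s <- e1 + i1 + 1; x1e <- x1s + e2 - 1
        x2s <- x1e + gap + 1; x2e <- x2s + rint(90, 220) - 1
        e4s <- x2e + i2 + 1
        a <- ex(1, e1, x1s, x1e, e4s, e4s + e3 - 1)
        b <- ex(1, e1, x2s, x2e, e4s, e4s + e3 - 1)
        list(txs = list(A = a, B = b), form1 = "A", ri = NULL)
    },
    AF = {   # alternative first exons into a shared acceptor; form 1 = distal
        f2s <- e1 + gap + 1; f2e <- f2s + rint(90, 220) - 1
        s2 <- f2e + i1 + 1
        a <- ex(1, e1, s2, s2 + e3 - 1)
        b <- ex(f2s, f2e, s2, s2 + e3 - 1)
        list(txs = list(A = a, B = b), form1 = "A", ri = NULL)
    },
    AL = {   # alternative last exons from a shared donor; form 1 = distal
        l2s <- e1 + i1 + 1; l2e <- l2s + e2 - 1
        l1s <- l2e + gap + 1; l1e <- l1s + rint(90, 220) - 1
        a <- ex(1, e1, l1s, l1e)
        b <- ex(1, e1, l2s, l2e)
        list(txs = list(A = a, B = b), form1 = "A", ri = NULL)
    },
    stop("unknown event type: ", type))
}

buildFillerTemplate <- function(singleExon) {
    e1 <- rint(150, 400)
    if (singleExon)
        list(txs = list(A = matrix(c(1, e1), ncol = 2)), form1 = "A", ri = NULL)
    else {
        i1 <- rint(150, 700); e2 <- rint(90, 220)
        list(txs = list(A = matrix(c(1, e1, e1 + i1 + 1, e1 + i1 + e2),
                                   ncol = 2, byrow = TRUE)),
             form1 = "A", ri = NULL)
    }
}

mirrorCoords <- function(m, span) {
    out <- cbind(span - m[, 2] + 1L, span - m[, 1] + 1L)
    out[rev(seq_len(nrow(out))), , drop = FALSE]
}

# plant canonical donor / acceptor / branch-point signal around one intron
plantSpliceSignals <- function(log, scf, s, e, minus) {
    donor <- mutateSeq("CAGGTAAGT", 0.15, fixed = c(4L, 5L))
    ppt <- paste(sample(c("C", "T"), 18, replace = TRUE), collapse = "")
    acceptor <- paste0(ppt, "AG", "G", randDna(2))
    bps <- mutateSeq("CTACTAC", 0.2, fixed = c(4L, 6L))
    if (!minus) {
        logEdit(log, scf, s - 3L, donor)
        logEdit(log, scf, e - 19L, acceptor)
        logEdit(log, scf, e - 24L, bps)
    } else {
        logEdit(log, scf, e - 5L, donor, minus = TRUE)
        logEdit(log, scf, s - 3L, acceptor, minus = TRUE)
        logEdit(log, scf, s + 18L, bps, minus = TRUE)
    }
    invisible(log)
}

#' Simulate gene models realizing a chosen mix of splicing events
#'
#' Each planted event becomes one gene with exactly two isoforms differing
#' only in that event's coordinates; remaining genes (up to
#' \code{nGenes}) are single-isoform fillers (alternating single- and
#' two-exon). Genes are laid left to right across scaffolds with random
#' intergenic gaps. For every intron of every isoform, canonical GT..AG
#' dinucleotides plus a degenerate donor/acceptor/branch-point consensus are
#' written into the genome so splice-site models trained downstream have
#' signal.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param genome \code{DNAStringSet} from \code{\link{simulateGenome}}.
#' @return A list with elements \code{models}
#'   (\linkS4class{TranscriptModels}), \code{truth} (ground-truth list with
#'   the planted event table, over-event designation, filler transcript ids
#'   and per-scaffold occupancy cursors) and \code{genome} (the edited
#'   \code{DNAStringSet}).
#' @export
simulateGeneModels <- function(config, genome) {
    stopifnot(is(config, "SimulationConfig"))
    set.seed(config@seed + 1L)
    log <- newEditLog()
    scfNames <- names(genome)
    nEvent <- sum(config@eventMix)
    if (config@nGenes < nEvent)
        stop("nGenes must be at least the number of planted events")
    types <- c(rep(names(config@eventMix), config@eventMix),
               rep(NA_character_, config@nGenes - nEvent))
    cursors <- setNames(rep(200L, length(genome)), scfNames)

    exRows <- list()               # per-transcript (scf, strand, starts, ends)
    evRows <- list(); filler <- character()
    fillerSingle <- TRUE
    for (g in seq_along(types)) {
        gid <- sprintf("g%04d", g)
        tmpl <- if (is.na(types[g])) {
            fillerSingle <- !fillerSingle
            buildFillerTemplate(!fillerSingle)
        } else buildEventTemplate(types[g])
        minus <- runif(1) < 0.5
        span <- max(vapply(tmpl$txs, function(m) max(m[, 2]), numeric(1)))
        # place on the first scaffold with room
        placed <- FALSE
        for (scf in scfNames) {
            off <- cursors[[scf]] + rint(300, 1000)
            if (off + span + 200L <= config@scaffoldLength) {
                cursors[[scf]] <- off + as.integer(span)
                placed <- TRUE
                break
            }
        }
        if (!placed)
            stop("placement error: gene ", gid, " does not fit on any scaffold")
        strandChr <- if (minus) "-" else "+"
        seenIntrons <- character()
        for (iso in names(tmpl$txs)) {
            m <- tmpl$txs[[iso]]
            if (minus) m <- mirrorCoords(m, span)
            abs <- m + off - 1L
            tid <- paste0(gid, ".", if (iso == "A") 1L else 2L)
            exRows[[tid]] <- list(gid = gid, scf = scf, strand = strandChr,
                                  starts = abs[, 1], ends = abs[, 2])
            if (nrow(abs) > 1) {
                for (k in seq_len(nrow(abs) - 1)) {
                    is <- abs[k, 2] + 1L; ie <- abs[k + 1, 1] - 1L
                    key <- paste(scf, is, ie)
                    if (key %in% seenIntrons) next
                    seenIntrons <- c(seenIntrons, key)
                    plantSpliceSignals(log, scf, is, ie, minus)
                }
            }
        }
        if (is.na(types[g])) {
            filler[length(filler) + 1L] <- paste0(gid, ".1")
        } else {
            ri <- tmpl$ri
            if (!is.null(ri)) {
                riAbs <- if (minus) rev(span - ri + 1L) else ri
                riAbs <- riAbs + off - 1L
            } else riAbs <- c(NA_integer_, NA_integer_)
            evRows[[length(evRows) + 1L]] <- list(
                gene_id = gid, type = types[g],
                tx_form1 = paste0(gid, ".", if (tmpl$form1 == "A") 1L else 2L),
                tx_form2 = paste0(gid, ".", if (tmpl$form1 == "A") 2L else 1L),
                scaffold = scf, strand = strandChr,
                ri_start = as.numeric(riAbs[1]), ri_end = as.numeric(riAbs[2]))
        }
    }
    pull <- function(rows, f, how) vapply(rows, `[[`, how, f)
    events <- data.frame(
        gene_id = pull(evRows, "gene_id", character(1)),
        type = pull(evRows, "type", character(1)),
        tx_form1 = pull(evRows, "tx_form1", character(1)),
        tx_form2 = pull(evRows, "tx_form2", character(1)),
        scaffold = pull(evRows, "scaffold", character(1)),
        strand = pull(evRows, "strand", character(1)),
        ri_start = as.integer(pull(evRows, "ri_start", numeric(1))),
        ri_end = as.integer(pull(evRows, "ri_end", numeric(1))),
        stringsAsFactors = FALSE)
    # designate "over" RI events: the first nOver RI rows carry the planted
    # Psi step at the activation transition
    events$over <- logical(nrow(events))
    riIdx <- which(events$type == "RI")
    if (length(riIdx) && config@nOver > 0)
        events$over[riIdx[seq_len(min(config@nOver, length(riIdx)))]] <- TRUE
    events$event_key <- paste(events$gene_id, events$type, sep = ":")

    nex <- vapply(exRows, function(r) length(r$starts), integer(1))
    gr <- GRanges(rep(pull(exRows, "scf", character(1)), nex),
                  IRanges(unlist(lapply(exRows, `[[`, "starts")),
                          unlist(lapply(exRows, `[[`, "ends"))),
                  strand = rep(pull(exRows, "strand", character(1)), nex))
    grl <- GenomicRanges::split(gr,
        factor(rep(names(exRows), nex), levels = names(exRows)))
    models <- TranscriptModels(grl,
        geneIds = pull(exRows, "gid", character(1)), smrtSupported = TRUE)
    genomeOut <- applyEdits(genome, log)
    list(models = models,
         truth = list(events = events, fillerTx = filler, cursors = cursors,
                      teLabels = character(), motifHosts = list(),
                      nFlanked = character()),
         genome = genomeOut)
}

#' Simulate a time-series TPM table with controlled Psi trajectories
#'
#' Every planted event receives a flat true Psi drawn uniformly from
#' [0.25, 0.55]; events designated "over" step up by
#' \code{plantedDeltaPsi} from the activation sample onward (mirroring the
#' rise of intron retention at zygotic genome activation). Form-1/form-2
#' transcript TPMs are the true Psi split of \code{baseTpm}, perturbed by
#' multiplicative log-normal noise of sd \code{noiseSd}; with zero noise the
#' TPM-implied Psi equals the true trajectory exactly. Filler transcripts get
#' log-normal TPM around \code{baseTpm}.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param truth Ground-truth list from \code{\link{simulateGeneModels}}.
#' @param lowExpressionEvents Event keys whose total TPM is scaled to 0.5 so
#'   that Psi is undefined downstream under the 1-TPM floor.
#' @return A list: \code{tpm} (transcript-by-sample matrix, columns
#'   \code{T2..}), \code{psiTrajectory} (event-by-sample true Psi, rows named
#'   by event key).
#' @export
simulateExpression <- function(config, truth, lowExpressionEvents = character()) {
    stopifnot(is(config, "SimulationConfig"))
    set.seed(config@seed + 2L)
    ns <- config@nSamples
    samples <- paste0("T", seq(2L, length.out = ns))
    ev <- truth$events
    base <- runif(nrow(ev), 0.25, 0.55)
    traj <- matrix(base, nrow = nrow(ev), ncol = ns,
                   dimnames = list(ev$event_key, samples))
    if (any(ev$over))
        traj[ev$over, seq(config@activationIndex, ns)] <-
            traj[ev$over, seq(config@activationIndex, ns)] + config@plantedDeltaPsi
    noise <- function(n) exp(rnorm(n, 0, config@noiseSd))
    rows <- list()
    for (i in seq_len(nrow(ev))) {
        tot <- config@baseTpm
        if (ev$event_key[i] %in% lowExpressionEvents) tot <- 0.5
        rows[[ev$tx_form1[i]]] <- traj[i, ] * tot * noise(ns)
        rows[[ev$tx_form2[i]]] <- (1 - traj[i, ]) * tot * noise(ns)
    }
    for (tid in truth$fillerTx)
        rows[[tid]] <- config@baseTpm * noise(ns)
    tpm <- do.call(rbind, rows)
    colnames(tpm) <- samples
    list(tpm = tpm, psiTrajectory = traj)
}

#' Simulate tissue-panel TPM columns with one shifted tissue
#'
#' Two replicate columns per tissue (mirroring the two late sampling dates).
#' Per tissue and event, true Psi is redrawn; in \code{shiftTissue} the RI
#' events are shifted up by \code{shiftDelta} (clamped to 0.95), planting a
#' tissue-specific intron-retention signal.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param truth Ground-truth list from \code{\link{simulateGeneModels}}.
#' @param tissues Tissue labels (default the nine-organ panel).
#' @param shiftTissue Tissue receiving the planted RI shift (default muscle).
#' @param shiftDelta Size of the planted shift.
#' @return A list: \code{tpm} (matrix with two columns per tissue, named
#'   \code{<tissue>_d1}/\code{_d2}), \code{tissueOf} (named map column ->
#'   tissue label).
#' @export
simulateTissueExpression <- function(config, truth,
                                     tissues = c("B", "M", "L", "G", "Sk",
                                                 "Sp", "K", "H", "I"),
                                     shiftTissue = "M", shiftDelta = 0.2) {
    set.seed(config@seed + 3L)
    ev <- truth$events
    cols <- as.vector(t(outer(tissues, c("_d1", "_d2"), paste0)))
    noise <- function(n) exp(rnorm(n, 0, config@noiseSd))
    tpm <- matrix(0, nrow = 0, ncol = length(cols))
    rows <- list()
    psiT <- matrix(runif(nrow(ev) * length(tissues), 0.25, 0.55),
                   nrow = nrow(ev), dimnames = list(ev$event_key, tissues))
    if (shiftTissue %in% tissues)
        psiT[ev$type == "RI", shiftTissue] <-
            pmin(psiT[ev$type == "RI", shiftTissue] + shiftDelta, 0.95)
    for (i in seq_len(nrow(ev))) {
        p <- rep(psiT[i, ], each = 2)
        rows[[ev$tx_form1[i]]] <- p * config@baseTpm * noise(length(cols))
        rows[[ev$tx_form2[i]]] <- (1 - p) * config@baseTpm * noise(length(cols))
    }
    for (tid in truth$fillerTx)
        rows[[tid]] <- config@baseTpm * noise(length(cols))
    tpm <- do.call(rbind, rows)
    colnames(tpm) <- cols
    list(tpm = tpm, tissueOf = setNames(rep(tissues, each = 2), cols))
}

#' Plant repeat intervals and sequence motifs with known ground truth
#'
#' Repeat intervals are written over designated host transcripts (single-exon
#' fillers) at controlled overlap fractions, so the transposon classifier's
#' three outcomes are all represented; background repeats from
#' \code{config@repeatPlant} go into unoccupied scaffold tails. Motif
#' consensus sequences are written into host transcript sense sequences at
#' constrained start offsets per \code{config@motifPlant}. Optionally an N
#' run is written just upstream of one planted transposon to exercise the
#' N-flank filter.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param genome Edited genome from \code{\link{simulateGeneModels}}.
#' @param models The \linkS4class{TranscriptModels}.
#' @param truth Ground-truth list (updated and returned).
#' @param tePlan data.frame(fraction_repeat, fraction_self, family): one host
#'   transcript per row, planted so that the merged repeat covers
#'   \code{fraction_self} of the transcript's exonic bases and the transcript
#'   covers \code{fraction_repeat} of the repeat's bases.
#' @param motifs List of \linkS4class{MotifModel} objects available for
#'   planting (default \code{\link{defaultMotifModels}()}).
#' @param plantNFlank Plant an N run 5 bp upstream of the first
#'   expressed-transposon host (default FALSE).
#' @return A list: \code{repeats} (GRanges with \code{family}),
#'   \code{motifs}, \code{genome} (edited), \code{truth} (with
#'   \code{teLabels}, \code{motifHosts}, \code{nFlanked} filled in).
#' @export
plantRepeatsAndMotifs <- function(config, genome, models, truth,
        tePlan = data.frame(
            fraction_repeat = c(0.95, 0.95, 0.50),
            fraction_self = c(0.95, 0.50, 0.95),
            family = c("unclassified SINE", "LINE/L2", "DNA/TcMar"),
            stringsAsFactors = FALSE),
        motifs = defaultMotifModels(),
        plantNFlank = FALSE) {
    set.seed(config@seed + 4L)
    if (nrow(tePlan) && (any(tePlan$fraction_repeat <= 0) ||
        any(tePlan$fraction_repeat > 1) || any(tePlan$fraction_self <= 0) ||
        any(tePlan$fraction_self > 1)))
        stop("overlap fractions must lie in (0, 1]")
    chars <- as.list(as.character(genome))
    spans <- txSpans(models)
    # hosts must be single-exon so exonic bases equal the genomic span
    pool <- truth$fillerTx[lengths(exonsByTx(models)[truth$fillerTx]) == 1L]
    needTe <- nrow(tePlan)
    needMotif <- if (nrow(config@motifPlant)) sum(config@motifPlant$count)
                 else 0L
    if (length(pool) < needTe + needMotif)
        stop("not enough single-isoform host transcripts: need ",
             needTe + needMotif, ", have ", length(pool))
    teHosts <- pool[seq_len(needTe)]
    motifPool <- pool[-seq_len(needTe)]

    repGr <- GRanges(); teLabels <- character()
    for (i in seq_len(needTe)) {
        sp <- spans[teHosts[i]]
        n <- width(sp)
        cov <- round(tePlan$fraction_self[i] * n)
        rlen <- round(cov / tePlan$fraction_repeat[i])
        rstart <- start(sp) + (n - cov)
        r <- GRanges(as.character(seqnames(sp)),
                     IRanges(rstart, rstart + rlen - 1L))
        r$family <- tePlan$family[i]
        r$class <- sub("/.*$", "", tePlan$family[i])
        repGr <- c(repGr, r)
        lab <- if (tePlan$fraction_repeat[i] > 0.9 &&
                   tePlan$fraction_self[i] > 0.9) "expressed_transposon"
               else if (tePlan$fraction_repeat[i] > 0.9) "te_associated"
               else "none"
        teLabels[teHosts[i]] <- lab
    }
    # background repeats in unoccupied scaffold tails
    if (nrow(config@repeatPlant)) {
        for (i in seq_len(nrow(config@repeatPlant))) {
            row <- config@repeatPlant[i, ]
            for (k in seq_len(row$count)) {
                scf <- sample(names(genome), 1L)
                lo <- truth$cursors[[scf]] + 2000L
                hi <- config@scaffoldLength - row$length - 10L
                if (lo >= hi) next
                s <- rint(lo, hi)
                r <- GRanges(scf, IRanges(s, s + row$length - 1L))
                r$family <- row$family
                r$class <- sub("/.*$", "", row$family)
                repGr <- c(repGr, r)
            }
        }
    }
    if (plantNFlank && any(teLabels == "expressed_transposon")) {
        host <- names(teLabels)[teLabels == "expressed_transposon"][1]
        sp <- spans[host]
        chars <- plantString(chars, as.character(seqnames(sp)),
                             start(sp) - 7L, "NNN")
        truth$nFlanked <- host
    }
    # motif plantings
    motifHosts <- list()
    if (needMotif) {
        byName <- setNames(motifs, vapply(motifs, function(m) m@motifId,
                                          character(1)))
        for (i in seq_len(nrow(config@motifPlant))) {
            row <- config@motifPlant[i, ]
            ids <- strsplit(row$motif_id, "+", fixed = TRUE)[[1]]
            for (k in seq_len(row$count)) {
                if (!length(motifPool)) stop("motif host pool exhausted")
                host <- motifPool[1]; motifPool <- motifPool[-1]
                sp <- spans[host]
                minusStrand <- as.character(strand(sp)) == "-"
                # plant tighter-constrained motifs first, then continue
                # downstream so co-planted motifs never overwrite each other
                ids <- ids[order(vapply(ids, function(id)
                    byName[[id]]@maxStart, integer(1)))]
                cursor <- NA_integer_
                for (id in ids) {
                    m <- byName[[id]]
                    if (is.null(m)) stop("unknown motif id: ", id)
                    cons <- motifConsensus(m)
                    off <- if (is.na(cursor))
                        rint(row$offset_min, row$offset_max)
                    else cursor + rint(2L, 6L)
                    if (off >= m@maxStart)
                        stop("motif ", id, " cannot be planted before its ",
                             "positional constraint (offset ", off, ")")
                    cursor <- off + nchar(cons)
                    at <- if (minusStrand)
                        end(sp) - (off - 1L) - nchar(cons) + 1L
                    else start(sp) + off - 1L
                    chars <- plantString(chars, as.character(seqnames(sp)),
                                         at, cons, minus = minusStrand)
                }
                motifHosts[[host]] <- sort(ids)
            }
        }
    }
    genomeOut <- Biostrings::DNAStringSet(unlist(chars))
    names(genomeOut) <- names(genome)
    truth$teLabels <- teLabels
    truth$motifHosts <- motifHosts
    list(repeats = sort(repGr), motifs = motifs, genome = genomeOut,
         truth = truth)
}

#' Run the whole generator
#'
#' Convenience wrapper: genome, gene models, repeats/motifs, and the
#' time-series TPM table, all from one seed.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param ... Passed to \code{\link{plantRepeatsAndMotifs}}.
#' @return A list with \code{genome}, \code{models}, \code{repeats},
#'   \code{motifs}, \code{tpm}, \code{psiTrajectory}, \code{truth}.
#' @export
simulateTranscriptome <- function(config, ...) {
    genome <- simulateGenome(config)
    gm <- simulateGeneModels(config, genome)
    pl <- plantRepeatsAndMotifs(config, gm$genome, gm$models, gm$truth, ...)
    expr <- simulateExpression(config, pl$truth)
    list(genome = pl$genome, models = gm$models, repeats = pl$repeats,
         motifs = pl$motifs, tpm = expr$tpm,
         psiTrajectory = expr$psiTrajectory, truth = pl$truth)
}

#' Write a simulated dataset to disk
#'
#' FASTA genome, GTF annotation, BED6 repeats, TSV TPM matrix, TSV
#' ground-truth event table and a JSON config echo.
#'
#' @param sim Output of \code{\link{simulateTranscriptome}}.
#' @param dir Output directory (created if missing).
#' @param config The \linkS4class{SimulationConfig} used.
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir, config) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeGenome(sim$genome, file.path(dir, "genome.fa"))
    writeGtf(sim$models, file.path(dir, "annotation.gtf"))
    writeRepeats(sim$repeats, file.path(dir, "repeats.bed"))
    writeTpm(sim$tpm, file.path(dir, "tpm.tsv"))
    utils::write.table(sim$truth$events, file.path(dir, "truth_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- list(seed = config@seed, nScaffolds = config@nScaffolds,
                scaffoldLength = config@scaffoldLength,
                nGenes = config@nGenes, eventMix = as.list(config@eventMix),
                nSamples = config@nSamples,
                activationIndex = config@activationIndex,
                plantedDeltaPsi = config@plantedDeltaPsi,
                nOver = config@nOver, noiseSd = config@noiseSd,
                baseTpm = config@baseTpm)
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(dir)
}
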