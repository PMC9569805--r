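---
title: "Methods: splicing dynamics at the zygotic genome activation transition"
author: "SpliceDynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splicing dynamics at the ZGA transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpliceDynamics)
```

# The analysis

SpliceDynamics analyses how alternative splicing changes across an
embryonic time series, with a focus on intron retention around zygotic
genome activation (ZGA) — the point, between the late cleavage stages and
the dome stage in fish embryos, at which the zygotic transcriptome takes
over from the maternal one. The inputs are an exon-level transcript
annotation (with per-transcript long-read support flags), transcript TPM
estimates across ordered samples, a repeat-element annotation, and binary
coding-potential calls from two predictors. All quantification is at the
transcript-model level: no read alignment or assembly happens here, and
TPM is consumed, never computed.

## Transcript curation

Assembled transcriptomes carry three well-known artifact classes that the
curation stage removes, in this order:

1. **Low expression.** A transcript is kept iff its TPM reaches the floor
   (default 1 TPM) in at least one sample. We interpret the floor against
   the per-transcript *maximum* across samples rather than per-sample or
   mean values: developmental series contain sharply stage-restricted
   transcripts (activation-specific transposons being the extreme case)
   that a per-sample rule would delete; `mode = "mean"`/`"all"` are
   available for sensitivity analyses.
2. **Fragmentation at scaffold edges.** In a fragmented assembly a
   transcript that runs off a scaffold edge is easily mistaken for a novel
   single- or few-exon gene. A transcript closer to either scaffold edge
   than a threshold, and not corroborated by long-read data, is removed.
   The threshold defaults to the 0.95 nearest-rank (type-1) quantile of
   all intron lengths pooled over transcripts — the rationale being that a
   transcript this close to an edge could have lost an entire typical
   intron-plus-exon beyond the boundary. Nearest-rank is used so the
   threshold is always an observed integer length.
3. **Unspliced precursors.** A single-exon transcript inside a gene that
   also has multi-exon isoforms exactly matches the unspliced precursor of
   those isoforms; such singletons are removed. Genes consisting only of
   single-exon transcripts are untouched — there the single exon is the
   gene.

Coding classification is a consensus of two external predictors: both
noncoding → lncRNA, both coding → mRNA, discordant → TUCP (transcript of
uncertain coding potential). A gene whose transcripts all share one class
inherits it; otherwise it is "misc".

## Event detection

The seven local event types — alternative 3′/5′ splice site (A3/A5),
alternative first/last exon (AF/AL), mutually exclusive exons (MX),
retained intron (RI) and skipped exon (SE) — are enumerated by exhaustive
pairwise comparison of a gene's isoforms in junction (intron) algebra and
deduplicated by their genomic coordinate signature, so the same local
event seen in several isoform pairs is counted once. Only simple binary
events are emitted; overlapping events are reported separately rather
than merged into complexes.

The discriminating rules are worth stating precisely, because A5/A3 and
AF/AL share the "two junctions with one common boundary" pattern:

* shared boundary + **overlapping** flanking exons → A5 or A3 (by which
  side varies, resolved through the strand);
* shared boundary + **disjoint terminal** flanking exons → AF or AL.

Each event carries two form signatures and the transcript sets F1/F2
compatible with them (a transcript joins a form iff its junction chain
contains the form's full signature; for the RI retaining form, iff an
exon covers the intron). Form-1 orientation is fixed per type so that Ψ
is interpretable: RI = the intron-retaining form; SE = inclusion;
A5/A3 = the longer-exon (proximal splice site) form; MX = the 5′-most
exon; AF/AL = the distal (outermost) terminal exon. Only the RI
orientation is biologically canonical; the others follow the common
event-catalog convention and are recorded in the event metadata.

When the annotation mixes technologies, `smrtOnly = TRUE` restricts
detection to long-read-supported transcripts, which is the setting used
for the splicing analysis proper.

## Ψ and its dynamics

For one event, Ψ = ΣF1 TPM / ΣF1∪F2 TPM, undefined unless the total
exceeds the floor (default 1 TPM). Undefined Ψ propagates as missing —
never as 0, because Ψ = 0 is the meaningful "all form 2" state.

Adjacent time points are compared per event type with a two-sided
Wilcoxon signed-rank test over events defined at both samples. Ψ pairs
tie exactly rather often (both samples can give identical ratios), so the
default zero policy is Pratt's: zeros stay in the ranking of |d| and are
dropped from the signs, keeping n honest; the classical drop-zeros policy
is available (`zeroMethod = "wilcoxon"`). The exact distribution (base
`psignrank`) is used when there are no ties and no zeros and n ≤ 50;
otherwise a normal approximation with tie and zero corrections, without
continuity correction. Tissue panels are compared pairwise after
averaging each tissue's replicate columns. Raw p-values are the primary
output (mirroring how such scans are usually reported); a
Benjamini–Hochberg column is emitted alongside.

An RI event is "**over**" when its Ψ difference across the designated
activation transition exceeds 0.07 (strict), i.e. proportionally more of
its expression moves onto the intron-retaining form after activation;
otherwise "normal". The threshold applies to RI by default and to any
type by argument.

## Intron features

Alternative introns are the retained introns of classified RI events;
constitutive introns occur in every isoform of their gene and are engaged
in no event. Both sets are crossed with the host gene's over/normal
status (a gene with at least one over RI event counts as over). We read
"constitutive introns of over transcripts" at the gene level, which is
the interpretation that keeps the four categories disjoint.

Features per intron: length; GC content (N excluded from the
denominator); position of the 5′ end relative to the TSS, scaled by the
gene's longest transcript span; donor and acceptor strengths; and a
branch-point score. Splice-site strength is a first-order
(independent-position) log-odds model — a position frequency matrix with
pseudocount 1, scored in bits against the window-wide background — trained
on the input's own constitutive sites. Windows are 3 exonic + 6 intronic
bases for donors and 20 intronic + 3 exonic for acceptors. Because the
scores are only ever used comparatively (alternative vs constitutive,
over vs normal), a self-trained first-order model suffices; no external
score tables are shipped. The branch point is scanned with a 7-mer
NNNYNAN PWM (position 4 pyrimidine-weighted at 0.45/0.45, position 6
adenine-dominant at 0.85) over a window whose 3′ edge sits 18–44 bp
upstream of the 3′ splice site — the region where branch points
concentrate; both bounds are arguments. Category contrasts use two-sided
Mann–Whitney U tests with the direction of the median difference.

## Transposon catalog and motif scans

A transcript is an **expressed transposon** when the merged repeat
intervals that touch it cover more than 90% of its exonic bases *and* the
transcript covers more than 90% of those repeats' bases; repeat-side
coverage above 90% alone makes it **TE-associated**. Thresholds are
strict, and the transcript-side denominator is exonic (spliced) bases by
default with the genomic span behind a switch — the classified objects
are transcripts, but the ambiguity is real, so both are implemented.
Transposons with any N within 20 bp of their span are deleted (assembly
gaps next to a call make the overlap fractions unreliable). Family
composition tables render percentages half-up to two decimals, the
convention of printed composition tables.

Motif scans are FIMO-like: summed log2((p + 0.01)/0.25) per position on
the transcript *sense* sequence (the positional constraint refers to the
transcript 5′ head, which is strand-defined), N-containing windows
skipped, a hit requiring both the score threshold (default 60% of the
consensus score — no external p-value calibration is assumed) and a best
start below the motif's positional bound (50 for motif 1, 40 for
motif 5). The shipped PWMs are synthetic stand-ins with the right widths
and constraints; real matrices can be supplied as `MotifModel` objects.
Co-occurrence grouping (both / only motif 1 / only motif 5 / none) is
plain set logic.

## PCA contributions

Expression is log2(TPM+1)-transformed and mean-centered, not unit-scaled
(the `prcomp` default; scaling would let near-constant transcripts
dominate), with samples as observations. Contribution of transcript t to
PC k is 100·loading(t,k)²/Σt loading(t,k)², summing to 100 per PC and
invariant to sign flips. Each PC is oriented so its largest-|loading|
transcript is positive, which makes outputs reproducible across
linear-algebra backends. A transcript is PC-k-related when k is its
argmax-contribution PC among those considered (ties break to the lowest
index), so the PC-related sets partition the transcripts.

# The synthetic-data generator

The generator is first-class, tested code: it is how every stage is
validated without external data. A `SimulationConfig` fixes a seed and the
study conditions; a fixed seed gives byte-identical outputs.

**What it emulates.** Multi-scaffold genomes of uniform random DNA; one
gene per planted event with exactly two isoforms differing only in that
event's coordinates (non-RI templates get one extra shared terminal exon
so every gene also contributes a constitutive intron); single-isoform
filler genes; canonical GT..AG dinucleotides plus degenerate
donor/acceptor/branch-point consensus written at every annotated intron,
so self-trained site models have signal; an ordered 19-sample series
labelled T2..T20 with the activation transition between columns 5 and 6
(T6→T7, mirroring the 256-cell → dome step); flat per-event Ψ drawn from
U(0.25, 0.55) with a planted step (+0.2 by default) at the transition for
designated "over" RI events; multiplicative log-normal TPM noise (sd 0.05
by default on the log scale — a mid-range value for replicate-level
abundance variability; 0 gives exact recovery); a per-event total of
20 TPM so events sit clearly above the definedness floor unless
deliberately planted low; repeats written over designated single-exon
hosts at controlled overlap fractions (0.95/0.95, 0.95/0.50, 0.50/0.95
by default, one per classifier outcome); and motif consensus planted at
constrained offsets, with co-planted motifs laid out sequentially so they
never overwrite each other.

**What it does not emulate.** Read-level noise (TPM is perturbed
directly, so estimation error structure — length bias, mapping ambiguity,
isoform deconvolution error — is absent); nested or combined splicing
events; genes with more than two event-bearing isoforms; realistic repeat
sequence content (repeat intervals have labels and coordinates, not SINE
biology); intron/exon length distributions beyond simple uniform ranges;
GC heterogeneity along the genome. Passing tests therefore demonstrate
the correctness of the algebra and the statistics under the stated noise
model, not robustness to quantification artifacts in real data.

**Problem sizes.** The test suite exercises the detector against planted
truth on 500 random genes across all seven types, and the Ψ-dynamics
recovery on 1000 RI events (200 over + 800 null, noise sd 0.05), sizes
chosen to hold Monte-Carlo error on recovery rates near or below a
percent while keeping the default suite around two minutes.

# Numerical and design choices

* Coordinates are 1-based closed (the IRanges convention) everywhere
  inside the package; GTF (1-based closed) and BED (0-based half-open)
  are converted at the I/O boundary by rtracklayer. One internal
  convention, conversions only at the edges.
* FASTA input is uppercased (soft-masking is not needed downstream) but N
  is preserved — the N-flank rule depends on it.
* The `smrt_supported` flag is carried as a GTF attribute and defaults to
  FALSE when absent; it is an input property, never recomputed.
* Quantiles are nearest-rank (type 1) so thresholds are observed values.
* The >90% rules and the >0.07 rule are strict inequalities, following
  their "more than" phrasing.
* Signed-rank p-values: exact only without ties/zeros (where the exact
  null is valid), otherwise the tie/zero-corrected normal approximation;
  no continuity correction by default so large-n values agree with the
  uncorrected reference to numerical precision.
* Event ids are `gene;type;signature` with signatures in genomic
  coordinates, so ids are stable across runs, orderings and relabelings.
* Degenerate inputs: empty F-sets give undefined Ψ; all-zero paired
  differences give p = 1; an all-N sequence is an error for GC content;
  introns too short for the branch-point window record NA rather than a
  score.

# Limitations

* Ψ is computed from transcript TPM, inheriting whatever isoform
  quantification error the upstream estimator had; no variance modeling
  across replicates is attempted (the time series has one sample per
  point).
* The splice-site model is first-order; dependencies between positions
  (which full maximum-entropy models capture) are ignored. Scores are
  comparable within a dataset, not across datasets.
* The over/normal threshold is a fixed effect-size cut, not a test; at
  0.07 with realistic noise the false-positive rate is small but not
  zero, and the suite quantifies it (≤10% at the planted conditions).
* Event composition ratios per stage depend on the definedness filter,
  so they are validated only against synthetic truth.

```{r session}
sessionInfo()
```
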