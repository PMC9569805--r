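# SpliceDynamics

Transcriptome-dynamics analysis for developmental time series, centered on
alternative splicing at zygotic genome activation (ZGA). The package was
built for the kind of study design used in non-model fish embryogenesis:
a curated transcript annotation (short-read assembly corroborated by
long-read/SMRT support flags), transcript-level TPM estimates over an
ordered series of embryonic time points plus a panel of juvenile tissues,
a repeat-element annotation, and coding-potential calls from two external
predictors.

It is a library-style R package in the Bioconductor idiom: transcript
models live in a `GRangesList`-backed S4 container, Ψ values in a
`SummarizedExperiment` subclass, and standard formats go through
`rtracklayer`/`Biostrings`.

## What it computes

* **Annotation curation** — an expression floor (max TPM ≥ 1 across
  samples), the fragmented-transcript rule (distance to the scaffold edge
  below the 95% pooled intron-length quantile and no long-read support),
  the precursor rule (single-exon isoforms inside multi-exon genes), and
  the two-predictor coding consensus (both noncoding → lncRNA, both coding
  → mRNA, discordant → TUCP; mixed-class genes → "misc").
* **Transposon catalog** — reciprocal-overlap classification against
  repeat intervals (repeat and transcript each covered >90% → expressed
  transposon; repeat >90% only → TE-associated), an N-flank deletion rule
  (any N within 20 bp of the span), family composition tables, and
  FIMO-style PWM scans with positional constraints on the transcript 5'
  region (motif 1 start < 50, motif 5 start < 40).
* **Alternative-splicing events** — the seven local event types (A3, A5,
  AF, AL, MX, RI, SE) enumerated from pairwise isoform comparison in
  junction algebra and deduplicated by coordinate signature, with the two
  splicing forms and their compatible transcript sets F1/F2. For RI, form
  1 is the intron-retaining form.
* **Ψ dynamics** — percent spliced-in per event and sample,

  Ψ = Σ<sub>k∈F1</sub> TPM<sub>k</sub> / Σ<sub>j∈F1∪F2</sub> TPM<sub>j</sub>,

  undefined unless the event's total expression exceeds 1 TPM; two-sided
  Wilcoxon signed-rank tests (Pratt zero policy) across adjacent time
  points and tissue pairs; and classification of RI events as **over**
  (ΔΨ across the activation transition > 0.07) vs **normal**.
* **Intron features** — alternative (RI-retained) vs constitutive introns
  crossed with the over/normal status of their host genes; length, GC,
  position relative to the TSS, donor/acceptor strength from
  independent-position log-odds models trained on the constitutive sites,
  and branch-point (NNNYNAN) scores; Mann–Whitney U contrasts between
  categories.
* **PCA contributions** — `prcomp` on log2(TPM+1), per-transcript variable
  contributions (100·loading²/Σloading²), and PC-related transcript sets
  by argmax contribution.
* **Synthetic data** — a fully seeded generator that plants gene models
  for all seven event types (with GT..AG splice sites and degenerate
  donor/acceptor/branch-point signal written into the genome), Ψ
  trajectories with a step at a designated activation sample, repeats at
  controlled overlap fractions, and motifs at constrained offsets — so
  every stage is testable against known ground truth.

## Worked example

```r
library(SpliceDynamics)

cfg <- simulationConfig(seed = 1, eventMix = c(RI = 60L, SE = 10L),
                        nGenes = 80L, nScaffolds = 2L,
                        scaffoldLength = 600000L, nOver = 30L,
                        plantedDeltaPsi = 0.2, noiseSd = 0.05)
res <- runPipeline(cfg)

res$events
#> SpliceEventSet with 70 events
#>   A3=0 A5=0 AF=0 AL=0 MX=0 RI=60 SE=10

adj <- res$adjacent[res$adjacent$type == "RI", ]
adj[which.min(adj$p), c("sample_a", "sample_b", "type", "n", "p")]
#>  sample_a sample_b type  n            p
#>        T6       T7   RI 60 4.956869e-07

sum(res$overNormal$status == "over")
#> [1] 30
```

The generator planted a +0.2 Ψ step in 30 of the 60 RI events at the
T6→T7 column (the activation transition); the signed-rank scan over all
18 adjacent pairs finds its minimum p-value at exactly that pair, and the
0.07 ΔΨ rule recovers the 30 planted "over" events. `res$report` records
per-stage counts, thresholds, wall times and the seed.

## Vignette

`vignettes/splicing-dynamics.Rmd` describes the models, parameter choices,
simulator design and its limitations.
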