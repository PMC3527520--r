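---
title: "Positional classification and comparative analysis of long ncRNAs"
author: "lncclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional classification and comparative analysis of long ncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncclass)
```

## The problem

Large catalogs of candidate long non-coding RNAs (lncRNAs) — reconstructed
from ESTs, RNA-seq assemblies or chromatin signatures — are only useful once
each transcript is placed relative to the protein-coding gene models of its
genome. `lncclass` implements that placement and the comparative analyses
that are usually built on it:

1. **Coding screen** — remove candidates that look protein-coding, by local
   alignment against known transcripts and by a six-frame ORF scan.
2. **Positional classification** — label each candidate *intergenic*,
   *intronic* or *overlapped* with respect to gene models, then refine
   near-gene intergenic transcripts into *UTR-related* RNAs.
3. **Neighbor association** — assign every intergenic transcript its closest
   protein-coding gene, the gene end it faces (5′ or 3′), and its
   sense/antisense orientation, inferring transcript strand from splice-site
   dinucleotides where the input leaves it unknown.
4. **Conservation** — length-normalized per-interval means over a per-base
   conservation track, compared against length-matched random intervals from
   un-transcribed regions.
5. **Overlap accounting** — per-category overlap counts against external
   lncRNA catalogs, with percentages over the intergenic total and exclusive
   Venn regions.
6. **GO over-representation** — EASE-score enrichment of neighbor-gene
   lists, and the intersection of significant terms across species.
7. **Cross-species conservation** — neighbor genes of gene-proximate
   intergenic ncRNAs compared across species by symbol and by sequence
   similarity.

A seeded synthetic-data generator produces every input the pipeline consumes
(genome, gene models, planted ncRNAs, conservation track, GO annotation,
species trios), so the whole chain is exercised and tested at desk scale
without any download.

## Coordinate convention

Internally every interval is **0-based half-open** `[start, end)`. The
conversion from 1-based inclusive formats (GFF3, wiggle) and back happens
only inside the parse/write functions in `R/genome_io.R`; every other module
assumes the internal convention. This removes a classic source of
off-by-one errors when UCSC-style (0-based) and GFF-style (1-based) inputs
are mixed.

## The classification model

Classification is **strand-agnostic** and purely positional:

* *overlapped* — at least one transcript block shares ≥ 1 bp with an exon of
  any gene. No upper bound is applied: a transcript spanning a whole gene is
  also overlapped.
* *intronic* — not overlapped, and the transcript span lies wholly inside
  some gene's span. Containment in the gene body (not in a single intron) is
  the criterion; a transcript threading several introns of a gene without
  touching an exon is still intronic. When nested genes both contain the
  transcript, the containing gene with the smaller start is recorded.
* *intergenic* — everything else.
* *UTR-related* — an intergenic transcript within 1 kb (`utr_distance_bp`)
  of a gene span, or whose best local alignment against a supplied UTR
  sequence exceeds 90% identity and 50% coverage (both configurable; the
  similarity thresholds are package defaults, chosen because "high
  similarity to an annotated UTR" needs an operational definition). The
  remaining intergenic transcripts are the *stringent* intergenic set used
  by all downstream neighbor analyses.

Neighbor distance is the gap between the transcript span and the gene span
(0 when abutting), not a midpoint distance. Equidistant genes are resolved
deterministically by smaller start, then lexicographic gene id. The facing
gene end is strand-aware: a transcript on the side of the gene's
transcription start faces its 5′ end. Orientation is *sense* when transcript
and neighbor strands agree. For spliced transcripts with unknown strand, the
terminal dinucleotides of each intron vote — `GT..AG` for plus, `CT..AC`
(its reverse complement) for minus — and only a unanimous vote assigns a
strand; conflicts and non-canonical motifs leave it unknown. Introns shorter
than 4 bp abstain.

Gene-proximate selection takes stringent intergenic transcripts with
neighbor distance ≤ 5 kb (`proximate_distance_bp`), partitioned by gene end.
Both distance cutoffs (1 kb, 5 kb) are the conventional flanking-region
choices for this analysis and are exposed in `classify_config()`.

## The coding screen

The similarity screen is an exact Smith–Waterman local alignment
(`Biostrings::pairwiseAlignment`) with match +1, mismatch −1 and affine gaps
(a gap of length L costs 2 + (L − 1)); `N` never counts as a match. Identity
is the percent of matching alignment columns; coverage is the percent of the
*query* inside the aligned region. A candidate is removed when some
reference exceeds both thresholds (defaults 90/90), or when its longest ORF
over all six frames reaches 100 amino acids. The ORF threshold is the
conventional lncRNA cutoff — the upstream pipelines this mirrors say only
"long ORFs" — and is configurable. An ORF is `ATG … stop` in frame; the
reported length counts codons from the initial Met up to, and excluding, the
stop. Exact dynamic programming is affordable here because reference sets at
desk scale are small; a BLAST-style heuristic would add a dependency without
changing the contract.

## Conservation scoring

The per-interval statistic is the mean per-base score over **covered exonic
bases**: uncovered bases are excluded from both numerator and denominator,
because scoring missing alignment data as zero would conflate "no
information" with "neutral". Each interval also reports its covered
fraction, and `compare_conservation()` drops intervals below 20% coverage
(configurable) before ranking groups. Controls are drawn from the complement
of all supplied transcribed intervals: gaps are chosen with probability
proportional to width among gaps at least `min_len` long, lengths are
uniform on [500, 15000] bp truncated to the enclosing gap, and (when
sequence is available) intervals with more than 50% `N` are rejected and
redrawn. The sampler is fully deterministic for a fixed seed. Group
comparison reports ECDFs (the cumulative-frequency curves usually plotted
for this analysis) and, as a formal counterpart of "more conserved than",
one-sided Mann–Whitney p-values per group pair — an extension beyond the
plotted curves, labeled as such.

## EASE-score enrichment

The enrichment statistic is the EASE score: a one-sided Fisher exact
(hypergeometric tail) p-value computed after removing one gene from the
list-hit cell, `p = P(X ≥ k − 1)` with `X ~ Hypergeom(N, K, n)`; `k = 0`
gives `p = 1`. The decrement makes the score conservative relative to the
classical Fisher test (a property the test suite asserts over random
tables). A term is flagged significant when its list count is at least 6
("gene count > 5") and its raw EASE p is below 0.05; no multiple-testing
correction is applied to the flags because the thresholding convention this
reproduces works on raw EASE p-values, but a Benjamini–Hochberg column is
emitted for users who want rigor over fidelity. The background universe
defaults to all genes of the supplied annotation and is always explicit in
the output.

## Cross-species conservation

Symbol comparison is an exact, case-folded intersection across species — no
ortholog database is consulted. Sequence conservation uses the same local
aligner as the coding screen: a neighbor gene is conserved when its best
alignment in *every* other species exceeds 60% identity and 60% coverage,
with coverage measured on the query sequence (which side carries the
coverage requirement is a genuinely open choice; the query side is
implemented and configurable callers can swap query and target sets).
One-directional best hits are used rather than reciprocal best hits, the
weaker and therefore more inclusive reading. Accounting reports conserved
counts per gene end and their sum.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed and are not tuned per test:

| parameter | default | what it emulates |
|---|---|---|
| class proportions | 0.40 / 0.30 / 0.15 / 0.15 | an intergenic + intronic dominated class mix |
| `p_prox` | 0.6 | enrichment of intergenic ncRNAs within 5 kb of gene ends |
| `sense_skew_3p` | 0.7 | sense-strand excess near 3′ gene ends |
| `sense_skew_5p` | 0.45 | mild antisense lean at 5′ ends |
| class score means | coding 3.0 > overlapped 2.0 > UTR-related 1.5 > intergenic 1.0 > intronic 0.5 > background 0.0 | the qualitative conservation ordering of transcript classes |
| `score_sd`, uncovered fraction | 0.5, 0.1 | per-base noise and missing track coverage |
| `homolog_fraction`, identity | 0.3, 0.85 | the minority of neighbor genes conserved across a species trio |
| GO planted fold | 5 | one over-represented term among neighbor genes |

The class means are generator conventions chosen to reproduce the
*ordering*, not any particular score scale. Planted placements keep safety
margins around every decision boundary (UTR-related gaps ≤ 950 bp, proximate
intergenic gaps in [1050, 4950], distal placements > 5100 bp from every
gene), so label recovery is expected to be exact up to rare collisions;
boundary-abutting behavior is tested separately with hand-built fixtures.
One subtlety worth recording: the proximate-vs-distal coin is tossed once
per transcript *before* placement retries, because re-drawing it on a failed
placement attempt would bias the realized proximate fraction toward
whichever mode is easier to place.

Spliced synthetic transcripts get canonical splice dinucleotides written
into the genome sequence so strand inference has signal; a
`noncanonical_fraction` knob leaves motifs random to exercise the
unknown-strand path, and `unknown_strand_fraction` blanks declared strands
while the ground truth retains them.

What the generator does **not** emulate: repeat content, sequencing error,
chimeric reconstructions, expression levels, alternative isoforms, and the
gene-model revision drift that real catalogs suffer from. Passing tests
therefore demonstrate algorithmic correctness and statistical calibration
under clean conditions, not robustness to dirty annotation.

## Numerical choices

* Percentages are round-half-to-even at 2 decimals throughout. One published
  table value this package's arithmetic cannot reproduce is an intergenic
  overlap percentage printed as 2.36% where the underlying counts
  (105/4,464) give 2.3521 → 2.35 under any standard rounding; the computed
  value is reported, not the printed one.
* Overlapping bedGraph records: the last written record wins, with a
  warning — real track exports contain duplicates, and determinism is
  preserved.
* Overlap between datasets is span-based, strand-agnostic, ≥ 1 bp, the
  ecosystem default for interval intersection; each of our transcripts is
  counted once per external dataset regardless of hit multiplicity.
* Ties everywhere (equidistant neighbors, equal ORF lengths across frames,
  nested containing genes) are broken deterministically and documented at
  the operation.
* All generators and the control sampler restore the caller's RNG state; a
  master seed derives independent per-stage seeds, so each stage is
  reproducible in isolation.

## Problem sizes

The bundled analyses and tests run on two to five chromosomes of 0.2–0.5 Mb
with 8–10 genes per chromosome and 40–2,000 planted ncRNAs — sizes chosen so
a full end-to-end run completes in about a minute on one CPU while leaving
every statistical check enough events (e.g. n = 2,000 for recovering the
proximity bias within three binomial standard deviations). Larger genomes
are limited mainly by the per-base score track, which is held as run-length
vectors per chromosome.

## Known limitations

* Translated (protein-space) similarity search is out of scope; the coding
  screen approximates it with nucleotide alignment against reference
  transcripts.
* GO term ancestry (true-path propagation) is applied only if a term graph
  is supplied; the exact category sets of web-based enrichment services are
  not reproducible offline, so the background is always stated explicitly.
* bigWig input is out of scope; tracks are consumed as text bedGraph or
  wiggle. A binary reader could be added behind `parse_score_track()`
  without changing any contract.
* The classifier assigns one neighbor per transcript; transcripts
  equidistant between two regulatory genes keep only the deterministic
  winner.
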