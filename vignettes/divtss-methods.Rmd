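---
title: "Methods: TSS detection, promoter architecture and the bidirectional screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS detection, promoter architecture and the bidirectional screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divtss)
```

## The problem

Differential RNA-seq (dRNA-seq) distinguishes genuine transcription start
sites (TSS) from RNA-processing sites by comparing two libraries made from
the same RNA: a TEX-treated library, in which the terminator
5'-phosphate-dependent exonuclease degrades processed (5'-monophosphate)
transcripts and spares primary (5'-triphosphate) ones, and an untreated
control (NOTEX). A genuine TSS appears as a sharp pile-up of read 5' ends
that is enriched in the TEX library. A third, fragmented library (FRAG)
provides quasi-uniform coverage over transcript bodies and anchors
transcript-level analyses such as operon inference.

`divtss` implements this analysis for a compact archaeal chromosome:
calling and classifying TSS, characterising the archaeal promoter elements
upstream of them, and screening primary promoters for divergent antisense
transcripts initiated from a *shared TATA element* — the bidirectional
transcription phenomenon in which a single TATA box, bound by the
symmetric TBP, supports initiation on both strands with the two start
sites roughly 50 bp apart.

## Coordinate conventions

External files use their standard conventions (GFF3 and wiggle 1-based
inclusive, BED 0-based half-open; conversions are handled by
`rtracklayer`). Internally everything is 1-based inclusive, the
R/Bioconductor convention, which keeps the package consistent with
`IRanges`/`GenomicRanges` arithmetic.

Offsets relative to a TSS follow the promoter convention: the transcribed
base is +1, the base immediately upstream is −1, and there is no offset 0.
A window −50..+10 therefore has 60 positions, and element annotations such
as "TATA box −30..−23" carry their usual meaning. On circular replicons all
windows wrap the origin, so genes near position 1 are treated like any
other.

## TSS calling

`call_tss()` declares position *p* on strand *s* a candidate when

1. the TEX 5'-end count reaches `min_height` (default 10),
2. the enrichment ratio `tex / (notex + pseudocount)` reaches
   `min_enrichment` (default 2, pseudocount 1), and
3. the TEX count is a local maximum within `cluster_width` bp (default 3);

surviving candidates closer than `cluster_width` merge, keeping the
highest-count position (ties break to the smaller coordinate). This is a
deliberately transparent stand-in for TSSpredator-style callers, whose
published descriptions do not fix their internal scoring: the defining
signal (TEX enrichment of sharp 5' ends) is the same, and every parameter
is an explicit, documented knob rather than the product of an opaque
optimisation. The caller is validated against a literal per-position
brute-force implementation on random tracks, and its parameters were set
from a detection-floor calculation: with negative-binomial TSS heights of
mean 100 and dispersion 0.3, the probability of a planted primary site
falling below `min_height = 10` is below 1%.

## Classification

`classify_tss()` assigns classes relative to every annotated gene:

* **Primary (P)** — the highest same-strand TSS within `utr_window`
  (default 300 bp) upstream of the gene start, the start itself included
  so leaderless transcripts (5' UTR = 0) are covered; ties go to the TSS
  closest to the start.
* **Secondary (S)** — every other same-strand TSS in that window.
* **Internal (I)** — same-strand TSS strictly inside the gene body
  (excluding the 5' start base, which is P-eligible).
* **Antisense (A)** — opposite-strand TSS within `antisense_flank`
  (default 100 bp) of the gene.

A TSS accumulates every class it earns across genes; dual labels are
biologically meaningful (a divergent pair of close gene starts regularly
produces TSS that are primary for one gene and antisense to its
neighbour). TSS earning no class are orphans and excluded from class
counts. The `antisense_flank` of 100 bp is deliberately narrower than the
300 bp windows used for *plotting* positional distributions: the two serve
different purposes and widening the classifier's flank would inflate
antisense counts.

## Promoter architecture

`extract_windows()` collects TSS-anchored sequences (reverse-complemented
for minus-strand TSS so every window reads 5'→3' into the gene), and
`build_pwm()` turns them into a position frequency matrix with
`(count + pseudocount) / (n + 4·pseudocount)` columns. The expected
architecture is the canonical archaeal promoter: a purine-rich BRE
(`RRAAA`) at −36..−32, the TATA box (`WTTTAAAW`) at −30..−23, an AT-rich
initially melted region at −11..−2, and a pyrimidine/purine initiator at
−1/+1.

Element location uses log-odds scanning of small consensus-derived models
(`consensus_pwm()`, 85% of the probability mass on the consensus set per
column) rather than de-novo motif discovery: MEME-style EM is out of scope
here, and for these short, well-characterised elements a PWM scan with an
explicit search range is reproducible and fully self-contained.
`locate_tata()` reports the offset of the element's *last* conserved base;
per class the expected locations are −23 (primary), −27 (secondary), −22
(internal) and −25 (antisense). Majority-rule IUPAC consensus calling adds
bases per column in decreasing frequency until half of the mass is
covered; note that a genuinely 50/50 column (a `W` position) may
legitimately collapse to whichever single base ended up more frequent in a
finite sample, so consensus agreement is assessed by base-set inclusion
(`A` agrees with `W`).

### The bidirectional BRE–TATA–BRE motif

`scan_bidirectional()` requires, within a −60..+1 window of a primary TSS:
a sense TATA with its 3' end in −30..−20, and a reverse-complement BRE
whose genomic left end lies 1–10 bp downstream of the TATA (i.e. between
the TATA and the primary TSS — on the antisense strand that BRE is 5' of
the shared TATA, exactly where TFB must bind to recruit the polymerase in
the divergent direction). Score thresholds are set to fractions of each
model's maximum (0.6 for TATA, 0.4 for BRE), chosen so that one base
deviating from consensus still passes while two do not; on uniform random
sequence the joint requirement fires in well under 10% of windows. The
implied antisense start is derived from the antisense BRE placement (a BRE
ends 32 bp upstream of its start site), which puts it ~25 bp upstream of
the TATA midpoint; with the canonical geometry this lands 49–53 bp
upstream of the primary TSS. Poly-A/T runs can tie adjacent BRE placements
and shift the implied start by ±1 bp.

## The coverage-based screen

The screen asks, for each head-to-tail primary TSS (restricting to
head-to-tail orientation removes the ambiguity of divergent gene pairs,
whose upstream antisense signal may simply be the neighbour's own primary
transcript): does more than 40% of the antisense-strand TEX signal within
±400 bp fall into the 100 bp immediately upstream? The inequality is
strict, read positions are approximated by 5'-end counts (read-level data
is out of scope; this is documented as a proxy), and the denominator is
antisense-strand signal only — the phrasing "more than 40% of the reads
from −400 to +400" is ambiguous about strandedness, so the weaker
both-strands denominator is exposed as `denominator = "both"`. Candidates
are paired with the nearest upstream opposite-strand antisense TSS within
100 bp; the spacing histogram's mode is the headline statistic, expected
at the planted spacing (49 bp by default).

`meta_profile()` underlies the orientation-split coverage figures: ±400 bp
windows in 10 bp bins (the no-zero offset convention makes the window
exactly 800 positions, so bins tile it without a split centre), each
site's window scaled to unit total mass over both strands before
averaging, so a handful of highly expressed sites cannot dominate the
mean profile.

## Positional analyses and transcription units

`scaled_position()` implements the three-zone metagene scale (fixed
flanks, length-scaled body, strand-aware), used both for TSS-versus-gene
plots (300 bp flanks) and for antisense TSS around IS elements (100 bp
flanks, with the fraction of IS elements carrying an antisense start over
the first 20% of the transposase ORF as the summary statistic).

`infer_units()` merges co-directional consecutive genes into one
transcription unit when the intergenic gap carries continuous FRAG
coverage (no run below `min_body_coverage = 3` longer than
`gap_threshold = 25` bp) and the downstream gene lacks its own primary
TSS. This is a stated simplification of pipeline-style operon callers:
it is validated against planted operons on synthetic data only, and no
claim is made that it reproduces any published operon catalogue.

## The synthetic-data generator

Every downstream stage is validated against `generate_genome()` /
`simulate_coverage()`, which plant a complete, machine-readable truth.
The generator emulates:

* a circular, AT-rich (40.75% GC) chromosome with genes packed
  sequentially on both strands; strand choice is a Markov chain whose
  flip probability equals the head-to-head fraction (default 0.47, the
  empirical orientation split of a dense archaeal genome);
* divergent ("head-to-head") intergenic gaps drawn around a 117 bp
  median — the tight spacing that makes divergent promoter signals
  overlap in real data;
* 5' UTRs from a log-normal with median 13 nt and a long right tail
  (mean ≈ 49 nt), truncated at 150 nt for packing, including leaderless
  starts;
* full promoters (BRE, TATA at the class-specific offset, melted region,
  initiator) for every transcription-unit leader, plus secondary and
  internal TSS; planting fidelity 0.95 per base;
* bidirectional promoters on a configurable fraction (default 0.2) of
  head-to-tail leaders: a divergent partner at exactly
  `ptss_atss_spacing` (default 49) bp with a reverse-strand BRE — the
  TATA is *shared*, which is possible because `WTTTAAAW` is its own
  reverse complement;
* operons (a gene joins its co-directional neighbour's unit with
  probability 0.25, losing its own primary TSS), and IS elements whose
  transposase carries an antisense TSS over the first 20% of its ORF;
* TEX 5'-end counts equal to the planted negative-binomial heights
  (dispersion fixed at 0.3; primary mean 100, internal 0.6×, antisense
  0.8×; secondary heights drawn conditional on — and strictly below —
  their primary's, so the rank order that defines the P/S distinction is
  well-posed in truth), NOTEX attenuated by `tex_enrichment` (default
  10) plus uniform processed ends at 20 per kb of transcript, FRAG
  per-base Poisson coverage over each transcript, and Poisson background
  at 0.02 per base on every track.

Antisense starts in the generator arise from bidirectional promoters and
IS elements, matching the modelled system; standalone antisense promoters
inside ordinary gene bodies are available (`fraction_antisense`) but off
by default.

What the generator does **not** emulate — and hence what green tests do
not show about real data: read-level noise and mapping artefacts,
sequencing-depth variation along the chromosome, RNA secondary structure
and condition-dependent expression, processing hotspots that mimic sharp
5' ends, CRISPR-derived repetitive promoters (a region blacklist is
provided for real data instead), and multi-replicon genomes. Recovery
rates on synthetic data are therefore upper bounds on real-data
performance, not estimates of it.

## Problem sizes and numerical choices

The tests and the acceptance script run three simulation sizes, chosen to
make each statistic well-conditioned while keeping the whole suite fast:
60 genes / 60 kb for detection and classification, 150 genes / 150 kb for
the screen (≈ 13 planted bidirectional pairs), and 250 genes / 250 kb
with 10 IS elements for promoter-architecture recovery (≈ 200 primary
promoters; ≈ 10 standalone antisense exemplars, whose median offset is the
class statistic). Bidirectional partners are excluded from the
antisense-class TATA-offset exemplars because they share their primary's
TATA by construction — sharing, not an independent −25 element, is the
phenomenon.

Degenerate inputs are defined rather than left to chance: an empty wiggle
body is an all-zero track; an antisense fraction with a zero denominator
is 0; a k-mer spectrum comparison with fewer than two shared words (or
zero variance) is flagged degenerate instead of returning `NaN`; an empty
TSS set makes the pipeline summary zero-valued rather than failing. Ties
are broken deterministically everywhere (caller: smaller coordinate;
primary selection: closest to the gene start; TATA placement: most
upstream).

## Known limitations

* The caller's parameters are fixed, not optimised against a reference
  TSS set; reproducing counts from any specific published dataset is not
  promised and would require that dataset's (unpublished) optimiser
  settings.
* The operon rule ignores terminator signals and condition-specific
  units.
* The bidirectional scan models only the canonical BRE/TATA geometry;
  non-canonical divergent promoters are invisible to it.
* "Reads" are 5'-end counts throughout the screen; with real read-level
  data the 40% filter may behave slightly differently.
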