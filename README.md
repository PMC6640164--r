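# divtss

Primary-transcriptome mapping and bidirectional-promoter screening from
differential RNA-seq (dRNA-seq), written for compact archaeal genomes.

## The problem

dRNA-seq compares a TEX-treated library (the terminator
5'-phosphate-dependent exonuclease degrades processed 5'-monophosphate
RNAs, sparing primary 5'-triphosphate transcripts) with an untreated
control, so genuine transcription start sites (TSS) stand out as sharp,
TEX-enriched 5'-end pile-ups. On a densely packed archaeal chromosome this
yields, besides the primary TSS of each gene, a large population of
*antisense* TSS. A striking source of these is **bidirectional
transcription from a shared TATA element**: the TATA box `WTTTAAAW` is its
own reverse complement and TBP binds it symmetrically, so a single
promoter can fire in both directions, producing a divergent antisense
transcript starting ~50 bp upstream of the primary TSS.

`divtss` provides, as an R package plus a numbered analysis workflow:

* **TSS calling** from TEX vs NOTEX 5'-end coverage — a position is a TSS
  when `tex >= min_height`, `tex / (notex + pseudocount) >= min_enrichment`,
  and it is a local maximum within `cluster_width` bp;
* **classification** into primary / secondary / internal / antisense
  (P/S/I/A) relative to annotated genes, with multi-class labels and
  5'-UTR statistics;
* **promoter architecture**: TSS-anchored position weight matrices over
  −50..+10, majority-rule consensus, and per-class location of the TATA
  box (expected 3'-end offsets: P −23, S −27, I −22, A −25), plus a
  scanner for the bidirectional **BRE–TATA–BRE** motif;
* **the screen**: orientation-split metagene profiles (±400 bp, 10 bp
  bins, per-site proportional scaling), the strict 40% antisense-signal
  filter (antisense 5'-end signal in the 100 bp upstream vs ±400 bp),
  pTSS–aTSS spacing distributions and intergene-distance summaries;
* **positional analyses**: length-scaled metagene positions with 300 bp
  flanks, antisense TSS around IS elements (100 bp flanks), and
  transcription-unit inference from primary TSS + fragmented-library
  coverage;
* **assembly comparison**: sixmer spectra and length/GC deltas;
* a **synthetic-data generator** that plants the whole architecture
  (promoters, operons, bidirectional pairs at 49 bp spacing, IS antisense
  TSS, three coverage tracks) with a machine-readable truth table, so
  every stage is validated without external data.

File formats (FASTA, GFF3, wiggle with the negative-minus-strand dialect,
BED, TSV) are read and written through Biostrings/rtracklayer.

## Worked example

The `analysis/` scripts run the whole study on a simulated 150-gene,
150 kb circular chromosome (seed 42) and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_tss.R
Rscript analysis/03_promoters.R
Rscript analysis/04_screen.R
Rscript analysis/05_positions.R
Rscript analysis/06_compare.R
```

Stage 2 calls and classifies TSS and scores them against the planted
truth:

```
<tss_classification> 231 TSS; P:133 S:44 I:45 A:74; 1 orphan
recovery vs planted truth: sensitivity 0.987, precision 1.000, class match 0.991
5'UTR of primary TSS: median 13.0 nt, mean 40.19 nt (n = 133)
```

i.e. essentially every planted start is recovered at ±1 bp, and primary
5' UTRs are short (median 13 nt) with a long tail — transcripts mostly
initiate just upstream of the start codon. Stage 3 recovers the promoter
architecture; the TATA box sits at −30..−23 of the global consensus and
its per-class position shifts exactly as planted:

```
TATA region (-30..-23): ATTTAAAA
  class   n n_hit median_offset
1     P 133   133           -23
2     S  44    44           -27
3     I  45    45           -22
```

Stage 4 is the core screen. Head-to-tail promoters show a sharp antisense
peak ~50 bp upstream of the primary TSS, the 40% filter flags 17% of them,
and the paired antisense starts sit at the shared-TATA spacing:

```
head-to-head (n = 62): antisense maximum in bin starting at -110 bp
head-to-tail (n = 71): antisense maximum in bin starting at -50 bp
screen: 12 / 71 head-to-tail pTSS pass the 40% filter (17%)
vs truth: recall 0.923, false-positive rate 0.0000
modal pTSS-aTSS spacing: 49 bp (n = 33 pairs)
```

Stage 5 maps all six IS elements' antisense TSS onto the start of their
transposase ORFs and reconstructs the planted operons (exact-composition
match 0.985); stage 6 compares the genome with a 1%-mutated copy (sixmer
correlation 0.996) and recomputes the published assembly length delta
(1,889,914 − 1,908,256 = −18,342 bp).

See `vignettes/divtss-methods.Rmd` for the model, parameter rationale and
the generator's scope and limits.

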