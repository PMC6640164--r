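#!/usr/bin/env Rscript
# Stage 5: positional metagene analyses and transcription units.
#
# Maps internal and antisense TSS onto length-scaled gene bodies with
# 300 bp flanks, maps antisense TSS around IS elements (100 bp flanks),
# and infers transcription units from primary TSS plus FRAG coverage,
# scoring them against the planted operons.

library(divtss)

rep <- read_fasta("results/data/genome.fasta", circular = TRUE)[[1]]
ann <- read_gff("results/data/annotation.gff3", rep = rep)
frag <- read_wiggle("results/data/frag_plus.wig",
                    "results/data/frag_minus.wig", rep$length, "FRAG",
                    what = "coverage")
assignments <- read_tsv("results/tss_assignments.tsv")
truth <- read_truth("results/data/truth.tsv")

ia <- assignments[assignments$class %in% c("I", "A"),
                  c("position", "strand", "gene_id", "class")]
sp <- scaled_positions(ia, ann$genes)
write_tsv(sp, "results/positions.tsv")
cat(sprintf("scaled positions: %d internal/antisense TSS mapped (%d upstream, %d body, %d downstream)\n",
            nrow(sp), sum(sp$zone == "upstream"), sum(sp$zone == "body"),
            sum(sp$zone == "downstream")))

atss <- unique(assignments[assignments$class == "A",
                           c("position", "strand")])
isel <- ann$genes[ann$genes$kind == "IS_element", ]
prof <- is_element_profile(atss, isel)
write_tsv(prof, "results/is_profile.tsv")
cat(sprintf("IS elements with an antisense TSS over the first 20%% of the transposase ORF: %.0f%% (n = %d)\n",
            100 * attr(prof, "fraction_orf_start"), nrow(isel)))

ptss <- unique(assignments[assignments$class == "P",
                           c("position", "strand", "gene_id")])
units <- infer_units(ann, ptss, frag)
write_tsv(units, "results/units.tsv")
rec <- unit_recovery(units, truth)
cat(sprintf("transcription units: %d inferred (%d multi-gene); exact match to planted operons %.3f\n",
            nrow(units), sum(units$n_genes > 1), rec$exact_match))
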