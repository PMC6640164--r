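#!/usr/bin/env Rscript
# Stage 2: call TSS from TEX vs NOTEX 5'-end coverage and classify them.
#
# Reads the simulated dataset from results/data/, runs the enrichment-ratio
# caller and the positional classifier, writes the classified TSS (GFF3 +
# TSV) under results/, and scores the calls against the planted truth.

library(divtss)

rep <- read_fasta("results/data/genome.fasta", circular = TRUE)[[1]]
ann <- read_gff("results/data/annotation.gff3", rep = rep)
tex <- read_wiggle("results/data/tex_plus.wig", "results/data/tex_minus.wig",
                   rep$length, "TEX")
notex <- read_wiggle("results/data/notex_plus.wig",
                     "results/data/notex_minus.wig", rep$length, "NOTEX")
truth <- read_truth("results/data/truth.tsv")

called <- call_tss(tex, notex, detection_params(), circular = TRUE)
cls <- classify_tss(called, ann)
print(cls)

write_tss_gff(cls$assignments, rep$name, "results/tss.gff3")
write_tsv(cls$tss, "results/tss_table.tsv")
write_tsv(cls$assignments, "results/tss_assignments.tsv")

rec <- tss_recovery(cls, truth, tolerance = 1L)
cat(sprintf("recovery vs planted truth: sensitivity %.3f, precision %.3f, class match %.3f\n",
            rec$sensitivity, rec$precision, rec$class_match))
utr <- utr_lengths(cls)
cat(sprintf("5'UTR of primary TSS: median %.1f nt, mean %.2f nt (n = %d)\n",
            utr$median, utr$mean, utr$n))
write_tsv(data.frame(metric = c("sensitivity", "precision", "class_match",
                                "utr_median", "utr_mean"),
                     value = c(rec$sensitivity, rec$precision,
                               rec$class_match, utr$median, utr$mean)),
          "results/tss_recovery.tsv")
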