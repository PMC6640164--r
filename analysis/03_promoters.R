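#!/usr/bin/env Rscript
# Stage 3: promoter architecture.
#
# Builds the global -50..+10 position weight matrix over all classified
# TSS, calls the majority-rule consensus (expected architecture: BRE
# RRAAA at -36..-32, TATA WTTTAAAW at -30..-23, AT-rich melted region
# -11..-2, initiator Y/R at -1/+1), locates the TATA box per TSS class,
# and scans every head-to-tail primary promoter region for the
# bidirectional BRE-TATA-BRE motif.

library(divtss)

rep <- read_fasta("results/data/genome.fasta", circular = TRUE)[[1]]
ann <- read_gff("results/data/annotation.gff3", rep = rep)
tss <- read_tsv("results/tss_table.tsv")
assignments <- read_tsv("results/tss_assignments.tsv")

wins <- extract_windows(tss, rep, -50L, 10L)
pwm <- build_pwm(wins, -50L)
write_pwm(pwm, "results/pwm.tsv")
cons <- pwm_consensus(pwm)
offs <- attr(pwm, "offsets")
cat("global promoter consensus (-50..+10):\n", cons, "\n")
cat("TATA region (-30..-23):",
    paste(strsplit(cons, "")[[1]][match(-30:-23, offs)], collapse = ""), "\n")

by_class <- lapply(c(P = "P", S = "S", I = "I", A = "A"), function(cl) {
  sub <- unique(assignments[assignments$class %in% cl,
                            c("position", "strand")])
  extract_windows(sub, rep, -50L, 10L)
})
by_class <- by_class[vapply(by_class, length, 1L) > 0]
toff <- tata_offsets_by_class(by_class)
cat("TATA 3'-end offset by class (median):\n")
print(toff)
write_tsv(toff, "results/tata_offsets.tsv")

# bidirectional motif scan over head-to-tail primary promoters
ptss <- unique(assignments[assignments$class == "P",
                           c("position", "strand", "gene_id")])
split <- orientation_split(ptss, ann)
ht <- split$head_to_tail
wins2 <- extract_windows(ht, rep, -60L, 1L)
hits <- lapply(seq_along(wins2), function(i)
  scan_bidirectional(wins2[i], window_from = -60L))
found <- !vapply(hits, is.null, logical(1))
implied <- vapply(hits[found], `[[`, numeric(1), "implied_atss_offset")
cat(sprintf("bidirectional BRE-TATA-BRE motif in %d / %d head-to-tail promoters (%.0f%%)\n",
            sum(found), nrow(ht), 100 * mean(found)))
cat("implied antisense start offsets:\n")
print(table(implied))
write_tsv(data.frame(position = ht$position[found], strand = ht$strand[found],
                     gene_id = ht$gene_id[found],
                     implied_atss_offset = implied),
          "results/bidirectional_motifs.tsv")
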