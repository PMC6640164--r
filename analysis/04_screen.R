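#!/usr/bin/env Rscript
# Stage 4: the bidirectional transcription screen.
#
# Splits primary TSS by upstream-gene orientation, computes metagene
# profiles of TEX 5'-end signal around each group (the head-to-tail group
# shows the divergent antisense peak near -50), applies the 40% antisense
# filter, pairs candidates with their antisense TSS, and summarises
# pTSS-aTSS spacings and intergene distances.

library(divtss)

rep <- read_fasta("results/data/genome.fasta", circular = TRUE)[[1]]
ann <- read_gff("results/data/annotation.gff3", rep = rep)
tex <- read_wiggle("results/data/tex_plus.wig", "results/data/tex_minus.wig",
                   rep$length, "TEX")
assignments <- read_tsv("results/tss_assignments.tsv")
truth <- read_truth("results/data/truth.tsv")

ptss <- unique(assignments[assignments$class == "P",
                           c("position", "strand", "gene_id")])
atss <- unique(assignments[assignments$class == "A",
                           c("position", "strand")])
split <- orientation_split(ptss, ann)
print(split)

for (k in c("head_to_head", "head_to_tail")) {
  mp <- meta_profile(split[[k]], tex, what = "five_prime")
  write_tsv(as.data.frame(mp), sprintf("results/profile_%s.tsv", k))
  peak <- mp$bin_start[which.max(mp$antisense)]
  cat(sprintf("%s (n = %d): antisense maximum in bin starting at %+d bp\n",
              sub("_", "-", sub("_to_", "-to-", k)),
              attr(mp, "n_sites"), peak))
}

cand <- screen_bidirectional(ptss, tex, ann, atss = atss, threshold = 0.40)
write_tsv(cand, "results/candidates.tsv")
bd_truth <- truth$tss$position[truth$tss$bidirectional &
                                 truth$tss$class == "P"]
nonbd_ht <- setdiff(split$head_to_tail$position, bd_truth)
cat(sprintf("screen: %d / %d head-to-tail pTSS pass the 40%% filter (%.0f%%)\n",
            nrow(cand), nrow(split$head_to_tail),
            100 * nrow(cand) / nrow(split$head_to_tail)))
cat(sprintf("vs truth: recall %.3f, false-positive rate %.4f\n",
            mean(bd_truth %in% cand$position),
            length(setdiff(cand$position, bd_truth)) / length(nonbd_ht)))

pd <- pair_distances(ptss, atss)
cat(sprintf("modal pTSS-aTSS spacing: %d bp (n = %d pairs)\n",
            pd$mode, length(pd$spacings)))
write_tsv(data.frame(spacing = as.integer(names(pd$histogram)),
                     count = as.integer(pd$histogram)),
          "results/spacing_histogram.tsv")

ig <- intergene_distances(split)
print(ig)
write_tsv(ig, "results/intergene_distances.tsv")
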