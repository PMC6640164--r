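#!/usr/bin/env Rscript
# Stage 1: simulate the study dataset.
#
# Generates a synthetic archaeal chromosome (150 genes on a 150 kb circular
# replicon, 20% of head-to-tail primary promoters bidirectional at 49 bp
# spacing, 6 IS elements) together with TEX / NOTEX / FRAG coverage tracks
# and the planted truth table, and writes everything as FASTA / GFF3 / BED /
# wiggle / TSV under results/data/.

library(divtss)

spec <- simulation_spec(n_genes = 150L, genome_length = 150000L,
                        n_is_elements = 6L, seed = 42L)
sim <- write_simulation(spec, "results/data")

cat("Simulated dataset written to results/data/\n")
print(sim$replicon)
print(sim$annotation)
print(sim$truth)
tt <- sim$truth$tss
cat(sprintf("planted bidirectional pairs: %d; planted operons of >1 gene: %d\n",
            sum(tt$bidirectional & tt$class == "A"),
            sum(table(sim$truth$operons$unit_id) > 1)))
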