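#!/usr/bin/env Rscript
# Step 1 — generate the synthetic multi-species dataset with ground truth.
#
# Eight species on the fixed tree; R-gene families with planted
# CC/TIR/NBS/LRR architectures evolving at twice the background rate under
# purifying selection, tandem clusters, planted structural defects and two
# unannotated loci per species. Everything downstream scores itself
# against truth tables emitted here.

source("analysis/00_common.R")

set.seed(SEED)
sim <- simulate_dataset(sim_config())
write_dataset(sim, DATASET_DIR)

g <- sim$genes
message(sprintf("species: %d; genes/species: %.0f (%d R-genes total, %d hidden)",
                length(sim$species), nrow(g) / length(sim$species),
                sum(g$type == "rgene"), sum(!g$annotated)))
message(sprintf("mean R protein length: %.0f aa; pseudogene fraction: %.2f",
                mean(nchar(g$protein[g$type == "rgene"])),
                mean(g$structure_truth[g$type == "rgene"] == "Pseudo")))

summary_tab <- data.frame(
  species = sim$species,
  n_genes = as.integer(table(g$species)[sim$species]),
  n_rgenes = as.integer(table(g$species[g$type == "rgene"])[sim$species]),
  n_hidden = as.integer(table(factor(g$species[!g$annotated],
                                     levels = sim$species))))
write_tsv(summary_tab, "dataset_summary.tsv")
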