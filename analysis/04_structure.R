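#!/usr/bin/env Rscript
# Step 4 — gene-structure classification of the identified R-genes.
#
# Annotated models are classified from their CDS (frameshift / premature
# stop -> Pseudo; then missing start/stop; then in-frame indels against
# the family seed; else Complete), mirroring a GeneWise-style structural
# re-annotation restricted to intronless models.

source("analysis/00_common.R")

inp <- read_species_inputs()
calls <- utils::read.delim(file.path(RESULTS, "rgene_calls.tsv"),
                           stringsAsFactors = FALSE)
truth <- inp$truth

rows <- list()
for (i in seq_len(nrow(calls))) {
  if (calls$evidence[i] != "original_annotation") next
  sp <- calls$species[i]
  gid <- calls$gene_id[i]
  cds <- inp$cds[[sp]][gid]
  if (is.na(cds)) next
  fam <- truth$family_id[truth$gene_id == gid]
  seed <- if (length(fam) == 1 && startsWith(fam, "fam"))
    inp$seeds[paste0("seed_", fam)] else NULL
  res <- classify_structure(cds, seed_protein = if (is.null(seed)) NULL
                            else unname(seed))
  rows[[length(rows) + 1L]] <- data.frame(
    gene_id = gid, species = sp, class = res$class,
    evidence = paste(res$evidence, collapse = ";"),
    stringsAsFactors = FALSE)
}
structures <- do.call(rbind, rows)
write_tsv(structures, "structures.tsv")

s <- summarize_structures(structures)
print(s$table)
message("pseudogene fraction per species: ",
        paste(sprintf("%s %.2f", colnames(s$table), s$pseudo_fraction),
              collapse = ", "))

# accuracy against the planted structure classes
m <- merge(structures, truth[, c("gene_id", "structure_truth")],
           by = "gene_id")
message(sprintf("structure-class accuracy vs truth: %.3f (n = %d)",
                mean(m$class == m$structure_truth), nrow(m)))
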