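#!/usr/bin/env Rscript
# Step 3 — genomic context: tandem clusters, orthology, chromosome
# anchoring to the out-group, and the synteny-supported R-locus map.
#
# Clusters use the eight-intervening-gene rule on gene ranks. Orthologs
# between one focal species and the out-group are retained at CIP > 60
# and E-value proxy < 1e-10, with reciprocal-best-hit flags; anchored
# chromosomes then support the R-locus map (>= 3 syntenic pairs within
# +/- 25 gene ranks).

source("analysis/00_common.R")

inp <- read_species_inputs()
calls <- utils::read.delim(file.path(RESULTS, "rgene_calls.tsv"),
                           stringsAsFactors = FALSE)

clusters <- do.call(rbind, lapply(inp$species, function(sp) {
  g <- inp$gene_tables[[sp]]
  rg <- intersect(calls$gene_id[calls$species == sp], g$gene_id)
  cl <- call_clusters(g, rg)
  cl$species <- sp
  cl
}))
write_tsv(clusters, "clusters.tsv")
frac <- tapply(clusters$size >= 2, clusters$species, mean)
message("clustered fraction per species: ",
        paste(sprintf("%s %.2f", names(frac), frac), collapse = ", "))

focal <- inp$species[1]
outgroup <- inp$species[length(inp$species)]     # the most distant taxon
pairs <- assign_orthologs(inp$proteomes[[focal]], inp$proteomes[[outgroup]])
write_tsv(pairs, "orthologs.tsv")
message(sprintf("%s vs %s: %d ortholog pairs (%d RBH)", focal, outgroup,
                nrow(pairs), sum(pairs$rbh)))

anchors <- anchor_chromosomes(pairs, inp$gene_tables[[focal]],
                              inp$gene_tables[[outgroup]])
write_tsv(anchors, "anchors.tsv")

r_focal <- calls[calls$species == focal &
                   calls$gene_id %in% inp$gene_tables[[focal]]$gene_id, ]
rmap <- map_r_loci(r_focal, pairs, inp$gene_tables[[focal]],
                   inp$gene_tables[[outgroup]])
write_tsv(rmap, "r_locus_map.tsv")
message(sprintf("R-locus map: %d/%d mapped (synteny value >= 3)",
                sum(rmap$mapped), nrow(rmap)))
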