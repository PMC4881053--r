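#!/usr/bin/env Rscript
# Step 6 — selection signals: NG86 Ka/Ks with Jukes-Cantor correction over
# RBH ortholog pairs of R-genes, the published selection bins, and Dxy.

source("analysis/00_common.R")

inp <- read_species_inputs()
truth <- inp$truth
calls <- utils::read.delim(file.path(RESULTS, "rgene_calls.tsv"),
                           stringsAsFactors = FALSE)

focal_pairs <- list(c(1, 2), c(1, 8))   # sister species and the out-group
rows <- list()
alns <- list()
for (fp in focal_pairs) {
  sp_a <- inp$species[fp[1]]; sp_b <- inp$species[fp[2]]
  rg_a <- inp$proteomes[[sp_a]][intersect(
    names(inp$proteomes[[sp_a]]), calls$gene_id[calls$species == sp_a])]
  rg_b <- inp$proteomes[[sp_b]][intersect(
    names(inp$proteomes[[sp_b]]), calls$gene_id[calls$species == sp_b])]
  pairs <- assign_orthologs(rg_a, rg_b)
  pairs <- pairs[pairs$rbh, ]
  for (i in seq_len(nrow(pairs))) {
    ca <- inp$cds[[sp_a]][[pairs$gene_a[i]]]
    cb <- inp$cds[[sp_b]][[pairs$gene_b[i]]]
    ok <- setNames(truth$structure_truth, truth$gene_id)[
      c(pairs$gene_a[i], pairs$gene_b[i])]
    if (any(ok == "Pseudo", na.rm = TRUE)) next   # pseudogenes excluded
    al <- tryCatch(codon_align_pair(ca, cb), error = function(e) NULL)
    if (is.null(al)) next
    r <- ng86(al$a, al$b)
    rows[[length(rows) + 1L]] <- data.frame(
      species_a = sp_a, species_b = sp_b,
      gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
      S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd, dS = r$dS, dN = r$dN,
      ratio = r$ratio, stringsAsFactors = FALSE)
    alns[[length(alns) + 1L]] <- al
  }
}
kaks <- do.call(rbind, rows)
write_tsv(kaks, "kaks.tsv")

sel <- classify_selection(kaks)
write_tsv(sel$table, "selection_bins.tsv")
print(sel$counts)
def <- sel$counts[c("purifying", "intermediate", "candidate", "positive")]
message(sprintf(
  "purifying fraction %.2f; candidates (0.8-1.0): %d; positive (>1): %d",
  def["purifying"] / max(1, sum(def)), def["candidate"], def["positive"]))
message(sprintf("Dxy over ortholog alignments: %.4f", dxy(alns)))
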