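# Shared prelude for the analysis scripts: seed handling and output paths.
# Each numbered script can be run standalone from the repository root:
#   Rscript analysis/01_simulate.R [--seed 42]

suppressMessages(library(rgevo))

.args <- commandArgs(trailingOnly = TRUE)
.get_opt <- function(flag, default) {
  i <- which(.args == flag)
  if (length(i) == 1L && i < length(.args)) .args[i + 1L] else default
}
SEED <- as.integer(.get_opt("--seed", "42"))
RESULTS <- .get_opt("--results", "results")
DATASET_DIR <- file.path(RESULTS, "dataset")
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

write_tsv <- function(x, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}

# The downstream scripts (02+) re-read the serialized dataset, exercising
# the standard-format readers rather than passing R objects around.
read_species_inputs <- function(dir = DATASET_DIR) {
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  species <- tree$tip.label
  list(
    tree = tree,
    species = species,
    proteomes = lapply(setNames(species, species), function(sp)
      read_fasta(file.path(dir, paste0(sp, ".protein.fasta")))),
    cds = lapply(setNames(species, species), function(sp)
      read_fasta(file.path(dir, paste0(sp, ".cds.fasta")))),
    genomes = lapply(setNames(species, species), function(sp)
      read_fasta(file.path(dir, paste0(sp, ".genome.fasta")))),
    gene_tables = lapply(setNames(species, species), function(sp)
      read_gff3(file.path(dir, paste0(sp, ".gff3")))),
    seeds = read_fasta(file.path(dir, "seeds.fasta")),
    truth = utils::read.delim(file.path(dir, "truth", "genes.tsv"),
                              stringsAsFactors = FALSE)
  )
}
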