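# End-to-end synthetic dataset assembly and serialisation.

.draw_structure_class <- function(probs) {
  r <- stats::runif(1)
  cum <- cumsum(probs)
  i <- which(r < cum)
  if (length(i) == 0L) "Complete" else names(probs)[i[1]]
}

#' Simulate a complete multi-species dataset with ground truth
#'
#' Runs the full generator: R-gene families with planted architectures
#' evolve along the species tree under birth-death copy-number dynamics
#' and purifying selection at twice the background rate; single-copy
#' background families provide synteny and negatives; tandem clusters,
#' structural defects and unannotated ("hidden") loci are planted; each
#' species' genome sequence embeds every CDS at known coordinates.
#'
#' Uses the R random number generator: call \code{set.seed()} first for
#' reproducible (byte-identical, via [write_dataset()]) output.
#'
#' @param config from [sim_config()].
#' @return list with genes (truth data.frame), genomes (species ->
#'   named chromosome sequences), seed_db (ancestral R proteins),
#'   family_counts, family_events, tree, species, config.
#' @export
simulate_dataset <- function(config = sim_config()) {
  tree <- ape::read.tree(text = config$tree_newick)
  species <- tree$tip.label
  n_tip <- length(species)
  fam <- simulate_families(config, tree)

  labels <- sample(names(config$arch_weights), config$n_rgene_families,
                   replace = TRUE, prob = config$arch_weights)
  rfam <- vector("list", config$n_rgene_families)
  for (f in seq_len(config$n_rgene_families)) {
    anc <- build_domain_protein(labels[f])
    cds <- paste0(back_translate(anc$protein), "TGA")
    n_cod <- nchar(cds) %/% 3L
    so <- rep(NA_real_, n_cod)
    so[anc$domain_sites] <- config$omega_domain
    so[anc$motif_sites] <- 0
    node_seqs <- .evolve_along_tree(cds, tree,
                                    rate = config$rate_multiplier_rgene,
                                    omega = config$omega_rgene,
                                    site_omega = so)
    rfam[[f]] <- list(label = labels[f], anc = anc, site_omega = so,
                      node_seqs = node_seqs)
  }

  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  bg_chrom <- rep(chroms, each = ceiling(config$n_background /
                                           config$n_chromosomes))[
                                             seq_len(config$n_background)]
  bgfam <- vector("list", config$n_background)
  for (b in seq_len(config$n_background)) {
    len <- sample(seq(config$background_codons[1],
                      config$background_codons[2]), 1L)
    prot <- paste0("M", .rand_aa(len - 1L))
    cds <- paste0(back_translate(prot), "TAA")
    bgfam[[b]] <- list(node_seqs = .evolve_along_tree(
      cds, tree, rate = 1, omega = config$omega_background))
  }

  all_genes <- list()
  genomes <- list()
  for (leaf in seq_len(n_tip)) {
    sp <- species[leaf]
    rows <- list()
    for (b in seq_len(config$n_background)) {
      gid <- sprintf("%s_bg%03d", sp, b)
      cds <- bgfam[[b]]$node_seqs[leaf]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, species = sp, type = "background",
        family_id = sprintf("bg%03d", b), architecture = NA_character_,
        cluster_id = NA_character_, structure_truth = "Complete",
        defect = "none", annotated = TRUE, omega = config$omega_background,
        chromosome = bg_chrom[b], cds = cds,
        protein = sub("\\*$", "", translate(cds)),
        domains = "", stringsAsFactors = FALSE)
    }
    for (f in seq_len(config$n_rgene_families)) {
      k <- fam$counts[f, leaf]
      if (k == 0L) next
      fr <- rfam[[f]]
      dom_str <- paste(sprintf("%s:%d-%d", fr$anc$domains$domain,
                               fr$anc$domains$start, fr$anc$domains$end),
                       collapse = ";")
      cl <- if (k >= 2L) sprintf("%s_fam%02d", sp, f) else NA_character_
      for (j in seq_len(k)) {
        gid <- sprintf("%s_fam%02d_%d", sp, f, j)
        cds <- evolve_cds(fr$node_seqs[leaf],
                          config$dup_divergence * config$rate_multiplier_rgene,
                          config$omega_rgene, fr$site_omega)
        gene <- list(cds = cds, domains = fr$anc$domains,
                     protein = sub("\\*$", "", translate(cds)),
                     structure_truth = "Complete", defect = "none")
        cls <- .draw_structure_class(config$defect_probs)
        if (cls != "Complete") gene <- plant_defects(gene, cls)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, species = sp, type = "rgene",
          family_id = sprintf("fam%02d", f), architecture = fr$label,
          cluster_id = cl, structure_truth = gene$structure_truth,
          defect = gene$defect, annotated = TRUE, omega = config$omega_rgene,
          chromosome = NA_character_, cds = gene$cds, protein = gene$protein,
          domains = dom_str, stringsAsFactors = FALSE)
      }
    }
    genes_sp <- do.call(rbind, rows)
    # hide a few intact cluster members from the annotation
    cand <- which(genes_sp$type == "rgene" & !is.na(genes_sp$cluster_id) &
                    genes_sp$structure_truth == "Complete")
    if (length(cand) > 0L && config$n_hidden_per_species > 0L) {
      hid <- sample(cand, min(config$n_hidden_per_species, length(cand)))
      genes_sp$annotated[hid] <- FALSE
    }
    lay <- layout_genome(genes_sp, config)
    all_genes[[sp]] <- lay$genes
    genomes[[sp]] <- lay$genome
  }
  genes <- do.call(rbind, all_genes)
  rownames(genes) <- NULL

  seed_db <- vapply(rfam, function(fr) {
    sub("\\*$", "", translate(fr$node_seqs[n_tip + 1L]))
  }, character(1))
  names(seed_db) <- sprintf("seed_fam%02d", seq_along(rfam))

  list(genes = genes, genomes = genomes, seed_db = seed_db,
       family_counts = fam$counts, family_events = fam$events,
       family_labels = labels, tree = tree, species = species,
       config = config)
}

#' Extract the annotated proteome / CDS set / gene table of one species
#'
#' @param sim from [simulate_dataset()].
#' @param sp species name.
#' @param what one of "protein", "cds", "genes".
#' @return named character vector of sequences, or the gene table
#'   (annotated genes only).
#' @export
dataset_part <- function(sim, sp, what = c("protein", "cds", "genes")) {
  what <- match.arg(what)
  g <- sim$genes[sim$genes$species == sp & sim$genes$annotated, , drop = FALSE]
  switch(what,
         protein = setNames(g$protein, g$gene_id),
         cds = setNames(g$cds, g$gene_id),
         genes = g)
}

#' Write a simulated dataset to disk
#'
#' Emits, per species, protein/CDS/genome FASTA and a GFF3 of annotated
#' genes, plus the seed protein database, the species tree (newick) and
#' tab-separated truth tables. Output is byte-identical for identical
#' simulations.
#'
#' @param sim from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  for (sp in sim$species) {
    write_fasta(dataset_part(sim, sp, "protein"),
                file.path(dir, paste0(sp, ".protein.fasta")))
    write_fasta(dataset_part(sim, sp, "cds"),
                file.path(dir, paste0(sp, ".cds.fasta")))
    write_fasta(sim$genomes[[sp]], file.path(dir, paste0(sp, ".genome.fasta")))
    write_gff3(dataset_part(sim, sp, "genes"),
               file.path(dir, paste0(sp, ".gff3")))
  }
  write_fasta(sim$seed_db, file.path(dir, "seeds.fasta"))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  truth <- sim$genes[, setdiff(names(sim$genes), c("cds", "protein"))]
  utils::write.table(truth, file.path(dir, "truth", "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$family_events,
                     file.path(dir, "truth", "family_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- as.data.frame(sim$family_counts)
  names(counts) <- paste0("node", seq_len(ncol(counts)))
  utils::write.table(cbind(family = seq_len(nrow(counts)), counts),
                     file.path(dir, "truth", "family_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
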