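# Multi-species synthetic genome simulator with full ground truth.
#
# The generator emulates the statistical structure of a legume-style R-gene
# study: ~8 species related by a fixed rooted tree, R-gene families with
# planted CC/TIR/NBS/LRR architectures evolving under birth-death dynamics
# and purifying selection, tandem clusters, planted structural defects
# (pseudogenes, truncated models), a background of single-copy random-codon
# genes providing synteny and negatives, and per-species genome sequences
# embedding every CDS at known coordinates. All downstream stages can be
# scored against the emitted truth tables.

#' Default species tree
#'
#' Eight taxa: two sister soybean-like species, two more millettioid-like
#' species, a three-taxon galegoid-like clade, and a distant out-group.
#' Branch lengths are neutral substitutions per site at four-fold
#' degenerate positions.
#'
#' @return newick string.
#' @export
default_species_tree <- function() {
  paste0("((((Gmax:0.01,Gsoja:0.01):0.06,(Ccajan:0.04,Pvulgaris:0.04):0.03)",
         ":0.02,((Mtruncatula:0.04,Carietinum:0.04):0.02,Ljaponicus:0.05)",
         ":0.03):0.08,Vvinifera:0.16);")
}

#' Simulation configuration
#'
#' Defaults define the study conditions: 8 species, ~300 genes per species
#' (260 background + R-gene families), R-genes evolving twice as fast as
#' background genes under purifying selection (omega 0.2), tandem clusters
#' with at most 8 intervening genes, ~10\% pseudogenization plus rarer
#' truncation defects, and 2 unannotated ("hidden") R loci per species.
#'
#' @param tree_newick rooted species tree with branch lengths
#'   (substitutions/site).
#' @param n_rgene_families,n_background numbers of R-gene and background
#'   (non-R, single-copy) families.
#' @param rate_multiplier_rgene substitution-rate multiplier for R-genes.
#' @param omega_rgene,omega_background target dN/dS per gene class.
#' @param omega_domain dN/dS applied to non-motif domain codons
#'   (diagnostic motif codons are held invariant; see vignette).
#' @param gain_rate,loss_rate per-branch Poisson means for family
#'   gains/losses.
#' @param root_counts pool from which each family's root copy number is
#'   drawn.
#' @param dup_divergence extra branch length applied to each tandem copy.
#' @param cluster_spacing_range range of intervening background genes
#'   between consecutive tandem cluster members.
#' @param min_rgene_separation minimum intervening genes between distinct
#'   R-gene loci (must exceed the cluster threshold of 8).
#' @param defect_probs named probabilities for planted structure classes;
#'   remainder is Complete.
#' @param n_hidden_per_species R loci left out of the annotation (present
#'   only in the genome sequence).
#' @param n_chromosomes chromosomes per species.
#' @param background_codons range of background gene lengths (codons).
#' @param intergenic_range intergenic spacer length range (nt).
#' @param arch_weights named sampling weights over the ten architecture
#'   labels.
#' @param one_event_per_family when TRUE, exactly one gain or loss event
#'   (per the sign of the configured rates) is planted on one random
#'   branch per family - a controlled-truth mode used for validating the
#'   event reconstruction.
#' @return list of class \code{rgevo_sim_config}.
#' @export
sim_config <- function(tree_newick = default_species_tree(),
                       n_rgene_families = 20,
                       n_background = 320,
                       rate_multiplier_rgene = 2,
                       omega_rgene = 0.2,
                       omega_background = 0.2,
                       omega_domain = 0.05,
                       gain_rate = 0.05,
                       loss_rate = 0.05,
                       root_counts = c(1, 1, 2, 2, 3),
                       dup_divergence = 0.01,
                       cluster_spacing_range = c(0, 8),
                       min_rgene_separation = 10,
                       defect_probs = c(`Pseudo-frameshift` = 0.05,
                                        `Pseudo-premature-stop` = 0.05,
                                        InDel = 0.05, LackStart = 0.03,
                                        LackStop = 0.03, LackBoth = 0.02),
                       n_hidden_per_species = 2,
                       n_chromosomes = 4,
                       background_codons = c(250, 500),
                       intergenic_range = c(80, 200),
                       arch_weights = c(CC = 4, `CC-NBS` = 9,
                                        `CC-NBS-LRR` = 8, `CC-TIR-NBS` = 1,
                                        LRR = 8, NBS = 26, `NBS-LRR` = 11,
                                        TIR = 10, `TIR-NBS` = 9,
                                        `TIR-NBS-LRR` = 6),
                       one_event_per_family = FALSE) {
  stopifnot(gain_rate >= 0, loss_rate >= 0,
            all(defect_probs >= 0), sum(defect_probs) <= 1,
            min_rgene_separation > 8)
  structure(as.list(environment()), class = "rgevo_sim_config")
}

# ---- residue/codon sampling -----------------------------------------------

# Filler alphabet for linkers and spacer residues: hydrophobics that feed
# the LRR/CC patterns are down-weighted so that linkers stay quiet.
.FILLER_AA <- c(A = 9, R = 6, N = 5, D = 6, C = 2, Q = 5, E = 8, G = 9,
                H = 3, I = 2, L = 3, K = 7, M = 2, F = 2, P = 6, S = 9,
                T = 7, W = 2, Y = 4, V = 3)

.rand_aa <- function(n) {
  if (n <= 0) return("")
  paste(sample(names(.FILLER_AA), n, replace = TRUE,
               prob = .FILLER_AA), collapse = "")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Reverse codon table (sense codons per amino acid).
.codon_env2 <- new.env(parent = emptyenv())
.aa_to_codons <- function() {
  if (is.null(.codon_env2$rev)) {
    gc <- .genetic_code()
    sense <- gc[gc != "*"]
    .codon_env2$rev <- split(names(sense), sense)
  }
  .codon_env2$rev
}

#' Back-translate a protein with random synonymous codons
#'
#' @param protein amino-acid string without stops.
#' @return nucleotide string (no terminal stop codon appended).
#' @export
back_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  rev_tab <- .aa_to_codons()
  paste(vapply(aa, function(a) {
    cods <- rev_tab[[a]]
    if (is.null(cods)) stop("cannot back-translate residue: ", a)
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

# ---- domain templates ------------------------------------------------------

# Each template returns list(seq, motif_rel): motif_rel marks the
# scanner-diagnostic residues (1-based, relative) that are held invariant
# during evolution.
.tmpl_cc <- function() {
  heptads <- replicate(6, {
    paste0(sample(c("L", "I", "V"), 1), .rand_aa(2),
           sample(c("L", "I", "V", "M"), 1), sample(c("E", "K", "Q", "R"), 1),
           .rand_aa(1), sample(c("E", "K", "R"), 1))
  })
  seq <- paste(heptads, collapse = "")
  motif <- sort(unlist(lapply(0:5, function(h) 7 * h + c(1, 4, 5, 7))))
  list(seq = seq, motif_rel = motif)
}

.tmpl_nbs <- function() {
  sp1 <- .rand_aa(35); sp2 <- .rand_aa(55); sp3 <- .rand_aa(45)
  seq <- paste0("GMGGLGKT", sp1, "LLVLDDVW", sp2, "GLPLAL", sp3)
  m1 <- 1:8
  m2 <- 8 + nchar(sp1) + 1:8
  m3 <- 8 + nchar(sp1) + 8 + nchar(sp2) + 1:6
  list(seq = seq, motif_rel = c(m1, m2, m3))
}

.tmpl_tir <- function() {
  list(seq = TIR_CONSENSUS, motif_rel = integer(0))
}

.tmpl_lrr <- function() {
  n_rep <- sample(4:7, 1)
  units <- replicate(n_rep, {
    paste0(sample(c("L", "L", "I", "V", "F"), 1), .rand_aa(2),
           sample(c("L", "L", "I", "V"), 1), .rand_aa(1),
           sample(c("L", "L", "I", "V"), 1), .rand_aa(2))
  })
  motif <- sort(unlist(lapply(0:(n_rep - 1), function(u) 8 * u + c(1, 4, 6))))
  list(seq = paste(units, collapse = ""), motif_rel = motif)
}

#' Build a protein with a planted domain architecture
#'
#' Emits, in order, the templates for the domains named by the label (CC =
#' six heptad repeats, NBS = P-loop + kinase-2 + GLPL motif blocks, TIR =
#' the bundled consensus block, LRR = 4-7 tandem LxxLxLxx repeats), joined
#' by random low-complexity linkers, with the planted domain coordinates
#' and a per-residue conservation class recorded.
#'
#' @param label one of the ten named architecture categories.
#' @return list with protein, domains (data.frame domain/start/end),
#'   motif_sites (residue indices held invariant under evolution) and
#'   domain_sites (residue indices inside domains).
#' @export
build_domain_protein <- function(label) {
  if (!label %in% setdiff(architecture_labels(), c("Others", "Un-annotated")))
    stop("unknown architecture label: ", label)
  parts <- strsplit(label, "-")[[1]]
  builders <- list(CC = .tmpl_cc, TIR = .tmpl_tir, NBS = .tmpl_nbs,
                   LRR = .tmpl_lrr)
  n_tail <- sample(100:250, 1)
  protein <- paste0("M", .rand_aa(sample(50:120, 1) - 1L))
  domains <- data.frame(domain = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
  motif_sites <- integer(0)
  domain_sites <- integer(0)
  for (i in seq_along(parts)) {
    t <- builders[[parts[i]]]()
    s <- nchar(protein) + 1L
    protein <- paste0(protein, t$seq)
    e <- nchar(protein)
    domains <- rbind(domains, data.frame(domain = parts[i], start = s,
                                         end = e, stringsAsFactors = FALSE))
    motif_sites <- c(motif_sites, s - 1L + t$motif_rel)
    domain_sites <- c(domain_sites, s:e)
    if (i < length(parts)) protein <- paste0(protein, .rand_aa(sample(30:70, 1)))
  }
  protein <- paste0(protein, .rand_aa(n_tail))
  list(protein = protein, domains = domains,
       motif_sites = motif_sites, domain_sites = domain_sites)
}

# ---- codon evolution -------------------------------------------------------

#' Evolve a coding sequence along a branch
#'
#' Acceptance-rejection codon evolution: the number of substitutions is
#' drawn as Poisson(branch_length x length); point changes are proposed
#' uniformly over positions and alternative bases, accepted with
#' probability 1 when synonymous and \code{omega} (or the site's own
#' omega) when non-synonymous; proposals creating an internal stop are
#' rejected. The first (start) and final (stop) codons are not mutated.
#'
#' @param cds coding sequence, length divisible by 3, no internal stop.
#' @param branch_length expected substitutions per nucleotide site.
#' @param omega gene-level dN/dS acceptance probability for
#'   non-synonymous changes.
#' @param site_omega optional numeric vector, one entry per codon
#'   (NA = use \code{omega}); used to hold domain/motif codons under
#'   stronger purifying selection.
#' @return descendant cds string.
#' @export
evolve_cds <- function(cds, branch_length, omega, site_omega = NULL) {
  if (omega < 0) stop("omega must be >= 0")
  stopifnot(branch_length >= 0, nchar(cds) %% 3 == 0)
  codons <- .codons(cds)
  nc <- length(codons)
  gc <- .genetic_code()
  aa <- gc[codons]
  if (any(aa[-nc] == "*")) stop("internal stop in ancestral cds")
  if (!is.null(site_omega)) stopifnot(length(site_omega) == nc)
  L <- nchar(cds)
  target <- stats::rpois(1, branch_length * L)
  if (target == 0) return(cds)
  bases <- c("A", "C", "G", "T")
  accepted <- 0L
  attempts <- 0L
  max_attempts <- 60L * target + 300L
  mutable <- L - 6L                       # exclude first and last codon
  if (mutable <= 0) return(cds)
  while (accepted < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    pos <- sample.int(mutable, 1L) + 3L
    ci <- (pos - 1L) %/% 3L + 1L
    wi <- (pos - 1L) %% 3L + 1L
    old_codon <- codons[ci]
    old_base <- substring(old_codon, wi, wi)
    new_base <- sample(bases[bases != old_base], 1L)
    new_codon <- old_codon
    substring(new_codon, wi, wi) <- new_base
    new_aa <- gc[new_codon]
    if (new_aa == "*") next
    syn <- new_aa == gc[old_codon]
    p_acc <- if (syn) 1 else {
      so <- if (!is.null(site_omega)) site_omega[ci] else NA_real_
      if (is.na(so)) omega else so
    }
    if (p_acc >= 1 || stats::runif(1) < p_acc) {
      codons[ci] <- new_codon
      accepted <- accepted + 1L
    }
  }
  paste(codons, collapse = "")
}

# Evolve a cds down every branch of a tree; returns character vector
# indexed by node number (ape numbering), root = ancestral cds.
.evolve_along_tree <- function(cds, tree, rate = 1, omega = 0.2,
                               site_omega = NULL) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- character(max(tree$edge))
  seqs[root] <- cds
  edges <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]
  # preorder: parents appear before children when traversing edges sorted
  # by parent after reordering cladewise
  tr <- stats::reorder(tree)
  for (i in seq_len(nrow(tr$edge))) {
    par <- tr$edge[i, 1L]; child <- tr$edge[i, 2L]
    bl <- tr$edge.length[i] * rate
    seqs[child] <- evolve_cds(seqs[par], bl, omega, site_omega)
  }
  seqs
}

# ---- family birth-death ----------------------------------------------------

#' Simulate gene-family copy numbers along the species tree
#'
#' Each family starts at the root with a copy number drawn from
#' \code{config$root_counts}; along each branch, gains and losses are
#' drawn as Poisson(\code{gain_rate}) and Poisson(\code{loss_rate}) and
#' the count is floored at zero. In \code{one_event_per_family} mode a
#' single event is planted on one uniformly chosen branch instead; the
#' two basal branches (children of the root) are excluded there because
#' an event on either side of the root cannot be polarized by any
#' reconstruction without a further out-group.
#'
#' @param config from [sim_config()].
#' @param tree ape phylo (defaults to the configured tree).
#' @return list with \code{counts} (families x nodes matrix, ape node
#'   numbering) and \code{events} (data.frame family, parent, child, gain,
#'   loss, net).
#' @export
simulate_families <- function(config, tree = ape::read.tree(text = config$tree_newick)) {
  nf <- config$n_rgene_families
  n_nodes <- max(tree$edge)
  counts <- matrix(0L, nrow = nf, ncol = n_nodes)
  tr <- stats::reorder(tree)
  root <- length(tree$tip.label) + 1L
  events <- list()
  non_basal <- which(tr$edge[, 1L] != root)
  for (f in seq_len(nf)) {
    counts[f, root] <- as.integer(sample(config$root_counts, 1))
    event_edge <- if (config$one_event_per_family)
      non_basal[sample.int(length(non_basal), 1L)] else 0L
    for (i in seq_len(nrow(tr$edge))) {
      par <- tr$edge[i, 1L]; child <- tr$edge[i, 2L]
      if (config$one_event_per_family) {
        gain <- if (i == event_edge && config$gain_rate > 0) 1L else 0L
        loss <- if (i == event_edge && config$gain_rate == 0 &&
                    config$loss_rate > 0) 1L else 0L
      } else {
        gain <- stats::rpois(1, config$gain_rate)
        loss <- stats::rpois(1, config$loss_rate)
      }
      newc <- max(0L, counts[f, par] + gain - loss)
      counts[f, child] <- newc
      events[[length(events) + 1L]] <- data.frame(
        family = f, parent = par, child = child,
        gain = gain, loss = loss, net = newc - counts[f, par])
    }
  }
  list(counts = counts, events = do.call(rbind, events), tree = tree)
}

# ---- structural defects ----------------------------------------------------

#' Plant a structural defect into a gene
#'
#' Introduces exactly the named defect into the CDS: a 1-bp deletion
#' (frameshift), a sense-to-stop point mutation (premature stop), an
#' in-frame 9-codon deletion (InDel), ATG->ATA (LackStart), stop->TGG
#' (LackStop), or both terminal defects (LackBoth). Point defects are
#' placed in the C-terminal tail downstream of the last planted domain so
#' that the planted architecture is preserved (recently disabled copies;
#' see vignette).
#'
#' @param gene list with at least \code{cds} (including the terminal stop
#'   codon) and optionally \code{domains} (aa coordinates).
#' @param defect_class one of InDel, LackStart, LackStop, LackBoth,
#'   Pseudo-frameshift, Pseudo-premature-stop.
#' @return the gene with mutated \code{cds}, re-derived \code{protein}
#'   (translation up to the first stop), and \code{structure_truth}.
#' @export
plant_defects <- function(gene, defect_class) {
  classes <- c("InDel", "LackStart", "LackStop", "LackBoth",
               "Pseudo-frameshift", "Pseudo-premature-stop")
  if (!defect_class %in% classes) stop("unknown defect class: ", defect_class)
  cds <- gene$cds
  n_cod <- nchar(cds) %/% 3L
  tail_start <- if (!is.null(gene$domains) && nrow(gene$domains) > 0)
    max(gene$domains$end) + 3L else max(3L, n_cod %/% 2L)
  lo <- min(tail_start, n_cod - 3L)
  hi <- n_cod - 3L
  if (hi - lo < 12L) stop("sequence too short to host defect")
  pick <- function() sample(lo:(hi - 10L), 1L)
  codon_sub <- function(cds, i, codon) {
    substring(cds, 3L * (i - 1L) + 1L, 3L * i) <- codon
    cds
  }
  if (defect_class %in% c("LackStart", "LackBoth"))
    cds <- codon_sub(cds, 1L, "ATA")
  if (defect_class %in% c("LackStop", "LackBoth"))
    cds <- codon_sub(cds, n_cod, "TGG")
  if (defect_class == "InDel") {
    d0 <- pick()
    cds <- paste0(substring(cds, 1L, 3L * (d0 - 1L)),
                  substring(cds, 3L * (d0 + 9L - 1L) + 1L))
  }
  if (defect_class == "Pseudo-frameshift") {
    p <- 3L * (pick() - 1L) + 1L
    cds <- paste0(substring(cds, 1L, p - 1L), substring(cds, p + 1L))
  }
  if (defect_class == "Pseudo-premature-stop") {
    cds <- codon_sub(cds, pick(), "TAA")
  }
  gene$cds <- cds
  gene$protein <- sub("\\*.*$", "", translate(cds))
  gene$structure_truth <- sub("^Pseudo-.*$", "Pseudo", defect_class)
  gene$defect <- defect_class
  gene
}

# ---- genome layout ---------------------------------------------------------

#' Lay out one species' genes on chromosomes and build the genome sequence
#'
#' Background genes keep a fixed synteny order across species; tandem
#' cluster members are interleaved with 0-8 (configurable) intervening
#' background genes; distinct R-gene loci are separated by more than 8
#' intervening genes. The genome sequence embeds every CDS at its
#' coordinates (minus-strand genes reverse-complemented); intergenic
#' spacers are random DNA.
#'
#' @param genes data.frame with gene_id, type ("rgene"/"background"),
#'   cluster_id (NA for non-clustered), cds; background rows must be
#'   pre-sorted in synteny order and carry a \code{chromosome} column.
#' @param config from [sim_config()].
#' @param spacings optional named list: cluster_id -> integer vector of
#'   intervening-gene counts between consecutive members (overrides the
#'   configured range; used to pin boundary behaviour).
#' @return list(genes = data.frame with chromosome/start/end/strand/rank,
#'   genome = named character vector chromosome -> sequence).
#' @export
layout_genome <- function(genes, config, spacings = NULL) {
  bg <- genes[genes$type == "background", , drop = FALSE]
  rg <- genes[genes$type == "rgene", , drop = FALSE]
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  placed <- list()
  genome <- character(0)
  # group R genes into loci: one locus per cluster, one per singleton
  loci <- if (nrow(rg)) split(seq_len(nrow(rg)),
                              ifelse(is.na(rg$cluster_id),
                                     paste0("s_", rg$gene_id),
                                     paste0("c_", rg$cluster_id)))
          else list()
  loci <- loci[sample(max(length(loci), 0L))]
  sep <- config$min_rgene_separation
  # draw intervening-gene gaps per locus, then assign loci to the least
  # loaded chromosome so capacity is balanced
  gaps_of <- lapply(names(loci), function(key) {
    k <- length(loci[[key]])
    if (!is.null(spacings) && !is.null(spacings[[sub("^c_", "", key)]]))
      as.integer(spacings[[sub("^c_", "", key)]])
    else if (k > 1L) {
      # tandem duplicates are mostly adjacent: favour small gaps
      rng <- seq(config$cluster_spacing_range[1],
                 config$cluster_spacing_range[2])
      sample(rng, k - 1L, replace = TRUE,
             prob = rev(seq_along(rng)))
    } else integer(0)
  })
  jitter_of <- lapply(seq_along(loci), function(i) sample.int(3L, 1L))
  load <- setNames(rep(0L, length(chroms)), chroms)
  chr_of_locus <- character(length(loci))
  consumption <- vapply(seq_along(loci), function(li)
    sep + jitter_of[[li]] + sum(gaps_of[[li]]), numeric(1))
  for (li in order(-consumption)) {      # heaviest loci placed first
    ch <- names(which.min(load))
    chr_of_locus[li] <- ch
    load[ch] <- load[ch] + consumption[li]
  }
  for (ch in chroms) {
    bgc <- bg[bg$chromosome == ch, , drop = FALSE]
    nb <- nrow(bgc)
    locus_ids <- which(chr_of_locus == ch)
    anchor <- 0L
    inserts <- list()                        # background index -> genes after it
    for (li in locus_ids) {
      members <- loci[[li]]
      gaps <- gaps_of[[li]]
      span <- sum(gaps)
      anchor <- anchor + sep + jitter_of[[li]]
      if (anchor + span > nb) stop("chromosome capacity exceeded on ", ch)
      pos <- anchor + c(0L, cumsum(gaps))
      for (j in seq_along(members)) {
        p <- pos[j]
        inserts[[as.character(p)]] <- c(inserts[[as.character(p)]], members[j])
      }
      anchor <- anchor + span
    }
    # build final order: background genes in synteny order with R genes
    # inserted after their anchor background index
    rows <- list()
    for (b in 0:nb) {
      if (b > 0) rows[[length(rows) + 1L]] <- bgc[b, , drop = FALSE]
      ins <- inserts[[as.character(b)]]
      if (!is.null(ins)) for (m in ins)
        rows[[length(rows) + 1L]] <- rg[m, , drop = FALSE]
    }
    ordered <- do.call(rbind, rows)
    if (is.null(ordered)) next
    # assign coordinates and build the sequence
    cursor <- 0L
    segs <- character(0)
    starts <- ends <- integer(nrow(ordered))
    strands <- character(nrow(ordered))
    for (i in seq_len(nrow(ordered))) {
      spacer <- sample(seq(config$intergenic_range[1],
                           config$intergenic_range[2]), 1L)
      segs <- c(segs, .rand_dna(spacer))
      cursor <- cursor + spacer
      cds <- ordered$cds[i]
      strand <- sample(c("+", "-"), 1L)
      gseq <- if (strand == "+") cds else reverse_complement(cds)
      starts[i] <- cursor + 1L
      ends[i] <- cursor + nchar(cds)
      strands[i] <- strand
      segs <- c(segs, gseq)
      cursor <- cursor + nchar(cds)
    }
    segs <- c(segs, .rand_dna(sample(seq(config$intergenic_range[1],
                                         config$intergenic_range[2]), 1L)))
    ordered$chromosome <- ch
    ordered$start <- starts
    ordered$end <- ends
    ordered$strand <- strands
    genome[ch] <- paste(segs, collapse = "")
    placed[[ch]] <- ordered
  }
  out <- do.call(rbind, placed)
  rownames(out) <- NULL
  out <- assign_ranks(out)
  list(genes = out, genome = genome)
}
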