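test_that("planted architectures are scanner-recoverable in order", {
  set.seed(21)
  bp <- build_domain_protein("CC-NBS-LRR")
  hits <- scan_domains(bp$protein)
  doms <- vapply(hits, `[[`, character(1), "domain")
  expect_setequal(doms, c("CC", "NBS", "LRR"))
  starts <- vapply(hits, `[[`, integer(1), "start")
  expect_identical(doms[order(starts)], c("CC", "NBS", "LRR"))
  expect_identical(classify_architecture(hits), "CC-NBS-LRR")

  nbs_only <- build_domain_protein("NBS")
  expect_null(scan_lrr(nbs_only$protein))
  expect_error(build_domain_protein("KINASE"), "unknown")
})

test_that("emitted protein lengths average near 500 aa at defaults", {
  set.seed(22)
  w <- sim_config()$arch_weights
  labels <- sample(names(w), 120, replace = TRUE, prob = w)
  lens <- vapply(labels, function(l) nchar(build_domain_protein(l)$protein),
                 numeric(1))
  expect_gte(mean(lens), 400)
  expect_lte(mean(lens), 600)
})

test_that("codon evolution respects omega limits and branch length", {
  set.seed(23)
  prot <- rand_protein(300)
  cds <- paste0(back_translate(prot), "TGA")
  expect_identical(translate(evolve_cds(cds, 0.4, 0)), translate(cds))
  expect_identical(evolve_cds(cds, 0, 0.5), cds)
  expect_error(evolve_cds(cds, 0.1, -1), "omega")
  d <- evolve_cds(cds, 0.1, 1)
  diffs <- sum(strsplit(cds, "")[[1]] != strsplit(d, "")[[1]])
  expect_gt(diffs / nchar(cds), 0.05)
  expect_lt(diffs / nchar(cds), 0.15)
  # no internal stops ever
  aa <- translate(d)
  expect_false(grepl("\\*", substring(aa, 1, nchar(aa) - 1)))
})

test_that("family copy-number simulation conserves path sums", {
  cfg <- small_config()
  tree <- ape::read.tree(text = cfg$tree_newick)
  set.seed(24)
  fam <- simulate_families(cfg, tree)
  root <- length(tree$tip.label) + 1L
  # leaf count = root count + sum of net changes along the root-to-leaf path
  for (f in seq_len(nrow(fam$counts))) {
    ev <- fam$events[fam$events$family == f, ]
    for (leaf in seq_along(tree$tip.label)) {
      node <- leaf
      path_net <- 0L
      while (node != root) {
        e <- ev[ev$child == node, ]
        path_net <- path_net + e$net
        node <- e$parent
      }
      expect_identical(fam$counts[f, leaf], fam$counts[f, root] + path_net)
    }
  }

  cfg0 <- small_config(gain_rate = 0, loss_rate = 0)
  set.seed(25)
  fam0 <- simulate_families(cfg0, tree)
  expect_true(all(fam0$counts == fam0$counts[, root]))

  cfg_loss <- small_config(gain_rate = 0, loss_rate = 0.4)
  set.seed(26)
  faml <- simulate_families(cfg_loss, tree)
  expect_true(all(faml$events$net <= 0))
  for (e in seq_len(nrow(faml$events)))
    expect_lte(faml$counts[1, faml$events$child[e]],
               faml$counts[1, faml$events$parent[e]])
})

test_that("genome layout pins cluster spacing at the 8-gene boundary", {
  cfg <- small_config()
  mk_genes <- function(gaps) {
    bg <- data.frame(gene_id = sprintf("bg%03d", 1:80), type = "background",
                     cluster_id = NA_character_,
                     chromosome = rep(c("chr1", "chr2"), each = 40),
                     cds = vapply(1:80, function(i)
                       paste0(back_translate(rand_protein(40)), "TAA"),
                       character(1)),
                     stringsAsFactors = FALSE)
    rg <- data.frame(gene_id = sprintf("r%d", seq_len(length(gaps) + 1)),
                     type = "rgene", cluster_id = "clA",
                     chromosome = NA_character_,
                     cds = vapply(seq_len(length(gaps) + 1), function(i)
                       paste0(back_translate(rand_protein(60)), "TGA"),
                       character(1)),
                     stringsAsFactors = FALSE)
    rbind(bg, rg)
  }
  set.seed(27)
  lay8 <- layout_genome(mk_genes(c(8L, 8L)), cfg,
                        spacings = list(clA = c(8L, 8L)))
  cl8 <- call_clusters(lay8$genes, sprintf("r%d", 1:3))
  expect_identical(sort(unique(cl8$size[startsWith(cl8$gene_id, "r")])), 3L)
  expect_length(unique(cl8$cluster_id), 1L)

  set.seed(27)
  lay9 <- layout_genome(mk_genes(c(9L, 9L)), cfg,
                        spacings = list(clA = c(9L, 9L)))
  cl9 <- call_clusters(lay9$genes, sprintf("r%d", 1:3))
  expect_true(all(cl9$size == 1L))
})

test_that("genome embeds each cds at its recorded coordinates", {
  sim <- small_sim()
  g <- sim$genes
  set.seed(28)
  for (i in sample(nrow(g), 25)) {
    emb <- substring(sim$genomes[[g$species[i]]][[g$chromosome[i]]],
                     g$start[i], g$end[i])
    if (g$strand[i] == "-") emb <- reverse_complement(emb)
    expect_identical(emb, g$cds[i])
  }
})

test_that("planted defects have exactly the named lesion", {
  set.seed(29)
  bp <- build_domain_protein("NBS-LRR")
  gene <- list(cds = paste0(back_translate(bp$protein), "TGA"),
               domains = bp$domains)

  ps <- plant_defects(gene, "Pseudo-premature-stop")
  aa <- translate(ps$cds)
  expect_true(grepl("\\*", substring(aa, 1, nchar(aa) - 1)))
  expect_identical(ps$structure_truth, "Pseudo")

  ls <- plant_defects(gene, "LackStart")
  expect_false(startsWith(ls$cds, "ATG"))
  expect_identical(nchar(ls$cds) %% 3L, 0L)

  id <- plant_defects(gene, "InDel")
  expect_identical(nchar(id$cds) %% 3L, 0L)
  aa2 <- translate(id$cds)
  expect_false(grepl("\\*", substring(aa2, 1, nchar(aa2) - 1)))
  expect_identical(nchar(id$cds), nchar(gene$cds) - 27L)

  fs <- plant_defects(gene, "Pseudo-frameshift")
  expect_identical(nchar(fs$cds) %% 3L, 2L)

  short <- list(cds = paste0("ATG", back_translate("AAAAA"), "TGA"),
                domains = NULL)
  expect_error(plant_defects(short, "InDel"), "too short")
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- small_config()
  set.seed(77)
  s1 <- simulate_dataset(cfg)
  set.seed(77)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$genomes, s2$genomes)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(s1, d1)
  write_dataset(s2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})
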