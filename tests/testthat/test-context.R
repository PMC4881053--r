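mk_table <- function(ranks, chromosome = "chr1") {
  data.frame(gene_id = sprintf("g%03d", seq_along(ranks)),
             chromosome = chromosome, rank = ranks,
             start = 1000L * (ranks + 1L), end = 1000L * (ranks + 1L) + 500L,
             stringsAsFactors = FALSE)
}

test_that("cluster chaining honours the eight-intervening-gene rule", {
  tab <- mk_table(0:30)
  r_at <- function(ranks) tab$gene_id[tab$rank %in% ranks]

  cl <- call_clusters(tab, r_at(c(10, 19)))      # 8 intervening: one cluster
  expect_identical(unique(cl$size), 2L)

  cl2 <- call_clusters(tab, r_at(c(10, 20)))     # 9 intervening: singletons
  expect_true(all(cl2$size == 1L))

  cl3 <- call_clusters(tab, r_at(c(0, 9, 18)))   # chained transitively
  expect_identical(unique(cl3$size), 3L)
  expect_length(unique(cl3$cluster_id), 1L)

  expect_error(call_clusters(tab, "nope"), "absent")
})

test_that("cluster calling is invariant under coordinate reversal", {
  set.seed(41)
  tab <- mk_table(0:40)
  rg <- tab$gene_id[tab$rank %in% c(3, 8, 25, 39)]
  cl_fwd <- call_clusters(tab, rg)
  rev_tab <- tab
  rev_tab$start <- max(tab$end) - tab$end
  rev_tab$end <- max(tab$end) - tab$start + 500L
  rev_tab$end <- rev_tab$start + 500L
  rev_tab <- assign_ranks(rev_tab[, c("gene_id", "chromosome", "start", "end")])
  cl_rev <- call_clusters(rev_tab, rg)
  sig <- function(cl) {
    s <- split(cl$gene_id, cl$cluster_id)
    unname(lapply(s[order(vapply(s, min, character(1)))], sort))
  }
  expect_identical(sig(cl_fwd), sig(cl_rev))
  # partition: sizes sum to total R genes
  expect_identical(sum(unique(cl_fwd[, c("cluster_id", "size")])$size),
                   length(rg))
})

test_that("CIP is identity over aligned length with boundary at 60", {
  seg <- data.frame(q_start = c(1, 101), q_end = c(80, 120),
                    n_identical = c(50, 10), aligned_length = c(80, 20))
  expect_equal(compute_cip(seg), 60)
  one <- data.frame(q_start = 1, q_end = 50, n_identical = 45,
                    aligned_length = 50)
  expect_equal(compute_cip(one), 90)
  perfect <- data.frame(q_start = 1, q_end = 100, n_identical = 100,
                        aligned_length = 100)
  expect_equal(compute_cip(perfect), 100)
  expect_equal(compute_cip(one[0, ]), 0)
})

test_that("ortholog assignment: RBH, tie-breaks, divergence cutoff", {
  set.seed(42)
  prots <- setNames(vapply(1:6, function(i) substring(rand_protein(151), 2),
                           character(1)), sprintf("p%d", 1:6))
  # identical proteomes: everything RBH at CIP 100
  pairs <- assign_orthologs(prots, setNames(prots, sprintf("q%d", 1:6)))
  self_pairs <- pairs[sub("p", "", pairs$gene_a) == sub("q", "", pairs$gene_b), ]
  expect_identical(nrow(self_pairs), 6L)
  expect_true(all(self_pairs$rbh))
  expect_true(all(self_pairs$cip == 100))

  # duplicated gene in species a: only the lexicographically first copy
  # is the RBH partner
  dup <- c(prots, a_copy1 = unname(prots["p1"]), a_copy0 = unname(prots["p1"]))
  dup <- dup[!names(dup) %in% "p1"]
  pairs2 <- assign_orthologs(dup, setNames(prots, sprintf("q%d", 1:6)))
  hits1 <- pairs2[pairs2$gene_b == "q1" & pairs2$rbh, ]
  expect_identical(hits1$gene_a, "a_copy0")

  # diverged beyond CIP 60: pair absent
  far <- setNames(mutate_protein(prots[["p1"]], 0.55), "far1")
  pairs3 <- assign_orthologs(far, prots["p1"])
  expect_true(nrow(pairs3) == 0L || all(pairs3$cip > 60))
  if (nrow(pairs3) > 0) expect_false(any(pairs3$cip <= 60))
})

test_that("chromosome anchoring follows plurality with score tie-break", {
  ga <- data.frame(gene_id = sprintf("a%d", 1:10),
                   chromosome = rep(c("A1", "A2"), each = 5))
  gb <- data.frame(gene_id = sprintf("b%d", 1:10),
                   chromosome = rep(c("B1", "B2"), each = 5))
  pairs <- data.frame(gene_a = sprintf("a%d", 1:5),
                      gene_b = c("b1", "b2", "b3", "b6", "b7"),
                      score = 100)
  anc <- anchor_chromosomes(pairs, ga, gb)
  expect_identical(anc$anchor[anc$chromosome == "A1"], "B1")  # 3 vs 2
  expect_false(anc$assigned[anc$chromosome == "A2"])

  none <- anchor_chromosomes(pairs[0, ], ga, gb)
  expect_true(all(!none$assigned))
})

test_that("R-locus mapping needs three supporting syntenic pairs", {
  ga <- mk_table(0:30)
  gb <- mk_table(0:30, chromosome = "B1")
  gb$gene_id <- sub("g", "h", gb$gene_id)
  mk_pairs <- function(n) data.frame(
    gene_a = ga$gene_id[2:(1 + n)], gene_b = gb$gene_id[2:(1 + n)],
    score = 100)
  rc <- data.frame(gene_id = ga$gene_id[ga$rank == 10])
  expect_true(map_r_loci(rc, mk_pairs(3), ga, gb)$mapped)
  expect_false(map_r_loci(rc, mk_pairs(2), ga, gb)$mapped)
  expect_false(map_r_loci(rc, mk_pairs(0)[0, ], ga, gb)$mapped)
  m <- map_r_loci(rc, mk_pairs(5), ga, gb)
  expect_identical(m$target_chromosome, "B1")
  expect_identical(m$synteny_value, 5L)
})

test_that("planted clusters are recovered exactly on simulated data", {
  sim <- small_sim()
  for (sp in sim$species[c(1, 5)]) {
    g <- sim$genes[sim$genes$species == sp & sim$genes$annotated, ]
    g <- assign_ranks(g)
    rg <- g$gene_id[g$type == "rgene"]
    cl <- call_clusters(g, rg)
    # truth: annotated members of each planted cluster
    truth <- split(g$gene_id[!is.na(g$cluster_id)],
                   g$cluster_id[!is.na(g$cluster_id)])
    truth <- truth[vapply(truth, length, integer(1)) >= 2]
    got <- split(cl$gene_id, cl$cluster_id)
    got <- got[vapply(got, length, integer(1)) >= 2]
    canon <- function(x) unname(lapply(x[order(vapply(x, min, character(1)))],
                                       sort))
    expect_identical(canon(got), canon(truth))
  }
})
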