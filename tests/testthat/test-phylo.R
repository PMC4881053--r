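test_that("single-copy filter keeps exactly one-per-species families", {
  fm <- list(
    counts = rbind(F1 = c(a = 1L, b = 1L, c = 1L),
                   F2 = c(a = 1L, b = 0L, c = 1L),
                   F3 = c(a = 2L, b = 1L, c = 1L)),
    members = list(F1 = c("a1", "b1", "c1"), F2 = c("a2", "c2"),
                   F3 = c("a3", "a4", "b3", "c3")))
  sc <- single_copy_families(fm)
  expect_identical(names(sc$members), "F1")
})

test_that("center-star alignment handles insertions and back-translates exactly", {
  set.seed(61)
  base <- substring(rand_protein(61), 2)
  ins <- paste0(substring(base, 1, 30), "W", substring(base, 31))
  prots <- c(s1 = base, s2 = base, s3 = ins)
  cds <- vapply(prots, back_translate, character(1))
  aln <- align_family(prots, cds)
  expect_length(unique(nchar(aln$aa)), 1L)
  # the insertion shows as a single gap column in the other sequences
  expect_identical(sum(strsplit(aln$aa[["s1"]], "")[[1]] == "-"), 1L)
  expect_identical(sum(strsplit(aln$aa[["s3"]], "")[[1]] == "-"), 0L)
  # back-translation preserves every codon
  for (id in names(prots)) {
    expect_identical(gsub("-", "", aln$codon[[id]]), cds[[id]])
  }
  # identical sequences align gap-free
  aln2 <- align_family(c(x = base, y = base), c(x = cds[[1]], y = cds[[1]]))
  expect_false(any(grepl("-", aln2$aa)))
  expect_error(align_family(c(x = base, y = base),
                            c(x = cds[[1]], y = substring(cds[[1]], 4))),
               "mismatch")
})

test_that("4D extraction requires conserved fourfold prefixes", {
  aln <- c(s1 = paste0("GGA", "ATG", "GGA", "CCT"),
           s2 = paste0("GGG", "ATG", "GAA", "CCA"),
           s3 = paste0("GGT", "ATG", "GGC", "CCG"))
  sites <- extract_4d_sites(aln)
  # column 1: GG- prefix conserved (4D) -> A,G,T ; column 2: ATG not 4D;
  # column 3: prefix differs (GG vs GA); column 4: CC- conserved -> T,A,G
  expect_identical(unname(sites), c("AT", "GA", "TG"))
  # order independence across families / columns
  perm <- c(s1 = paste0("CCT", "GGA"), s2 = paste0("CCA", "GGG"),
            s3 = paste0("CCG", "GGT"))
  expect_identical(unname(extract_4d_sites(perm)), c("TA", "AG", "GT"))
})

test_that("K2P matches the closed form and flags saturation", {
  a <- strrep("A", 100)
  expect_equal(k2p_distance(a, a)$distance, 0)
  # 10 transitions (A->G), 5 transversions (A->C) in 100 sites
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  r <- k2p_distance(a, b)
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0.05)
  expect_equal(r$distance, 0.170181, tolerance = 1e-5)
  expect_equal(r$distance,
               -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05),
               tolerance = 1e-9)
  # P=0.45, Q=0.1 saturates the first log argument
  c_ <- paste0(strrep("G", 45), strrep("C", 10), strrep("A", 45))
  expect_true(k2p_distance(a, c_)$saturated)
  # K2P equals JC when transitions:transversions are 1:2
  p <- 0.3
  d <- paste0(strrep("G", 10), strrep("C", 10), strrep("T", 10),
              strrep("A", 70))
  r2 <- k2p_distance(a, d)
  expect_equal(r2$distance, jc_correct(p), tolerance = 1e-9)
})

test_that("NJ recovers additive matrices exactly and clamps negatives", {
  set.seed(62)
  for (n in 4:8) {
    tr <- ape::rtree(n)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
    D <- stats::cophenetic(tr)
    nj <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0)
    expect_lt(max(abs(stats::cophenetic(nj)[rownames(D), colnames(D)] - D)),
              1e-9)
  }
  # equal distances: star resolution, internal branches ~ 0
  De <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(De) <- 0
  st <- nj_tree(De)
  internal <- st$edge[, 2] > length(st$tip.label)
  expect_true(all(st$edge.length[internal] < 1e-9))
  expect_true(all(st$edge.length >= 0))
  expect_error(nj_tree(De[1:2, 1:2]), "3 taxa")
})

test_that("NJ agrees with an ultrametric UPGMA oracle and with ape", {
  set.seed(63)
  # ultrametric (coalescent) tree: NJ topology equals the UPGMA topology
  tr <- ape::rcoal(6)
  D <- stats::cophenetic(tr)
  nj <- nj_tree(D)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  up <- ape::as.phylo(hc)
  expect_equal(as.numeric(ape::dist.topo(nj, ape::unroot(up))), 0)
  # agreement with ape::nj on noisy matrices
  for (i in 1:5) {
    tr2 <- ape::rtree(7)
    tr2$edge.length <- stats::runif(nrow(tr2$edge), 0.05, 0.4)
    D2 <- stats::cophenetic(tr2)
    noise <- matrix(stats::runif(49, 0, 0.01), 7, 7)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    D2n <- D2 + noise
    expect_equal(as.numeric(ape::dist.topo(nj_tree(D2n), ape::nj(D2n))), 0)
  }
})

test_that("NJ recovers simulated topologies at 10k sites", {
  set.seed(64)
  tree <- ape::read.tree(text = default_species_tree())
  L <- 10000L
  hits <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    seqs <- setNames(rep(NA_character_, max(tree$edge)), NULL)
    bases <- c("A", "C", "G", "T")
    root <- length(tree$tip.label) + 1L
    seqs[root] <- paste(sample(bases, L, TRUE), collapse = "")
    tr <- stats::reorder(tree)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      v <- strsplit(seqs[par], "")[[1]]
      k <- stats::rbinom(1, L, tr$edge.length[e])
      if (k > 0) {
        pos <- sample(L, k)
        v[pos] <- vapply(v[pos], function(x) sample(setdiff(bases, x), 1), "")
      }
      seqs[ch] <- paste(v, collapse = "")
    }
    tips <- setNames(seqs[seq_along(tree$tip.label)], tree$tip.label)
    nj <- nj_tree(k2p_matrix(tips))
    if (as.numeric(ape::dist.topo(ape::unroot(tree), nj)) == 0)
      hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("bootstrap gives full support without homoplasy, reproducibly", {
  set.seed(65)
  tree <- ape::read.tree(text = "(((a,b),(c,d)),(e,f));")
  # dedicated diagnostic sites per clade: zero homoplasy
  clades <- list(c("a", "b"), c("c", "d"), c("a", "b", "c", "d"),
                 c("e", "f"))
  tips <- tree$tip.label
  L <- 1000L                      # 25 diagnostic sites per clade, rest constant
  m <- matrix("A", length(tips), L, dimnames = list(tips, NULL))
  for (i in seq_along(clades)) {
    cols <- ((i - 1L) * 25L + 1L):(i * 25L)
    m[clades[[i]], cols] <- "G"
  }
  seqs <- apply(m, 1, paste, collapse = "")
  bs <- bootstrap_support(seqs, n_replicates = 50, seed = 9)
  expect_true(all(bs$support == 100))
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  bs2 <- bootstrap_support(seqs, n_replicates = 50, seed = 9)
  expect_identical(bs$support, bs2$support)
})

test_that("rate comparison is a branch-length ratio with linear scaling", {
  tr <- ape::rtree(5)
  tr$edge.length <- rep(0.1, nrow(tr$edge))
  expect_equal(compare_rates(tr, tr)$ratio, 1)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 3
  expect_equal(compare_rates(tr2, tr)$ratio, 3)
  expect_equal(unname(compare_rates(tr2, tr)$per_leaf), rep(3, 5))
  tr0 <- tr
  tr0$edge.length <- rep(0, nrow(tr$edge))
  expect_error(compare_rates(tr, tr0), "zero")
})
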