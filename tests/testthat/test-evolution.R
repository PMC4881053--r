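test_that("MCL separates disconnected blocks, invariant to order and scale", {
  block <- function(n) matrix(0.8, n, n) - diag(0.8, n) + diag(0, n)
  w <- matrix(0, 7, 7)
  w[1:3, 1:3] <- block(3)
  w[4:7, 4:7] <- block(4)
  cl <- mcl(w)
  expect_length(cl, 2)
  expect_setequal(cl[[1]], 1:3)
  expect_setequal(cl[[2]], 4:7)
  # uniform scaling of weights does not change the clustering
  expect_identical(mcl(w * 5), cl)
  # input order invariance
  perm <- c(4, 1, 6, 2, 7, 3, 5)
  clp <- mcl(w[perm, perm])
  back <- lapply(clp, function(x) sort(perm[x]))
  expect_setequal(lapply(back, paste, collapse = ","),
                  lapply(cl, paste, collapse = ","))
})

test_that("families from similarity recover planted memberships", {
  sim <- small_sim()
  g <- sim$genes[sim$genes$type == "rgene" & sim$genes$annotated, ]
  proteomes <- lapply(split(g, g$species), function(d)
    setNames(d$protein, d$gene_id))
  fm <- build_families(proteomes)
  truth <- setNames(g$family_id, g$gene_id)
  # every inferred family maps to exactly one planted family and the
  # partition matches
  for (m in fm$members) {
    expect_length(unique(truth[m]), 1L)
  }
  got_sizes <- sort(vapply(fm$members, length, integer(1)))
  want_sizes <- sort(unname(table(truth)))
  expect_identical(as.integer(got_sizes), as.integer(want_sizes))
  # a single weak edge below the E-value threshold keeps families split
  p1 <- setNames(vapply(1:2, function(i) substring(rand_protein(161), 2),
                        character(1)), c("x1", "x2"))
  p2 <- setNames(c(p1[[1]], substring(rand_protein(161), 2)), c("y1", "y2"))
  fm2 <- build_families(list(a = p1, b = p2), evalue = 1e-300)
  expect_length(fm2$members, 4L)
})

test_that("Sankoff reconstruction matches exhaustive search on small trees", {
  set.seed(71)
  for (rep in 1:12) {
    n <- sample(3:5, 1)
    tr <- ape::rtree(n)
    counts <- matrix(sample(0:4, n, replace = TRUE), nrow = 1,
                     dimnames = list(NULL, tr$tip.label))
    smax <- max(counts)
    rec <- reconstruct_counts(counts, tr)
    oracle <- oracle_sankoff(tr, counts[1, ], smax)
    got_cost <- sum(rec$branch_events$gain + rec$branch_events$loss)
    expect_identical(as.numeric(got_cost), as.numeric(oracle$cost))
    root <- length(tr$tip.label) + 1L
    expect_identical(as.numeric(rec$node_states[1, root]),
                     as.numeric(oracle$min_root))
  }
})

test_that("Sankoff honours the documented examples and conservation", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  flat <- reconstruct_counts(
    matrix(c(2L, 2L, 2L), 1, dimnames = list(NULL, c("A", "B", "C"))), tr)
  expect_true(all(flat$node_states == 2L))
  expect_true(all(flat$branch_events$gain + flat$branch_events$loss == 0L))

  rec <- reconstruct_counts(
    matrix(c(2L, 2L, 0L), 1, dimnames = list(NULL, c("A", "B", "C"))), tr)
  expect_identical(rec$node_states[1, 4], 0L)   # root, smallest-tie rule
  expect_identical(rec$node_states[1, 5], 2L)   # (A,B) ancestor
  stem <- rec$branch_events[rec$branch_events$child == 5, ]
  expect_identical(stem$gain, 2L)
  # conservation: leaf = root + path sums
  for (leaf in 1:3) {
    path <- 0L
    node <- leaf
    while (node != 4) {
      e <- rec$branch_events[rec$branch_events$child == node, ]
      path <- path + e$net
      node <- e$parent
    }
    expect_identical(rec$node_states[1, leaf], rec$node_states[1, 4] + path)
  }
})

test_that("NG86 equals brute-force pathway enumeration", {
  set.seed(72)
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (case in 1:60) {
    a <- paste(sample(codons, 50, replace = TRUE), collapse = "")
    b <- paste(sample(codons, 50, replace = TRUE), collapse = "")
    got <- ng86(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$N, want$N, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
    expect_equal(got$S + got$N, 3 * got$L)
    # symmetry
    rev <- ng86(b, a)
    expect_equal(rev$Sd, got$Sd, tolerance = 1e-12)
    expect_equal(rev$Nd, got$Nd, tolerance = 1e-12)
  }
})

test_that("NG86 handles the canonical single-codon cases", {
  r <- ng86("TTT", "TTC")
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$S, 1 / 3)
  same <- ng86("ATGAAA", "ATGAAA")
  expect_equal(same$pS, 0)
  expect_equal(same$pN, 0)
  expect_false(same$defined)
  expect_true(is.na(same$ratio))
  expect_error(ng86("---", "---"), "no ungapped")
})

test_that("Jukes-Cantor correction matches the closed form, monotone", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.3), 0.383119, tolerance = 1e-5)
  expect_equal(jc_correct(0.3), -0.75 * log(1 - 0.4), tolerance = 1e-12)
  p <- seq(0, 0.7, by = 0.05)
  d <- vapply(p, jc_correct, numeric(1))
  expect_true(all(diff(d) > 0))
  sat <- jc_correct(0.8)
  expect_true(is.na(sat))
  expect_true(attr(sat, "saturated"))
})

test_that("codon alignment is codon-atomic with gaps at insertions", {
  set.seed(73)
  p <- substring(rand_protein(81), 2)
  cds1 <- paste0(back_translate(p), "TGA")
  ins <- paste0(substring(p, 1, 40), "W", substring(p, 41))
  cds2 <- paste0(back_translate(ins), "TGA")
  al <- codon_align_pair(cds1, cds2)
  expect_identical(nchar(al$a), nchar(al$b))
  expect_identical(nchar(al$a) %% 3L, 0L)
  expect_identical(gsub("---", "", al$a, fixed = TRUE),
                   sub("TGA$", "", cds1))
  gap_runs <- gregexpr("-+", al$a)[[1]]
  expect_identical(attr(gap_runs, "match.length"), 3L)
  al2 <- codon_align_pair(cds1, cds1)
  expect_false(grepl("-", al2$a))
  bad <- paste0("ATG", "TAA", "GCTTGA")
  expect_error(codon_align_pair(bad, cds1), "internal stop")
})

test_that("Dxy is the JC-corrected mean difference proportion", {
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 30), strrep("A", 70))
  expect_equal(dxy(list(list(a = a, b = a))), 0)
  expect_equal(dxy(list(list(a = a, b = b))), jc_correct(0.3))
  # brute-force average over two pairs
  c_ <- paste0(strrep("G", 10), strrep("A", 90))
  got <- dxy(list(list(a = a, b = b), list(a = a, b = c_)))
  expect_equal(got, jc_correct(0.2), tolerance = 1e-12)
})

test_that("selection bins follow the published thresholds", {
  res <- data.frame(pair = c("p1", "p2", "p3", "p4", "p5"),
                    ratio = c(0.10, 0.90, 1.50, 0.25, NA))
  cl <- classify_selection(res)
  expect_identical(cl$table$bin,
                   c("purifying", "candidate", "positive", "intermediate",
                     NA))
  expect_identical(unname(cl$counts["undefined"]), 1L)
  expect_identical(sum(cl$counts[c("purifying", "intermediate", "candidate",
                                   "positive")]),
                   sum(!is.na(res$ratio)))
})
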