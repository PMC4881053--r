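test_that("FASTA round trip preserves ids and sequences, wrapped at 60", {
  recs <- c(a = "MKV", b = paste(rep("ACDEFGHIKL", 13), collapse = ""),
            c = "WWWW")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  lines <- readLines(f)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_fasta(f)
  expect_identical(back, recs)
})

test_that("FASTA reader handles degenerate and malformed input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(">a\nMKV", f)
  expect_identical(read_fasta(f), c(a = "MKV"))

  writeLines(character(0), f)
  expect_warning(out <- read_fasta(f), "empty")
  expect_length(out, 0)

  writeLines(c("MKV", ">a", "MKV"), f)
  expect_error(read_fasta(f), "line 1")
})

test_that("GFF3 ranks are start-order permutations per chromosome", {
  g <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    species = "sp",
    chromosome = c("chr1", "chr1", "chr2", "chr2"),
    start = c(100L, 50L, 10L, 500L),
    end = c(200L, 80L, 40L, 700L),
    strand = c("+", "-", "+", "+"))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g, f)
  got <- read_gff3(f)
  expect_equal(got$rank[match(c("g1", "g2"), got$gene_id)], c(1L, 0L))
  expect_equal(sort(got$rank[got$chromosome == "chr2"]), 0:1)
  expect_identical(got$strand[match("g2", got$gene_id)], "-")
})

test_that("GFF3 reader rejects bad coordinates and strands", {
  g <- data.frame(gene_id = "g1", species = "sp", chromosome = "chr1",
                  start = 100L, end = 50L, strand = "+")
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g, f)
  expect_error(read_gff3(f), "end < start")

  g$end <- 200L
  g$strand <- "?"
  write_gff3(g, f)
  expect_error(read_gff3(f), "strand")
})

test_that("rank assignment is stable under shuffling and idempotent", {
  set.seed(5)
  g <- data.frame(gene_id = sprintf("g%02d", 1:20),
                  chromosome = rep(c("c1", "c2"), 10),
                  start = sample(1000, 20))
  r1 <- assign_ranks(g)
  r2 <- assign_ranks(g[sample(nrow(g)), ])
  expect_identical(r1[order(r1$gene_id), ], r2[order(r2$gene_id), ])
  r3 <- assign_ranks(r1)
  expect_identical(r1$rank[order(r1$gene_id)], r3$rank[order(r3$gene_id)])
  # ties on start break by gene_id
  tie <- data.frame(gene_id = c("b", "a"), chromosome = "c1",
                    start = c(10L, 10L))
  rt <- assign_ranks(tie)
  expect_equal(rt$rank[match(c("a", "b"), rt$gene_id)], c(0L, 1L))
})

test_that("translation follows the standard code with stops and ambiguity", {
  expect_identical(translate("ATGGCTTAA"), "MA*")
  expect_identical(translate("ATGGCTTAA", 1), "WL")
  expect_identical(translate("ATGNNN"), "MX")
  expect_identical(nchar(translate("ATGGCTTA", 0)), 2L)
})

test_that("six-frame translation matches a per-codon oracle", {
  set.seed(42)
  for (rep in 1:5) {
    s <- rand_dna(300)
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                collapse = "")
    fr <- translate_six_frames(s)
    for (f in 0:2) {
      expect_identical(fr[[f + 1]], oracle_translate(s, f))
      expect_identical(fr[[f + 4]], oracle_translate(rc, f))
    }
  }
})

test_that("local alignment scores equal an affine Smith-Waterman oracle", {
  set.seed(7)
  mat <- rgevo:::.blosum62()
  for (rep in 1:20) {
    a <- substring(rand_protein(12), 2)   # drop leading M for variety
    b <- substring(rand_protein(12), 2)
    got <- align_local(a, b)$raw_score
    want <- oracle_sw(a, b, mat)
    expect_equal(got, want, tolerance = 1e-9)
    expect_equal(align_local(b, a)$raw_score, got, tolerance = 1e-9)
  }
})

test_that("self alignment is perfect; unrelated is near zero", {
  r <- align_local(c(q = "MKVLLR"), c(s = "MKVLLR"))
  expect_equal(r$normalized_score, 1)
  expect_equal(r$segments$n_identical, 6L)
  r2 <- align_local("MKV", "QQQ")
  expect_lt(r2$normalized_score, 0.2)
})

test_that("exact substring alignment scores the matrix diagonal sum", {
  set.seed(8)
  mat <- rgevo:::.blosum62()
  q <- substring(rand_protein(31), 2)     # 30-aa query
  subj <- paste0(substring(rand_protein(21), 2), q,
                 substring(rand_protein(21), 2))
  aa <- strsplit(q, "")[[1]]
  want <- sum(mat[cbind(aa, aa)])
  expect_gte(align_local(q, subj)$raw_score, want)
  expect_equal(align_local(q, q)$raw_score, want)
})

test_that("six-frame search locates planted loci on both strands", {
  set.seed(9)
  q <- substring(rand_protein(41), 2)     # 40 aa
  planted <- back_translate(q)
  genome <- paste0(rand_dna(300), planted, rand_dna(300))
  hits <- search_six_frame(c(q = q), genome,
                           align_params(evalue_threshold = 1e-5))
  expect_gt(length(hits), 0)
  top <- hits[[1]]
  expect_true(startsWith(top$frame, "+"))
  expect_lte(top$g_start, 301 + 2)
  expect_gte(top$g_end, 300 + nchar(planted) - 2)

  genome_rc <- paste0(rand_dna(150),
                      reverse_complement(planted), rand_dna(150))
  hits_rc <- search_six_frame(c(q = q), genome_rc,
                              align_params(evalue_threshold = 1e-5))
  expect_true(startsWith(hits_rc[[1]]$frame, "-"))
  expect_lte(hits_rc[[1]]$g_start, 151 + 2)

  none <- search_six_frame(c(q = q), rand_dna(600),
                           align_params(evalue_threshold = 1e-20))
  expect_length(none, 0)
})
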