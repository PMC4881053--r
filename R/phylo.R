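# Supergene phylogenetics: single-copy family selection, center-star
# protein alignment back-translated to codons, four-fold degenerate site
# extraction, Kimura two-parameter distances, neighbor joining (with the
# package's negative-branch handling), column bootstrap, and divergence
# rate comparison between gene cohorts.

#' Select families with exactly one member in every listed species
#'
#' @param fm family matrix from [build_families()] (list with counts and
#'   members).
#' @param species species to require.
#' @return fm restricted to strictly single-copy families.
#' @export
single_copy_families <- function(fm, species = colnames(fm$counts)) {
  cnt <- fm$counts[, species, drop = FALSE]
  keep <- apply(cnt, 1L, function(x) all(x == 1L))
  list(counts = fm$counts[keep, , drop = FALSE],
       members = fm$members[keep])
}

# ---- center-star multiple alignment ---------------------------------------

# Merge a new pairwise alignment (center row cst, other row oth) into a
# growing master center string; returns updated master plus re-gapped rows.
.merge_into <- function(master_center, rows, cst, oth) {
  mc <- strsplit(master_center, "")[[1]]
  cc <- strsplit(cst, "")[[1]]
  oo <- strsplit(oth, "")[[1]]
  new_center <- character(0)
  new_rows <- lapply(rows, function(r) character(0))
  new_oth <- character(0)
  i <- 1L; j <- 1L
  rows_split <- lapply(rows, function(r) strsplit(r, "")[[1]])
  while (i <= length(mc) || j <= length(cc)) {
    a <- if (i <= length(mc)) mc[i] else NA
    b <- if (j <= length(cc)) cc[j] else NA
    if (!is.na(a) && a == "-" && (is.na(b) || b != "-")) {
      # master has a gap column the new alignment lacks
      new_center <- c(new_center, "-")
      for (k in seq_along(new_rows))
        new_rows[[k]] <- c(new_rows[[k]], rows_split[[k]][i])
      new_oth <- c(new_oth, "-")
      i <- i + 1L
    } else if (!is.na(b) && b == "-" && (is.na(a) || a != "-")) {
      # new alignment inserts a gap into the center
      new_center <- c(new_center, "-")
      for (k in seq_along(new_rows))
        new_rows[[k]] <- c(new_rows[[k]], "-")
      new_oth <- c(new_oth, oo[j])
      j <- j + 1L
    } else {
      new_center <- c(new_center, a)
      for (k in seq_along(new_rows))
        new_rows[[k]] <- c(new_rows[[k]], rows_split[[k]][i])
      new_oth <- c(new_oth, oo[j])
      i <- i + 1L; j <- j + 1L
    }
  }
  list(center = paste(new_center, collapse = ""),
       rows = lapply(new_rows, paste, collapse = ""),
       oth = paste(new_oth, collapse = ""))
}

#' Center-star multiple alignment, back-translated to codons
#'
#' The center sequence maximises the summed pairwise global alignment
#' scores; every other sequence is aligned to the center and merged
#' ("once a gap, always a gap"). Each aligned residue is then replaced by
#' its source codon (gaps become \code{---}), so the codon alignment is
#' codon-atomic and exact by construction.
#'
#' @param proteins named amino-acid vector (no stops).
#' @param cds_list named CDS vector matching \code{proteins} (terminal
#'   stop codon allowed and ignored).
#' @param params alignment parameters.
#' @return list with aa (named aligned protein strings) and codon (named
#'   aligned codon strings).
#' @export
align_family <- function(proteins, cds_list, params = align_params()) {
  stopifnot(length(proteins) >= 2L, all(names(proteins) %in% names(cds_list)))
  for (id in names(proteins)) {
    body <- sub("(TAA|TAG|TGA)$", "", cds_list[[id]])
    if (nchar(body) != 3L * nchar(proteins[[id]]))
      stop("CDS/protein length mismatch for ", id)
  }
  n <- length(proteins)
  ids <- names(proteins)
  glob <- function(a, b) Biostrings::pairwiseAlignment(
    Biostrings::AAString(.clean_aa(a)), Biostrings::AAString(.clean_aa(b)),
    type = "global", substitutionMatrix = .blosum62(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  scores <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- Biostrings::score(glob(proteins[i], proteins[j]))
    scores[i, j] <- s; scores[j, i] <- s
  }
  center <- which.max(rowSums(scores))
  master <- proteins[[center]]
  aligned <- list()
  order_others <- setdiff(seq_len(n), center)
  for (o in order_others) {
    aln <- glob(proteins[center], proteins[o])
    cst <- as.character(Biostrings::alignedPattern(aln))
    oth <- as.character(Biostrings::alignedSubject(aln))
    m <- .merge_into(master, aligned, cst, oth)
    master <- m$center
    aligned <- m$rows
    aligned[[length(aligned) + 1L]] <- m$oth
  }
  aa <- c(list(master), aligned)
  names(aa) <- ids[c(center, order_others)]
  aa <- aa[ids]
  codon <- lapply(ids, function(id) {
    cods <- .codons(sub("(TAA|TAG|TGA)$", "", cds_list[[id]]))
    chars <- strsplit(aa[[id]], "")[[1]]
    out <- character(length(chars))
    k <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- cods[k] }
    }
    paste(out, collapse = "")
  })
  names(codon) <- ids
  list(aa = unlist(aa), codon = unlist(codon))
}

# 4-fold degenerate codon-family prefixes.
.FOURFOLD_PREFIXES <- c("TC", "CT", "CC", "CG", "AC", "GT", "GC", "GG")

#' Extract four-fold degenerate sites from a codon alignment
#'
#' A codon column contributes its third positions when the column is
#' gap-free, all species share identical first two codon positions, and
#' that prefix belongs to a four-fold degenerate codon family.
#'
#' @param codon_aln named equal-length codon strings.
#' @return named vector of per-species 4D-site nucleotide strings (equal
#'   lengths; possibly empty strings).
#' @export
extract_4d_sites <- function(codon_aln) {
  lens <- nchar(codon_aln)
  stopifnot(length(unique(lens)) == 1L, lens[1] %% 3L == 0L)
  nc <- lens[1] %/% 3L
  mats <- lapply(codon_aln, .codons)
  keep <- logical(nc)
  for (i in seq_len(nc)) {
    col <- vapply(mats, `[`, character(1), i)
    if (any(grepl("[^ACGT]", col))) next
    pre <- substring(col, 1L, 2L)
    if (length(unique(pre)) == 1L && pre[1] %in% .FOURFOLD_PREFIXES)
      keep[i] <- TRUE
  }
  out <- vapply(mats, function(m)
    paste(substring(m[keep], 3L, 3L), collapse = ""), character(1))
  out
}

#' Concatenate per-family four-fold degenerate sites into a supergene
#'
#' For each family the member proteins are aligned (center-star), the
#' alignment is back-translated and 4D sites are extracted; sites are
#' concatenated across families in the given order.
#'
#' @param family_cds list of families; each a named (by species) CDS
#'   vector with one member per species.
#' @param params alignment parameters.
#' @return named per-species nucleotide strings (equal length).
#' @export
supergene_4d <- function(family_cds, params = align_params()) {
  stopifnot(length(family_cds) >= 1L)
  species <- names(family_cds[[1]])
  parts <- lapply(family_cds, function(cds) {
    stopifnot(setequal(names(cds), species))
    prots <- vapply(cds, function(x) sub("\\*$", "", translate(x)),
                    character(1))
    aln <- align_family(prots, cds, params)
    extract_4d_sites(aln$codon)[species]
  })
  out <- vapply(species, function(sp)
    paste(vapply(parts, `[[`, character(1), sp), collapse = ""),
    character(1))
  out
}

#' Kimura two-parameter distance
#'
#' \eqn{d = -\frac{1}{2}\ln(1 - 2P - Q) - \frac{1}{4}\ln(1 - 2Q)} with P
#' and Q the transition and transversion proportions over pairwise
#' comparable sites (gaps and ambiguous bases excluded pairwise).
#'
#' @param seq_a,seq_b equal-length nucleotide strings.
#' @return list with distance, P, Q, n_sites, saturated.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  stopifnot(nchar(seq_a) == nchar(seq_b))
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("no comparable sites")
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    return(list(distance = NA_real_, P = P, Q = Q, n_sites = n,
                saturated = TRUE))
  list(distance = -0.5 * log(arg1) - 0.25 * log(arg2), P = P, Q = Q,
       n_sites = n, saturated = FALSE)
}

#' Pairwise K2P distance matrix
#'
#' @param seqs named equal-length nucleotide strings.
#' @return symmetric matrix of distances (saturated pairs are NA).
#' @export
k2p_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- k2p_distance(seqs[[i]], seqs[[j]])$distance
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration. A negative branch length arising at a join
#' is clamped to zero with the deficit moved to its sister branch (their
#' sum is preserved); the terminal three-branch resolution clamps at zero
#' without redistribution.
#'
#' @param d symmetric distance matrix with dimnames, n >= 3.
#' @return ape phylo (unrooted).
#' @export
nj_tree <- function(d) {
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  stopifnot(!is.null(rownames(d)))
  if (any(is.na(d)))
    stop("distance matrix contains NA (saturated) entries")
  labels <- rownames(d)
  sub <- labels                       # newick fragments per active node
  D <- d
  while (length(sub) > 3L) {
    m <- length(sub)
    r <- rowSums(D)
    Qm <- (m - 2) * D - outer(r, r, `+`)
    diag(Qm) <- Inf
    ij <- which(Qm == min(Qm), arr.ind = TRUE)
    ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE][1L, ]
    i <- min(ij); j <- max(ij)
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    newsub <- sprintf("(%s:%.12g,%s:%.12g)", sub[i], bi, sub[j], bj)
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    sub <- c(sub[keep], newsub)
    D <- D2
  }
  b1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 sub[1], b1, sub[2], b2, sub[3], b3)
  ape::read.tree(text = nwk)
}

# Canonical unrooted bipartitions of a tree: for each internal edge, the
# sorted tip-label set on the side not containing the lexicographically
# smallest label (stable across trees with different tip orders).
.bipartitions <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  anchor <- min(labs)
  n <- length(labs)
  out <- character(0)
  for (p in pp) {
    if (length(p) <= 1L || length(p) >= n - 1L) next
    side <- labs[p]
    if (anchor %in% side) side <- setdiff(labs, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Bootstrap support for a supergene NJ tree
#'
#' Columns are resampled with replacement; per replicate a K2P distance
#' matrix and NJ tree are computed; support for each bipartition of the
#' original tree is the percentage of replicates containing it. The
#' resampling indices are all drawn up front from the master seed, so the
#' result is reproducible.
#'
#' @param seqs named equal-length nucleotide strings (e.g. 4D supergene).
#' @param n_replicates number of bootstrap replicates.
#' @param seed master RNG seed.
#' @return list with tree (original NJ tree) and support (named vector,
#'   bipartition -> percentage).
#' @export
bootstrap_support <- function(seqs, n_replicates = 100L, seed = 1L) {
  stopifnot(n_replicates >= 1L)
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1L, L > 0L)
  orig <- nj_tree(k2p_matrix(seqs))
  target <- .bipartitions(orig)
  counts <- setNames(rep(0L, length(target)), target)
  mats <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  set.seed(seed)
  idx_all <- matrix(sample.int(L, L * n_replicates, replace = TRUE),
                    nrow = n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    idx <- idx_all[rep_i, ]
    rs <- vapply(mats, function(m) paste(m[idx], collapse = ""), character(1))
    bt <- tryCatch(nj_tree(k2p_matrix(rs)), error = function(e) NULL)
    if (is.null(bt)) next
    bp <- .bipartitions(bt)
    hit <- target %in% bp
    counts[hit] <- counts[hit] + 1L
  }
  list(tree = orig, support = 100 * counts / n_replicates)
}

#' Compare divergence rates between two trees
#'
#' @param tree_a,tree_b ape phylo objects over the same leaf set.
#' @return list with ratio (total branch length of a over b) and
#'   per_leaf (named root-to-tip ratios).
#' @export
compare_rates <- function(tree_a, tree_b) {
  stopifnot(setequal(tree_a$tip.label, tree_b$tip.label))
  tot_b <- sum(tree_b$edge.length)
  if (tot_b == 0) stop("zero total branch length in denominator tree")
  depth <- function(tr) {
    d <- ape::node.depth.edgelength(tr)
    setNames(d[seq_along(tr$tip.label)], tr$tip.label)
  }
  da <- depth(tree_a); db <- depth(tree_b)
  list(ratio = sum(tree_a$edge.length) / tot_b,
       per_leaf = da[tree_a$tip.label] / db[tree_a$tip.label])
}
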