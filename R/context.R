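# Genomic context of R-genes: tandem cluster calling on gene-rank
# coordinates, CIP-based orthology with reciprocal best hits, anchoring of
# chromosomes to the out-group, and the synteny-supported R-locus map.

#' Call tandem R-gene clusters
#'
#' Single-linkage chaining on gene-order ranks: two R-genes on the same
#' chromosome belong to one cluster when no more than
#' \code{max_intervening} (8) genes lie between them.
#'
#' @param gene_table one species' gene table with gene_id, chromosome,
#'   rank (from [read_gff3()] / [assign_ranks()]).
#' @param r_gene_ids ids of the R-gene calls.
#' @param max_intervening cluster threshold (default 8 intervening genes).
#' @return data.frame with one row per R-gene: gene_id, chromosome, rank,
#'   cluster_id (chromosome-scoped), size (cluster size; 1 = singleton),
#'   span_start and span_end (member ranks).
#' @export
call_clusters <- function(gene_table, r_gene_ids, max_intervening = 8L) {
  missing <- setdiff(r_gene_ids, gene_table$gene_id)
  if (length(missing) > 0L)
    stop("R-gene ids absent from gene table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  r <- gene_table[gene_table$gene_id %in% r_gene_ids, , drop = FALSE]
  r <- r[order(r$chromosome, r$rank), , drop = FALSE]
  out <- list()
  for (ch in unique(r$chromosome)) {
    rc <- r[r$chromosome == ch, , drop = FALSE]
    gap_new <- c(TRUE, diff(rc$rank) - 1L > max_intervening)
    grp <- cumsum(gap_new)
    for (g in unique(grp)) {
      m <- rc[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        gene_id = m$gene_id, chromosome = ch, rank = m$rank,
        cluster_id = sprintf("%s_cl%02d", ch, g), size = nrow(m),
        span_start = min(m$rank), span_end = max(m$rank),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of R-genes in clusters (size >= 2)
#' @param clusters from [call_clusters()].
#' @return numeric fraction.
#' @export
clustered_fraction <- function(clusters) {
  if (nrow(clusters) == 0L) return(NA_real_)
  mean(clusters$size >= 2L)
}

#' Cumulative identity percentage over alignment segments
#'
#' CIP = 100 x (sum of identities) / (sum of aligned lengths) over the
#' retained segments; query-overlapping segments are resolved by keeping
#' the higher-identity segment.
#'
#' @param segments data.frame with q_start, q_end, n_identical,
#'   aligned_length.
#' @return percentage in [0, 100]; 0 when nothing aligned.
#' @export
compute_cip <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0L) return(0)
  segments <- segments[order(-segments$n_identical), , drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    clash <- any(vapply(kept, function(k)
      s$q_start <= k$q_end && s$q_end >= k$q_start, logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- s
  }
  kept <- do.call(rbind, kept)
  tot <- sum(kept$aligned_length)
  if (tot == 0) return(0)
  100 * sum(kept$n_identical) / tot
}

#' Ortholog/allele pairs between two proteomes
#'
#' All-vs-all local alignment (shared-k-mer prefilter); pairs are retained
#' when CIP > \code{cip_min} (60) and the E-value proxy is below
#' \code{evalue} (1e-10); a pair is flagged RBH when each gene is the
#' other's best hit (score, then E-value, then lexicographic id).
#'
#' @param prot_a,prot_b named protein vectors.
#' @param cip_min CIP retention threshold (exclusive).
#' @param evalue E-value retention threshold.
#' @param kmer_top candidates per query.
#' @param params alignment parameters.
#' @return data.frame gene_a, gene_b, score, evalue, cip, rbh.
#' @export
assign_orthologs <- function(prot_a, prot_b, cip_min = 60, evalue = 1e-10,
                             kmer_top = 5L, params = align_params()) {
  stopifnot(length(prot_a) > 0L, length(prot_b) > 0L)
  cand <- .kmer_candidates(prot_a, prot_b, top = kmer_top)
  rows <- list()
  for (i in seq_along(prot_a)) {
    for (j in cand[[i]]) {
      r <- align_local(prot_a[i], prot_b[j], params)
      seg <- r$segments
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = names(prot_a)[i], gene_b = names(prot_b)[j],
        score = r$raw_score, evalue = r$evalue_proxy,
        cip = compute_cip(seg), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), evalue = numeric(0),
                      cip = numeric(0), rbh = logical(0)))
  pairs <- do.call(rbind, rows)
  best_of <- function(df, key, other) {
    o <- order(df[[key]], -df$score, df$evalue, df[[other]])
    df <- df[o, , drop = FALSE]
    df[!duplicated(df[[key]]), c(key, other)]
  }
  ba <- best_of(pairs, "gene_a", "gene_b")
  bb <- best_of(pairs, "gene_b", "gene_a")
  pairs$rbh <- paste(pairs$gene_a, pairs$gene_b) %in%
    intersect(paste(ba$gene_a, ba$gene_b), paste(bb$gene_a, bb$gene_b))
  keep <- pairs$cip > cip_min & pairs$evalue < evalue
  res <- pairs[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Anchor chromosomes to the out-group
#'
#' Each query-species chromosome is assigned to the out-group chromosome
#' contributing the plurality of its ortholog partners; ties are broken
#' by the larger summed raw score. Chromosomes without orthologs are
#' reported unassigned.
#'
#' @param pairs from [assign_orthologs()].
#' @param genes_a,genes_b gene tables carrying gene_id and chromosome.
#' @return data.frame chromosome, anchor (out-group chromosome or NA),
#'   n_pairs, assigned.
#' @export
anchor_chromosomes <- function(pairs, genes_a, genes_b) {
  chr_a <- setNames(genes_a$chromosome, genes_a$gene_id)
  chr_b <- setNames(genes_b$chromosome, genes_b$gene_id)
  out <- list()
  for (ch in sort(unique(genes_a$chromosome))) {
    p <- pairs[chr_a[pairs$gene_a] == ch, , drop = FALSE]
    if (nrow(p) == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        chromosome = ch, anchor = NA_character_, n_pairs = 0L,
        assigned = FALSE, stringsAsFactors = FALSE)
      next
    }
    tgt <- chr_b[p$gene_b]
    cnt <- tapply(rep(1L, nrow(p)), tgt, sum)
    scr <- tapply(p$score, tgt, sum)
    o <- order(-cnt, -scr, names(cnt))
    out[[length(out) + 1L]] <- data.frame(
      chromosome = ch, anchor = names(cnt)[o[1]],
      n_pairs = as.integer(cnt[o[1]]), assigned = TRUE,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map R-loci onto the out-group by syntenic support
#'
#' An R-locus is mapped when at least \code{min_support} (3) ortholog
#' pairs within a +/- \code{window} gene-rank neighbourhood support one
#' out-group chromosome; its projected position is the partner position
#' of the nearest supporting pair. Loci below the support threshold are
#' flagged unmapped.
#'
#' @param r_calls data.frame with gene_id (must appear in genes_a).
#' @param pairs from [assign_orthologs()].
#' @param genes_a,genes_b gene tables (gene_id, chromosome, rank, start).
#' @param window neighbourhood half-width in gene ranks (default 25).
#' @param min_support syntenic support threshold (default 3).
#' @return data.frame gene_id, mapped, synteny_value, target_chromosome,
#'   projected_position.
#' @export
map_r_loci <- function(r_calls, pairs, genes_a, genes_b, window = 25L,
                       min_support = 3L) {
  info_a <- genes_a[match(pairs$gene_a, genes_a$gene_id), ]
  pos_b <- setNames(genes_b$start, genes_b$gene_id)
  chr_b <- setNames(genes_b$chromosome, genes_b$gene_id)
  out <- list()
  for (i in seq_len(nrow(r_calls))) {
    gid <- r_calls$gene_id[i]
    g <- genes_a[genes_a$gene_id == gid, , drop = FALSE]
    if (nrow(g) == 0L) stop("R call absent from gene table: ", gid)
    nb <- pairs[info_a$chromosome == g$chromosome &
                  abs(info_a$rank - g$rank) <= window, , drop = FALSE]
    row <- data.frame(gene_id = gid, mapped = FALSE,
                      synteny_value = 0L, target_chromosome = NA_character_,
                      projected_position = NA_integer_,
                      stringsAsFactors = FALSE)
    if (nrow(nb) > 0L) {
      tgt <- chr_b[nb$gene_b]
      cnt <- sort(table(tgt), decreasing = TRUE)
      best <- names(cnt)[1]
      support <- as.integer(cnt[1])
      row$synteny_value <- support
      if (support >= min_support) {
        sup <- nb[tgt == best, , drop = FALSE]
        d <- abs(genes_a$rank[match(sup$gene_a, genes_a$gene_id)] - g$rank)
        nearest <- sup$gene_b[which.min(d)]
        row$mapped <- TRUE
        row$target_chromosome <- best
        row$projected_position <- as.integer(pos_b[nearest])
      }
    }
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
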