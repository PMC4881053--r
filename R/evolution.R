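# Gene-family evolution: Markov-clustering family construction from the
# protein similarity graph, linear-cost (Sankoff) parsimony reconstruction
# of per-branch family gains and losses, and selection-signal detection
# with the Nei-Gojobori method under Jukes-Cantor correction.

#' Markov clustering of a weighted adjacency matrix
#'
#' Column-stochastic flow simulation: expansion (matrix square),
#' inflation (elementwise power, columns renormalised), pruning of small
#' entries, iterated to convergence. Clusters are read off the attractor
#' rows; overlapping attractor sets are merged.
#'
#' @param w symmetric non-negative weight matrix (self-loops are added).
#' @param inflation inflation exponent (default 1.5).
#' @param prune entries below this are zeroed each sweep (default 1e-5).
#' @param tol convergence threshold on the max absolute change.
#' @param max_iter iteration cap.
#' @return list of integer vectors (cluster members, matrix indices).
#' @export
mcl <- function(w, inflation = 1.5, prune = 1e-5, tol = 1e-8,
                max_iter = 100L) {
  n <- nrow(w)
  if (n == 1L) return(list(1L))
  M <- w
  # self-loops at the max incident weight: keeps flow local without
  # letting the loop dominate the (normalised, <= 1) edge weights
  loop <- apply(w, 2L, max)
  diag(M) <- ifelse(loop > 0, loop, 1)
  M <- sweep(M, 2L, pmax(colSums(M), .Machine$double.eps), `/`)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    cs <- pmax(colSums(M2), .Machine$double.eps)
    M2 <- sweep(M2, 2L, cs, `/`)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  attractors <- which(diag(M) > 1e-6)
  clusters <- lapply(attractors, function(a) which(M[a, ] > 1e-6))
  # merge overlapping attractor systems
  merged <- list()
  for (cl in clusters) {
    hit <- which(vapply(merged, function(m) length(intersect(m, cl)) > 0L,
                        logical(1)))
    if (length(hit) == 0L) merged[[length(merged) + 1L]] <- sort(cl)
    else {
      merged[[hit[1]]] <- sort(Reduce(union, c(merged[hit], list(cl))))
      if (length(hit) > 1L) merged <- merged[-hit[-1L]]
    }
  }
  covered <- unlist(merged)
  for (i in setdiff(seq_len(n), covered))
    merged[[length(merged) + 1L]] <- i
  merged[order(vapply(merged, min, integer(1)))]
}

#' Build gene families from protein similarity
#'
#' All-vs-all local alignment (shared-k-mer prefilter); edges connect
#' pairs with E-value proxy below \code{evalue}, weighted by the
#' symmetrised normalised score; families are the Markov clusters of the
#' resulting graph.
#'
#' @param proteomes named list: species -> named protein vector.
#' @param evalue edge threshold (default 1e-10).
#' @param inflation MCL inflation.
#' @param kmer_top prefilter candidates per protein.
#' @param params alignment parameters.
#' @return list with members (list family_id -> gene ids), counts
#'   (families x species matrix), gene_family (named vector gene ->
#'   family id).
#' @export
build_families <- function(proteomes, evalue = 1e-10, inflation = 1.5,
                           kmer_top = 10L, params = align_params()) {
  stopifnot(length(proteomes) >= 2L)
  prots <- unlist(unname(lapply(proteomes, function(x) as.list(x))))
  prots <- unlist(prots)
  species_of <- rep(names(proteomes),
                    vapply(proteomes, length, integer(1)))
  names(species_of) <- unlist(lapply(proteomes, names))
  ids <- names(prots)
  n <- length(ids)
  selfs <- vapply(unname(prots), function(p) .self_score(.clean_aa(p)),
                  numeric(1))
  cand <- .kmer_candidates(prots, prots, top = kmer_top + 1L)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    js <- setdiff(cand[[i]], i)
    js <- js[js > i]                      # each unordered pair once
    for (j in js) {
      r <- align_local(prots[i], prots[j], params)
      if (r$evalue_proxy >= evalue) next
      wgt <- max(0, min(1, 2 * r$raw_score / (selfs[i] + selfs[j])))
      W[i, j] <- W[j, i] <- wgt
    }
  }
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  fam_members <- list()
  for (cm in sort(unique(comp))) {
    idx <- which(comp == cm)
    cls <- mcl(W[idx, idx, drop = FALSE], inflation = inflation)
    for (cl in cls)
      fam_members[[length(fam_members) + 1L]] <- ids[idx[cl]]
  }
  fam_members <- fam_members[order(vapply(fam_members, `[`, character(1), 1L))]
  names(fam_members) <- sprintf("F%04d", seq_along(fam_members))
  species <- names(proteomes)
  counts <- t(vapply(fam_members, function(m) {
    tab <- table(factor(species_of[m], levels = species))
    as.integer(tab)
  }, integer(length(species))))
  colnames(counts) <- species
  gene_family <- setNames(rep(names(fam_members),
                              vapply(fam_members, length, integer(1))),
                          unlist(fam_members))
  list(members = fam_members, counts = counts, gene_family = gene_family)
}

#' Parsimony reconstruction of family copy numbers on the species tree
#'
#' Per family, ancestral integer counts minimising the summed absolute
#' change over branches (Sankoff dynamic programme over states 0..max
#' leaf count, linear cost); ties are resolved toward the smallest
#' ancestral count. Per-branch gains and losses are summed over families.
#'
#' @param counts families x species integer matrix (column names matching
#'   tree tips).
#' @param tree rooted ape phylo.
#' @return list with node_states (families x nodes), branch_events
#'   (data.frame parent, child, gain, loss, net summed over families),
#'   node_totals (summed counts per node).
#' @export
reconstruct_counts <- function(counts, tree) {
  stopifnot(all(tree$tip.label %in% colnames(counts)))
  n_tip <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  root <- n_tip + 1L
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  post <- rev(unique(stats::reorder(tree)$edge[, 1L]))   # parents, deepest first
  nf <- nrow(counts)
  states <- matrix(0L, nf, n_nodes)
  for (f in seq_len(nf)) {
    leaf_counts <- counts[f, tree$tip.label]
    smax <- max(leaf_counts, 0L)
    svals <- 0:smax
    cost <- matrix(0, n_nodes, length(svals))
    # leaves
    for (l in seq_len(n_tip))
      cost[l, ] <- abs(svals - leaf_counts[l]) * 1e9   # pin leaf states
    for (v in post) {
      for (ch in children[[as.character(v)]]) {
        trans <- vapply(svals, function(s)
          min(abs(s - svals) + cost[ch, ]), numeric(1))
        cost[v, ] <- cost[v, ] + trans
      }
    }
    root_state <- svals[which.min(cost[root, ])]   # which.min = smallest tie
    states[f, root] <- root_state
    # top-down assignment, preorder
    pre <- unique(stats::reorder(tree)$edge[, 1L])
    for (v in pre) {
      for (ch in children[[as.character(v)]]) {
        s_par <- states[f, v]
        obj <- abs(s_par - svals) + cost[ch, ]
        states[f, ch] <- svals[which.min(obj)]
      }
    }
    states[f, seq_len(n_tip)] <- leaf_counts
  }
  ev <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L])
  net <- vapply(seq_len(nrow(ev)), function(i)
    sum(states[, ev$child[i]] - states[, ev$parent[i]]), numeric(1))
  gain <- vapply(seq_len(nrow(ev)), function(i)
    sum(pmax(states[, ev$child[i]] - states[, ev$parent[i]], 0L)),
    numeric(1))
  loss <- vapply(seq_len(nrow(ev)), function(i)
    sum(pmax(states[, ev$parent[i]] - states[, ev$child[i]], 0L)),
    numeric(1))
  ev$gain <- as.integer(gain)
  ev$loss <- as.integer(loss)
  ev$net <- as.integer(net)
  list(node_states = states, branch_events = ev,
       node_totals = colSums(states))
}

# ---- Nei-Gojobori selection ------------------------------------------------

#' Jukes-Cantor corrected distance from a difference proportion
#'
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}; p at or above 3/4 is
#' saturated (NA with attribute).
#'
#' @param p proportion of differing sites in [0, 1].
#' @return corrected distance; NA with attr saturated=TRUE when p >= 3/4.
#' @export
jc_correct <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p >= 0.75) {
    out <- NA_real_
    attr(out, "saturated") <- TRUE
    return(out)
  }
  -0.75 * log(1 - 4 * p / 3)
}

.ng_env <- new.env(parent = emptyenv())

# Per-codon potential synonymous site count: sum over the 3 positions of
# the fraction of the 3 alternative bases that leave the amino acid
# unchanged (changes to stop codons count as non-synonymous).
.ng86_sites <- function() {
  if (!is.null(.ng_env$sites)) return(.ng_env$sites)
  gc <- .genetic_code()
  bases <- c("A", "C", "G", "T")
  codons <- names(gc)[gc != "*"]
  s <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    aa <- gc[cd]
    syn <- 0
    for (pos in 1:3) {
      old <- substring(cd, pos, pos)
      for (b in setdiff(bases, old)) {
        alt <- cd
        substring(alt, pos, pos) <- b
        if (gc[alt] == aa) syn <- syn + 1 / 3
      }
    }
    s[cd] <- syn
  }
  .ng_env$sites <- s
  s
}

# Pathway-averaged synonymous/non-synonymous difference counts between
# two codons; paths through stop codons are excluded (all-blocked pairs
# fall back to counting over all paths, stop steps as non-synonymous).
.ng86_path <- function(c1, c2) {
  key <- paste0(c1, c2)
  if (!is.null(.ng_env$paths[[key]])) return(.ng_env$paths[[key]])
  gc <- .genetic_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) {
    res <- c(sd = 0, nd = 0)
  } else {
    step <- function(from, p) {
      to <- from
      substring(to, p, p) <- substring(c2, p, p)
      to
    }
    walk <- function(from, remaining, allow_stop) {
      if (length(remaining) == 0L)
        return(list(c(sd = 0, nd = 0)))
      out <- list()
      for (ri in seq_along(remaining)) {
        p <- remaining[ri]
        to <- step(from, p)
        if (gc[to] == "*" && !allow_stop) next
        syn <- gc[to] == gc[from]
        rest <- walk(to, remaining[-ri], allow_stop)
        for (r in rest)
          out[[length(out) + 1L]] <- r + c(sd = as.numeric(syn),
                                           nd = as.numeric(!syn))
      }
      out
    }
    paths <- walk(c1, pos, allow_stop = FALSE)
    if (length(paths) == 0L) paths <- walk(c1, pos, allow_stop = TRUE)
    m <- do.call(rbind, paths)
    res <- c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
  }
  if (is.null(.ng_env$paths)) .ng_env$paths <- new.env(parent = emptyenv())
  .ng_env$paths[[key]] <- res
  res
}

#' Nei-Gojobori (1986) synonymous/non-synonymous substitution estimates
#'
#' Potential synonymous sites per codon are the fractions of single-base
#' changes that are synonymous, averaged over the two sequences; observed
#' synonymous/non-synonymous differences are averaged over all mutational
#' pathways between each codon pair (pathways through stop codons
#' excluded); proportions are Jukes-Cantor corrected to dS and dN.
#'
#' @param cds_a,cds_b aligned codon strings of equal length (codon-atomic
#'   gaps \code{---} allowed and excluded pairwise).
#' @return list with L (codons compared), S, N, Sd, Nd, pS, pN, dS, dN,
#'   ratio (dN/dS; NA when undefined) and defined flag.
#' @export
ng86 <- function(cds_a, cds_b) {
  stopifnot(nchar(cds_a) == nchar(cds_b), nchar(cds_a) %% 3L == 0L)
  ca <- .codons(cds_a)
  cb <- .codons(cds_b)
  gc <- .genetic_code()
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb) &
    gc[ca] != "*" & gc[cb] != "*"
  ok[is.na(ok)] <- FALSE
  ca <- ca[ok]; cb <- cb[ok]
  L <- length(ca)
  if (L == 0L) stop("no ungapped codon pairs")
  sites <- .ng86_sites()
  S <- sum((sites[ca] + sites[cb]) / 2)
  N <- 3 * L - S
  Sd <- 0; Nd <- 0
  differ <- which(ca != cb)
  for (i in differ) {
    pr <- .ng86_path(ca[i], cb[i])
    Sd <- Sd + pr["sd"]
    Nd <- Nd + pr["nd"]
  }
  pS <- Sd / S
  pN <- Nd / N
  dS <- if (pS < 0.75) jc_correct(pS) else NA_real_
  dN <- if (pN < 0.75) jc_correct(pN) else NA_real_
  defined <- !is.na(dS) && !is.na(dN) && dS > 0
  list(L = L, S = unname(S), N = unname(N), Sd = unname(Sd),
       Nd = unname(Nd), pS = unname(pS), pN = unname(pN),
       dS = unname(dS), dN = unname(dN),
       ratio = if (defined) unname(dN / dS) else NA_real_,
       defined = defined)
}

#' Pairwise codon alignment via global protein alignment
#'
#' @param cds_a,cds_b coding sequences (terminal stop allowed); internal
#'   stops are an error (route such models through the structure module
#'   first).
#' @param params alignment parameters.
#' @return list with a and b: gap-padded codon strings of equal length.
#' @export
codon_align_pair <- function(cds_a, cds_b, params = align_params()) {
  pa <- translate(cds_a)
  pb <- translate(cds_b)
  pa <- sub("\\*$", "", pa); pb <- sub("\\*$", "", pb)
  if (grepl("*", pa, fixed = TRUE) || grepl("*", pb, fixed = TRUE))
    stop("internal stop codon; classify structure first")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(.clean_aa(pa)), Biostrings::AAString(.clean_aa(pb)),
    type = "global", substitutionMatrix = .blosum62(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  coda <- .codons(sub("(TAA|TAG|TGA)$", "", cds_a))
  codb <- .codons(sub("(TAA|TAG|TGA)$", "", cds_b))
  ka <- 0L; kb <- 0L
  outa <- character(length(ap)); outb <- character(length(as_))
  for (i in seq_along(ap)) {
    if (ap[i] == "-") outa[i] <- "---" else { ka <- ka + 1L; outa[i] <- coda[ka] }
    if (as_[i] == "-") outb[i] <- "---" else { kb <- kb + 1L; outb[i] <- codb[kb] }
  }
  list(a = paste(outa, collapse = ""), b = paste(outb, collapse = ""))
}

#' Average nucleotide divergence (Dxy) over ortholog alignments
#'
#' Mean raw pairwise difference proportion across the pairs, then
#' Jukes-Cantor corrected.
#'
#' @param alignments list of pairwise alignments (each a list with a, b).
#' @return corrected divergence (NA when saturated).
#' @export
dxy <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  ps <- vapply(alignments, function(al) {
    a <- strsplit(al$a, "")[[1]]
    b <- strsplit(al$b, "")[[1]]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    if (!any(ok)) return(NA_real_)
    mean(a[ok] != b[ok])
  }, numeric(1))
  jc_correct(mean(ps, na.rm = TRUE))
}

#' Bin Ka/Ks ratios into selection categories
#'
#' ratio < 0.25: purifying; [0.25, 0.8): intermediate; [0.8, 1.0]:
#' candidate; > 1: positive. Undefined ratios are reported separately and
#' never binned.
#'
#' @param results data.frame with pair identifiers and a \code{ratio}
#'   column (NA = undefined), e.g. rows built from [ng86()] output.
#' @return list with table (rows with a bin column; undefined rows keep
#'   NA) and counts (named bin counts plus undefined).
#' @export
classify_selection <- function(results) {
  bin1 <- function(r) {
    if (is.na(r)) return(NA_character_)
    if (r < 0.25) "purifying"
    else if (r < 0.8) "intermediate"
    else if (r <= 1.0) "candidate"
    else "positive"
  }
  results$bin <- vapply(results$ratio, bin1, character(1))
  counts <- c(
    purifying = sum(results$bin == "purifying", na.rm = TRUE),
    intermediate = sum(results$bin == "intermediate", na.rm = TRUE),
    candidate = sum(results$bin == "candidate", na.rm = TRUE),
    positive = sum(results$bin == "positive", na.rm = TRUE),
    undefined = sum(is.na(results$bin))
  )
  list(table = results, counts = counts)
}
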