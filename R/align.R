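# Pairwise alignment engine shared by the identification, orthology and
# structure stages. Dynamic programming is delegated to
# Biostrings::pairwiseAlignment; this layer adds the scoring conventions
# (BLOSUM62, affine 11/1), a Karlin-Altschul-style E-value proxy, score
# normalisation against the query self-alignment, six-frame genome search,
# and a shared-k-mer prefilter used to keep all-vs-all comparisons tractable.

.align_env <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.align_env$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .align_env$mat <- e$BLOSUM62
  }
  .align_env$mat
}

#' Alignment parameters
#'
#' BLOSUM62 with affine gap penalties 11 (open) / 1 (extend) and fixed
#' Karlin-Altschul-style constants for the E-value proxy
#' \eqn{E = K m n e^{-\lambda S}}. The E-value thresholds used by the
#' identification pipeline (1e-10 for protein validation, 1e-5 for genome
#' search) are applied to this proxy and are configurable here.
#'
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param K,lambda Karlin-Altschul constants for the E-value proxy.
#' @param evalue_threshold default reporting threshold for searches.
#' @return list of parameters.
#' @export
align_params <- function(gap_open = 11, gap_extend = 1,
                         K = 0.041, lambda = 0.267,
                         evalue_threshold = 1e-5) {
  list(gap_open = gap_open, gap_extend = gap_extend, K = K, lambda = lambda,
       evalue_threshold = evalue_threshold)
}

# Self-alignment score: sum of diagonal substitution scores (the local
# optimum for a self comparison, since BLOSUM62 diagonals are maximal).
.self_score <- function(protein) {
  mat <- .blosum62()
  aa <- strsplit(protein, "")[[1]]
  aa[!aa %in% rownames(mat)] <- "X"
  sum(mat[cbind(aa, aa)])
}

.evalue_proxy <- function(score, m, n, params) {
  params$K * m * n * exp(-params$lambda * score)
}

.clean_aa <- function(x) gsub("[^ARNDCQEGHILKMFPSTWYVBZX*]", "X", toupper(x))

#' Local protein alignment
#'
#' Smith-Waterman optimum under BLOSUM62 with affine gaps, reported with
#' the identity count, a score normalised by the query self-alignment
#' score, and the E-value proxy.
#'
#' @param query,subject amino-acid strings (optionally named; names become
#'   query_id/subject_id).
#' @param params from [align_params()].
#' @return list with query_id, subject_id, segments (one-row data.frame
#'   with q_start, q_end, s_start, s_end, frame, n_identical,
#'   aligned_length), raw_score, normalized_score, evalue_proxy.
#' @export
align_local <- function(query, subject, params = align_params()) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  qid <- if (!is.null(names(query))) names(query) else ""
  sid <- if (!is.null(names(subject))) names(subject) else ""
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(.clean_aa(query)), Biostrings::AAString(.clean_aa(subject)),
    type = "local", substitutionMatrix = .blosum62(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  sc <- Biostrings::score(aln)
  self <- .self_score(.clean_aa(unname(query)))
  seg <- data.frame(
    q_start = Biostrings::start(Biostrings::pattern(aln)),
    q_end = Biostrings::end(Biostrings::pattern(aln)),
    s_start = Biostrings::start(Biostrings::subject(aln)),
    s_end = Biostrings::end(Biostrings::subject(aln)),
    frame = 0L,
    n_identical = Biostrings::nmatch(aln),
    aligned_length = Biostrings::nchar(aln)
  )
  list(
    query_id = qid, subject_id = sid, segments = seg, raw_score = sc,
    normalized_score = max(0, min(1, sc / self)),
    evalue_proxy = .evalue_proxy(sc, nchar(query), nchar(subject), params)
  )
}

# Batched local alignment of many queries against one subject.
# Returns a data.frame; one row per query.
.align_many <- function(queries, subject, params = align_params()) {
  if (length(queries) == 0L) {
    return(data.frame(query_id = character(0), score = numeric(0),
                      nmatch = integer(0), length = integer(0),
                      normalized = numeric(0), evalue = numeric(0)))
  }
  pat <- Biostrings::AAStringSet(.clean_aa(unname(queries)))
  aln <- Biostrings::pairwiseAlignment(
    pat, Biostrings::AAString(.clean_aa(subject)), type = "local",
    substitutionMatrix = .blosum62(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  sc <- Biostrings::score(aln)
  selfs <- vapply(.clean_aa(unname(queries)), .self_score, numeric(1),
                  USE.NAMES = FALSE)
  data.frame(
    query_id = names(queries), score = sc,
    nmatch = Biostrings::nmatch(aln), length = Biostrings::nchar(aln),
    normalized = pmax(0, pmin(1, sc / selfs)),
    evalue = .evalue_proxy(sc, nchar(queries), nchar(subject), params),
    stringsAsFactors = FALSE
  )
}

#' Six-frame translated search of a protein against a genome sequence
#'
#' The genome (and its reverse complement) is translated in all six frames
#' and the query is locally aligned to each translation; hits passing the
#' E-value proxy threshold are returned sorted by raw score. Reported
#' coordinates are genomic (1-based, inclusive, forward strand).
#'
#' @param query named or unnamed amino-acid string.
#' @param genome nucleotide string.
#' @param params from [align_params()]; \code{evalue_threshold} filters hits.
#' @return list of hits, each with frame (+1..+3, -1..-3), raw_score,
#'   normalized_score, evalue_proxy, protein-level q_start/q_end, and
#'   genomic g_start/g_end.
#' @export
search_six_frame <- function(query, genome, params = align_params()) {
  frames <- translate_six_frames(genome)
  L <- nchar(genome)
  hits <- list()
  labels <- c("+1", "+2", "+3", "-1", "-2", "-3")
  for (i in seq_along(frames)) {
    tr <- frames[[i]]
    if (nchar(tr) < 1L) next
    res <- align_local(query, tr, params)
    if (res$evalue_proxy >= params$evalue_threshold) next
    off <- (i - 1L) %% 3L                 # frame offset 0..2
    aa_s <- res$segments$s_start
    aa_e <- res$segments$s_end
    nt_s <- 3L * (aa_s - 1L) + off + 1L
    nt_e <- 3L * aa_e + off
    if (i > 3L) {                          # reverse-strand frames
      g_start <- L - nt_e + 1L
      g_end <- L - nt_s + 1L
    } else {
      g_start <- nt_s
      g_end <- nt_e
    }
    hits[[length(hits) + 1L]] <- list(
      query_id = res$query_id, frame = labels[i],
      raw_score = res$raw_score, normalized_score = res$normalized_score,
      evalue_proxy = res$evalue_proxy,
      q_start = res$segments$q_start, q_end = res$segments$q_end,
      g_start = g_start, g_end = g_end
    )
  }
  hits[order(-vapply(hits, `[[`, numeric(1), "raw_score"))]
}

# ---- shared-k-mer prefilter ------------------------------------------------

.kmers <- function(seq, k = 6L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

# For each query, indices of the `top` subjects sharing at least
# `min_share` k-mers (one or two shared words arise by chance between
# unrelated proteins). Returns a list of integer vectors parallel to
# `queries`.
.kmer_candidates <- function(queries, subjects, k = 6L, top = 10L,
                             min_share = 3L) {
  sub_kmers <- lapply(subjects, .kmers, k = k)
  idx <- data.frame(
    kmer = unlist(sub_kmers, use.names = FALSE),
    subject = rep.int(seq_along(subjects),
                      vapply(sub_kmers, length, integer(1)))
  )
  index <- split(idx$subject, idx$kmer)
  lapply(queries, function(q) {
    km <- .kmers(q, k)
    hit <- unlist(index[km], use.names = FALSE)
    if (is.null(hit) || length(hit) == 0L) return(integer(0))
    counts <- tabulate(hit, nbins = length(subjects))
    cand <- which(counts >= min_share)
    cand[order(-counts[cand], cand)][seq_len(min(top, length(cand)))]
  })
}
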