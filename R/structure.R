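# Gene-structure re-annotation and classification: a frame-aware chaining
# re-annotator over the three forward reading frames (intronless stand-in
# for splice-aware re-annotation; see vignette), and the six-way
# classification Complete / InDel / LackStart / LackStop / LackBoth /
# Pseudo with precedence Pseudo > LackBoth > LackStart/LackStop > InDel >
# Complete.

#' Re-align a seed protein to a genomic locus across the 3 forward frames
#'
#' The locus is translated in frames 0..2; the seed is locally aligned to
#' each translation, and the highest-scoring chain of query- and
#' subject-colinear segments is kept. A frame change between adjacent
#' chained segments is recorded as a frameshift event at the segment
#' boundary.
#'
#' @param locus_dna candidate region on the coding strand.
#' @param seed_protein seed amino-acid sequence.
#' @param params alignment parameters.
#' @param min_score minimum segment score retained (default 60; chance
#'   local alignments of an unrelated ~500-aa seed against a multi-kb
#'   locus stay below this).
#' @return data.frame chain (frame, q_start, q_end, s_start, s_end in
#'   nucleotides, score), with attribute \code{frameshifts}: data.frame of
#'   positions (nt) where the frame changes. Empty chain when nothing
#'   aligns.
#' @export
realign_locus <- function(locus_dna, seed_protein, params = align_params(),
                          min_score = 60) {
  segs <- list()
  for (f in 0:2) {
    tr <- translate(locus_dna, f)
    if (nchar(tr) < 5L) next
    r <- align_local(c(seed = seed_protein), tr, params)
    if (r$raw_score < min_score) next
    s <- r$segments
    segs[[length(segs) + 1L]] <- data.frame(
      frame = f, q_start = s$q_start, q_end = s$q_end,
      s_start = 3L * (s$s_start - 1L) + f + 1L,
      s_end = 3L * s$s_end + f,
      score = r$raw_score)
  }
  empty <- data.frame(frame = integer(0), q_start = integer(0),
                      q_end = integer(0), s_start = integer(0),
                      s_end = integer(0), score = numeric(0))
  if (length(segs) == 0L) {
    attr(empty, "frameshifts") <- data.frame(position = integer(0))
    return(empty)
  }
  segs <- do.call(rbind, segs)
  # best chain over <= 3 segments: enumerate subsets, require colinearity
  # (allowing small overlaps, trimmed implicitly by the caller's use)
  n <- nrow(segs)
  best <- NULL
  best_score <- -Inf
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    sub <- segs[idx, , drop = FALSE]
    sub <- sub[order(sub$q_start), , drop = FALSE]
    ok <- TRUE
    if (nrow(sub) > 1L) {
      for (i in 2:nrow(sub)) {
        if (sub$q_start[i] < sub$q_end[i - 1L] - 15L ||
            sub$s_start[i] < sub$s_end[i - 1L] - 45L) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    sc <- sum(sub$score)
    if (sc > best_score) { best_score <- sc; best <- sub }
  }
  rownames(best) <- NULL
  fs <- if (nrow(best) > 1L) {
    chg <- which(diff(best$frame) != 0L)
    data.frame(position = as.integer(round((best$s_end[chg] +
                                              best$s_start[chg + 1L]) / 2)))
  } else data.frame(position = integer(0))
  attr(best, "frameshifts") <- fs
  best
}

#' Classify the structure of an R-gene model
#'
#' From an annotated CDS: Pseudo when the reading frame is broken (length
#' not divisible by 3) or an internal stop codon is present; otherwise
#' LackStart when the first codon is not ATG and/or LackStop when the
#' last codon is not a stop (both = LackBoth); otherwise InDel when the
#' alignment against the seed protein contains an internal gap of at
#' least \code{indel_codons} codons; otherwise Complete.
#'
#' @param cds coding sequence of the gene model.
#' @param seed_protein optional intact reference protein for the InDel
#'   check (skipped when NULL).
#' @param indel_codons internal gap threshold in codons (default 3).
#' @param params alignment parameters.
#' @return list with \code{class} and \code{evidence} (character vector
#'   of events).
#' @export
classify_structure <- function(cds, seed_protein = NULL, indel_codons = 3L,
                               params = align_params()) {
  if (is.null(cds) || !nzchar(cds)) stop("empty input")
  ev <- character(0)
  frameshift <- nchar(cds) %% 3L != 0L
  if (frameshift) ev <- c(ev, sprintf("frameshift:len%%3=%d", nchar(cds) %% 3L))
  aa <- translate(cds)
  body <- substring(aa, 1L, nchar(aa) - 1L)
  stop_at <- regexpr("*", body, fixed = TRUE)
  if (stop_at > 0L) ev <- c(ev, sprintf("premature_stop:codon%d", stop_at))
  if (frameshift || stop_at > 0L)
    return(list(class = "Pseudo", evidence = ev))
  cods <- .codons(cds)
  lack_start <- cods[1] != "ATG"
  lack_stop <- !cods[length(cods)] %in% .STOPS
  if (lack_start) ev <- c(ev, "missing_start")
  if (lack_stop) ev <- c(ev, "missing_stop")
  if (lack_start && lack_stop) return(list(class = "LackBoth", evidence = ev))
  if (lack_start) return(list(class = "LackStart", evidence = ev))
  if (lack_stop) return(list(class = "LackStop", evidence = ev))
  if (!is.null(seed_protein)) {
    prot <- sub("\\*$", "", aa)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(.clean_aa(prot)),
      Biostrings::AAString(.clean_aa(seed_protein)),
      type = "global", substitutionMatrix = .blosum62(),
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    gap <- .internal_gap(as.character(Biostrings::alignedPattern(aln)),
                         as.character(Biostrings::alignedSubject(aln)))
    if (gap >= indel_codons) {
      ev <- c(ev, sprintf("internal_gap:%daa", gap))
      return(list(class = "InDel", evidence = ev))
    }
  }
  list(class = "Complete", evidence = ev)
}

# Longest internal run of gap characters in either aligned string.
.internal_gap <- function(p, s) {
  longest <- 0L
  for (x in c(p, s)) {
    r <- gregexpr("-+", x)[[1]]
    if (r[1] < 0) next
    starts <- as.integer(r)
    lens <- attr(r, "match.length")
    internal <- starts > 1L & (starts + lens - 1L) < nchar(x)
    if (any(internal)) longest <- max(longest, lens[internal])
  }
  longest
}

#' Classify the structure of a genomic locus via frame-aware re-alignment
#'
#' Runs [realign_locus()] and classifies the result: a frame change in
#' the chain is a Pseudo (frameshift) call; otherwise the chained region
#' is extracted in frame and classified as a CDS.
#'
#' @param locus_dna locus sequence on the coding strand.
#' @param seed_protein seed protein.
#' @param params alignment parameters.
#' @return as [classify_structure()], with the chain attached as
#'   \code{chain}.
#' @export
classify_locus <- function(locus_dna, seed_protein,
                           params = align_params()) {
  chain <- realign_locus(locus_dna, seed_protein, params)
  if (nrow(chain) == 0L) stop("empty chain: nothing aligned")
  fs <- attr(chain, "frameshifts")
  if (nrow(fs) > 0L) {
    return(list(class = "Pseudo",
                evidence = sprintf("frameshift:nt%d", fs$position),
                chain = chain))
  }
  cds <- substring(locus_dna, chain$s_start[1], chain$s_end[nrow(chain)])
  res <- classify_structure(cds, seed_protein, params = params)
  res$chain <- chain
  res
}

#' Summarise structure calls per species
#'
#' @param calls data.frame with species and class columns.
#' @return list with \code{table} (6 classes x species counts) and
#'   \code{pseudo_fraction} (named per-species Pseudo / total).
#' @export
summarize_structures <- function(calls) {
  classes <- c("Complete", "InDel", "LackStart", "LackStop", "LackBoth",
               "Pseudo")
  tab <- table(factor(calls$class, levels = classes), calls$species)
  frac <- tab["Pseudo", ] / pmax(1, colSums(tab))
  list(table = tab, pseudo_fraction = frac)
}
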