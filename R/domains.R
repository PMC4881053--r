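# Typical R-protein domain detection. These scanners take the place of
# profile-HMM / coiled-coil engines: the NBS (NB-ARC) domain is called from
# its three diagnostic motifs (P-loop, kinase-2, GLPL), the LRR region from
# runs of the LxxLxLxx repeat, the TIR domain by local alignment against a
# bundled consensus block, and the CC domain by a sliding-window heptad
# log-propensity score mapped through a logistic to a probability, with the
# conventional "probability >= 0.5" call threshold.

# Diagnostic motif patterns (shared with the sequence simulator, which
# plants scanner-recoverable templates).
.PLOOP_RE <- "[GA].{4}GK[ST]"
.KIN2_RE <- "[LIVMF]{2}.{0,2}DD"
.GLPL_RE <- "GLPL"
.LRR_RE <- "[LIVF]..[LIVF].[LIVF].."

# Bundled TIR consensus block (synthetic consensus matched to the
# simulator's TIR template; see the methods vignette).
TIR_CONSENSUS <- paste0(
  "DVFLSFRGEDTRKTFVSHLYAALERAGIHVFRDDEELRKGEEISPELLRAIRESRIAIVVFSKNYA",
  "ESSWCLDELVEILECRRTKGQIVIPVFYDVDPSEVRKQTGSFGKAFA"
)

.domain_hit <- function(domain, start, end, score, detail = "") {
  list(domain = domain, start = as.integer(start), end = as.integer(end),
       score = score, detail = detail)
}

#' Scan a protein for the NBS (NB-ARC) domain
#'
#' A hit requires a P-loop motif (\code{[GA]x4GK[ST]}) plus at least one of
#' the kinase-2 (\code{[LIVMF]2 x0-2 DD}) or GLPL motifs downstream of it;
#' the hit spans the first to the last matched motif.
#'
#' @param protein amino-acid string.
#' @return a domain hit (list) or \code{NULL}.
#' @export
scan_nbs <- function(protein) {
  stopifnot(nzchar(protein))
  p <- regexpr(.PLOOP_RE, protein, perl = TRUE)
  if (p[1] < 0) return(NULL)
  p_end <- p[1] + attr(p, "match.length") - 1L
  rest <- substring(protein, p_end + 1L)
  found <- "P-loop"
  last_end <- p_end
  k <- regexpr(.KIN2_RE, rest, perl = TRUE)
  if (k[1] > 0) {
    found <- c(found, "kinase-2")
    last_end <- max(last_end, p_end + k[1] + attr(k, "match.length") - 1L)
  }
  g <- regexpr(.GLPL_RE, rest, perl = TRUE)
  if (g[1] > 0) {
    found <- c(found, "GLPL")
    last_end <- max(last_end, p_end + g[1] + attr(g, "match.length") - 1L)
  }
  if (length(found) < 2L) return(NULL)
  .domain_hit("NBS", p[1], last_end, length(found),
              paste(found, collapse = "+"))
}

#' Scan a protein for an LRR region
#'
#' Finds runs of the LxxLxLxx repeat (L in \{L,I,V,F\}) in which each
#' repeat begins at most 30 residues after the previous repeat ends; the
#' longest run is reported if it contains at least 3 repeats.
#'
#' @param protein amino-acid string.
#' @return a domain hit with the repeat count in \code{detail}, or NULL.
#' @export
scan_lrr <- function(protein) {
  stopifnot(nzchar(protein))
  m <- gregexpr(.LRR_RE, protein, perl = TRUE)[[1]]
  if (m[1] < 0) return(NULL)
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  # chain matches into runs: next start within 30 aa of previous end
  run_id <- cumsum(c(1L, as.integer(starts[-1] > ends[-length(ends)] + 30L)))
  runs <- split(seq_along(starts), run_id)
  sizes <- vapply(runs, length, integer(1))
  best <- runs[[which.max(sizes)]]
  if (length(best) < 3L) return(NULL)
  .domain_hit("LRR", starts[best[1]], ends[best[length(best)]],
              length(best), as.character(length(best)))
}

#' Scan a protein for a TIR domain
#'
#' Local alignment of the bundled TIR consensus against the protein; a hit
#' is called when the score normalised by the consensus self-alignment
#' reaches \code{threshold}.
#'
#' @param protein amino-acid string.
#' @param tir_consensus consensus block (default [TIR_CONSENSUS]).
#' @param threshold normalised-score call threshold (default 0.4).
#' @param params alignment parameters.
#' @return a domain hit or NULL.
#' @export
scan_tir <- function(protein, tir_consensus = TIR_CONSENSUS,
                     threshold = 0.4, params = align_params()) {
  stopifnot(nzchar(protein))
  res <- align_local(c(consensus = tir_consensus), protein, params)
  if (res$normalized_score < threshold) return(NULL)
  .domain_hit("TIR", res$segments$s_start, res$segments$s_end,
              res$normalized_score, sprintf("norm=%.3f", res$normalized_score))
}

# Heptad log-propensity of one residue at heptad position 0..6 (0 = a).
.cc_propensity_vec <- function(aa, heptad_pos) {
  s <- numeric(length(aa))
  ad <- heptad_pos %in% c(0L, 3L)
  eg <- heptad_pos %in% c(4L, 6L)
  hydro <- aa %in% c("L", "I", "V", "M", "F")
  charged <- aa %in% c("E", "K", "Q", "R")
  s[ad & hydro] <- 2
  s[ad & !hydro] <- -1
  s[eg & charged] <- 1
  s
}

#' Scan a protein for a coiled-coil (CC) domain
#'
#' Slides a 28-residue window; for each of the 7 heptad registers the mean
#' log-propensity is computed from a bundled table (hydrophobic residues
#' favoured at heptad positions a/d, charged at e/g), and the
#' best-register score is mapped through a logistic
#' \code{p = plogis(alpha * s + beta)}. A hit is any window with
#' \code{p >= p_threshold}; the reported span is the union of qualifying
#' windows.
#'
#' @param protein amino-acid string.
#' @param alpha,beta logistic calibration (bundled defaults 10, -6; a
#'   window needs a mean log-propensity of 0.6 to reach probability 0.5).
#' @param p_threshold call threshold (default 0.5, i.e. probability 50).
#' @param window window length (default 28 = four heptads).
#' @return a domain hit with the peak probability as score, or NULL.
#' @export
scan_cc <- function(protein, alpha = 10, beta = -6, p_threshold = 0.5,
                    window = 28L) {
  stopifnot(nzchar(protein))
  n <- nchar(protein)
  if (n < window) return(NULL)
  aa <- strsplit(protein, "")[[1]]
  pos <- seq_len(n) - 1L
  # per-register rolling mean via cumulative sums
  best <- rep(-Inf, n - window + 1L)
  for (r in 0:6) {
    sc <- .cc_propensity_vec(aa, (pos + r) %% 7L)
    cs <- c(0, cumsum(sc))
    wm <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
    best <- pmax(best, wm)
  }
  prob <- stats::plogis(alpha * best + beta)
  qual <- which(prob >= p_threshold)
  if (length(qual) == 0L) return(NULL)
  # report the contiguous run of qualifying windows containing the peak
  runs <- split(qual, cumsum(c(1L, diff(qual) > 1L)))
  peak <- qual[which.max(prob[qual])]
  run <- runs[[which(vapply(runs, function(r) peak %in% r, logical(1)))]]
  .domain_hit("CC", min(run), max(run) + window - 1L, max(prob),
              sprintf("peak=%.3f", max(prob)))
}

#' Run all four domain scanners on one protein
#'
#' The CC and LRR patterns are short periodic motifs that can fire inside
#' globular domains; a CC or LRR hit whose span overlaps a TIR or NBS hit
#' by at least half of its own length is therefore suppressed (the same
#' role clan competition plays in profile-based domain annotation).
#'
#' @param protein amino-acid string.
#' @param tir_consensus,tir_threshold passed to [scan_tir()].
#' @return list of domain hits (possibly empty).
#' @export
scan_domains <- function(protein, tir_consensus = TIR_CONSENSUS,
                         tir_threshold = 0.4) {
  hits <- list(scan_cc(protein), scan_tir(protein, tir_consensus,
                                          tir_threshold),
               scan_nbs(protein), scan_lrr(protein))
  hits <- hits[!vapply(hits, is.null, logical(1))]
  dom <- vapply(hits, `[[`, character(1), "domain")
  globular <- hits[dom %in% c("TIR", "NBS")]
  keep <- vapply(hits, function(h) {
    if (!h$domain %in% c("CC", "LRR")) return(TRUE)
    len <- h$end - h$start + 1L
    for (g in globular) {
      ov <- min(h$end, g$end) - max(h$start, g$start) + 1L
      if (ov >= len / 2) return(FALSE)
    }
    TRUE
  }, logical(1))
  hits <- hits[keep]
  # CC and LRR are both short periodic patterns and can fire on each
  # other's repeats: on heavy mutual overlap keep the longer hit
  dom <- vapply(hits, `[[`, character(1), "domain")
  ci <- match("CC", dom); li <- match("LRR", dom)
  if (!is.na(ci) && !is.na(li)) {
    cc <- hits[[ci]]; lr <- hits[[li]]
    ov <- min(cc$end, lr$end) - max(cc$start, lr$start) + 1L
    lens <- c(cc$end - cc$start + 1L, lr$end - lr$start + 1L)
    if (ov >= min(lens) / 2) hits <- hits[-c(ci, li)[which.min(lens)]]
  }
  hits
}

#' Classify a domain-hit set into an architecture category
#'
#' Maps presence and N-to-C order of CC/TIR/NBS/LRR hits onto the ten
#' named architecture categories; order violations (an LRR before the NBS,
#' an N-terminal domain overlapping the NBS, or all four domains together)
#' fall into \code{"Others"}; proteins with no hits are
#' \code{"Un-annotated"}.
#'
#' @param hits list of domain hits as returned by [scan_domains()].
#' @param protein_length unused except for sanity checks; optional.
#' @return a single label string.
#' @export
classify_architecture <- function(hits, protein_length = NA_integer_) {
  if (length(hits) == 0L) return("Un-annotated")
  dom <- vapply(hits, `[[`, character(1), "domain")
  get <- function(d) hits[[match(d, dom)]]
  has <- function(d) d %in% dom
  if (!has("NBS")) {
    if (length(dom) == 1L) return(dom)
    return("Others")                     # multi-domain without NBS: residual
  }
  if (has("CC") && has("TIR") && has("LRR")) return("Others")
  nbs <- get("NBS")
  pre <- character(0)
  if (has("CC")) {
    cc <- get("CC")
    if (cc$end >= nbs$start) return("Others")   # CC must lie N of the NBS
    pre <- c(pre, "CC")
  }
  if (has("TIR")) {
    tir <- get("TIR")
    if (tir$end >= nbs$start) return("Others")
    if (has("CC") && get("CC")$start >= tir$start) return("Others")
    pre <- c(pre, "TIR")
  }
  post <- character(0)
  if (has("LRR")) {
    lrr <- get("LRR")
    if (lrr$start <= nbs$end) return("Others")  # LRR must lie C of the NBS
    post <- "LRR"
  }
  paste(c(pre, "NBS", post), collapse = "-")
}

#' The twelve architecture categories
#' @return character vector of the ten named categories plus Others and
#'   Un-annotated.
#' @export
architecture_labels <- function() {
  c("CC", "CC-NBS", "CC-NBS-LRR", "CC-TIR-NBS", "LRR", "NBS", "NBS-LRR",
    "TIR", "TIR-NBS", "TIR-NBS-LRR", "Others", "Un-annotated")
}
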