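# The identification pipeline: screen annotated proteins with the NBS
# scanner or by alignment against the growing seed database, recover
# unannotated loci by six-frame genome search, and iterate to a fixpoint.

#' Identification parameters
#'
#' @param evalue_protein E-value proxy threshold for validating annotated
#'   proteins against the seed database (default 1e-10).
#' @param evalue_nbs_validate lenient validation threshold applied to
#'   NBS-scanner-positive proteins: a profile hit alone is not accepted,
#'   it must also find some support in the seed database (default 1e-5;
#'   random motif coincidences in non-R proteins find none).
#' @param evalue_genome E-value proxy threshold for six-frame genome
#'   search (default 1e-5).
#' @param max_iter iteration cap; exceeding it with continuing growth is
#'   an error.
#' @param kmer_top number of seed candidates per query retained by the
#'   shared-k-mer prefilter.
#' @param tir_threshold passed to the TIR scanner during classification.
#' @param min_segment minimum intergenic segment length (nt) considered
#'   in genome search.
#' @param align alignment parameters ([align_params()]).
#' @return parameter list.
#' @export
identify_params <- function(evalue_protein = 1e-10,
                            evalue_nbs_validate = 1e-5,
                            evalue_genome = 1e-5,
                            max_iter = 10L, kmer_top = 3L,
                            tir_threshold = 0.4, min_segment = 120L,
                            align = align_params()) {
  list(evalue_protein = evalue_protein,
       evalue_nbs_validate = evalue_nbs_validate,
       evalue_genome = evalue_genome,
       max_iter = max_iter, kmer_top = kmer_top,
       tir_threshold = tir_threshold, min_segment = min_segment,
       align = align)
}

# Intergenic segments (annotated gene space masked) of one genome.
.intergenic_segments <- function(genome, gene_table, min_len = 120L) {
  out <- list()
  for (ch in names(genome)) {
    L <- nchar(genome[[ch]])
    g <- gene_table[gene_table$chromosome == ch, , drop = FALSE]
    covered <- rep(FALSE, L)
    for (i in seq_len(nrow(g))) covered[g$start[i]:g$end[i]] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- !r$values & r$lengths >= min_len
    for (i in which(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        chromosome = ch, start = starts[i], end = ends[i],
        seq = substring(genome[[ch]], starts[i], ends[i]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# Best-hit tie-break: highest raw score, then lowest E-value proxy, then
# lexicographic subject id.
.best_hit <- function(df) {
  df[order(-df$score, df$evalue, df$subject_id), , drop = FALSE][1L, ]
}

#' Iterative identification of R-gene candidates
#'
#' Repeats until a fixpoint: (1) annotated proteins pass if the NBS
#' scanner fires (validated by lenient support in the current seed set;
#' a bare motif coincidence in a non-R protein finds none) or if their
#' best alignment to the seed set beats the strict protein E-value
#' threshold; (2) validated candidates join the seed
#' set; (3) the current seeds are searched six-frame against the
#' unannotated (intergenic) genome space to recover loci missing from the
#' annotation. The candidate set grows monotonically; an iteration that
#' adds nothing terminates the loop.
#'
#' @param proteomes named list: species -> named character vector of
#'   annotated proteins.
#' @param seed_db named character vector of seed R proteins.
#' @param genomes optional named list: species -> named chromosome
#'   sequences (enables the genome-search stage).
#' @param gene_tables optional named list: species -> gene table
#'   (gene_id, chromosome, start, end, strand, rank), required with
#'   \code{genomes}.
#' @param params from [identify_params()].
#' @return data.frame of calls: gene_id, species, evidence
#'   (original_annotation / iterative_search), best_hit_id, architecture,
#'   iteration_found, chromosome/start/end for genome-search loci, and
#'   domain spans.
#' @export
iterative_identify <- function(proteomes, seed_db, genomes = NULL,
                               gene_tables = NULL,
                               params = identify_params()) {
  if (length(seed_db) == 0L) stop("seed database is empty")
  seeds <- seed_db
  calls <- list()
  called <- character(0)
  growth <- integer(0)
  segs <- list()
  if (!is.null(genomes)) {
    stopifnot(!is.null(gene_tables))
    for (sp in names(genomes)) {
      s <- .intergenic_segments(genomes[[sp]], gene_tables[[sp]],
                                params$min_segment)
      if (!is.null(s)) { s$done <- FALSE; segs[[sp]] <- s }
    }
  }
  nbs_pass <- lapply(proteomes, function(pr)
    vapply(pr, function(p) !is.null(scan_nbs(p)), logical(1)))

  for (iter in seq_len(params$max_iter)) {
    n_new <- 0L
    for (sp in names(proteomes)) {
      prots <- proteomes[[sp]]
      todo <- setdiff(names(prots), called)
      if (length(todo) == 0L) next
      cand <- .kmer_candidates(prots[todo], seeds, top = params$kmer_top)
      for (i in seq_along(todo)) {
        ci <- cand[[i]]
        if (length(ci) == 0L) next
        gid <- todo[i]
        hits <- do.call(rbind, lapply(ci, function(s) {
          r <- align_local(stats::setNames(prots[gid], gid),
                           stats::setNames(seeds[s], names(seeds)[s]),
                           params$align)
          data.frame(subject_id = names(seeds)[s], score = r$raw_score,
                     evalue = r$evalue_proxy, stringsAsFactors = FALSE)
        }))
        best <- .best_hit(hits)
        # an NBS profile pass is accepted with lenient seed-database
        # support; otherwise the alignment alone must be significant
        threshold <- if (nbs_pass[[sp]][[gid]]) params$evalue_nbs_validate
                     else params$evalue_protein
        if (best$evalue < threshold) {
          calls[[length(calls) + 1L]] <- data.frame(
            gene_id = gid, species = sp, evidence = "original_annotation",
            best_hit_id = best$subject_id, iteration_found = iter,
            chromosome = NA_character_, start = NA_integer_,
            end = NA_integer_, protein = unname(prots[gid]),
            stringsAsFactors = FALSE)
          called <- c(called, gid)
          seeds[gid] <- prots[gid]
          n_new <- n_new + 1L
        }
      }
    }
    # genome search of the unannotated space
    for (sp in names(segs)) {
      s <- segs[[sp]]
      open <- which(!s$done)
      if (length(open) == 0L) next
      cand <- .kmer_candidates(
        vapply(open, function(i) paste(translate_six_frames(s$seq[i]),
                                       collapse = "X"), character(1)),
        seeds, top = params$kmer_top)
      for (k in seq_along(open)) {
        i <- open[k]
        ci <- cand[[k]]
        if (length(ci) == 0L) next
        best <- NULL
        best_seed <- NA_character_
        for (sd in ci) {
          p <- params$align
          p$evalue_threshold <- params$evalue_genome
          h <- search_six_frame(stats::setNames(seeds[sd], names(seeds)[sd]),
                                s$seq[i], p)
          if (length(h) > 0L && (is.null(best) ||
                                 h[[1]]$raw_score > best$raw_score)) {
            best <- h[[1]]
            best_seed <- names(seeds)[sd]
          }
        }
        if (is.null(best)) next
        g_start <- s$start[i] + best$g_start - 1L
        g_end <- s$start[i] + best$g_end - 1L
        gid <- sprintf("%s_locus_%s_%d", sp, s$chromosome[i], g_start)
        fwd <- !startsWith(best$frame, "-")
        region <- substring(s$seq[i], best$g_start, best$g_end)
        prot <- translate(if (fwd) region else reverse_complement(region))
        calls[[length(calls) + 1L]] <- data.frame(
          gene_id = gid, species = sp, evidence = "iterative_search",
          best_hit_id = best_seed, iteration_found = iter,
          chromosome = s$chromosome[i], start = g_start, end = g_end,
          protein = prot, stringsAsFactors = FALSE)
        called <- c(called, gid)
        seeds[gid] <- prot
        segs[[sp]]$done[i] <- TRUE
        n_new <- n_new + 1L
      }
    }
    growth <- c(growth, n_new)
    if (n_new == 0L) break
    if (iter == params$max_iter && n_new > 0L)
      stop("identification did not converge within ", params$max_iter,
           " iterations; growth per iteration: ",
           paste(growth, collapse = ", "))
  }
  if (length(calls) == 0L)
    return(data.frame(gene_id = character(0), species = character(0),
                      evidence = character(0), best_hit_id = character(0),
                      iteration_found = integer(0),
                      architecture = character(0),
                      domain_spans = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  # classify architectures from the called proteins
  arch <- character(nrow(out))
  spans <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    p <- sub("\\*.*$", "", out$protein[i])
    hits <- if (nzchar(p))
      scan_domains(p, tir_threshold = params$tir_threshold) else list()
    arch[i] <- classify_architecture(hits, nchar(p))
    spans[i] <- paste(vapply(hits, function(h)
      sprintf("%s:%d-%d", h$domain, h$start, h$end), character(1)),
      collapse = ";")
  }
  out$architecture <- arch
  out$domain_spans <- spans
  out$protein <- NULL
  out
}

#' Tabulate R-gene calls by architecture and species
#'
#' @param calls data.frame from [iterative_identify()] (needs species and
#'   architecture columns).
#' @return matrix: 12 architecture rows plus a Total row; one column per
#'   species plus a Total column.
#' @export
summarize_inventory <- function(calls) {
  labs <- architecture_labels()
  species <- sort(unique(calls$species))
  m <- matrix(0L, nrow = length(labs) + 1L, ncol = length(species) + 1L,
              dimnames = list(c(labs, "Total"), c(species, "Total")))
  if (nrow(calls) > 0L) {
    tab <- table(factor(calls$architecture, levels = labs), calls$species)
    m[seq_along(labs), species] <- tab[, species, drop = FALSE]
  }
  m["Total", ] <- colSums(m[seq_along(labs), , drop = FALSE])
  m[, "Total"] <- rowSums(m[, species, drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Published per-species R-gene counts bundled with the package
#'
#' The seven-species legume R-gene census (counts as printed in the study
#' this pipeline re-implements), used for aggregate checks.
#'
#' @return data.frame with species and count columns.
#' @export
rgene_census <- function() {
  path <- system.file("extdata", "legume_rgene_counts.tsv",
                      package = "rgevo", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Aggregate a census table
#'
#' @param census data.frame from [rgene_census()].
#' @return list with \code{total} (sum over species) and
#'   \code{wild_minus_cultivated} (wild minus cultivated soybean count).
#' @export
census_summary <- function(census = rgene_census()) {
  list(
    total = sum(census$count),
    wild_minus_cultivated =
      census$count[census$species == "wild_soybean"] -
      census$count[census$species == "cultivated_soybean"]
  )
}
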