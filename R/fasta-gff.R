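#' Read a FASTA file
#'
#' Thin wrapper over \code{Biostrings::readBStringSet} returning plain named
#' character strings, with an up-front structural check so that a sequence
#' line appearing before any header is reported with its line number.
#'
#' @param path path to a FASTA file.
#' @return named character vector (names = record ids, first whitespace
#'   token of the header; values = sequences). Empty file returns an empty
#'   vector with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  non_empty <- which(nzchar(trimws(lines)))
  if (length(non_empty) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  first <- non_empty[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: sequence line before header at line ", first,
         " of ", path)
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  setNames(toupper(seqs), ids)
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (length(records) == 0L) stop("no records to write")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("all records must be named")
  set <- Biostrings::BStringSet(unname(records))
  names(set) <- names(records)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Keeps \code{gene} features only and assigns each gene a 0-based rank
#' along its chromosome by start coordinate (ties broken by gene id,
#' lexicographically), the gene-order coordinate used by tandem-cluster
#' calling and synteny windows.
#'
#' @param path path to a GFF3 file (1-based inclusive coordinates).
#' @return data.frame with columns gene_id, species (from the \code{species}
#'   attribute when present, else NA), chromosome, start, end, strand, rank.
#' @export
read_gff3 <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  g <- g[g$type == "gene", , drop = FALSE]
  id <- if ("ID" %in% names(g)) as.character(g$ID) else stop("GFF3 gene records need ID attributes")
  bad <- g$end < g$start
  if (any(bad)) {
    stop("GFF3 record with end < start: ", paste(id[bad], collapse = ", "))
  }
  strand <- as.character(g$strand)
  if (any(!strand %in% c("+", "-"))) {
    stop("GFF3 record with unknown strand: ",
         paste(id[!strand %in% c("+", "-")], collapse = ", "))
  }
  out <- data.frame(
    gene_id = id,
    species = if ("species" %in% names(g)) as.character(g$species) else NA_character_,
    chromosome = as.character(g$seqid),
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = strand,
    stringsAsFactors = FALSE
  )
  assign_ranks(out)
}

#' Assign 0-based gene ranks per chromosome
#'
#' Sort by start within each chromosome, ties broken by gene_id. Idempotent
#' and invariant to input row order.
#'
#' @param genes data.frame with gene_id, chromosome, start.
#' @return same data.frame, re-ordered, with an integer \code{rank} column.
#' @export
assign_ranks <- function(genes) {
  o <- order(genes$chromosome, genes$start, genes$gene_id)
  genes <- genes[o, , drop = FALSE]
  genes$rank <- as.integer(stats::ave(seq_len(nrow(genes)), genes$chromosome,
                                      FUN = seq_along)) - 1L
  rownames(genes) <- NULL
  genes
}

#' Write gene models as GFF3
#'
#' @param genes data.frame with gene_id, chromosome, start, end, strand and
#'   optionally species.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  attrs <- paste0("ID=", genes$gene_id)
  if (!is.null(genes$species)) attrs <- paste0(attrs, ";species=", genes$species)
  writeLines(paste(genes$chromosome, "rgevo", "gene", genes$start, genes$end,
                   ".", genes$strand, ".", attrs, sep = "\t"), con)
  invisible(path)
}
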