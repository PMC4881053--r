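# Codon table derived once from the standard genetic code.
.codon_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.codon_env$gc)) {
    gc <- Biostrings::GENETIC_CODE
    .codon_env$gc <- setNames(as.character(gc), names(gc))
  }
  .codon_env$gc
}

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of DNA strings over {A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a coding sequence
#'
#' Standard genetic code; stop codons are rendered as \code{"*"} and kept
#' (downstream structure calls rely on them); any codon containing an
#' ambiguous base (or a partial codon) is rendered as \code{"X"}.
#'
#' @param cds nucleotide string over {A,C,G,T,N}.
#' @param frame reading-frame offset, one of 0, 1, 2.
#' @return amino-acid string of length \code{floor((nchar(cds) - frame) / 3)}.
#' @export
translate <- function(cds, frame = 0) {
  stopifnot(length(cds) == 1L, frame %in% 0:2)
  n <- nchar(cds)
  len <- (n - frame) %/% 3
  if (len <= 0) return("")
  starts <- frame + 1 + 3 * (0:(len - 1))
  codons <- substring(cds, starts, starts + 2)
  gc <- .genetic_code()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Six-frame translation
#'
#' Frames 1:3 translate the forward strand at offsets 0:2; frames 4:6
#' translate the reverse complement at offsets 0:2.
#'
#' @param dna nucleotide string.
#' @return named character vector of 6 translations (\code{F1..F3, R1..R3}).
#' @export
translate_six_frames <- function(dna) {
  rc <- reverse_complement(dna)
  out <- c(
    F1 = translate(dna, 0), F2 = translate(dna, 1), F3 = translate(dna, 2),
    R1 = translate(rc, 0), R2 = translate(rc, 1), R3 = translate(rc, 2)
  )
  out
}

# Split a CDS into codons (frame 0). Internal helper.
.codons <- function(cds) {
  n <- nchar(cds) %/% 3
  if (n == 0) return(character(0))
  starts <- 1 + 3 * (0:(n - 1))
  substring(cds, starts, starts + 2)
}

.STOPS <- c("TAA", "TAG", "TGA")
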