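#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   writeXStringSet readDNAStringSet pairwiseAlignment
#'   nucleotideSubstitutionMatrix alignedPattern alignedSubject nmatch
#' @importFrom IRanges IRanges
#' @importFrom stats rnorm runif rbinom median hclust as.dist phyper p.adjust
#'   setNames uniroot dist sd
#' @importFrom utils head tail write.table read.table
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Generate random DNA sequences
#'
#' Uniform i.i.d. bases; used by the simulator for reference background and
#' LTR prototype sequences.
#'
#' @param lengths integer vector of sequence lengths.
#' @return character vector of sequences over A/C/G/T.
#' @keywords internal
random_dna <- function(lengths) {
  vapply(lengths, function(n) {
    paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
  }, character(1))
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of A/C/G/T (N allowed) sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Check that sequences only use A/C/G/T
#' @keywords internal
assert_acgt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters (first offender: %s)",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

# Hamming matches between equal-length strings (vectorised over pairs).
count_matches <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) == charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

# substr with 0-based half-open coordinates, the convention used throughout
# for genome positions.
substr0 <- function(x, start0, end0) {
  substr(x, start0 + 1L, end0)
}

# Split sequences into a character matrix of single bases (rows = sequences).
seq_to_matrix <- function(seqs) {
  n <- nchar(seqs)
  if (length(unique(n)) != 1L) stop("sequences must have equal length")
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}
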