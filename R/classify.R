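#' Contig classification against the LTR library
#'
#' Contigs are aligned locally (Smith-Waterman, via Biostrings) against
#' every library entry on both strands, and the raw score is converted to
#' an e-value-like statistic of the Karlin-Altschul form
#' `E = K * m * n * exp(-lambda * S)`, with `m` the contig length and `n`
#' the total library length (library-size correction).  The family of the
#' entry with the lowest e-value wins, provided the e-value passes the
#' threshold.
#'
#' @name classification
NULL

# Ungapped Karlin-Altschul lambda for uniform base composition:
# solve (1/4) e^(lambda*match) + (3/4) e^(lambda*mismatch) = 1.
karlin_lambda <- function(match = 1, mismatch = -2) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

KARLIN_K <- 0.1  # fixed K; adequate for a relative, threshold-style e-value

default_scoring <- function() {
  list(match = 1, mismatch = -2, gap_open = 5, gap_ext = 2)
}

align_local <- function(queries, subject, scoring = default_scoring()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(queries),
    subject = Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext,
    scoreOnly = TRUE)
}

#' Classify a contig against the LTR library
#'
#' @param contig contig sequence (non-empty character scalar).
#' @param library an `ltr_library`.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_ext`
#'   (defaults +1/-2/5/2).
#' @param evalue_max e-value threshold for assigning a family
#'   (default 1e-5).
#' @return one-row data.frame: `family` (or `"unclassified"`),
#'   `best_entry`, `score`, `evalue_like`, `strand`.
#' @export
classify_contig <- function(contig, library, scoring = default_scoring(),
                            evalue_max = 1e-5) {
  if (is.null(contig) || !nzchar(contig)) stop("empty contig")
  if (!length(library)) stop("empty LTR library")
  lambda <- karlin_lambda(scoring$match, scoring$mismatch)
  lib_total <- sum(nchar(library_sequences(library)))
  m <- nchar(contig)
  res <- do.call(rbind, lapply(library, function(e) {
    sc <- align_local(c(contig, revcomp(contig)), e$sequence, scoring)
    strand <- if (sc[2] > sc[1]) "-" else "+"
    s <- max(sc)
    data.frame(entry = e$name, family = e$family, score = s,
               evalue_like = KARLIN_K * m * lib_total * exp(-lambda * s),
               strand = strand, stringsAsFactors = FALSE)
  }))
  res <- res[order(res$evalue_like, res$entry), , drop = FALSE]
  best <- res[1, ]
  data.frame(
    family = if (best$evalue_like <= evalue_max) best$family else "unclassified",
    best_entry = best$entry, score = best$score,
    evalue_like = best$evalue_like, strand = best$strand,
    stringsAsFactors = FALSE
  )
}

#' Exclude loci explained by reference-resident LTRs
#'
#' Extracts `flank` bp of reference sequence immediately upstream and
#' downstream of the breakpoint and classifies each flank against the
#' library; a hit on either side means the apparent insertion signal is
#' attributable to an ERV already present in the reference, and the locus
#' should be excluded.
#'
#' @param call single-row call (uses `chrom`, `position`).
#' @param reference named chromosome sequences.
#' @param library an `ltr_library`.
#' @param flank flank length in bp (default 200).
#' @param evalue_max e-value threshold (default 1e-5).
#' @return TRUE when the locus should be excluded.
#' @export
exclude_reference_ltr <- function(call, reference, library, flank = 200L,
                                  evalue_max = 1e-5) {
  ref_seq <- reference[[call$chrom]]
  if (is.null(ref_seq) || call$position < 0 || call$position > nchar(ref_seq)) {
    stop("breakpoint outside the reference")
  }
  lo <- max(0L, call$position - flank)
  hi <- min(nchar(ref_seq), call$position + flank)
  if (lo > call$position - flank + 0L || hi < call$position + flank) {
    message("breakpoint within ", flank, " bp of a contig end; flank truncated")
  }
  up <- substr0(ref_seq, lo, call$position)
  down <- substr0(ref_seq, call$position, hi)
  for (fl in c(up, down)) {
    if (nchar(fl) < 10L) next
    if (classify_contig(fl, library, evalue_max = evalue_max)$family !=
        "unclassified") {
      return(TRUE)
    }
  }
  FALSE
}
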