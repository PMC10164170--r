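#' Minimal SAM text reader and writer
#'
#' The pipeline operates on an in-memory alignment table (one row per SAM
#' record, columns = the 11 mandatory SAM fields).  Plain-text SAM is the
#' interchange format; BAM inputs can be converted externally with
#' `samtools view -h`.
#'
#' @name sam_io
NULL

SAM_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq")

#' Read a SAM file into an alignment table
#'
#' @param path path to a plain-text SAM file with header.
#' @return a data.frame with the mandatory fields (QUAL dropped), `flag`,
#'   `pos`, `mapq`, `pnext`, `tlen` as integers, plus attribute
#'   `ref_lengths` (named integer vector from the \code{@SQ} lines).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  ref_lengths <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    ref_lengths <- setNames(ln, sn)
  }
  if (!length(body)) {
    out <- as.data.frame(setNames(rep(list(character(0)), 10), SAM_COLS))
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    get <- function(i) vapply(fields, `[[`, character(1), i)
    out <- data.frame(
      qname = get(1), flag = as.integer(get(2)), rname = get(3),
      pos = as.integer(get(4)), mapq = as.integer(get(5)), cigar = get(6),
      rnext = get(7), pnext = as.integer(get(8)), tlen = as.integer(get(9)),
      seq = get(10), stringsAsFactors = FALSE
    )
  }
  attr(out, "ref_lengths") <- ref_lengths
  out
}

#' Write an alignment table as coordinate-sorted SAM
#'
#' @param aln alignment table (as produced by [emit_truth_alignments()] or
#'   [read_sam()]).
#' @param path output path.
#' @param ref_lengths named integer vector of reference sequence lengths for
#'   the \code{@SQ} header lines; taken from `attr(aln, "ref_lengths")` when
#'   missing.
#' @export
write_sam <- function(aln, path, ref_lengths = NULL) {
  if (is.null(ref_lengths)) ref_lengths <- attr(aln, "ref_lengths")
  if (is.null(ref_lengths)) stop("ref_lengths required to write a SAM header")
  aln <- sort_sam(aln)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), ref_lengths), con)
  writeLines("@PG\tID:ltrscout\tPN:ltrscout", con)
  if (nrow(aln)) {
    writeLines(paste(aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                     aln$cigar, aln$rnext, aln$pnext, aln$tlen, aln$seq,
                     "*", sep = "\t"), con)
  }
  invisible(path)
}

# Coordinate sort: mapped records (and unmapped-with-mapped-mate placed at
# the mate position) by rname then pos; records with rname "*" last.
sort_sam <- function(aln) {
  if (!nrow(aln)) return(aln)
  unplaced <- aln$rname == "*"
  key_chrom <- aln$rname
  ord <- order(unplaced, key_chrom, aln$pos, aln$qname, aln$flag)
  out <- aln[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ref_lengths") <- attr(aln, "ref_lengths")
  out
}

## ---- flag helpers -----------------------------------------------------

FLAG_PAIRED <- 0x1L; FLAG_PROPER <- 0x2L; FLAG_UNMAPPED <- 0x4L
FLAG_MUNMAPPED <- 0x8L; FLAG_REVERSE <- 0x10L; FLAG_MREVERSE <- 0x20L
FLAG_FIRST <- 0x40L; FLAG_SECOND <- 0x80L

flag_isset <- function(flag, bit) bitwAnd(flag, bit) != 0L

## ---- CIGAR helpers ----------------------------------------------------

cigar_ops <- function(cigar) {
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
  Map(function(l, o) setNames(as.integer(l), o), lens, ops)
}

#' Reference-consumed length of CIGAR strings
#' @keywords internal
cigar_ref_len <- function(cigar) {
  out <- integer(length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (any(ok)) {
    out[ok] <- vapply(cigar_ops(cigar[ok]), function(x) {
      sum(x[names(x) %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
  }
  out
}

# Soft-clip lengths at each end (left = before first M, right = after last M).
cigar_clips <- function(cigar) {
  n <- length(cigar)
  left <- integer(n); right <- integer(n)
  ok <- !is.na(cigar) & cigar != "*"
  has_l <- ok & grepl("^[0-9]+S", cigar)
  has_r <- ok & grepl("[0-9]+S$", cigar)
  left[has_l] <- as.integer(sub("^([0-9]+)S.*", "\\1", cigar[has_l]))
  right[has_r] <- as.integer(sub(".*?([0-9]+)S$", "\\1", cigar[has_r]))
  cbind(left = left, right = right)
}
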