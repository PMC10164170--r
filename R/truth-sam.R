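#' Project simulated reads onto the reference as truth alignments
#'
#' Each mate is projected from donor coordinates to reference coordinates
#' through the individual's insertion map, reproducing the paired-end
#' mapping signatures a real aligner would emit around a non-reference
#' insertion:
#' \itemize{
#'   \item mates fully within retained reference sequence map with full-M
#'     CIGARs;
#'   \item mates crossing the 5' insertion junction are soft-clipped at the
#'     junction (`<m>M<c>S`);
#'   \item mates crossing the 3' junction start inside the inserted LTR and
#'     run through the duplicated target site into downstream reference --
#'     since the TSD copy is identical to the reference slice immediately
#'     5' of the insertion point, the projected alignment starts at the TSD
#'     (`<c>S<m>M` at reference position `p - L`), which is what creates
#'     the characteristic 1-10 bp junction overlap used for TSD detection;
#'   \item mates fully inside the inserted sequence are emitted unmapped
#'     (the singleton signature);
#'   \item mapped stretches shorter than `min_anchor` are emitted unmapped,
#'     since no aligner would place them confidently.
#' }
#'
#' @param reads data.frame from [generate_reads()] (truth coordinates in
#'   the read names / columns).
#' @param reference named chromosome sequences (used for header lengths).
#' @param truth truth table from [simulate_cohort()].
#' @param library the `ltr_library` used in the simulation.
#' @param individual which individual's insertion map to project through.
#' @param config the [cohort_config()] (read length, insert-size bounds).
#' @param min_anchor minimum mapped length for a mate to be emitted as
#'   mapped (default 20 bp).
#' @return coordinate-sorted alignment table (see [read_sam()]) with
#'   attribute `ref_lengths`; write with [write_sam()].
#' @export
emit_truth_alignments <- function(reads, reference, truth, library,
                                  individual, config, min_anchor = 20L) {
  if (!all(grepl("^[^:]+:[^:]+:[0-9]+:[0-9]+:", reads$qname))) {
    stop("read names lack truth coordinates (ind:chrom:start:end:serial)")
  }
  rl <- config$read_length
  imap <- insertion_map(truth, library, individual)

  proj <- function(chrom, s) {
    # project donor interval [s, s+rl) on `chrom`; returns list of vectors
    n <- length(s)
    e <- s + rl
    out <- list(mapped = rep(TRUE, n), pos0 = s, cigar = rep(sprintf("%dM", rl), n),
                mlen = rep(rl, n), clip_left = integer(n), clip_right = integer(n))
    m <- imap[[chrom]]
    if (is.null(m) || !nrow(m)) return(out)
    ci <- findInterval(e - 1L, m$a)          # last insertion starting before read end
    has <- ci > 0L
    if (!any(has)) return(out)
    A <- m$a[pmax(ci, 1L)]; B <- m$b[pmax(ci, 1L)]
    P <- m$p[pmax(ci, 1L)]; L <- m$L[pmax(ci, 1L)]
    cb <- m$cum_before[pmax(ci, 1L)]; ca <- m$cum_after[pmax(ci, 1L)]

    after   <- has & s >= B                   # fully right of insertion ci
    cross5  <- has & s < A & e > A            # crosses the 5' junction
    inside  <- has & s >= A & e <= B          # fully inside inserted block
    cross3  <- has & s >= A & s < B & e > B   # crosses the 3' junction

    out$pos0[after] <- s[after] - ca[after]
    out$pos0[cross5] <- s[cross5] - cb[cross5]
    mlen5 <- A[cross5] - s[cross5]
    out$mlen[cross5] <- mlen5
    out$clip_right[cross5] <- rl - mlen5
    out$cigar[cross5] <- sprintf("%dM%dS", mlen5, rl - mlen5)

    t3 <- pmax(s[cross3], B[cross3] - L[cross3])
    clip3 <- t3 - s[cross3]
    mlen3 <- rl - clip3
    out$pos0[cross3] <- P[cross3] - (B[cross3] - t3)
    out$mlen[cross3] <- mlen3
    out$clip_left[cross3] <- clip3
    out$cigar[cross3] <- ifelse(clip3 > 0L,
                                sprintf("%dS%dM", clip3, mlen3),
                                sprintf("%dM", rl))
    out$mapped[inside] <- FALSE
    short <- out$mapped & out$mlen < min_anchor
    out$mapped[short] <- FALSE
    out$cigar[!out$mapped] <- "*"
    out
  }

  recs <- lapply(split(reads, reads$chrom), function(rd) {
    ch <- rd$chrom[1]
    p1 <- proj(ch, rd$start)
    p2 <- proj(ch, rd$end - rl)
    n <- nrow(rd)
    both <- p1$mapped & p2$mapped
    proper <- both & p1$cigar == sprintf("%dM", rl) &
      p2$cigar == sprintf("%dM", rl) &
      (p2$pos0 + rl - p1$pos0) >= rl &
      (p2$pos0 + rl - p1$pos0) <= config$fragment_mean + 4L * config$fragment_sd

    f1 <- rep(FLAG_PAIRED + FLAG_FIRST, n)
    f2 <- rep(FLAG_PAIRED + FLAG_SECOND, n)
    f1 <- f1 + ifelse(proper, FLAG_PROPER, 0L) + ifelse(!p1$mapped, FLAG_UNMAPPED, 0L) +
      ifelse(!p2$mapped, FLAG_MUNMAPPED, 0L) + ifelse(p2$mapped, FLAG_MREVERSE, 0L)
    f2 <- f2 + ifelse(proper, FLAG_PROPER, 0L) + ifelse(!p2$mapped, FLAG_UNMAPPED, 0L) +
      ifelse(!p1$mapped, FLAG_MUNMAPPED, 0L) + ifelse(p2$mapped, FLAG_REVERSE, 0L)

    # SAM stores SEQ in reference-forward orientation for mapped reverse
    # strand mates; unmapped mates keep the as-sequenced read.
    seq2 <- ifelse(p2$mapped, revcomp(rd$seq2), rd$seq2)
    pos1 <- ifelse(p1$mapped, p1$pos0, ifelse(p2$mapped, p2$pos0, -1L)) + 1L
    pos2 <- ifelse(p2$mapped, p2$pos0, ifelse(p1$mapped, p1$pos0, -1L)) + 1L
    rname1 <- ifelse(pos1 > 0L, ch, "*")
    rname2 <- ifelse(pos2 > 0L, ch, "*")
    tlen <- ifelse(both, (p2$pos0 + cigar_ref_len(p2$cigar)) - p1$pos0, 0L)

    data.frame(
      qname = rep(rd$qname, 2L),
      flag = c(f1, f2),
      rname = c(rname1, rname2),
      pos = pmax(c(pos1, pos2), 0L),
      mapq = c(ifelse(p1$mapped, 60L, 0L), ifelse(p2$mapped, 60L, 0L)),
      cigar = c(p1$cigar, p2$cigar),
      rnext = c(ifelse(rname2 == "*", "*", "="), ifelse(rname1 == "*", "*", "=")),
      pnext = pmax(c(pos2, pos1), 0L),
      tlen = c(tlen, -tlen),
      seq = c(rd$seq1, seq2),
      stringsAsFactors = FALSE
    )
  })
  aln <- do.call(rbind, recs)
  rownames(aln) <- NULL
  attr(aln, "ref_lengths") <- setNames(nchar(reference), names(reference))
  sort_sam(aln)
}

#' Map truth-SAM reference coordinates back to donor coordinates
#'
#' Inverse of the projection performed by [emit_truth_alignments()]: a
#' mapped record's reference start is translated back into the donor
#' coordinate of its first aligned base.  Used to verify the projection
#' round-trips exactly in error-free mode.
#'
#' @param pos0 0-based reference start positions.
#' @param clip_left left soft-clip lengths (bases preceding the aligned
#'   start in the read).
#' @param chrom chromosome name (scalar).
#' @param truth,library,individual as in [emit_truth_alignments()].
#' @return 0-based donor coordinates of the first aligned base.
#' @export
ref_to_donor <- function(pos0, clip_left, chrom, truth, library, individual) {
  m <- insertion_map(truth, library, individual)[[chrom]]
  if (is.null(m)) return(pos0)
  # a reference base at pos0 >= p sits downstream of that insertion in the
  # donor; k = number of insertion points at or before pos0
  k <- findInterval(pos0, m$p)
  off <- ifelse(k > 0L, m$cum_after[pmax(k, 1L)], 0L)
  out <- pos0 + off
  # left-clipped junction reads start within the TSD re-match region
  # [p-L, p): their first aligned base is the TSD copy *inside* the
  # insertion, at donor coordinate b - (p - pos0)
  j <- findInterval(pos0, m$p - m$L)
  tsd_case <- j > k & j <= nrow(m) & clip_left > 0L
  jj <- pmax(j, 1L)
  out[tsd_case] <- (m$b[jj] - (m$p[jj] - pos0))[tsd_case]
  out
}

#' Write the truth table as TSV
#' @param truth truth data.frame from [simulate_cohort()].
#' @param path output path.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the truth table as a symbolic-allele VCF
#'
#' Emits one `<INS:ME>` record per insertion event (VCF 4.2), with the
#' LTR name, family, TSD and carrier list in INFO.
#'
#' @param truth truth data.frame from [simulate_cohort()].
#' @param reference named chromosome sequences (for REF base and contigs).
#' @param path output path.
#' @export
write_truth_vcf <- function(truth, reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=INS:ME,Description=\"Mobile element insertion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=MEINFO,Number=4,Type=String,Description=\"Mobile element info: name,family,TSDlen,TSDseq\">",
    "##INFO=<ID=CARRIERS,Number=.,Type=String,Description=\"Carrier individuals\">",
    sprintf("##contig=<ID=%s,length=%d>", names(reference), nchar(reference)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(truth)) {
    ref_base <- substr0(reference[truth$chrom], truth$pos - 1L, truth$pos)
    writeLines(sprintf(
      "%s\t%d\t%s\t%s\t<INS:ME>\t.\tPASS\tSVTYPE=INS;MEINFO=%s,%s,%d,%s;CARRIERS=%s",
      truth$chrom, truth$pos, truth$locus_id, ref_base, truth$ltr_name,
      truth$family, truth$tsd_length, truth$tsd_sequence, truth$carriers), con)
  }
  invisible(path)
}
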