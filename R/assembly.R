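#' Extract reads local to a TSD for assembly
#'
#' Returns all records whose mapped reference interval intersects the TSD
#' padded by `window` bp on each side, together with their mates (mapped
#' or not), which carry the inserted sequence.
#'
#' @param call single-row pass call (used for the chromosome).
#' @param tsd single-row TSD record from [detect_tsd()].
#' @param aln alignment table (see [read_sam()]).
#' @param window padding around the TSD in bp (default 150).
#' @return subset of `aln` rows (unique records).
#' @export
extract_local_reads <- function(call, tsd, aln, window = 150L) {
  lo <- tsd$start - window
  hi <- tsd$end + window             # half-open: [lo, hi)
  mapped <- !flag_isset(aln$flag, FLAG_UNMAPPED)
  pos0 <- aln$pos - 1L
  ref_end <- pos0 + cigar_ref_len(aln$cigar)
  in_win <- mapped & aln$rname == call$chrom & pos0 < hi & ref_end > lo
  qn <- unique(aln$qname[in_win])
  out <- aln[aln$qname %in% qn, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- greedy overlap-layout-consensus assembly -------------------------

# Best suffix(a)-prefix(b) overlap of length >= min_overlap at identity
# >= min_identity.  Candidate overlap lengths come from exact occurrences
# of two 12-mer seeds from the start of b inside a, so a mismatch cannot
# hide in both seed windows at identity levels of interest.
# Returns list(len, matches) or NULL.  Also detects containment of b in a
# (returned with len = nchar(b)).
best_overlap <- function(a, b, min_overlap, min_identity, seed_len = 12L) {
  la <- nchar(a); lb <- nchar(b)
  if (lb < min_overlap || la < min_overlap) return(NULL)
  cands <- integer(0)
  for (s in 0:1) {
    if (lb < (s + 1L) * seed_len) break
    seed <- substr(b, s * seed_len + 1L, (s + 1L) * seed_len)
    occ <- gregexpr(seed, a, fixed = TRUE)[[1]]
    if (occ[1] != -1L) cands <- c(cands, la - (occ - 1L) + s * seed_len)
  }
  cands <- unique(cands[cands >= min_overlap & cands <= la])
  if (!length(cands)) return(NULL)
  best <- NULL
  for (ov in sort(cands, decreasing = TRUE)) {
    span <- min(ov, lb)
    m <- count_matches(substr(a, la - ov + 1L, la - ov + span),
                       substr(b, 1L, span))
    if (m / span >= min_identity) {
      cand <- list(len = span, ov = ov, matches = m,
                   contained = ov >= lb)
      if (is.null(best) || cand$matches > best$matches) best <- cand
    }
  }
  best
}

merge_overlap <- function(a, b, ov, count_a, count_b, prefer_a) {
  la <- nchar(a); lb <- nchar(b)
  span <- min(ov, lb)
  if (ov >= lb) return(a)                       # containment
  asub <- substr(a, la - ov + 1L, la)
  bsub <- substr(b, 1L, span)
  if (asub != bsub) {
    # consensus on the overlap: majority by read count, ties to the
    # lexicographically leading contig
    ra <- charToRaw(asub); rb <- charToRaw(bsub)
    use_b <- count_b > count_a || (count_b == count_a && !prefer_a)
    if (use_b) ra[ra != rb] <- rb[ra != rb]
    asub <- rawToChar(ra)
  }
  paste0(substr(a, 1L, la - ov), asub, substr(b, span + 1L, lb))
}

#' Greedy overlap-layout-consensus assembly
#'
#' Repeatedly merges the pair of contigs with the highest-scoring
#' suffix-prefix overlap (>= `min_overlap` bp at >= `min_identity`), both
#' orientations considered, with consensus by majority read count and
#' deterministic tie-breaking by lexicographic read id.  Reads contained
#' in a longer contig are absorbed.  The result is independent of input
#' order.
#'
#' @param seqs character vector of read/contig sequences (>= 1).
#' @param ids read identifiers (default `r1`, `r2`, ...).
#' @param min_overlap minimum overlap length in bp (default 30).
#' @param min_identity minimum identity over the overlap (default 0.95).
#' @return data.frame of contigs: `contig_id`, `sequence`, `read_count`,
#'   `read_ids` (comma-separated), ordered by decreasing length.
#' @export
assemble_contigs <- function(seqs, ids = NULL,
                             min_overlap = 30L, min_identity = 0.95) {
  if (!length(seqs)) stop("no reads to assemble")
  if (is.null(ids)) ids <- sprintf("r%04d", seq_along(seqs))
  ord <- order(ids)
  seqs <- seqs[ord]; ids <- ids[ord]
  # collapse exact duplicates
  dup <- duplicated(seqs)
  counts <- as.integer(table(factor(seqs, levels = seqs[!dup])))
  id_groups <- split(ids, factor(seqs, levels = seqs[!dup]))
  contigs <- lapply(seq_along(which(!dup)), function(i) {
    s <- seqs[!dup][i]
    list(seq = s, rc = revcomp(s), count = counts[i],
         ids = sort(id_groups[[i]]), lead = sort(id_groups[[i]])[1])
  })

  pair_best <- function(ci, cj) {
    # best directed overlap ci -> cj over orientation combinations
    # (reverse complements are cached on the contigs)
    best <- NULL
    for (oa in c(FALSE, TRUE)) for (ob in c(FALSE, TRUE)) {
      a <- if (oa) ci$rc else ci$seq
      b <- if (ob) cj$rc else cj$seq
      r <- best_overlap(a, b, min_overlap, min_identity)
      if (!is.null(r) && (is.null(best) || r$matches > best$matches)) {
        best <- c(r, list(oa = oa, ob = ob))
      }
    }
    best
  }

  n <- length(contigs)
  info <- vector("list", n * n)
  score <- matrix(-1, n, n)
  set_pair <- function(i, j) {
    if (i == j || is.null(contigs[[i]]) || is.null(contigs[[j]])) {
      score[i, j] <<- -1; return(invisible())
    }
    r <- pair_best(contigs[[i]], contigs[[j]])
    info[(i - 1L) * n + j] <<- list(r)   # keep NULLs without shifting slots
    score[i, j] <<- if (is.null(r)) -1 else r$matches
  }
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) set_pair(i, j)

  repeat {
    m <- max(score)
    if (m < min_overlap * min_identity || m < 0) break
    hits <- which(score == m, arr.ind = TRUE)
    if (nrow(hits) > 1) {
      leads <- cbind(vapply(hits[, 1], function(i) contigs[[i]]$lead, ""),
                     vapply(hits[, 2], function(j) contigs[[j]]$lead, ""))
      hits <- hits[order(leads[, 1], leads[, 2]), , drop = FALSE]
    }
    i <- hits[1, 1]; j <- hits[1, 2]
    r <- info[[(i - 1L) * n + j]]
    ci <- contigs[[i]]; cj <- contigs[[j]]
    a <- if (r$oa) ci$rc else ci$seq
    b <- if (r$ob) cj$rc else cj$seq
    merged <- merge_overlap(a, b, r$ov, ci$count, cj$count,
                            prefer_a = ci$lead <= cj$lead)
    contigs[[i]] <- list(seq = merged, rc = revcomp(merged),
                         count = ci$count + cj$count,
                         ids = sort(c(ci$ids, cj$ids)),
                         lead = min(ci$lead, cj$lead))
    contigs[j] <- list(NULL)
    score[j, ] <- -1; score[, j] <- -1
    for (k in seq_len(n)) if (k != i) { set_pair(i, k); set_pair(k, i) }
  }

  keep <- !vapply(contigs, is.null, logical(1))
  out <- do.call(rbind, lapply(contigs[keep], function(ct) {
    data.frame(sequence = ct$seq, read_count = ct$count,
               read_ids = paste(ct$ids, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-nchar(out$sequence), out$sequence), , drop = FALSE]
  out <- cbind(contig_id = sprintf("ctg%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Deduce the inserted sequence from a junction-spanning contig
#'
#' The non-reference insertion is delimited on each side by the TSD; when
#' the TSD is shorter than `flank` bp it is too short to anchor reliably,
#' and the `flank` bp of reference sequence immediately 5' and 3' of the
#' TSD are used as delimiters instead (the TSD copies inside the
#' delimited region are then stripped).  Both contig orientations are
#' tried.  A delimiter occurring more than the expected number of times
#' makes the locus ambiguous: NULL is returned with a warning.
#'
#' @param contig contig sequence (character scalar).
#' @param tsd single-row TSD record (see [detect_tsd()]).
#' @param reference named chromosome sequences.
#' @param flank delimiter length when the TSD is insufficient (default 6).
#' @return the inserted (LTR) sequence, or NULL when the contig does not
#'   span both junctions or the delimiters are ambiguous.
#' @export
deduce_insertion_sequence <- function(contig, tsd, reference, flank = 6L) {
  ref_seq <- reference[[tsd$chrom]]
  use_tsd <- tsd$length >= flank
  for (ctg in c(contig, revcomp(contig))) {
    if (use_tsd) {
      occ <- gregexpr(tsd$sequence, ctg, fixed = TRUE)[[1]]
      if (occ[1] == -1L) next
      if (length(occ) > 2L) {
        warning("ambiguous TSD delimiter (>2 occurrences); locus skipped")
        return(NULL)
      }
      if (length(occ) != 2L) next
      ins <- substr(ctg, occ[1] + tsd$length, occ[2] - 1L)
      if (nchar(ins) > 0L) return(ins)
    } else {
      d5 <- substr0(ref_seq, tsd$start - flank, tsd$start)
      d3 <- substr0(ref_seq, tsd$end, tsd$end + flank)
      o5 <- gregexpr(d5, ctg, fixed = TRUE)[[1]]
      o3 <- gregexpr(d3, ctg, fixed = TRUE)[[1]]
      if (o5[1] == -1L || o3[1] == -1L) next
      if (length(o5) > 1L || length(o3) > 1L) {
        warning("ambiguous flank delimiter (multiple occurrences); locus skipped")
        return(NULL)
      }
      inner <- substr(ctg, o5 + flank, o3 - 1L)   # TSD + LTR + TSD
      L <- tsd$length
      if (nchar(inner) <= 2L * L) next
      if (substr(inner, 1L, L) != tsd$sequence ||
          substr(inner, nchar(inner) - L + 1L, nchar(inner)) != tsd$sequence) {
        next
      }
      return(substr(inner, L + 1L, nchar(inner) - L))
    }
  }
  NULL
}
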