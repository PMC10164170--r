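#' Read-pair taxonomy and anchor discovery
#'
#' Paired-end mapping signatures around a non-reference insertion: proper
#' pairs (both mates mapped, opposite strands, expected insert), discordant
#' pairs (unexpected span/orientation), split reads (long soft-clip at the
#' junction), singletons (one mate unmapped) and unmapped pairs.  Split
#' reads, singletons and discordant pairs whose free end matches the LTR
#' query library become anchor evidence for breakpoint calling.
#'
#' @name pair_classes
NULL

PAIR_CLASSES <- c("proper", "discordant", "split", "singleton", "unmapped_pair")

#' Join an alignment table into mate pairs
#'
#' @param aln alignment table (see [read_sam()]).
#' @return data.frame with one row per read pair, mate fields suffixed
#'   `_1` / `_2`, plus derived columns (`mapped_i`, `reverse_i`,
#'   `ref_len_i`, `clip_left_i`, `clip_right_i`).
#' @export
pair_records <- function(aln) {
  first <- aln[flag_isset(aln$flag, FLAG_FIRST), , drop = FALSE]
  second <- aln[flag_isset(aln$flag, FLAG_SECOND), , drop = FALSE]
  idx <- match(first$qname, second$qname)
  if (anyNA(idx)) stop("unpaired records: mate missing for some read names")
  second <- second[idx, , drop = FALSE]
  decorate <- function(x, suffix) {
    d <- data.frame(
      rname = x$rname, pos0 = x$pos - 1L, mapq = x$mapq, cigar = x$cigar,
      seq = x$seq,
      mapped = !flag_isset(x$flag, FLAG_UNMAPPED),
      reverse = flag_isset(x$flag, FLAG_REVERSE),
      ref_len = cigar_ref_len(x$cigar),
      stringsAsFactors = FALSE
    )
    clips <- cigar_clips(x$cigar)
    d$clip_left <- clips[, "left"]; d$clip_right <- clips[, "right"]
    names(d) <- paste0(names(d), suffix)
    d
  }
  out <- cbind(data.frame(qname = first$qname, stringsAsFactors = FALSE),
               decorate(first, "_1"), decorate(second, "_2"))
  rownames(out) <- NULL
  out
}

#' Estimate insert-size limits from proper-orientation pairs
#'
#' Limits are mean +/- `n_sd` standard deviations of the inferred insert
#' over a sample of both-mapped, opposite-strand, same-chromosome pairs.
#'
#' @param pairs data.frame from [pair_records()].
#' @param n_sd number of standard deviations (default 4).
#' @param max_pairs sample size cap (default 100,000).
#' @return numeric `c(lower, upper)`.
#' @export
estimate_insert_limits <- function(pairs, n_sd = 4, max_pairs = 100000L) {
  ok <- pairs$mapped_1 & pairs$mapped_2 & pairs$rname_1 == pairs$rname_2 &
    xor(pairs$reverse_1, pairs$reverse_2)
  sub <- head(pairs[ok, , drop = FALSE], max_pairs)
  if (!nrow(sub)) stop("no proper-orientation pairs to estimate insert size")
  ins <- pmax(sub$pos0_1 + sub$ref_len_1, sub$pos0_2 + sub$ref_len_2) -
    pmin(sub$pos0_1, sub$pos0_2)
  m <- mean(ins); s <- stats::sd(ins)
  if (is.na(s)) s <- 0
  c(lower = max(0, m - n_sd * s), upper = m + n_sd * s)
}

#' Classify read pairs into the five-class taxonomy
#'
#' Precedence: `unmapped_pair` (neither mate mapped) > `singleton` (exactly
#' one mapped) > `split` (a mate carries a soft-clip >= `min_clip`) >
#' `proper` (both mapped, opposite strands, same chromosome, inferred
#' insert within `insert_limits`) > `discordant`.
#'
#' @param pairs data.frame from [pair_records()].
#' @param insert_limits numeric `c(lower, upper)`.
#' @param min_clip minimum soft-clip length for the split class (default 10).
#' @return factor of classes, one per pair.
#' @export
classify_pairs <- function(pairs, insert_limits, min_clip = 10L) {
  n <- nrow(pairs)
  insert <- ifelse(pairs$mapped_1 & pairs$mapped_2 &
                     pairs$rname_1 == pairs$rname_2,
                   pmax(pairs$pos0_1 + pairs$ref_len_1,
                        pairs$pos0_2 + pairs$ref_len_2) -
                     pmin(pairs$pos0_1, pairs$pos0_2), NA_real_)
  has_clip <- pmax(pairs$clip_left_1, pairs$clip_right_1,
                   pairs$clip_left_2, pairs$clip_right_2) >= min_clip
  cls <- rep("discordant", n)
  cls[pairs$mapped_1 & pairs$mapped_2 & !has_clip &
        xor(pairs$reverse_1, pairs$reverse_2) &
        !is.na(insert) & insert >= insert_limits[1] &
        insert <= insert_limits[2]] <- "proper"
  cls[(pairs$mapped_1 | pairs$mapped_2) & has_clip] <- "split"
  cls[xor(pairs$mapped_1, pairs$mapped_2) & !has_clip] <- "singleton"
  cls[!pairs$mapped_1 & !pairs$mapped_2] <- "unmapped_pair"
  factor(cls, levels = PAIR_CLASSES)
}

#' Classify a single read pair
#'
#' @param rec1,rec2 single-row alignment records (mates of one pair).
#' @param insert_limits numeric `c(lower, upper)`.
#' @param min_clip minimum soft-clip length for the split class.
#' @return one of `"proper"`, `"discordant"`, `"split"`, `"singleton"`,
#'   `"unmapped_pair"`.
#' @export
classify_read_pair <- function(rec1, rec2, insert_limits, min_clip = 10L) {
  if (rec1$qname != rec2$qname) stop("mismatched read names")
  aln <- rbind(rec1, rec2)
  as.character(classify_pairs(pair_records(aln), insert_limits, min_clip))
}

## ---- library k-mer matching -------------------------------------------

# k-mer index over the library: named vector kmer -> "entry_idx:pos"
# (first occurrence wins; random-sequence libraries have few collisions).
library_kmer_index <- function(library, k) {
  seqs <- library_sequences(library)
  ent <- integer(0); pos <- integer(0); kmer <- character(0)
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[i]) - k + 1L
    if (n < 1L) next
    kmer <- c(kmer, substring(seqs[i], seq_len(n), seq_len(n) + k - 1L))
    ent <- c(ent, rep(i, n)); pos <- c(pos, seq_len(n))
  }
  keep <- !duplicated(kmer)
  list(kmer = kmer[keep], entry = ent[keep], pos = pos[keep], k = k)
}

#' Match query sequences against the LTR library
#'
#' Exact k-mer seeding (k-mers sampled along the query at stride k) followed
#' by ungapped extension along the seed diagonal; the best hit per query is
#' kept if its identity over the overlap reaches `min_identity`.  Both
#' query strands are searched.
#'
#' @param queries character vector of query sequences.
#' @param library an `ltr_library`.
#' @param k seed length (default 15).
#' @param min_identity minimum identity over the ungapped overlap
#'   (default 0.9).
#' @param min_span minimum overlap length in bp (default `k`).
#' @return data.frame (one row per query) with `entry` (library name or
#'   NA), `identity`, `span`.
#' @export
match_library <- function(queries, library, k = 15L, min_identity = 0.9,
                          min_span = k) {
  if (!length(library)) stop("empty LTR library")
  idx <- library_kmer_index(library, k)
  seqs <- library_sequences(library)
  lib_len <- nchar(seqs)
  nq <- length(queries)
  best <- data.frame(entry = rep(NA_character_, nq),
                     identity = rep(NA_real_, nq),
                     span = rep(NA_integer_, nq))
  if (!nq) return(best)

  strands <- list(fwd = queries, rev = revcomp(queries))
  cand <- list()
  for (st in names(strands)) {
    q <- strands[[st]]
    qlen <- nchar(q)
    offs <- lapply(qlen, function(l) {
      if (l < k) return(integer(0))
      unique(c(seq(1L, l - k + 1L, by = k), l - k + 1L))
    })
    n_off <- lengths(offs)
    if (!sum(n_off)) next
    qi <- rep(seq_len(nq), n_off)
    o <- unlist(offs, use.names = FALSE)
    kmers <- substring(q[qi], o, o + k - 1L)
    hit <- match(kmers, idx$kmer)
    ok <- !is.na(hit)
    if (!any(ok)) next
    cand[[st]] <- data.frame(query = qi[ok], offset = o[ok],
                             entry = idx$entry[hit[ok]],
                             lpos = idx$pos[hit[ok]],
                             strand = st, stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand)) return(best)
  cand$diag <- cand$lpos - cand$offset
  cand <- cand[!duplicated(cand[c("query", "entry", "strand", "diag")]), ]

  q <- ifelse(cand$strand == "fwd", queries[cand$query],
              revcomp(queries[cand$query]))
  qlen <- nchar(q)
  j1 <- pmax(1L, 1L - cand$diag)
  j2 <- pmin(qlen, lib_len[cand$entry] - cand$diag)
  span <- j2 - j1 + 1L
  qsub <- substr(q, j1, j2)
  lsub <- substr(seqs[cand$entry], j1 + cand$diag, j2 + cand$diag)
  matches <- count_matches(qsub, lsub)
  cand$span <- span
  cand$identity <- matches / pmax(span, 1L)
  cand <- cand[cand$span >= min_span & cand$identity >= min_identity, ]
  if (!nrow(cand)) return(best)
  cand <- cand[order(cand$query, -cand$identity * cand$span, cand$entry), ]
  top <- cand[!duplicated(cand$query), ]
  best$entry[top$query] <- names(library)[top$entry]
  best$identity[top$query] <- top$identity
  best$span[top$query] <- top$span
  best
}

#' Discover anchor evidence for non-reference LTR insertions
#'
#' Scans read pairs for the non-proper signatures, matches each pair's
#' free end (unmapped mate, distant mate, or clipped tail) against the LTR
#' library, and emits one anchor-evidence row per supporting read.  The
#' anchor side records the anchor's orientation relative to the putative
#' insertion: a forward-strand anchor (or a right-clipped split read) faces
#' the insertion from the 5' side; a reverse-strand anchor (or left clip)
#' from the 3' side.
#'
#' @param aln alignment table (see [read_sam()]), coordinate-sorted.
#' @param library an `ltr_library`.
#' @param insert_limits numeric `c(lower, upper)`; estimated from the data
#'   via [estimate_insert_limits()] when NULL.
#' @param min_mapq minimum mapping quality for the anchor mate (default 20).
#' @param min_clip minimum soft-clip length for split evidence (default 10).
#' @param k seed length for library matching (default 15).
#' @param min_identity minimum identity for a library hit (default 0.9).
#' @return data.frame of anchor evidence sorted by chromosome and position:
#'   `chrom`, `position` (0-based), `side`, `mate_hit`, `evidence_kind`,
#'   `read_id`, `identity`.
#' @export
discover_anchors <- function(aln, library, insert_limits = NULL,
                             min_mapq = 20L, min_clip = 10L, k = 15L,
                             min_identity = 0.9) {
  if (!length(library)) stop("empty LTR library")
  pairs <- pair_records(aln)
  if (is.null(insert_limits)) insert_limits <- estimate_insert_limits(pairs)
  cls <- classify_pairs(pairs, insert_limits, min_clip)

  cand <- list()
  add_cand <- function(df) if (nrow(df)) cand[[length(cand) + 1L]] <<- df

  anchor_fields <- function(p, mate) {
    # anchor geometry for mate 1 or 2 of the pair rows `p`
    sfx <- paste0("_", mate)
    data.frame(
      chrom = p[[paste0("rname", sfx)]],
      position = ifelse(p[[paste0("reverse", sfx)]],
                        p[[paste0("pos0", sfx)]],
                        p[[paste0("pos0", sfx)]] + p[[paste0("ref_len", sfx)]]),
      side = ifelse(p[[paste0("reverse", sfx)]], "three_prime", "five_prime"),
      read_id = paste0(p$qname, "/", mate),
      stringsAsFactors = FALSE
    )
  }

  # singleton: unmapped mate searched against the library
  for (mate in 1:2) {
    other <- 3L - mate
    sel <- cls == "singleton" & pairs[[paste0("mapped_", mate)]] &
      pairs[[paste0("mapq_", mate)]] >= min_mapq
    if (any(sel)) {
      p <- pairs[sel, , drop = FALSE]
      a <- anchor_fields(p, mate)
      a$query <- p[[paste0("seq_", other)]]
      a$evidence_kind <- "singleton"
      add_cand(a)
    }
  }

  # split: clipped tail searched against the library; the junction itself
  # is the anchor position
  for (mate in 1:2) {
    m <- paste0("_", mate)
    sel <- cls == "split" & pairs[[paste0("mapped", m)]] &
      pairs[[paste0("mapq", m)]] >= min_mapq &
      pmax(pairs[[paste0("clip_left", m)]],
           pairs[[paste0("clip_right", m)]]) >= min_clip
    if (any(sel)) {
      p <- pairs[sel, , drop = FALSE]
      cl <- p[[paste0("clip_left", m)]]; cr <- p[[paste0("clip_right", m)]]
      use_right <- cr >= cl
      seqs <- p[[paste0("seq", m)]]
      a <- data.frame(
        chrom = p[[paste0("rname", m)]],
        position = ifelse(use_right,
                          p[[paste0("pos0", m)]] + p[[paste0("ref_len", m)]],
                          p[[paste0("pos0", m)]]),
        side = ifelse(use_right, "five_prime", "three_prime"),
        read_id = paste0(p$qname, "/", mate),
        query = ifelse(use_right,
                       substr(seqs, nchar(seqs) - cr + 1L, nchar(seqs)),
                       substr(seqs, 1L, cl)),
        evidence_kind = "split", stringsAsFactors = FALSE
      )
      add_cand(a)
    }
  }

  # discordant with a distant mate: the distant mate is the library query
  disc <- cls == "discordant" & pairs$mapped_1 & pairs$mapped_2 &
    (pairs$rname_1 != pairs$rname_2 |
       pmax(pairs$pos0_1 + pairs$ref_len_1, pairs$pos0_2 + pairs$ref_len_2) -
       pmin(pairs$pos0_1, pairs$pos0_2) > insert_limits[2])
  for (mate in 1:2) {
    other <- 3L - mate
    sel <- disc & pairs[[paste0("mapq_", mate)]] >= min_mapq
    if (any(sel)) {
      p <- pairs[sel, , drop = FALSE]
      a <- anchor_fields(p, mate)
      a$query <- p[[paste0("seq_", other)]]
      a$evidence_kind <- "discordant"
      add_cand(a)
    }
  }

  empty <- data.frame(chrom = character(0), position = integer(0),
                      side = character(0), mate_hit = character(0),
                      evidence_kind = character(0), read_id = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE)
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  hits <- match_library(cand$query, library, k = k,
                        min_identity = min_identity)
  keep <- !is.na(hits$entry)
  if (!any(keep)) return(empty)
  out <- data.frame(chrom = cand$chrom[keep],
                    position = as.integer(cand$position[keep]),
                    side = cand$side[keep],
                    mate_hit = hits$entry[keep],
                    evidence_kind = cand$evidence_kind[keep],
                    read_id = cand$read_id[keep],
                    identity = hits$identity[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$position, out$read_id), ]
  rownames(out) <- NULL
  out
}
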