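#' Breakpoint calling from anchor evidence
#'
#' Anchors within a clustering window on one chromosome form one candidate
#' breakpoint call.  Split-read junctions, when present, pin the position:
#' the call position is the midpoint between the rightmost 5'-side junction
#' and the leftmost 3'-side junction (which differ by the TSD length at a
#' genuine insertion).  Without split reads, the midpoint between the
#' rightmost 5'-side anchor end and the leftmost 3'-side anchor start is
#' used, falling back to the median anchor position for one-sided clusters.
#'
#' @param anchors anchor-evidence data.frame from [discover_anchors()],
#'   sorted by chromosome and position.
#' @param window clustering window in bp (default 400, of the order of the
#'   fragment mean).
#' @param max_depth per-call cap on counted evidence reads (default 10,000).
#' @param library optional `ltr_library` used to translate anchor entry
#'   names into family labels; without it, entry names are grouped by a
#'   name-based heuristic.
#' @return data.frame of calls: `chrom`, `position` (0-based),
#'   `support_5p`, `support_3p`, `support_total`, `split_5p`, `split_3p`,
#'   `split_support`, `n_families`, `family`, `orient_consistent`,
#'   `filter_level`, `status` (NA until [filter_and_merge()]).
#' @export
call_breakpoints <- function(anchors, window = 400L, max_depth = 10000L,
                             library = NULL) {
  fam_lookup <- if (!is.null(library)) {
    setNames(library_families(library), names(library))
  } else NULL
  cols <- c("chrom", "position", "support_5p", "support_3p", "support_total",
            "split_5p", "split_3p", "split_support", "n_families", "family",
            "orient_consistent", "filter_level", "status")
  if (is.null(anchors) || !nrow(anchors)) {
    out <- data.frame(chrom = character(0), position = integer(0),
                      support_5p = integer(0), support_3p = integer(0),
                      support_total = integer(0), split_5p = integer(0),
                      split_3p = integer(0), split_support = integer(0),
                      n_families = integer(0), family = character(0),
                      orient_consistent = logical(0),
                      filter_level = integer(0), status = character(0))
    return(out)
  }
  anchors <- anchors[order(anchors$chrom, anchors$position), , drop = FALSE]
  new_cluster <- c(TRUE, diff(anchors$position) > window |
                     anchors$chrom[-1] != anchors$chrom[-nrow(anchors)])
  cl <- cumsum(new_cluster)
  calls <- lapply(split(anchors, cl), function(a) {
    if (nrow(a) > max_depth) a <- a[seq_len(max_depth), , drop = FALSE]
    is5 <- a$side == "five_prime"
    split5 <- a$evidence_kind == "split" & is5
    split3 <- a$evidence_kind == "split" & !is5
    pos <- if (any(split5) && any(split3)) {
      (max(a$position[split5]) + min(a$position[split3])) %/% 2L
    } else if (any(split5)) {
      max(a$position[split5])
    } else if (any(split3)) {
      min(a$position[split3])
    } else if (any(is5) && any(!is5)) {
      (max(a$position[is5]) + min(a$position[!is5])) %/% 2L
    } else {
      as.integer(median(a$position))
    }
    fams <- if (!is.null(fam_lookup)) unname(fam_lookup[a$mate_hit]) else
      library_family_of(a$mate_hit)
    fam_tab <- sort(table(fams), decreasing = TRUE)
    overlap_ok <- any(is5) && any(!is5) &&
      (max(a$position[is5]) - min(a$position[!is5])) <= 12L
    data.frame(
      chrom = a$chrom[1], position = pos,
      support_5p = sum(is5), support_3p = sum(!is5),
      support_total = nrow(a),
      split_5p = sum(split5), split_3p = sum(split3),
      split_support = sum(split5) + sum(split3),
      n_families = length(fam_tab),
      family = names(fam_tab)[1],
      orient_consistent = overlap_ok,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, calls)
  out <- out[order(out$chrom, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out$filter_level <- vapply(seq_len(nrow(out)), function(i) {
    assign_filter_level(out[i, ])
  }, integer(1))
  out$status <- NA_character_
  out
}

# anchors carry entry names; map to family via a small lookup built once
library_family_of <- function(entry_names) {
  fam <- sub("-LTR.*$", "", entry_names)
  fam[startsWith(entry_names, "EAV")] <- "EAV"
  fam
}

#' Confidence ladder for a breakpoint call
#'
#' A monotone eight-rung surrogate for per-call confidence: starting from
#' 1, one rung each for (a) evidence on both sides, (b) at least 3 reads on
#' each side, (c) total support of at least 10, (d) a single supporting
#' library family, (e) consistent two-sided geometry (the 5'- and 3'-side
#' evidence fronts overlap by at most a TSD-scale margin), (f) any
#' split-read support, and (g) split-read support on both sides.  Level 8
#' is therefore only reachable with split support on both sides, and the
#' level never decreases when any evidence count increases (with family
#' composition and geometry held fixed).
#'
#' @param call single-row call data.frame (see [call_breakpoints()]).
#' @return integer level 1-8.
#' @export
assign_filter_level <- function(call) {
  lvl <- 1L
  if (call$support_5p >= 1 && call$support_3p >= 1) lvl <- lvl + 1L
  if (call$support_5p >= 3 && call$support_3p >= 3) lvl <- lvl + 1L
  if (call$support_total >= 10) lvl <- lvl + 1L
  if (call$n_families <= 1) lvl <- lvl + 1L
  if (isTRUE(call$orient_consistent)) lvl <- lvl + 1L
  if (call$split_support >= 1) lvl <- lvl + 1L
  if (call$split_5p >= 1 && call$split_3p >= 1) lvl <- lvl + 1L
  as.integer(lvl)
}

#' Filter calls by support and level, merging near-duplicates
#'
#' Calls below `min_reads` total support are flagged `low_support`; calls
#' below `min_level` are flagged `low_level`.  Among the remaining passing
#' calls, any group on one chromosome linked by gaps of at most
#' `merge_window` bp is considered one locus: the highest-support member is
#' kept (`pass`), the rest are flagged `merged_away`.  The operation is
#' idempotent and leaves no two pass calls within `merge_window` of each
#' other.
#'
#' @param calls call data.frame from [call_breakpoints()].
#' @param min_reads minimum total supporting reads (default 10).
#' @param min_level minimum filter level (default 7).
#' @param merge_window merge distance in bp (default 500).
#' @return the calls with `status` filled in, original order preserved.
#' @export
filter_and_merge <- function(calls, min_reads = 10L, min_level = 7L,
                             merge_window = 500L) {
  if (!nrow(calls)) return(calls)
  status <- rep("pass", nrow(calls))
  status[calls$filter_level < min_level] <- "low_level"
  status[calls$support_total < min_reads] <- "low_support"
  passing <- which(status == "pass")
  if (length(passing) > 1) {
    p <- calls[passing, , drop = FALSE]
    ord <- order(p$chrom, p$position)
    po <- p[ord, , drop = FALSE]
    new_cluster <- c(TRUE, diff(po$position) > merge_window |
                       po$chrom[-1] != po$chrom[-nrow(po)])
    cl <- cumsum(new_cluster)
    for (g in split(seq_len(nrow(po)), cl)) {
      if (length(g) == 1) next
      best <- g[order(-po$support_total[g], po$position[g])][1]
      losers <- setdiff(g, best)
      status[passing[ord[losers]]] <- "merged_away"
    }
  }
  calls$status <- status
  calls
}

#' Detect the target-site duplication at a passing call
#'
#' Junction reads on the two sides of a genuine insertion overlap on the
#' reference by the length of the duplicated target site: 5'-side junction
#' reads (right soft-clip) end at the insertion point while 3'-side
#' junction reads (left soft-clip) start at the beginning of the TSD.  Let
#' `R5` be the rightmost reference coordinate reached by 5'-side junctions
#' and `L3` the leftmost coordinate where 3'-side junctions start; if
#' `1 <= R5 - L3 <= max_len` the interval `[L3, R5)` is reported as the
#' TSD.
#'
#' @param call single-row pass call.
#' @param aln alignment table (see [read_sam()]).
#' @param reference named chromosome sequences.
#' @param window how far from the call position junctions are collected
#'   (default 20 bp).
#' @param max_len maximum TSD length (default 10).
#' @return a one-row data.frame (`chrom`, `start`, `end`, `sequence`,
#'   `length`) or NULL when no 1-`max_len` bp overlap exists.
#' @export
detect_tsd <- function(call, aln, reference, window = 20L, max_len = 10L) {
  ref_seq <- reference[[call$chrom]]
  if (is.null(ref_seq) || call$position < 0 || call$position > nchar(ref_seq)) {
    stop("call position outside the reference")
  }
  near <- aln[aln$rname == call$chrom & !flag_isset(aln$flag, FLAG_UNMAPPED) &
                abs(aln$pos - 1L - call$position) <= window + 200L, ,
              drop = FALSE]
  if (!nrow(near)) return(NULL)
  clips <- cigar_clips(near$cigar)
  ref_len <- cigar_ref_len(near$cigar)
  right_j <- near$pos - 1L + ref_len   # junction of right-clipped reads
  left_j <- near$pos - 1L              # junction of left-clipped reads
  r_ok <- clips[, "right"] > 0L & abs(right_j - call$position) <= window
  l_ok <- clips[, "left"] > 0L & abs(left_j - call$position) <= window
  if (!any(r_ok) || !any(l_ok)) return(NULL)
  R5 <- max(right_j[r_ok])
  L3 <- min(left_j[l_ok])
  ov <- R5 - L3
  if (ov < 1L || ov > max_len) return(NULL)
  data.frame(chrom = call$chrom, start = L3, end = R5,
             sequence = substr0(ref_seq, L3, R5), length = ov,
             stringsAsFactors = FALSE)
}
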