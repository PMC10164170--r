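#' Per-locus LTR sequence analysis
#'
#' Multi-sequence comparison of the LTR copies recovered at one locus
#' across individuals: progressive alignment, substitution counting,
#' U3/R/U5 segmentation against an annotated prototype, EAV mosaic-pattern
#' typing, and distance-based phylogeny (K2P + neighbor joining).
#'
#' @name ltr_analysis
NULL

IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

nw_scoring <- function() list(match = 1, mismatch = -1, gap = -2)

# Global Needleman-Wunsch via Biostrings with the module's linear gap
# model (gap open 0, extension |gap|); returns aligned pattern/subject
# strings and the identity over alignment columns.
#
# Fast path for equal-length sequences: at >= 90% ungapped identity the
# gap-free alignment is optimal (a gap pair costs more than the mismatches
# it can save under gap -2 / mismatch -1); at <= 40% the pair is far below
# every decision gate in this module (0.6 segmentation, 0.8 region typing)
# and only the identity value is consumed, so the ungapped identity is an
# adequate lower bound.  The 0.4-0.9 band always takes the exact DP.
.nw_cache <- new.env(parent = emptyenv())

nw_align <- function(query, subject, scoring = nw_scoring()) {
  if (nchar(query) == nchar(subject) && nchar(query) > 0) {
    m <- count_matches(query, subject)
    if (m / nchar(query) >= 0.9 || m / nchar(query) <= 0.4) {
      return(list(query = query, subject = subject,
                  identity = m / nchar(query)))
    }
  }
  key <- sprintf("m_%g_%g", scoring$match, scoring$mismatch)
  mat <- .nw_cache[[key]]
  if (is.null(mat)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
    .nw_cache[[key]] <- mat
  }
  al <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = "global",
    substitutionMatrix = mat, gapOpening = 0,
    gapExtension = abs(scoring$gap))
  ap <- as.character(Biostrings::alignedPattern(al))
  as <- as.character(Biostrings::alignedSubject(al))
  list(query = ap, subject = as,
       identity = Biostrings::nmatch(al) / nchar(ap))
}

## ---- progressive multiple alignment -----------------------------------

# profile = character matrix (rows = sequences, named; cols = alignment
# columns).  Profile-profile Needleman-Wunsch with sum-of-pairs column
# scores and a linear per-column gap penalty.
profile_counts <- function(prof) {
  bases <- c("A", "C", "G", "T")
  out <- matrix(0, 4L, ncol(prof), dimnames = list(bases, NULL))
  for (b in bases) out[b, ] <- colSums(prof == b)
  out
}

align_profiles <- function(pa, pb, scoring = nw_scoring()) {
  fa <- profile_counts(pa); fb <- profile_counts(pb)
  s5 <- matrix(scoring$mismatch, 4, 4); diag(s5) <- scoring$match
  cs <- (t(fa) %*% s5 %*% fb) / (nrow(pa) * nrow(pb))
  la <- ncol(pa); lb <- ncol(pb); g <- scoring$gap
  H <- matrix(0, la + 1L, lb + 1L)
  H[1, ] <- g * (0:lb); H[, 1] <- g * (0:la)
  for (d in 2:(la + lb)) {
    i <- max(1L, d - lb):min(la, d - 1L)
    j <- d - i
    H[cbind(i + 1L, j + 1L)] <- pmax(H[cbind(i, j)] + cs[cbind(i, j)],
                                     H[cbind(i, j + 1L)] + g,
                                     H[cbind(i + 1L, j)] + g)
  }
  # traceback (diagonal > up > left for determinism)
  i <- la; j <- lb
  path <- character(la + lb)
  np <- 0L
  eps <- 1e-9
  while (i > 0L || j > 0L) {
    np <- np + 1L
    if (i > 0L && j > 0L &&
        abs(H[i + 1L, j + 1L] - (H[i, j] + cs[i, j])) < eps) {
      path[np] <- "D"; i <- i - 1L; j <- j - 1L
    } else if (i > 0L && abs(H[i + 1L, j + 1L] - (H[i, j + 1L] + g)) < eps) {
      path[np] <- "U"; i <- i - 1L
    } else {
      path[np] <- "L"; j <- j - 1L
    }
  }
  path <- rev(path[seq_len(np)])
  ncols <- length(path)
  out <- matrix("-", nrow(pa) + nrow(pb), ncols,
                dimnames = list(c(rownames(pa), rownames(pb)), NULL))
  ai <- cumsum(path != "L"); bi <- cumsum(path != "U")
  acols <- path != "L"; bcols <- path != "U"
  out[seq_len(nrow(pa)), acols] <- pa[, ai[acols], drop = FALSE]
  out[nrow(pa) + seq_len(nrow(pb)), bcols] <- pb[, bi[bcols], drop = FALSE]
  out
}

#' Progressive multiple alignment of the LTR copies at a locus
#'
#' Pairwise global-alignment distances feed an average-linkage (UPGMA)
#' guide tree; profiles are then merged bottom-up with a profile-profile
#' Needleman-Wunsch (sum-of-pairs scores, linear gap penalty).  The
#' procedure is deterministic.
#'
#' @param seqs named character vector of >= 2 sequences, each >= 50 bp,
#'   IUPAC nucleotide characters only.
#' @param scoring list with `match`, `mismatch`, `gap` (defaults +1/-1/-2).
#' @return object of class `locus_alignment`: list with `seqs` (named
#'   aligned sequences, gap `-`) and `ncol`.
#' @export
align_locus_sequences <- function(seqs, scoring = nw_scoring()) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (any(nchar(seqs) < 50)) stop("sequences must be at least 50 bp")
  if (any(grepl(sprintf("[^%s]", IUPAC_CHARS), seqs))) {
    stop("sequences contain non-IUPAC characters")
  }
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  n <- length(seqs)
  dmat <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dmat[i, j] <- dmat[j, i] <- 1 - nw_align(seqs[[i]], seqs[[j]], scoring)$identity
  }
  profiles <- lapply(seq_len(n), function(i) {
    matrix(strsplit(seqs[[i]], "", fixed = TRUE)[[1]], nrow = 1,
           dimnames = list(names(seqs)[i], NULL))
  })
  if (n == 2) {
    merged <- align_profiles(profiles[[1]], profiles[[2]], scoring)
  } else {
    hc <- hclust(as.dist(dmat), method = "average")
    node_prof <- vector("list", n - 1)
    get_prof <- function(k) if (k < 0) profiles[[-k]] else node_prof[[k]]
    for (m in seq_len(n - 1)) {
      node_prof[[m]] <- align_profiles(get_prof(hc$merge[m, 1]),
                                       get_prof(hc$merge[m, 2]), scoring)
    }
    merged <- node_prof[[n - 1]]
  }
  merged <- merged[names(seqs), , drop = FALSE]
  aligned <- setNames(apply(merged, 1, paste, collapse = ""), names(seqs))
  structure(list(seqs = aligned, ncol = ncol(merged)),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("locus_alignment: %d sequences x %d columns\n",
              length(x$seqs), x$ncol))
  invisible(x)
}

#' Count substituted columns in a locus alignment
#'
#' A column counts as one substitution when it contains at least two
#' distinct non-gap bases; columns differing only by gaps do not count.
#'
#' @param alignment a `locus_alignment` (or named character vector of
#'   equal-length aligned sequences).
#' @return integer number of substituted columns.
#' @export
count_substitutions <- function(alignment) {
  seqs <- if (inherits(alignment, "locus_alignment")) alignment$seqs
  else alignment
  m <- seq_to_matrix(unname(seqs))
  sum(apply(m, 2, function(col) {
    length(unique(col[col != "-"])) >= 2
  }))
}

#' Segment an LTR sequence into U3/R/U5 via an annotated prototype
#'
#' The query is globally aligned to the prototype and the prototype's
#' U3|R and R|U5 boundary columns are projected through the alignment onto
#' the query, yielding three query intervals that partition it.  Query
#' insertions sitting exactly on a boundary are assigned to the upstream
#' region.
#'
#' @param sequence query LTR sequence.
#' @param prototype an `ltr_entry` with annotated boundaries.
#' @param min_identity minimum alignment identity; below it the prototype
#'   is considered wrong and the call fails (default 0.6).
#' @return list of 0-based half-open intervals `u3`, `r`, `u5` on the
#'   query, plus `identity`.
#' @export
segment_ltr <- function(sequence, prototype, min_identity = 0.6) {
  al <- nw_align(sequence, prototype$sequence)
  if (al$identity < min_identity) {
    stop(sprintf("alignment identity %.2f below %.2f: wrong prototype?",
                 al$identity, min_identity))
  }
  qc <- strsplit(al$query, "", fixed = TRUE)[[1]]
  pc <- strsplit(al$subject, "", fixed = TRUE)[[1]]
  colq <- cumsum(qc != "-")
  colp <- cumsum(pc != "-")
  project <- function(b) {
    if (b <= 0) return(0L)
    idx <- which(colp == b)
    if (!length(idx)) return(as.integer(max(colq)))
    as.integer(colq[max(idx)])
  }
  q1 <- project(prototype$u3[["end"]])
  q2 <- project(prototype$r[["end"]])
  qlen <- nchar(sequence)
  list(u3 = c(start = 0L, end = q1),
       r = c(start = q1, end = q2),
       u5 = c(start = q2, end = qlen),
       identity = al$identity)
}

#' Type an EAV LTR by its U3 and R+U5 mosaic pattern
#'
#' The sequence is segmented against the closest EAV prototype in the
#' library, each region is assigned to the region prototype with the
#' highest alignment identity, and the (U3-type, RU5-type) combination is
#' mapped to the mosaic letters: (I,I) -> A, (I,II) -> B, (II,II) -> C,
#' (III,I) -> D; any other combination, or a region identity below
#' `min_region_identity`, gives `novel`.
#'
#' @param sequence query LTR sequence.
#' @param library an `ltr_library` whose EAV entries carry `region_types`.
#' @param min_region_identity identity gate per region (default 0.8).
#' @param min_seg_identity segmentation gate (default 0.6); failure to
#'   segment against any EAV prototype is an error.
#' @return one-row data.frame: `u3_type`, `ru5_type`, `pattern`,
#'   `u3_identity`, `ru5_identity`.
#' @export
classify_eav_pattern <- function(sequence, library, min_region_identity = 0.8,
                                 min_seg_identity = 0.6) {
  eav <- library[library_families(library) == "EAV"]
  if (!length(eav)) stop("library has no EAV entries with region prototypes")
  glob_id <- vapply(eav, function(e) {
    nw_align(sequence, e$sequence)$identity
  }, numeric(1))
  best <- eav[[which.max(glob_id)]]
  seg <- segment_ltr(sequence, best, min_identity = min_seg_identity)

  u3_q <- substr0(sequence, seg$u3[["start"]], seg$u3[["end"]])
  ru5_q <- substr0(sequence, seg$r[["start"]], seg$u5[["end"]])
  u3_protos <- region_prototypes(eav, "u3")
  ru5_protos <- region_prototypes(eav, "ru5")
  pick <- function(query, protos) {
    ids <- vapply(protos, function(p) nw_align(query, p)$identity, numeric(1))
    best_i <- which.max(ids)
    list(type = names(protos)[best_i], identity = ids[best_i])
  }
  u3_hit <- pick(u3_q, u3_protos)
  ru5_hit <- pick(ru5_q, ru5_protos)
  u3_type <- if (u3_hit$identity >= min_region_identity) u3_hit$type else NA
  ru5_type <- if (ru5_hit$identity >= min_region_identity) ru5_hit$type else NA
  combo <- paste(sub("^U3-", "", u3_type), sub("^RU5-", "", ru5_type))
  pattern <- switch(combo, "I I" = "A", "I II" = "B", "II II" = "C",
                    "III I" = "D", "novel")
  data.frame(u3_type = u3_type, ru5_type = ru5_type, pattern = pattern,
             u3_identity = u3_hit$identity, ru5_identity = ru5_hit$identity,
             stringsAsFactors = FALSE)
}

region_prototypes <- function(eav_entries, region) {
  key <- if (region == "u3") "u3" else "ru5"
  types <- vapply(eav_entries, function(e) e$region_types[[key]], character(1))
  out <- list()
  for (i in seq_along(eav_entries)) {
    tp <- types[i]
    if (is.na(tp) || tp %in% names(out)) next
    out[[tp]] <- ltr_region(eav_entries[[i]], region)
  }
  out
}

#' Kimura two-parameter distance between aligned sequences
#'
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`, with `P` and `Q` the
#' transition and transversion proportions over columns where both
#' sequences have a base.
#'
#' @param seq_a,seq_b aligned sequences of equal length (gap `-`).
#' @return the K2P distance.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("aligned lengths differ")
  a <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  b <- strsplit(seq_b, "", fixed = TRUE)[[1]]
  ok <- a %in% DNA_BASES4 & b %in% DNA_BASES4
  if (!any(ok)) stop("no comparable columns")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- mean(transition)
  Q <- mean(diff & !transition)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("saturated distance: K2P undefined")
  -0.5 * log(w1 * sqrt(w2))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (via \pkg{ape}), with rows and
#' columns ordered by label for deterministic tie-breaking and negative
#' branch lengths clamped to zero (with a warning).
#'
#' @param d symmetric distance matrix or `dist` with >= 3 taxa.
#' @return an `ape` `phylo` tree.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(m))) stop("distance matrix must be symmetric")
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- sprintf("t%d", seq_len(nrow(m)))
  }
  ord <- order(rownames(m))
  m <- m[ord, ord]
  tr <- ape::nj(as.dist(m))
  if (any(tr$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}
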