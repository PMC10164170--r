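#' Evaluate a simulated cohort run against its truth tables
#'
#' Simulation-study helpers: given a [run_cohort_pipeline()] result, score
#' the detection layer (locus recall, positional error, TSD exactness) and
#' the sequence layer (insertion-sequence identity, family accuracy,
#' reference-decoy exclusion) against the generator's truth.
#'
#' @name evaluate
NULL

#' Score detection recall and TSD exactness
#'
#' A carried truth locus counts as recovered when the carrier individual
#' has exactly one pass call within `tol` bp of the true insertion point;
#' its TSD counts as exact when the detected duplication sequence and
#' length equal the truth.
#'
#' @param run result of [run_cohort_pipeline()].
#' @param tol positional tolerance in bp (default 5).
#' @return list with `per_locus` (one row per truth locus x carrier) and
#'   `summary` (`n`, `recall`, `tsd_exact`, `mean_abs_error`).
#' @export
evaluate_detection <- function(run, tol = 5L) {
  truth <- run$sim$truth
  carriers <- strsplit(truth$carriers, ",")
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    for (ind in carriers[[i]]) {
      calls <- run$results[[ind]]$calls
      near <- calls[calls$status == "pass" & calls$chrom == truth$chrom[i] &
                      abs(calls$position - truth$pos[i]) <= tol, ,
                    drop = FALSE]
      loci <- run$results[[ind]]$loci
      tsd_exact <- FALSE
      if (nrow(near) >= 1 && !is.null(loci)) {
        l <- loci[loci$chrom == near$chrom[1] &
                    loci$position == near$position[1], , drop = FALSE]
        tsd_exact <- nrow(l) == 1 && !is.na(l$tsd_sequence) &&
          l$tsd_sequence == truth$tsd_sequence[i] &&
          l$tsd_length == truth$tsd_length[i]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = truth$locus_id[i], individual = ind,
        recovered = nrow(near) == 1,
        abs_error = if (nrow(near)) abs(near$position[1] - truth$pos[i])
        else NA_integer_,
        tsd_exact = tsd_exact, stringsAsFactors = FALSE)
    }
  }
  per_locus <- do.call(rbind, rows)
  list(per_locus = per_locus,
       summary = list(n = nrow(per_locus),
                      recall = mean(per_locus$recovered),
                      tsd_exact = mean(per_locus$tsd_exact),
                      mean_abs_error = mean(per_locus$abs_error,
                                            na.rm = TRUE)))
}

#' Score insertion-sequence fidelity, classification and flank exclusion
#'
#' For each truth locus, the junction contig is assembled from the first
#' carrier's reads and the insertion sequence deduced and classified;
#' planted reference-resident decoys are tested with the 200 bp
#' flank-exclusion rule, as are all pass calls (which sit in plain
#' background and must not be excluded).
#'
#' @param run result of [run_cohort_pipeline()] with
#'   `keep_alignments = TRUE`.
#' @param tol positional tolerance for matching calls to truth (default 5).
#' @return list with `per_locus`, and `summary`: `n_loci`, `deduced`
#'   (count), `identical` (fraction of deduced sequences byte-equal to the
#'   planted LTR), `family_acc` (fraction of classified loci with the
#'   correct family), `decoys_excluded` (fraction), `background_excluded`
#'   (count of pass calls wrongly excluded).
#' @export
evaluate_fidelity <- function(run, tol = 5L) {
  sim <- run$sim
  truth <- sim$truth
  library <- sim$library
  carriers <- strsplit(truth$carriers, ",")
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    ind <- carriers[[i]][1]
    r <- run$results[[ind]]
    if (is.null(r$aln)) stop("run needs keep_alignments = TRUE")
    calls <- r$calls
    near <- calls[calls$status == "pass" & calls$chrom == truth$chrom[i] &
                    abs(calls$position - truth$pos[i]) <= tol, , drop = FALSE]
    row <- data.frame(locus_id = truth$locus_id[i], individual = ind,
                      deduced = FALSE, identical = NA, family_ok = NA,
                      stringsAsFactors = FALSE)
    if (nrow(near) >= 1) {
      tsd <- detect_tsd(near[1, ], r$aln, sim$reference)
      if (!is.null(tsd)) {
        asm <- suppressWarnings(assemble_locus(near[1, ], tsd, r$aln,
                                               sim$reference, library))
        if (!is.null(asm)) {
          true_seq <- library[[truth$ltr_name[i]]]$sequence
          if (asm$intact) {
            row$deduced <- TRUE
            row$identical <- identical(asm$insertion_sequence, true_seq)
          }
          if (!is.na(asm$family)) {
            row$family_ok <- identical(asm$family, truth$family[i])
          }
        }
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  per_locus <- do.call(rbind, rows)

  decoys_excluded <- logical(0)
  if (nrow(sim$decoys)) {
    decoys_excluded <- vapply(seq_len(nrow(sim$decoys)), function(j) {
      d <- sim$decoys[j, ]
      call <- data.frame(chrom = d$chrom,
                         position = as.integer((d$start + d$end) %/% 2),
                         stringsAsFactors = FALSE)
      exclude_reference_ltr(call, sim$reference, library)
    }, logical(1))
  }
  background_excluded <- sum(vapply(run$results, function(r) {
    if (is.null(r$loci)) 0L else sum(r$loci$excluded_reference_ltr)
  }, integer(1)))

  list(per_locus = per_locus,
       summary = list(
         n_loci = nrow(per_locus),
         deduced = sum(per_locus$deduced),
         identical = mean(per_locus$identical[per_locus$deduced]),
         family_acc = mean(per_locus$family_ok, na.rm = TRUE),
         decoys_excluded = mean(decoys_excluded),
         background_excluded = background_excluded))
}

#' Robinson-Foulds distance between the cohort tree and the species tree
#'
#' Builds the cross-individual locus matrix from the run's pass calls,
#' clusters individuals on the binary distance, and compares the resulting
#' topology to the simulation's species tree.
#'
#' @param run result of [run_cohort_pipeline()].
#' @param linkage linkage for [hierarchical_tree()] (default average).
#' @return list with `tree` (phylo), `rf` (Robinson-Foulds distance to the
#'   simulated species tree) and `locus_matrix`.
#' @export
evaluate_cohort_tree <- function(run, linkage = "average") {
  calls <- cohort_pass_calls(run$results)
  lm <- build_locus_matrix(calls)
  tr <- hierarchical_tree(binary_distance(lm), linkage = linkage)
  rf <- ape::dist.topo(ape::unroot(tr), ape::unroot(run$sim$tree))
  list(tree = tr, rf = as.numeric(rf), locus_matrix = lm)
}
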