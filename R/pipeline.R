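#' End-to-end non-reference LTR detection for one individual
#'
#' Runs the full per-genome pipeline on an alignment table: anchor
#' discovery against the LTR library, breakpoint clustering, support/level
#' filtering with 500 bp merging, TSD detection, reference-flank
#' exclusion, and (optionally) local assembly of junction reads with
#' insertion-sequence deduction and classification.
#'
#' @param aln alignment table (see [read_sam()]) or SAM path.
#' @param reference named chromosome sequences or FASTA path.
#' @param library an `ltr_library`.
#' @param cluster_window anchor clustering window in bp (default 400).
#' @param min_reads,min_level,merge_window filtering thresholds (defaults
#'   10 reads, level 7, 500 bp).
#' @param insert_limits optional insert-size limits (estimated otherwise).
#' @param do_assembly assemble junction contigs and deduce/classify the
#'   inserted sequence per pass locus (default TRUE).
#' @param max_reads_per_locus cap on reads fed to the per-locus assembler;
#'   junction-informative reads (clipped, unmapped mates) are kept
#'   preferentially and the remainder subsampled evenly (default 60).
#' @param min_mapq,min_clip,k,min_identity anchor-discovery parameters
#'   (see [discover_anchors()]).
#' @return list with `anchors`, `calls` (all statuses), and `loci`: one
#'   row per pass call with TSD coordinates/sequence, exclusion flag,
#'   deduced insertion sequence and classification (NA where a stage
#'   found nothing).
#' @export
detect_insertions <- function(aln, reference, library,
                              cluster_window = 400L, min_reads = 10L,
                              min_level = 7L, merge_window = 500L,
                              insert_limits = NULL, do_assembly = TRUE,
                              max_reads_per_locus = 60L, min_mapq = 20L,
                              min_clip = 10L, k = 15L, min_identity = 0.9) {
  if (is.character(aln) && length(aln) == 1) aln <- read_sam(aln)
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- read_genome_fasta(reference)
  }
  anchors <- discover_anchors(aln, library, insert_limits = insert_limits,
                              min_mapq = min_mapq, min_clip = min_clip,
                              k = k, min_identity = min_identity)
  calls <- call_breakpoints(anchors, window = cluster_window,
                            library = library)
  calls <- filter_and_merge(calls, min_reads = min_reads,
                            min_level = min_level,
                            merge_window = merge_window)
  pass_idx <- which(calls$status == "pass")
  loci <- list()
  for (i in pass_idx) {
    call <- calls[i, ]
    excl <- exclude_reference_ltr(call, reference, library)
    if (excl) calls$status[i] <- "reference_ltr"
    tsd <- detect_tsd(call, aln, reference)
    row <- data.frame(chrom = call$chrom, position = call$position,
                      support_total = call$support_total,
                      filter_level = call$filter_level,
                      excluded_reference_ltr = excl,
                      tsd_start = NA_integer_, tsd_end = NA_integer_,
                      tsd_sequence = NA_character_, tsd_length = NA_integer_,
                      insertion_sequence = NA_character_,
                      family = NA_character_, best_entry = NA_character_,
                      evalue_like = NA_real_, intact = FALSE,
                      stringsAsFactors = FALSE)
    if (!is.null(tsd)) {
      row$tsd_start <- tsd$start; row$tsd_end <- tsd$end
      row$tsd_sequence <- tsd$sequence; row$tsd_length <- tsd$length
      if (do_assembly && !excl) {
        asm <- assemble_locus(call, tsd, aln, reference, library,
                              max_reads = max_reads_per_locus)
        if (!is.null(asm)) {
          row$insertion_sequence <- asm$insertion_sequence
          row$intact <- asm$intact
          row$family <- asm$family
          row$best_entry <- asm$best_entry
          row$evalue_like <- asm$evalue_like
        }
      }
    }
    loci[[length(loci) + 1L]] <- row
  }
  loci <- if (length(loci)) do.call(rbind, loci) else NULL
  list(anchors = anchors, calls = calls, loci = loci)
}

#' Assemble the junction contig at one locus and deduce the insertion
#'
#' Extracts reads local to the TSD, assembles them into contigs, deduces
#' the inserted sequence from the TSD-delimited junctions, and classifies
#' it against the library.  When no contig yields a deduction, the longest
#' contig is classified instead (`intact = FALSE`).
#'
#' @param call single-row pass call.
#' @param tsd single-row TSD record from [detect_tsd()].
#' @param aln alignment table.
#' @param reference named chromosome sequences.
#' @param library an `ltr_library`.
#' @param max_reads cap on reads fed to the assembler (default 60).
#' @return one-row data.frame (`insertion_sequence`, `intact`, `family`,
#'   `best_entry`, `evalue_like`, `contig`, `read_count`) or NULL when
#'   fewer than 2 local reads exist.
#' @export
assemble_locus <- function(call, tsd, aln, reference, library,
                           max_reads = 60L) {
  local <- extract_local_reads(call, tsd, aln)
  local <- thin_local_reads(local, max_reads)
  if (nrow(local) < 2) return(NULL)
  ctgs <- assemble_contigs(local$seq,
                           ids = paste0(local$qname, "/",
                                        ifelse(flag_isset(local$flag,
                                                          FLAG_FIRST),
                                               1L, 2L)))
  out <- data.frame(insertion_sequence = NA_character_, intact = FALSE,
                    family = NA_character_, best_entry = NA_character_,
                    evalue_like = NA_real_, contig = ctgs$sequence[1],
                    read_count = ctgs$read_count[1],
                    stringsAsFactors = FALSE)
  for (ci in seq_len(nrow(ctgs))) {
    ins <- deduce_insertion_sequence(ctgs$sequence[ci], tsd, reference)
    if (!is.null(ins)) {
      cls <- classify_contig(ins, library)
      out$insertion_sequence <- ins
      out$intact <- TRUE
      out$family <- cls$family
      out$best_entry <- cls$best_entry
      out$evalue_like <- cls$evalue_like
      out$contig <- ctgs$sequence[ci]
      out$read_count <- ctgs$read_count[ci]
      return(out)
    }
  }
  cls <- classify_contig(ctgs$sequence[1], library)
  out$family <- cls$family
  out$best_entry <- cls$best_entry
  out$evalue_like <- cls$evalue_like
  out
}

# Keep junction-informative records (soft-clipped or unmapped) and an even
# subsample of the plain fully-mapped remainder.  Deterministic.
thin_local_reads <- function(local, max_reads) {
  if (nrow(local) <= max_reads) return(local)
  clips <- cigar_clips(local$cigar)
  informative <- rowSums(clips) > 0L | flag_isset(local$flag, FLAG_UNMAPPED)
  keep <- which(informative)
  if (length(keep) > max_reads) {
    keep <- keep[order(local$qname[keep])]
    keep <- keep[unique(as.integer(seq(1L, length(keep),
                                       length.out = max_reads)))]
  }
  rest <- which(!informative)
  rest <- rest[order(local$pos[rest], local$qname[rest])]
  room <- max(0L, max_reads - length(keep))
  if (room > 0L && length(rest)) {
    take <- rest[unique(as.integer(seq(1L, length(rest),
                                       length.out = min(room, length(rest)))))]
    keep <- c(keep, take)
  }
  out <- local[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA path.
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a genome as FASTA
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unlist(genome))
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write breakpoint calls as TSV
#' @param calls call data.frame.
#' @param path output path.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pass loci as a symbolic-allele VCF
#'
#' @param loci `loci` data.frame from [detect_insertions()].
#' @param reference named chromosome sequences.
#' @param path output path.
#' @export
write_loci_vcf <- function(loci, reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=INS:ME,Description=\"Mobile element insertion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=FAMILY,Number=1,Type=String,Description=\"LTR family\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "##INFO=<ID=LEVEL,Number=1,Type=Integer,Description=\"Filter level\">",
    "##INFO=<ID=TSD,Number=1,Type=String,Description=\"Target site duplication\">",
    sprintf("##contig=<ID=%s,length=%d>", names(reference), nchar(reference)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (!is.null(loci) && nrow(loci)) {
    ref_base <- substr0(reference[loci$chrom],
                        pmax(loci$position - 1L, 0L), loci$position)
    writeLines(sprintf(
      "%s\t%d\tlocus%03d\t%s\t<INS:ME>\t.\t%s\tSVTYPE=INS;FAMILY=%s;SUPPORT=%d;LEVEL=%d;TSD=%s",
      loci$chrom, loci$position, seq_len(nrow(loci)), ref_base,
      ifelse(loci$excluded_reference_ltr, "refLTR", "PASS"),
      ifelse(is.na(loci$family), ".", loci$family),
      loci$support_total, loci$filter_level,
      ifelse(is.na(loci$tsd_sequence), ".", loci$tsd_sequence)), con)
  }
  invisible(path)
}

#' Simulate a cohort and run the pipeline on every individual
#'
#' Convenience driver for end-to-end runs on synthetic data: simulates the
#' cohort, generates reads and truth alignments per individual, runs
#' [detect_insertions()] on each, and returns everything needed for
#' downstream comparative analysis.
#'
#' @param config a [cohort_config()].
#' @param library an `ltr_library` (defaults to
#'   `build_ltr_library(seed = config$seed)`).
#' @param do_assembly per-locus assembly on/off (default TRUE).
#' @param individuals subset of individuals to process (default all).
#' @param keep_alignments keep each individual's truth alignment table in
#'   the result (needed for later per-locus assembly; default FALSE).
#' @param ... passed to [detect_insertions()].
#' @return list with `sim` (the [simulate_cohort()] result) and `results`
#'   (per-individual [detect_insertions()] outputs, each with an `aln`
#'   element when `keep_alignments`).
#' @export
run_cohort_pipeline <- function(config, library = NULL, do_assembly = TRUE,
                                individuals = NULL, keep_alignments = FALSE,
                                ...) {
  if (is.null(library)) library <- build_ltr_library(seed = config$seed)
  sim <- simulate_cohort(config, library)
  if (is.null(individuals)) individuals <- names(sim$donors)
  results <- lapply(setNames(individuals, individuals), function(ind) {
    reads <- generate_reads(sim$donors[[ind]], config, individual = ind)
    aln <- emit_truth_alignments(reads, sim$reference, sim$truth, library,
                                 ind, config)
    out <- detect_insertions(aln, sim$reference, library,
                             cluster_window = config$fragment_mean,
                             do_assembly = do_assembly, ...)
    if (keep_alignments) out$aln <- aln
    out
  })
  list(sim = sim, results = results)
}

#' Collect per-individual pass calls into a cohort call table
#'
#' @param results per-individual results from [run_cohort_pipeline()].
#' @return data.frame with `individual`, `chrom`, `position`, `family`,
#'   suitable for [build_locus_matrix()].
#' @export
cohort_pass_calls <- function(results) {
  out <- do.call(rbind, lapply(names(results), function(ind) {
    calls <- results[[ind]]$calls
    p <- calls[calls$status == "pass", , drop = FALSE]
    if (!nrow(p)) return(NULL)
    data.frame(individual = ind, chrom = p$chrom, position = p$position,
               family = p$family, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(individual = character(0), chrom = character(0),
                      position = integer(0), family = character(0))
  }
  rownames(out) <- NULL
  out
}
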