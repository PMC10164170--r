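# Shared fixtures: a small simulated cohort (1 chromosome, 1 insertion per
# branch) run through the detection pipeline once per test session.

tiny_library <- build_ltr_library(seed = 1)

tiny_config <- cohort_config(chrom_count = 1L, chrom_length = 30000L,
                             insertions_per_branch = 1L, seed = 3L,
                             decoys_per_chrom = 1L)

tiny_sim <- simulate_cohort(tiny_config, tiny_library)

tiny_reads <- generate_reads(tiny_sim$donors$red, tiny_config, "red")

tiny_aln <- emit_truth_alignments(tiny_reads, tiny_sim$reference,
                                  tiny_sim$truth, tiny_library, "red",
                                  tiny_config)

tiny_truth_red <- tiny_sim$truth[
  vapply(strsplit(tiny_sim$truth$carriers, ","),
         function(x) "red" %in% x, logical(1)), ]

tiny_result <- detect_insertions(tiny_aln, tiny_sim$reference, tiny_library,
                                 cluster_window = tiny_config$fragment_mean)

# single-row SAM-record constructor for unit fixtures
sam_rec <- function(qname, flag, rname = "chr1", pos = 0L, mapq = 60L,
                    cigar = "*", rnext = "*", pnext = 0L, tlen = 0L,
                    seq = strrep("A", 100L)) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, rnext = rnext, pnext = pnext,
             tlen = tlen, seq = seq, stringsAsFactors = FALSE)
}

# anchor-evidence row constructor
anchor_row <- function(chrom = "chr1", position, side, kind = "discordant",
                       mate_hit = "EAV-LTR-A", read_id = "r1") {
  data.frame(chrom = chrom, position = as.integer(position), side = side,
             mate_hit = mate_hit, evidence_kind = kind, read_id = read_id,
             identity = 1, stringsAsFactors = FALSE)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, positions, bases = NULL) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_along(positions)) {
    p <- positions[i]
    b <- if (is.null(bases)) setdiff(c("A", "C", "G", "T"), chars[p])[1]
    else bases[i]
    chars[p] <- b
  }
  paste(chars, collapse = "")
}
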