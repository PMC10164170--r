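limits <- c(lower = 200, upper = 600)

make_pair <- function(flag1, flag2, pos1 = 1000L, pos2 = 1300L,
                      cigar1 = "100M", cigar2 = "100M",
                      rname1 = "chr1", rname2 = "chr1") {
  rbind(sam_rec("p1", flag1, rname1, pos1, cigar = cigar1),
        sam_rec("p1", flag2, rname2, pos2, cigar = cigar2))
}

test_that("the five pair classes are assigned per their mapping signatures", {
  # both mapped FR within limits -> proper
  aln <- make_pair(0x1 + 0x40 + 0x20, 0x1 + 0x80 + 0x10)
  p <- pair_records(aln)
  expect_identical(as.character(classify_pairs(p, limits)), "proper")
  # one mate unmapped -> singleton
  aln <- make_pair(0x1 + 0x40 + 0x8, 0x1 + 0x80 + 0x4, cigar2 = "*")
  expect_identical(as.character(classify_pairs(pair_records(aln), limits)),
                   "singleton")
  # neither mapped -> unmapped_pair
  aln <- make_pair(0x1 + 0x40 + 0x4 + 0x8, 0x1 + 0x80 + 0x4 + 0x8,
                   cigar1 = "*", cigar2 = "*")
  expect_identical(as.character(classify_pairs(pair_records(aln), limits)),
                   "unmapped_pair")
  # long soft clip -> split (even though insert is within limits)
  aln <- make_pair(0x1 + 0x40 + 0x20, 0x1 + 0x80 + 0x10, cigar1 = "60M40S")
  expect_identical(as.character(classify_pairs(pair_records(aln), limits)),
                   "split")
  # both mapped, same strand -> discordant
  aln <- make_pair(0x1 + 0x40, 0x1 + 0x80)
  expect_identical(as.character(classify_pairs(pair_records(aln), limits)),
                   "discordant")
  # insert outside limits -> discordant
  aln <- make_pair(0x1 + 0x40 + 0x20, 0x1 + 0x80 + 0x10, pos2 = 5000L)
  expect_identical(as.character(classify_pairs(pair_records(aln), limits)),
                   "discordant")
})

test_that("classification partitions all simulated pairs", {
  p <- pair_records(tiny_aln)
  cls <- classify_pairs(p, estimate_insert_limits(p))
  expect_identical(sum(table(cls)), nrow(p))
  expect_identical(nrow(p), nrow(tiny_reads))
  expect_false(anyNA(cls))
  # a 30x genome is dominated by proper pairs
  expect_gt(mean(cls == "proper"), 0.9)
})

test_that("classification is symmetric in mate order and checks read names", {
  aln <- make_pair(0x1 + 0x40 + 0x20, 0x1 + 0x80 + 0x10, cigar1 = "60M40S")
  swapped <- aln[2:1, ]
  expect_identical(classify_read_pair(aln[1, ], aln[2, ], limits),
                   classify_read_pair(swapped[2, ], swapped[1, ], limits))
  other <- sam_rec("different", 0x1 + 0x80)
  expect_error(classify_read_pair(aln[1, ], other, limits), "read names")
})

test_that("insert-size limits recover the simulated fragment distribution", {
  lims <- estimate_insert_limits(pair_records(tiny_aln))
  expect_lt(lims["lower"], tiny_config$fragment_mean)
  expect_gt(lims["upper"], tiny_config$fragment_mean)
  expect_lt(lims["upper"], tiny_config$fragment_mean +
              5 * tiny_config$fragment_sd)
})

test_that("library matching finds exact substrings and respects identity", {
  lib <- tiny_library
  q_exact <- substr(lib[["Ovex1-LTR"]]$sequence, 40, 139)
  q_rc <- revcomp(substr(lib[["ALV-E-LTR"]]$sequence, 10, 109))
  set.seed(2)
  q_random <- random_seq(100)
  hits <- match_library(c(q_exact, q_rc, q_random), lib)
  expect_identical(hits$entry[1:2], c("Ovex1-LTR", "ALV-E-LTR"))
  expect_equal(hits$identity[1:2], c(1, 1))
  expect_true(is.na(hits$entry[3]))
})

test_that("anchor discovery emits true evidence and nothing else", {
  anchors <- discover_anchors(tiny_aln, tiny_library)
  expect_gt(nrow(anchors), 0)
  # no false anchors: every anchor is within a fragment length of a true
  # insertion carried by this individual
  near_truth <- vapply(seq_len(nrow(anchors)), function(i) {
    any(tiny_truth_red$chrom == anchors$chrom[i] &
          abs(tiny_truth_red$pos - anchors$position[i]) <=
          tiny_config$fragment_mean + 4 * tiny_config$fragment_sd)
  }, logical(1))
  expect_true(all(near_truth))
  # the matched family is the planted one at each locus (entries sharing
  # U3 or R+U5 blocks are interchangeable for reads internal to a block)
  fams <- vapply(tiny_library, function(e) e$family, character(1))
  for (i in seq_len(nrow(tiny_truth_red))) {
    ev <- tiny_truth_red[i, ]
    at <- anchors[abs(anchors$position - ev$pos) <= 600, ]
    expect_gt(nrow(at), 0)
    expect_true(all(fams[at$mate_hit] == ev$family))
    expect_setequal(unique(at$side), c("five_prime", "three_prime"))
  }
  # split-read anchors sit at the junctions (within TSD length of truth)
  splits <- anchors[anchors$evidence_kind == "split", ]
  expect_gt(nrow(splits), 0)
  off <- vapply(seq_len(nrow(splits)), function(i) {
    min(abs(tiny_truth_red$pos - splits$position[i]))
  }, numeric(1))
  expect_true(all(off <= 10))
})

test_that("a split read whose clip equals an LTR terminus yields a split anchor", {
  lib <- tiny_library
  clip_seq <- substr(lib[["EAV-LTR-D"]]$sequence, 1, 40)
  # brute-force oracle: the U3-III terminus occurs only in the D entry
  contains <- vapply(lib, function(e) {
    grepl(clip_seq, e$sequence, fixed = TRUE)
  }, logical(1))
  expect_identical(names(lib)[contains], "EAV-LTR-D")
  seq1 <- paste0(random_seq(60), clip_seq)
  aln <- rbind(
    sam_rec("sp1", 0x1 + 0x40 + 0x20, pos = 2001L, cigar = "60M40S",
            seq = seq1),
    sam_rec("sp1", 0x1 + 0x80 + 0x10, pos = 2301L, cigar = "100M"))
  a <- discover_anchors(aln, lib, insert_limits = c(200, 600))
  expect_identical(nrow(a), 1L)
  expect_identical(a$evidence_kind, "split")
  expect_identical(a$mate_hit, "EAV-LTR-D")
  expect_identical(a$position, 2060L)       # 0-based clip position
  expect_identical(a$side, "five_prime")
})

test_that("proper pairs contribute no anchors and empty libraries fail", {
  aln <- make_pair(0x1 + 0x2 + 0x40 + 0x20, 0x1 + 0x2 + 0x80 + 0x10)
  a <- discover_anchors(aln, tiny_library, insert_limits = limits)
  expect_identical(nrow(a), 0L)
  expect_error(discover_anchors(aln, list(), insert_limits = limits),
               "empty")
})
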