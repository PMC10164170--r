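test_that("anchors cluster into calls by window with side tallies", {
  # 12 anchors, 6 per side, tight cluster -> one call with support 12
  a <- do.call(rbind, c(
    lapply(1:6, function(i) anchor_row(position = 995 + i, side = "five_prime",
                                       read_id = paste0("r", i))),
    lapply(1:6, function(i) anchor_row(position = 1005 + i, side = "three_prime",
                                       read_id = paste0("s", i)))))
  calls <- call_breakpoints(a, window = 400)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$support_total, 12L)
  expect_identical(calls$support_5p, 6L)
  expect_identical(calls$support_3p, 6L)
  # two clusters 10 kb apart -> two calls
  b <- rbind(a, within(a, position <- position + 10000L))
  expect_identical(nrow(call_breakpoints(b, window = 400)), 2L)
  # empty input -> empty output
  expect_identical(nrow(call_breakpoints(a[0, ])), 0L)
})

test_that("split-read junctions pin the call position", {
  # midpoint rule oracle recomputed by hand: discordant anchors spread
  # widely, one split junction on each side at 2000 and 1994
  a <- rbind(
    anchor_row(position = 1700, side = "five_prime", read_id = "d1"),
    anchor_row(position = 1820, side = "five_prime", read_id = "d2"),
    anchor_row(position = 2000, side = "five_prime", kind = "split",
               read_id = "sp5"),
    anchor_row(position = 1994, side = "three_prime", kind = "split",
               read_id = "sp3"),
    anchor_row(position = 2200, side = "three_prime", read_id = "d3"))
  calls <- call_breakpoints(a, window = 400)
  expect_identical(calls$position, (2000L + 1994L) %/% 2L)
  # without splits the midpoint between side fronts is used
  b <- a[a$evidence_kind != "split", ]
  expect_identical(call_breakpoints(b, window = 400)$position,
                   (1820L + 2200L) %/% 2L)
})

ladder_call <- function(s5, s3, sp5, sp3, n_fam = 1L, orient = TRUE) {
  data.frame(chrom = "chr1", position = 1000L, support_5p = s5,
             support_3p = s3, support_total = s5 + s3, split_5p = sp5,
             split_3p = sp3, split_support = sp5 + sp3,
             n_families = n_fam, family = "EAV", orient_consistent = orient,
             stringsAsFactors = FALSE)
}

test_that("the confidence ladder spans 1-8 with the documented extremes", {
  # maximal evidence: both sides >= 5 reads, splits both sides, one family
  expect_identical(assign_filter_level(ladder_call(5L, 5L, 2L, 2L)), 8L)
  # one-sided evidence only stays at level <= 4
  expect_lte(assign_filter_level(ladder_call(20L, 0L, 5L, 0L,
                                             orient = FALSE)), 4L)
  # minimal evidence
  expect_identical(assign_filter_level(ladder_call(1L, 0L, 0L, 0L,
                                                   n_fam = 2L,
                                                   orient = FALSE)), 1L)
})

test_that("the ladder is monotone in every evidence count", {
  # oracle: enumerate evidence vectors; adding one read of any kind never
  # lowers the level (family mix and geometry held fixed)
  grid <- expand.grid(s5 = c(0L, 1L, 3L, 6L), s3 = c(0L, 1L, 3L, 6L),
                      sp5 = c(0L, 1L), sp3 = c(0L, 1L),
                      fam = c(1L, 2L), orient = c(TRUE, FALSE))
  grid <- grid[grid$sp5 <= grid$s5 & grid$sp3 <= grid$s3, ]
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    base <- assign_filter_level(ladder_call(g$s5, g$s3, g$sp5, g$sp3,
                                            g$fam, g$orient))
    for (bump in list(c(1, 0, 0, 0), c(0, 1, 0, 0), c(1, 0, 1, 0),
                      c(0, 1, 0, 1))) {
      up <- assign_filter_level(ladder_call(g$s5 + bump[1], g$s3 + bump[2],
                                            g$sp5 + bump[3], g$sp3 + bump[4],
                                            g$fam, g$orient))
      expect_gte(up, base)
    }
  }
  # duplicating an existing anchor never lowers a real call's level
  anchors <- discover_anchors(tiny_aln, tiny_library)
  calls <- call_breakpoints(anchors, window = 400, library = tiny_library)
  dup <- anchors[rep(seq_len(nrow(anchors)), each = 2), ]
  dup$read_id <- paste0(dup$read_id, "_", seq_len(nrow(dup)) %% 2)
  calls2 <- call_breakpoints(dup, window = 400, library = tiny_library)
  expect_true(all(calls2$filter_level >= calls$filter_level))
})

test_that("support and level thresholds gate the pass status", {
  calls <- rbind(ladder_call(5L, 4L, 1L, 1L),    # support 9 -> low_support
                 ladder_call(6L, 6L, 0L, 0L),    # level 6 -> low_level
                 ladder_call(6L, 6L, 1L, 1L))    # pass
  calls$filter_level <- vapply(seq_len(nrow(calls)), function(i) {
    assign_filter_level(calls[i, ])
  }, integer(1))
  calls$status <- NA_character_
  out <- filter_and_merge(calls)
  expect_identical(out$status, c("low_support", "low_level", "pass"))
})

test_that("pass calls within 500 bp merge to the strongest; merging is idempotent", {
  mk <- function(pos, s5) {
    x <- ladder_call(s5, 6L, 1L, 1L)
    x$position <- pos
    x$support_total <- x$support_5p + x$support_3p
    x
  }
  calls <- rbind(mk(1000L, 6L), mk(1400L, 9L), mk(3000L, 6L))
  calls$filter_level <- vapply(seq_len(nrow(calls)), function(i) {
    assign_filter_level(calls[i, ])
  }, integer(1))
  calls$status <- NA_character_
  out <- filter_and_merge(calls)
  expect_identical(out$status, c("merged_away", "pass", "pass"))
  # idempotent
  expect_identical(filter_and_merge(out), out)
  # invariant: no two pass calls within 500 bp
  p <- out[out$status == "pass", ]
  expect_true(all(diff(p$position[order(p$chrom, p$position)]) > 500))
})

test_that("TSD detection performs the junction-overlap interval arithmetic", {
  set.seed(4)
  ref <- c(chr1 = random_seq(3000))
  call <- data.frame(chrom = "chr1", position = 997L, status = "pass",
                     stringsAsFactors = FALSE)
  mk_read <- function(qn, pos, cigar) {
    sam_rec(qn, 0x1 + 0x40, pos = pos, cigar = cigar)
  }
  # R5 = 1000 (right-clipped reads end there), L3 = 994 -> TSD length 6
  aln <- rbind(mk_read("a", 921L, "80M20S"),
               mk_read("b", 941L, "60M40S"),
               mk_read("c", 995L, "30S70M"),
               mk_read("d", 995L, "50S50M"))
  tsd <- detect_tsd(call, aln, ref)
  expect_identical(tsd$start, 994L)
  expect_identical(tsd$end, 1000L)
  expect_identical(tsd$length, 6L)
  expect_identical(tsd$sequence, substr(ref[["chr1"]], 995, 1000))
  # blunt junction (R5 - L3 = 0) -> none
  aln0 <- rbind(mk_read("a", 921L, "80M20S"), mk_read("c", 1001L, "30S70M"))
  expect_null(detect_tsd(call, aln0, ref))
  # overlap beyond 10 bp -> none
  aln11 <- rbind(mk_read("a", 921L, "80M20S"), mk_read("c", 990L, "30S70M"))
  expect_null(detect_tsd(call, aln11, ref))
  # out-of-bounds call errors
  bad <- call; bad$position <- 99999L
  expect_error(detect_tsd(bad, aln, ref), "outside")
})

test_that("detected TSDs equal the simulator truth at every locus", {
  loci <- tiny_result$loci
  expect_identical(nrow(loci), nrow(tiny_truth_red))
  for (i in seq_len(nrow(tiny_truth_red))) {
    ev <- tiny_truth_red[i, ]
    l <- loci[abs(loci$position - ev$pos) <= 5, ]
    expect_identical(nrow(l), 1L)
    expect_identical(l$tsd_sequence, ev$tsd_sequence)
    expect_identical(l$tsd_length, ev$tsd_length)
    expect_identical(l$tsd_end - l$tsd_start, ev$tsd_length)
  }
})
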