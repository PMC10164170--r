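test_that("progressive alignment handles identical, substituted and gapped inputs", {
  lib <- tiny_library
  a <- lib[["EAV-LTR-A"]]$sequence
  # identical sequences -> gap-free alignment
  al <- align_locus_sequences(c(s1 = a, s2 = a, s3 = a))
  expect_identical(al$ncol, nchar(a))
  expect_false(any(grepl("-", al$seqs, fixed = TRUE)))
  # a single internal 3 bp deletion -> one 3-column gap block; oracle:
  # optimal pairwise alignment has exactly ncol = original length
  b <- paste0(substr(a, 1, 99), substr(a, 103, nchar(a)))
  al2 <- align_locus_sequences(c(full = a, del = b))
  expect_identical(al2$ncol, nchar(a))
  gaps <- gregexpr("-+", al2$seqs[["del"]])[[1]]
  expect_identical(length(gaps), 1L)
  expect_identical(attr(gaps, "match.length"), 3L)
  expect_false(grepl("-", al2$seqs[["full"]], fixed = TRUE))
  # determinism
  expect_identical(align_locus_sequences(c(full = a, del = b)), al2)
  # input validation
  expect_error(align_locus_sequences(c(a)), "at least 2")
  expect_error(align_locus_sequences(c(a, "ACGT")), "50 bp")
  expect_error(align_locus_sequences(c(a, gsub("A", "Z", a))), "IUPAC")
})

test_that("substitution counting ignores gap-only columns", {
  al <- list(seqs = c(x = "ACG-TT", y = "ACGAT-", z = "ACTATT"), ncol = 6L)
  class(al) <- "locus_alignment"
  # column 3 G/G/T -> substitution; others identical up to gaps
  expect_identical(count_substitutions(al), 1L)
  expect_identical(count_substitutions(c(a = "AAAA", b = "AAAA")), 0L)
  expect_identical(count_substitutions(c(a = "AATA", b = "ACAA", c = "ACAA")),
                   2L)
})

test_that("a 346 bp locus with 9 planted substitutions counts exactly 9", {
  a <- tiny_library[["EAV-LTR-A"]]$sequence
  expect_identical(nchar(a), 346L)
  set.seed(41)
  cols <- sort(sample(346, 9))
  b <- mutate_seq(a, cols[1:5])
  c_ <- mutate_seq(a, cols[6:9])
  al <- align_locus_sequences(c(red = a, gray = b, ceylon = c_))
  expect_identical(count_substitutions(al), 9L)
})

test_that("segmentation projects prototype boundaries through the alignment", {
  lib <- tiny_library
  proto <- lib[["EAV-LTR-A"]]
  # query identical to the prototype: boundaries unchanged
  seg <- segment_ltr(proto$sequence, proto)
  expect_identical(seg$u3[["end"]], proto$u3[["end"]])
  expect_identical(seg$r[["end"]], proto$r[["end"]])
  expect_identical(seg$u5[["end"]], nchar(proto$sequence))
  # 5 bp insertion inside U3 -> U3 five columns longer, R/U5 unchanged
  q <- paste0(substr(proto$sequence, 1, 80), "ACGTA",
              substr(proto$sequence, 81, nchar(proto$sequence)))
  seg2 <- segment_ltr(q, proto)
  expect_identical(seg2$u3[["end"]], proto$u3[["end"]] + 5L)
  expect_identical(seg2$r[["end"]] - seg2$r[["start"]],
                   proto$r[["end"]] - proto$r[["start"]])
  expect_identical(seg2$u5[["end"]], nchar(q))
  # partition invariant: concatenated regions reconstruct the query
  rebuilt <- paste0(substr(q, seg2$u3[["start"]] + 1, seg2$u3[["end"]]),
                    substr(q, seg2$r[["start"]] + 1, seg2$r[["end"]]),
                    substr(q, seg2$u5[["start"]] + 1, seg2$u5[["end"]]))
  expect_identical(rebuilt, q)
  # unrelated prototype fails the identity gate
  set.seed(42)
  expect_error(segment_ltr(random_seq(300), proto), "identity")
})

test_that("segmentation partition holds under random perturbations", {
  set.seed(43)
  proto <- tiny_library[["EAV-LTR-C"]]
  n_trials <- 100
  for (i in seq_len(n_trials)) {
    q <- mutate_seq(proto$sequence, sample(346, sample(1:7, 1)))
    seg <- segment_ltr(q, proto)
    expect_identical(seg$u3[["start"]], 0L)
    expect_identical(seg$u3[["end"]], seg$r[["start"]])
    expect_identical(seg$r[["end"]], seg$u5[["start"]])
    expect_identical(seg$u5[["end"]], nchar(q))
  }
})

test_that("EAV mosaic typing recovers A-D and degrades to novel, never wrong", {
  lib <- tiny_library
  for (letter in c("A", "B", "C", "D")) {
    res <- classify_eav_pattern(lib[[paste0("EAV-LTR-", letter)]]$sequence, lib)
    expect_identical(res$pattern, letter)
  }
  # 2% substitution noise keeps the labels
  set.seed(44)
  for (trial in 1:25) {
    letter <- sample(c("A", "B", "C", "D"), 1)
    seqn <- lib[[paste0("EAV-LTR-", letter)]]$sequence
    noisy <- mutate_seq(seqn, sample(nchar(seqn), round(0.02 * nchar(seqn))))
    expect_identical(classify_eav_pattern(noisy, lib)$pattern, letter)
  }
  # heavy noise in one region -> novel, never a different letter
  for (trial in 1:10) {
    letter <- sample(c("A", "B", "C", "D"), 1)
    seqn <- lib[[paste0("EAV-LTR-", letter)]]$sequence
    u3_end <- lib[[paste0("EAV-LTR-", letter)]]$u3[["end"]]
    noisy <- mutate_seq(seqn, sample(u3_end, round(0.35 * u3_end)))
    got <- classify_eav_pattern(noisy, lib)$pattern
    expect_true(got %in% c(letter, "novel"))
    if (got != "novel") succeed() # identity may stay above the gate by chance
  }
})

test_that("K2P distance matches the closed form and is symmetric", {
  # P = 0.1, Q = 0 over 100 columns: d = -0.5 * ln(0.8)
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(k2p_distance(a, b), -0.5 * log(0.8), tolerance = 1e-12)
  expect_identical(k2p_distance(a, b), k2p_distance(b, a))
  expect_equal(k2p_distance(a, a), 0)
  # transversions enter through Q: P = 0, Q = 0.1
  c_ <- paste0(strrep("C", 10), strrep("A", 90))
  expect_equal(k2p_distance(a, c_),
               -0.5 * log((1 - 0.1) * sqrt(1 - 0.2)), tolerance = 1e-12)
  # gaps excluded from the comparable columns
  expect_equal(k2p_distance(paste0("----", a), paste0("AAAA", b)),
               -0.5 * log(0.8), tolerance = 1e-12)
  expect_error(k2p_distance("A", "AC"), "lengths differ")
  expect_error(k2p_distance("----", "AAAA"), "comparable")
  # saturation
  expect_error(k2p_distance(strrep("A", 10), strrep("G", 10)), "saturated")
})

test_that("K2P agrees with an established reference implementation", {
  set.seed(45)
  a <- random_seq(500)
  b <- mutate_seq(a, sample(500, 60))
  m <- rbind(strsplit(tolower(a), "")[[1]], strsplit(tolower(b), "")[[1]])
  rownames(m) <- c("a", "b")
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "K80"))["a", "b"]
  expect_equal(k2p_distance(a, b), ref, tolerance = 1e-12)
})

test_that("neighbor joining recovers additive four-taxon topologies", {
  set.seed(46)
  for (trial in 1:25) {
    # random additive matrix from the quartet (A,B)|(C,D)
    e <- runif(5, 0.05, 1)   # a, b, internal, c, d
    labs <- c("A", "B", "C", "D")
    d <- matrix(0, 4, 4, dimnames = list(labs, labs))
    d["A", "B"] <- d["B", "A"] <- e[1] + e[2]
    d["C", "D"] <- d["D", "C"] <- e[4] + e[5]
    d["A", "C"] <- d["C", "A"] <- e[1] + e[3] + e[4]
    d["A", "D"] <- d["D", "A"] <- e[1] + e[3] + e[5]
    d["B", "C"] <- d["C", "B"] <- e[2] + e[3] + e[4]
    d["B", "D"] <- d["D", "B"] <- e[2] + e[3] + e[5]
    expect_identical(four_point_split(d), "12|34")   # oracle
    tr <- nj_tree(d)
    expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")))
    # branch lengths are recovered for additive input
    coph <- ape::cophenetic.phylo(tr)[labs, labs]
    expect_equal(coph, d, tolerance = 1e-9)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), "3 taxa")
})

test_that("family-mixed LTR distances give family-monophyletic NJ trees", {
  lib <- tiny_library
  set.seed(47)
  seqs <- c()
  for (nm in c("EAV-LTR-A", "EAV-LTR-B", "ALV-E-LTR", "Ovex1-LTR")) {
    s <- lib[[nm]]$sequence
    seqs[paste0(nm, "_1")] <- mutate_seq(s, sample(nchar(s), 3))
    seqs[paste0(nm, "_2")] <- mutate_seq(s, sample(nchar(s), 3))
  }
  al <- align_locus_sequences(seqs)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- k2p_distance(al$seqs[[i]], al$seqs[[j]])
  }
  # non-additive distances can produce tiny negative branches, which
  # nj_tree clamps (with its documented warning); topology is what matters
  tr <- suppressWarnings(nj_tree(d))
  for (nm in c("EAV-LTR-A", "EAV-LTR-B", "ALV-E-LTR", "Ovex1-LTR")) {
    expect_true(ape::is.monophyletic(tr, paste0(nm, c("_1", "_2"))))
  }
})
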