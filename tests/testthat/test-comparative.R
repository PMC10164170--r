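test_that("locus matrix merges calls across individuals within 500 bp", {
  calls <- data.frame(
    individual = c("a", "b", "a", "b"),
    chrom = "chr1",
    position = c(1000L, 1100L, 5000L, 5600L),   # 100 apart; 600 apart
    family = "EAV", stringsAsFactors = FALSE)
  lm <- build_locus_matrix(calls)
  expect_identical(ncol(lm$mat), 3L)
  expect_identical(unname(lm$mat[, 1]), c(1L, 1L))   # both carry locus 1
  expect_identical(sum(lm$mat[, 2]), 1L)
  expect_identical(sum(lm$mat[, 3]), 1L)
  expect_identical(lm$loci$position[1], 1050L)       # median position
})

test_that("matrix row sums match per-individual call counts (clustering oracle)", {
  set.seed(31)
  n <- 60
  calls <- data.frame(
    individual = sample(c("a", "b", "c"), n, replace = TRUE),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    position = sample(1:50000, n), stringsAsFactors = FALSE)
  lm <- build_locus_matrix(calls, merge_window = 500L)
  oracle_cl <- slow_single_linkage(calls$chrom, calls$position, 500L)
  expect_identical(ncol(lm$mat), length(unique(oracle_cl)))
  for (ind in c("a", "b", "c")) {
    expect_equal(unname(rowSums(lm$mat)[ind]),
                 length(unique(oracle_cl[calls$individual == ind])))
  }
})

test_that("Venn cells are disjoint and satisfy inclusion-exclusion", {
  set.seed(32)
  for (trial in 1:20) {
    k <- sample(2:4, 1)
    n_ind <- k * 2
    n_loci <- sample(10:40, 1)
    mat <- matrix(rbinom(n_ind * n_loci, 1, 0.4), n_ind, n_loci,
                  dimnames = list(sprintf("i%02d", 1:n_ind), NULL))
    mat[, colSums(mat) == 0] <- 1   # every locus needs a carrier
    grouping <- setNames(rep(sprintf("g%d", 1:k), each = 2), rownames(mat))
    v <- venn_counts(mat, grouping)
    expect_identical(sum(v$cells$count), v$n_loci)
    # inclusion-exclusion: each group total equals the sum of its cells
    for (g in unique(grouping)) {
      in_g <- grepl(paste0("(^|\\+)", g, "($|\\+)"), v$cells$groups)
      expect_identical(unname(v$group_totals[g]),
                       as.numeric(sum(v$cells$count[in_g])))
    }
  }
  expect_error(venn_counts(mat, grouping[-1]), "group label")
})

test_that("binary distances follow the set-arithmetic definition", {
  mat <- rbind(a = c(1L, 1L, 0L), b = c(1L, 0L, 0L), c = c(0L, 0L, 1L))
  d <- as.matrix(binary_distance(mat, method = "jaccard"))
  expect_identical(d["a", "a"], 0)
  expect_equal(d["a", "b"], 0.5)      # s = 1/2
  expect_equal(d["a", "c"], 1)        # disjoint
  ds <- as.matrix(binary_distance(mat))
  expect_equal(ds["a", "b"], sqrt(0.5))
  # base-R oracle: dist(method = "binary") is 1 - Jaccard
  set.seed(33)
  m2 <- matrix(rbinom(60, 1, 0.5), 6, 10)
  m2[rowSums(m2) == 0, 1] <- 1L
  rownames(m2) <- letters[1:6]
  expect_equal(as.matrix(binary_distance(m2, "jaccard")),
               as.matrix(dist(m2, method = "binary")), tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero-locus individual warns, distance maximal
  m3 <- rbind(a = c(1L, 1L), b = c(0L, 0L))
  expect_warning(d3 <- binary_distance(m3), "zero loci")
  expect_equal(as.matrix(d3)["a", "b"], 1)
})

test_that("jaccard distance is a metric on random presence profiles", {
  set.seed(34)
  for (trial in 1:20) {
    m <- matrix(rbinom(8 * 15, 1, 0.5), 8, 15)
    m[rowSums(m) == 0, 1] <- 1L
    rownames(m) <- sprintf("i%d", 1:8)
    d <- as.matrix(binary_distance(m, "jaccard"))
    for (i in 1:8) for (j in 1:8) for (k in 1:8) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
    expect_true(isSymmetric(d))
  }
})

test_that("hierarchical clustering matches a brute-force agglomeration", {
  # 2 taxa: a single cherry at their distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  tr2 <- hierarchical_tree(as.dist(d2))
  expect_identical(sort(tr2$tip.label), c("x", "y"))
  expect_equal(sum(tr2$edge.length), 0.4)
  # ultrametric input: cophenetic distances reproduce the input exactly
  labs <- c("a", "b", "c", "d")
  dm <- matrix(c(0, .2, .6, .6,
                 .2, 0, .6, .6,
                 .6, .6, 0, .4,
                 .6, .6, .4, 0), 4, dimnames = list(labs, labs))
  tr <- hierarchical_tree(as.dist(dm))
  coph_oracle <- slow_upgma_cophenetic(dm)
  hc <- attr(tr, "hclust")
  coph <- as.matrix(stats::cophenetic(hc))
  expect_equal(coph[labs, labs], coph_oracle[labs, labs], tolerance = 1e-12)
  expect_equal(coph[labs, labs], dm, tolerance = 1e-12)
  expect_error(hierarchical_tree(matrix(c(0, 1, 2, 0, 0, 1, 0, 0, 0), 3)),
               "symmetric")
})

test_that("gene overlap annotation equals a brute-force interval scan", {
  set.seed(35)
  genes <- data.frame(chrom = rep(c("chr1", "chr2"), each = 5),
                      start = c(seq(1000, 41000, by = 10000),
                                seq(2000, 42000, by = 10000)),
                      gene = sprintf("g%02d", 1:10),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + 2000L
  loci <- data.frame(locus_id = sprintf("L%02d", 1:30),
                     chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                     position = sample(0:45000, 30), stringsAsFactors = FALSE)
  got <- annotate_gene_overlap(loci, genes, near_window = 5000L)
  oracle <- slow_gene_overlap(loci, genes, 5000L)
  key <- function(x) sort(paste(x$locus_id, x$gene))
  expect_identical(key(got), if (is.null(oracle)) character(0) else key(oracle))
  # inside / just-outside window cases
  loci2 <- data.frame(locus_id = c("in", "near", "far"), chrom = "chr1",
                      position = c(1500L, 1000L - 4000L, 1000L - 6000L))
  got2 <- annotate_gene_overlap(loci2, genes, near_window = 5000L)
  expect_setequal(got2$locus_id[got2$gene == "g01"], c("in", "near"))
})

test_that("GFF3 annotation files are parsed for gene spans", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t3000\t.\t+\t.\tID=gene:x1;gene_id=GENE1",
    "chr1\ttest\texon\t1001\t1500\t.\t+\t.\tParent=gene:x1",
    "chr1\ttest\tgene\t9001\t9500\t.\t-\t.\tID=gene:x2;gene_id=GENE2"), gff)
  loci <- data.frame(locus_id = "L1", chrom = "chr1", position = 1200L)
  got <- annotate_gene_overlap(loci, gff, near_window = 0L)
  expect_identical(got$gene, "GENE1")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # all configurations at several universe sizes up to 25
  for (N in c(6L, 12L, 20L, 25L)) {
    universe <- sprintf("g%03d", seq_len(N))
    for (K in c(1L, N %/% 3, N %/% 2)) {
      for (n in c(1L, N %/% 3, N %/% 2)) {
        g2g <- data.frame(gene = universe[seq_len(K)], term = "T1")
        hits <- universe[seq_len(n)]          # overlap k = min(K, n)
        res <- go_enrichment(hits, universe, g2g)
        k <- min(K, n)
        expect_equal(res$p[res$term == "T1"], slow_hyper_p(k, K, N, n),
                     tolerance = 1e-12)
        # a disjoint hit set: k = 0
        if (K < N && n <= N - K) {
          hits0 <- universe[N - seq_len(n) + 1L]
          res0 <- go_enrichment(hits0, universe, g2g)
          expect_equal(res0$p[res0$term == "T1"],
                       slow_hyper_p(0, K, N, n), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("enrichment ranks a fully-hit term first and validates inputs", {
  universe <- sprintf("g%02d", 1:20)
  g2g <- rbind(data.frame(gene = universe[1:4], term = "cell adhesion"),
               data.frame(gene = universe[5:14], term = "metabolism"))
  res <- go_enrichment(universe[1:4], universe, g2g)
  expect_identical(res$term[1], "cell adhesion")
  expect_lt(res$q[1], 0.05)
  expect_error(go_enrichment("not_in_universe", universe, g2g), "subset")
  expect_error(go_enrichment(universe[1], universe, g2g[0, ]), "empty")
})
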