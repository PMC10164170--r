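# Independent oracles, deliberately naive implementations.

# Plain O(n*m) Smith-Waterman (linear in affine-free form with open/extend
# folded per-gap-column), small inputs only.
slow_smith_waterman <- function(a, b, match = 1, mismatch = -2,
                                gap_open = 5, gap_ext = 2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in b (vertical)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in a (horizontal)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_ext,
                             E[i, j + 1] - gap_ext)
      F[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_ext,
                             F[i + 1, j] - gap_ext)
      s <- if (av[i] == bv[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# Brute-force single-linkage clustering of positions via the full pairwise
# distance matrix (per chromosome).
slow_single_linkage <- function(chrom, position, window) {
  n <- length(position)
  cl <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (cl[i] != cl[j] && chrom[i] == chrom[j] &&
          abs(position[i] - position[j]) <= window) {
        cl[cl == cl[j]] <- cl[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(cl, unique(cl[order(chrom, position)]))
}

# O(n*m) interval scan for gene overlap.
slow_gene_overlap <- function(loci, genes, near_window) {
  out <- NULL
  for (i in seq_len(nrow(loci))) {
    for (j in seq_len(nrow(genes))) {
      if (loci$chrom[i] == genes$chrom[j] &&
          loci$position[i] >= genes$start[j] - near_window &&
          loci$position[i] < genes$end[j] + near_window) {
        out <- rbind(out, data.frame(locus_id = loci$locus_id[i],
                                     gene = genes$gene[j]))
      }
    }
  }
  out
}

# Exhaustive-enumeration upper-tail hypergeometric probability.
slow_hyper_p <- function(k, K, N, n) {
  j <- max(0, k):min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Which of the three unrooted 4-taxon topologies does an additive matrix
# support (four-point condition)?  Returns the pair grouped with taxon 1.
four_point_split <- function(d) {
  s12 <- d[1, 2] + d[3, 4]
  s13 <- d[1, 3] + d[2, 4]
  s14 <- d[1, 4] + d[2, 3]
  c("12|34", "13|24", "14|23")[which.min(c(s12, s13, s14))]
}

# Split of taxon-1's partner in an unrooted 4-taxon phylo tree.
tree_split <- function(tr) {
  tr <- ape::unroot(tr)
  tips <- tr$tip.label
  # the internal edge partitions the 4 tips 2|2; find taxon 1's partner
  for (partner in 2:4) {
    pair <- c(tips[1], tips[partner])
    mrca_ok <- ape::is.monophyletic(tr, pair)
    if (mrca_ok) return(paste0("1", partner, "|", paste(setdiff(2:4, partner), collapse = "")))
  }
  NA_character_
}

# Brute-force UPGMA-style agglomeration returning merge heights per pair.
slow_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- as.list(labels)
  coph <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  active <- rep(TRUE, length(clusters))
  dm <- d
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); bestd <- Inf
    for (i in idx) for (j in idx) {
      if (i < j && dm[i, j] < bestd) { bestd <- dm[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- bestd
    }
    # average linkage update
    ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
    for (k in idx) {
      if (k != i && k != j) {
        dm[i, k] <- dm[k, i] <- (ni * dm[i, k] + nj * dm[j, k]) / (ni + nj)
      }
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    active[j] <- FALSE
    dm[j, ] <- Inf; dm[, j] <- Inf
  }
  diag(coph) <- 0
  coph
}
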