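#' Build a cross-individual presence/absence locus matrix
#'
#' Per-individual pass calls are merged into cohort loci by single-linkage
#' clustering of positions within `merge_window` bp on each chromosome
#' (the same distance rule used to merge duplicate breakpoints within one
#' genome, applied across individuals).  A cell is 1 when the individual
#' has a pass call in the cluster; the locus position is the median of the
#' member positions.
#'
#' @param calls data.frame of pass calls with columns `individual`,
#'   `chrom`, `position` and optionally `family`.
#' @param merge_window single-linkage distance in bp (default 500).
#' @return an object of class `locus_matrix`: list with `loci` (data.frame
#'   `locus_id`, `chrom`, `position`, `family`), `individuals`, and `mat`
#'   (0/1 matrix, individuals x loci).
#' @export
build_locus_matrix <- function(calls, merge_window = 500L) {
  stopifnot(all(c("individual", "chrom", "position") %in% names(calls)))
  individuals <- sort(unique(calls$individual))
  calls <- calls[order(calls$chrom, calls$position), , drop = FALSE]
  new_cluster <- if (nrow(calls) > 1) {
    c(TRUE, diff(calls$position) > merge_window |
        calls$chrom[-1] != calls$chrom[-nrow(calls)])
  } else rep(TRUE, nrow(calls))
  cl <- cumsum(new_cluster)
  loci <- do.call(rbind, lapply(split(calls, cl), function(g) {
    data.frame(chrom = g$chrom[1],
               position = as.integer(median(g$position)),
               family = if ("family" %in% names(g)) {
                 names(sort(table(g$family), decreasing = TRUE))[1]
               } else NA_character_,
               stringsAsFactors = FALSE)
  }))
  loci <- cbind(locus_id = sprintf("LOC%04d", seq_len(nrow(loci))), loci)
  rownames(loci) <- NULL
  mat <- matrix(0L, nrow = length(individuals), ncol = nrow(loci),
                dimnames = list(individuals, loci$locus_id))
  for (k in seq_along(unique(cl))) {
    g <- calls[cl == unique(cl)[k], , drop = FALSE]
    mat[unique(g$individual), k] <- 1L
  }
  structure(list(loci = loci, individuals = individuals, mat = mat),
            class = "locus_matrix")
}

#' @export
print.locus_matrix <- function(x, ...) {
  cat(sprintf("locus_matrix: %d individuals x %d loci (%d carried cells)\n",
              nrow(x$mat), ncol(x$mat), sum(x$mat)))
  invisible(x)
}

#' Venn partition of loci across groups
#'
#' A locus belongs to a group when any member individual carries it; the
#' loci are then partitioned into the `2^k - 1` disjoint Venn cells over
#' the `k` groups.
#'
#' @param lm a `locus_matrix`, or a plain 0/1 matrix (individuals x loci).
#' @param grouping named character vector mapping each individual to a
#'   group.
#' @return list with `cells` (data.frame `groups` (`+`-separated), `count`)
#'   including empty cells, `group_totals`, and `n_loci` (distinct loci,
#'   equal to the sum over cells).
#' @export
venn_counts <- function(lm, grouping) {
  mat <- if (inherits(lm, "locus_matrix")) lm$mat else lm
  if (!all(rownames(mat) %in% names(grouping))) {
    stop("every individual needs a group label")
  }
  groups <- sort(unique(unname(grouping[rownames(mat)])))
  k <- length(groups)
  if (k > 6L) stop("more than 6 groups; Venn partition not supported")
  gmat <- do.call(rbind, lapply(groups, function(g) {
    members <- rownames(mat)[grouping[rownames(mat)] == g]
    as.integer(colSums(mat[members, , drop = FALSE]) > 0)
  }))
  rownames(gmat) <- groups
  mask <- as.integer(2^(seq_len(k) - 1) %*% gmat)
  cells <- data.frame(
    mask = seq_len(2^k - 1),
    groups = vapply(seq_len(2^k - 1), function(m) {
      paste(groups[bitwAnd(m, 2^(seq_len(k) - 1)) > 0], collapse = "+")
    }, character(1)),
    count = vapply(seq_len(2^k - 1), function(m) sum(mask == m), integer(1))
  )
  list(cells = cells[, c("groups", "count")],
       group_totals = setNames(rowSums(gmat), groups),
       n_loci = sum(mask > 0))
}

#' Binary (Jaccard) distance between carried-locus profiles
#'
#' With `A`, `B` the carried-locus sets of two individuals and
#' `s = |A n B| / |A u B|`, the default distance is `sqrt(1 - s)` (the
#' convention of classical binary-distance coefficients used for
#' presence/absence clustering); `method = "jaccard"` gives the plain
#' `1 - s`.  Two empty profiles have distance 0; an empty against a
#' non-empty profile has maximal distance (with a warning).
#'
#' @param lm a `locus_matrix` or 0/1 matrix (individuals x loci).
#' @param method `"jaccard_sqrt"` (default) or `"jaccard"`.
#' @return a `dist` object over individuals.
#' @export
binary_distance <- function(lm, method = c("jaccard_sqrt", "jaccard")) {
  method <- match.arg(method)
  mat <- if (inherits(lm, "locus_matrix")) lm$mat else lm
  if (nrow(mat) < 2) stop("need at least 2 individuals")
  storage.mode(mat) <- "numeric"
  inter <- mat %*% t(mat)
  sizes <- rowSums(mat)
  uni <- outer(sizes, sizes, "+") - inter
  if (any(sizes == 0)) {
    warning("individual(s) with zero loci; distance to non-empty profiles is maximal")
  }
  s <- ifelse(uni > 0, inter / uni, 1)   # two empty profiles: similarity 1
  d <- 1 - s
  if (method == "jaccard_sqrt") d <- sqrt(d)
  diag(d) <- 0
  as.dist(d)
}

#' Agglomerative clustering tree from a distance matrix
#'
#' @param d a `dist` or symmetric matrix.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return an `ape` `phylo` tree (branch lengths from merge heights), with
#'   the `hclust` object attached as attribute `"hclust"`.
#' @export
hierarchical_tree <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
    d <- as.dist(d)
  }
  if (attr(d, "Size") == 2) {
    # single cherry at the pairwise distance
    labs <- attr(d, "Labels")
    if (is.null(labs)) labs <- c("t1", "t2")
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", labs[1], d[1] / 2,
                                        labs[2], d[1] / 2))
    return(tr)
  }
  hc <- hclust(d, method = linkage)
  tr <- ape::as.phylo(hc)
  attr(tr, "hclust") <- hc
  tr
}

#' Newick string for a tree
#' @param tree a `phylo` object.
#' @return newick character scalar.
#' @export
tree_newick <- function(tree) ape::write.tree(tree)

#' Annotate loci with overlapping or nearby genes
#'
#' @param loci data.frame with `locus_id`, `chrom`, `position` (0-based).
#' @param annotation GFF3/BED file path, or a `GRanges`, or a data.frame
#'   with `chrom`, `start`, `end` (0-based half-open) and `gene`.
#' @param near_window pad around each gene span in bp (default 5000);
#'   "near a gene" is not a sharply defined notion, so the window is
#'   exposed as a parameter.
#' @return data.frame `locus_id`, `gene` (one row per locus-gene hit).
#' @export
annotate_gene_overlap <- function(loci, annotation, near_window = 5000L) {
  genes <- load_gene_annotation(annotation)
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  gr_loci <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(start = loci$position + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_loci, gr_genes,
                                      maxgap = as.integer(near_window))
  data.frame(locus_id = loci$locus_id[S4Vectors::queryHits(hits)],
             gene = genes$gene[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

# Accepts GFF3/BED paths (via rtracklayer), GRanges, or a ready data.frame;
# returns chrom/start/end (0-based half-open) + gene name.
load_gene_annotation <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1) {
    gr <- rtracklayer::import(annotation)
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md)) {
      keep <- as.character(md$type) == "gene"
      if (any(keep)) gr <- gr[keep]
    }
    md <- S4Vectors::mcols(gr)
    gene <- if ("gene_id" %in% names(md)) md$gene_id
    else if ("Name" %in% names(md)) md$Name
    else if ("ID" %in% names(md)) md$ID
    else if ("name" %in% names(md)) md$name
    else as.character(seq_along(gr))
    bad <- is.na(gene)
    if (any(bad)) {
      warning(sum(bad), " annotation record(s) without a usable gene name skipped")
      gr <- gr[!bad]; gene <- gene[!bad]
    }
    return(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      gene = as.character(gene), stringsAsFactors = FALSE))
  }
  if (inherits(annotation, "GRanges")) {
    md <- S4Vectors::mcols(annotation)
    gene <- if ("gene_id" %in% names(md)) md$gene_id else md$Name
    return(data.frame(chrom = as.character(GenomicRanges::seqnames(annotation)),
                      start = GenomicRanges::start(annotation) - 1L,
                      end = GenomicRanges::end(annotation),
                      gene = as.character(gene), stringsAsFactors = FALSE))
  }
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(annotation)))
  annotation
}

#' Hypergeometric GO-term enrichment with BH correction
#'
#' For each term with at least one universe gene, the upper-tail
#' hypergeometric probability of the observed overlap between the hit
#' genes and the term's genes is computed, followed by
#' Benjamini-Hochberg adjustment across the tested terms.
#'
#' @param hit_genes character vector of genes of interest (must be a
#'   subset of `universe_genes`).
#' @param universe_genes character vector, the gene universe.
#' @param gene2go data.frame with columns `gene` and `term` (or a TSV path
#'   with those columns).
#' @return data.frame sorted by adjusted p: `term`, `k` (hits in term),
#'   `n` (hits), `K` (universe genes in term), `N` (universe size), `p`,
#'   `q` (BH-adjusted).
#' @export
go_enrichment <- function(hit_genes, universe_genes, gene2go) {
  if (is.character(gene2go) && length(gene2go) == 1) {
    gene2go <- read.table(gene2go, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  }
  if (!nrow(gene2go)) stop("empty gene-to-term mapping")
  stopifnot(all(c("gene", "term") %in% names(gene2go)))
  hit_genes <- unique(hit_genes)
  universe_genes <- unique(universe_genes)
  if (!all(hit_genes %in% universe_genes)) {
    stop("hit_genes must be a subset of universe_genes")
  }
  gene2go <- gene2go[gene2go$gene %in% universe_genes, , drop = FALSE]
  N <- length(universe_genes)
  n <- length(hit_genes)
  terms <- split(unique(gene2go[c("gene", "term")])$gene,
                 unique(gene2go[c("gene", "term")])$term)
  out <- do.call(rbind, lapply(names(terms), function(tm) {
    K <- length(terms[[tm]])
    k <- sum(hit_genes %in% terms[[tm]])
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
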