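#' Cohort simulation configuration
#'
#' Bundles the parameters of the cohort simulator: genome shape, species
#' tree, per-branch insertion counts, read geometry, coverage, error rate
#' and the master seed.  Defaults emulate a small Illumina-style WGS design:
#' 100 bp paired-end reads from ~400 bp fragments at 30x coverage, with
#' germline LTR insertions carried on the branches of a four-species tree.
#'
#' @param chrom_count number of chromosomes in the toy reference.
#' @param chrom_length length of each chromosome (bp).
#' @param species_tree newick string; insertions are placed on its branches
#'   (edges plus the root stem) and inherited by all leaves below.
#' @param insertions_per_branch germline LTR insertions per branch.
#' @param read_length read length in bp (default 100).
#' @param fragment_mean,fragment_sd fragment length distribution (normal,
#'   truncated below at `read_length` and above at mean + 4 sd).
#' @param coverage haploid sequencing depth per individual.
#' @param error_rate per-base substitution error rate.
#' @param seed master integer seed; all randomness derives from it.
#' @param min_spacing minimum distance between planted elements; must exceed
#'   2 x `fragment_mean` so evidence clusters of neighbouring loci cannot
#'   bleed into each other (default 4 x `fragment_mean`).
#' @param decoys_per_chrom LTR copies planted directly into the reference
#'   background ("reference-resident" decoys) to exercise the 200 bp
#'   flank-exclusion stage.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(chrom_count = 2L, chrom_length = 70000L,
                          species_tree = "(((red,gray),ceylon),green);",
                          insertions_per_branch = 10L,
                          read_length = 100L,
                          fragment_mean = 400L, fragment_sd = 40L,
                          coverage = 30, error_rate = 0,
                          seed = 1L,
                          min_spacing = 4L * fragment_mean,
                          decoys_per_chrom = 2L) {
  stopifnot(chrom_count >= 1, chrom_length > 0, coverage > 0,
            read_length > 0, fragment_mean > 0, fragment_sd >= 0,
            error_rate >= 0, error_rate < 1)
  if (read_length >= fragment_mean) {
    stop("read_length must be smaller than fragment_mean")
  }
  if (min_spacing <= 2L * fragment_mean) {
    stop("min_spacing must exceed 2 * fragment_mean")
  }
  tree <- ape::read.tree(text = species_tree)
  if (is.null(tree) || length(tree$tip.label) < 2) {
    stop("species_tree must be a newick tree with >= 2 leaves")
  }
  structure(list(
    chrom_count = as.integer(chrom_count),
    chrom_length = as.integer(chrom_length),
    species_tree = species_tree, tree = tree,
    insertions_per_branch = as.integer(insertions_per_branch),
    read_length = as.integer(read_length),
    fragment_mean = as.integer(fragment_mean),
    fragment_sd = as.integer(fragment_sd),
    coverage = coverage, error_rate = error_rate,
    seed = as.integer(seed), min_spacing = as.integer(min_spacing),
    decoys_per_chrom = as.integer(decoys_per_chrom)
  ), class = "cohort_config")
}

# Branch table of a rooted tree: one row per edge plus a synthetic "root"
# branch; carriers of a branch are all leaves below it.
tree_branches <- function(tree) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  clade_tips <- function(node) {
    if (node <= n_tip) return(tips[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, clade_tips))
  }
  ids <- character(0); carriers <- list()
  for (i in seq_len(nrow(tree$edge))) {
    child <- tree$edge[i, 2]
    leaves <- sort(clade_tips(child))
    ids <- c(ids, paste0("b_", paste(leaves, collapse = "+")))
    carriers <- c(carriers, list(leaves))
  }
  ids <- c(ids, "root"); carriers <- c(carriers, list(sort(tips)))
  data.frame(branch = ids, carriers = I(carriers),
             stringsAsFactors = FALSE)
}

#' Simulate a cohort of donor genomes carrying LTR insertions
#'
#' Builds an insertion-free random reference genome (optionally with
#' reference-resident LTR decoys planted in the background), places
#' germline insertion events on the branches of the species tree, and
#' splices each event -- LTR followed by a duplicated copy of the 4-8 bp
#' target site -- into the genomes of all carrier individuals.
#'
#' Coordinate convention: an event at 0-based reference position `p` with
#' TSD length `L` duplicates the reference slice `[p-L, p)`; the donor is
#' `ref[0,p) + LTR + TSD + ref[p,...)`, so carriers gain
#' `nchar(LTR) + L` bp per event.
#'
#' @param config a [cohort_config()].
#' @param library an `ltr_library` from [build_ltr_library()].
#' @return a list with elements:
#'   \describe{
#'     \item{reference}{named character vector of chromosome sequences}
#'     \item{donors}{per-individual named list of chromosome sequences}
#'     \item{truth}{data.frame of insertion events (`locus_id`, `chrom`,
#'       `pos` (0-based), `ltr_name`, `family`, `tsd_length`,
#'       `tsd_sequence`, `branch`, `carriers` comma-separated)}
#'     \item{decoys}{data.frame of reference-resident LTR copies
#'       (`chrom`, `start`, `end` 0-based half-open, `ltr_name`)}
#'     \item{config, library, tree}{inputs, for downstream stages}
#'   }
#' @export
simulate_cohort <- function(config, library) {
  stopifnot(inherits(config, "cohort_config"), inherits(library, "ltr_library"))
  set.seed(config$seed)
  tree <- config$tree
  branches <- tree_branches(tree)
  n_events <- nrow(branches) * config$insertions_per_branch
  n_decoys <- config$chrom_count * config$decoys_per_chrom

  # slot grid guaranteeing min_spacing between all planted elements
  margin <- config$min_spacing
  usable <- config$chrom_length - 2L * margin
  slots_per_chrom <- max(0L, usable %/% config$min_spacing)
  total_slots <- slots_per_chrom * config$chrom_count
  if (n_events + n_decoys > total_slots) {
    stop(sprintf(paste0("cannot place %d insertions + %d decoys with spacing ",
                        "%d bp on %d x %d bp chromosomes"),
                 n_events, n_decoys, config$min_spacing,
                 config$chrom_count, config$chrom_length))
  }
  chroms <- sprintf("chr%d", seq_len(config$chrom_count))
  slot_tab <- data.frame(
    chrom = rep(chroms, each = slots_per_chrom),
    slot = rep(seq_len(slots_per_chrom), times = config$chrom_count)
  )
  # jittered position inside each slot (0-based)
  jitter_room <- config$min_spacing %/% 4L
  slot_tab$pos <- margin + (slot_tab$slot - 1L) * config$min_spacing +
    sample.int(jitter_room, nrow(slot_tab), replace = TRUE)
  picked <- slot_tab[sample.int(nrow(slot_tab), n_events + n_decoys), ]

  decoy_rows <- if (n_decoys > 0) picked[seq_len(n_decoys), ] else picked[0, ]
  event_rows <- picked[seq_len(n_events) + n_decoys, ]

  # reference background, then plant decoys (reference-resident LTR copies)
  reference <- setNames(random_dna(rep(config$chrom_length, config$chrom_count)),
                        chroms)
  decoys <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), ltr_name = character(0))
  if (nrow(decoy_rows)) {
    decoy_rows$ltr_name <- sample(names(library), nrow(decoy_rows),
                                  replace = TRUE)
    decoy_rows <- decoy_rows[order(decoy_rows$chrom, -decoy_rows$pos), ]
    for (i in seq_len(nrow(decoy_rows))) {
      ch <- decoy_rows$chrom[i]; p <- decoy_rows$pos[i]
      ltr <- library[[decoy_rows$ltr_name[i]]]$sequence
      reference[[ch]] <- paste0(substr(reference[[ch]], 1, p), ltr,
                                substr(reference[[ch]], p + 1,
                                       nchar(reference[[ch]])))
    }
    # decoy coordinates on the *final* reference: positions planted from the
    # right are unshifted at plant time; earlier (left) decoys are too, since
    # splicing proceeds right-to-left per chromosome.  Downstream decoys are
    # shifted by the lengths of the decoys planted to their left.
    decoy_rows <- decoy_rows[order(decoy_rows$chrom, decoy_rows$pos), ]
    lens <- vapply(decoy_rows$ltr_name,
                   function(n) nchar(library[[n]]$sequence), integer(1))
    shift <- unlist(lapply(split(lens, decoy_rows$chrom), function(l) {
      cumsum(c(0L, l[-length(l)]))
    }), use.names = FALSE)
    decoys <- data.frame(chrom = decoy_rows$chrom,
                         start = decoy_rows$pos + shift,
                         end = decoy_rows$pos + shift + lens,
                         ltr_name = decoy_rows$ltr_name,
                         stringsAsFactors = FALSE)
    rownames(decoys) <- NULL
    # event positions shift by the decoy lengths planted to their left
    # (compared in pre-splice coordinates)
    for (i in seq_len(nrow(event_rows))) {
      d <- decoy_rows$chrom == event_rows$chrom[i] &
        decoy_rows$pos < event_rows$pos[i]
      event_rows$pos[i] <- event_rows$pos[i] + sum(lens[d])
    }
  }

  # assign events to branches and LTR entries
  event_rows <- event_rows[sample.int(nrow(event_rows)), ]
  branch_idx <- rep(seq_len(nrow(branches)), each = config$insertions_per_branch)
  tsd_len <- sample(4:8, n_events, replace = TRUE)
  ltr_names <- sample(names(library), n_events, replace = TRUE)
  truth <- data.frame(
    locus_id = sprintf("L%03d", seq_len(n_events)),
    chrom = event_rows$chrom,
    pos = event_rows$pos,
    ltr_name = ltr_names,
    family = library_families(library)[ltr_names],
    tsd_length = tsd_len,
    branch = branches$branch[branch_idx],
    stringsAsFactors = FALSE
  )
  truth$tsd_sequence <- substr0(reference[truth$chrom],
                                truth$pos - truth$tsd_length, truth$pos)
  truth$carriers <- vapply(branch_idx, function(i) {
    paste(branches$carriers[[i]], collapse = ",")
  }, character(1))
  truth <- truth[order(truth$chrom, truth$pos), ]
  truth$locus_id <- sprintf("L%03d", seq_len(n_events))
  rownames(truth) <- NULL

  # donor genomes: splice carried events right-to-left
  donors <- lapply(setNames(tree$tip.label, tree$tip.label), function(ind) {
    genome <- reference
    carried <- truth[vapply(strsplit(truth$carriers, ","),
                            function(cs) ind %in% cs, logical(1)), ]
    carried <- carried[order(carried$chrom, -carried$pos), ]
    for (i in seq_len(nrow(carried))) {
      ch <- carried$chrom[i]; p <- carried$pos[i]
      ins <- paste0(library[[carried$ltr_name[i]]]$sequence,
                    carried$tsd_sequence[i])
      genome[[ch]] <- paste0(substr(genome[[ch]], 1, p), ins,
                             substr(genome[[ch]], p + 1, nchar(genome[[ch]])))
    }
    genome
  })

  list(reference = reference, donors = donors, truth = truth,
       decoys = decoys, config = config, library = library, tree = tree)
}

# Donor-coordinate layout of the events carried by one individual: for each
# chromosome, inserted blocks [a, b) in donor coordinates with cumulative
# offsets, used by the truth-alignment projector and round-trip checks.
insertion_map <- function(truth, library, individual) {
  carried <- truth[vapply(strsplit(truth$carriers, ","),
                          function(cs) individual %in% cs, logical(1)), ,
                   drop = FALSE]
  carried <- carried[order(carried$chrom, carried$pos), , drop = FALSE]
  if (!nrow(carried)) return(list())
  carried$ins_len <- vapply(carried$ltr_name, function(n) {
    nchar(library[[n]]$sequence)
  }, integer(1)) + carried$tsd_length
  lapply(split(carried, carried$chrom), function(ev) {
    cum_before <- cumsum(c(0L, ev$ins_len[-nrow(ev)]))
    data.frame(locus_id = ev$locus_id,
               p = ev$pos, L = ev$tsd_length,
               a = ev$pos + cum_before,
               b = ev$pos + cum_before + ev$ins_len,
               cum_before = cum_before,
               cum_after = cum_before + ev$ins_len,
               stringsAsFactors = FALSE)
  })
}

#' Generate paired-end reads from a donor genome
#'
#' Fragments are drawn per chromosome with normal lengths (truncated below
#' at `read_length`, above at mean + 4 sd) and uniform start positions; the
#' two mates are `read_length` bases from opposite fragment ends, with the
#' 3' mate reverse-complemented.  Substitution errors are applied per base
#' at `error_rate`.  Read names encode the individual, chromosome and true
#' fragment coordinates (0-based half-open): `ind:chrom:start:end:serial`.
#'
#' @param donor named list/vector of chromosome sequences.
#' @param config a [cohort_config()].
#' @param individual identifier embedded in read names.
#' @param seed integer seed for this individual's reads (default derives
#'   from `config$seed` so different individuals get different reads).
#' @return data.frame with `qname`, `chrom`, `start`, `end` (fragment,
#'   donor 0-based), `seq1`, `seq2` (as sequenced).
#' @export
generate_reads <- function(donor, config, individual = "ind", seed = NULL) {
  rl <- config$read_length
  if (is.null(seed)) {
    seed <- (config$seed + sum(utf8ToInt(individual)) * 1009L) %% .Machine$integer.max
  }
  set.seed(seed)
  frag_max <- config$fragment_mean + 4L * config$fragment_sd
  out <- lapply(names(donor), function(ch) {
    len <- nchar(donor[[ch]])
    if (config$fragment_mean > len) {
      stop(sprintf("fragment_mean (%d) exceeds length of %s (%d)",
                   config$fragment_mean, ch, len))
    }
    n <- as.integer(round(config$coverage * len / (2 * rl)))
    flen <- as.integer(round(rnorm(n, config$fragment_mean, config$fragment_sd)))
    flen <- pmin(pmax(flen, rl), min(frag_max, len))
    start <- as.integer(floor(runif(n, 0, len - flen + 1)))
    end <- start + flen
    seq1 <- substr0(rep(donor[[ch]], n), start, start + rl)
    seq2 <- revcomp(substr0(rep(donor[[ch]], n), end - rl, end))
    data.frame(qname = sprintf("%s:%s:%d:%d:%06d", individual, ch, start, end,
                               seq_len(n)),
               chrom = ch, start = start, end = end,
               seq1 = seq1, seq2 = seq2, stringsAsFactors = FALSE)
  })
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL
  if (config$error_rate > 0) {
    reads$seq1 <- add_errors(reads$seq1, config$error_rate)
    reads$seq2 <- add_errors(reads$seq2, config$error_rate)
  }
  reads
}

add_errors <- function(seqs, rate) {
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    chars[pos] <- vapply(chars[pos], function(b) {
      sample(setdiff(DNA_BASES4, b), 1)
    }, character(1))
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Write paired reads as FASTQ
#' @param reads data.frame from [generate_reads()].
#' @param prefix output prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` (`.fastq.gz` when `gzip`).
#' @param gzip compress the output (default FALSE).
#' @export
write_fastq <- function(reads, prefix, gzip = FALSE) {
  for (mate in 1:2) {
    seqs <- reads[[paste0("seq", mate)]]
    lines <- as.vector(rbind(paste0("@", reads$qname, "/", mate), seqs,
                             "+", strrep("I", nchar(seqs))))
    path <- sprintf("%s_R%d.fastq%s", prefix, mate, if (gzip) ".gz" else "")
    con <- if (gzip) gzfile(path, "w") else file(path, "w")
    writeLines(lines, con)
    close(con)
  }
  invisible(prefix)
}

#' Write / read a cohort configuration as a key:value file
#'
#' Plain `key: value` lines (YAML-compatible), one per scalar parameter.
#'
#' @param config a [cohort_config()].
#' @param path file path.
#' @export
write_cohort_config <- function(config, path) {
  keys <- c("chrom_count", "chrom_length", "species_tree",
            "insertions_per_branch", "read_length", "fragment_mean",
            "fragment_sd", "coverage", "error_rate", "seed", "min_spacing",
            "decoys_per_chrom")
  writeLines(vapply(keys, function(k) {
    sprintf("%s: %s", k, format(config[[k]], scientific = FALSE))
  }, character(1)), path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  vals <- setNames(lapply(kv, `[[`, 3), trimws(vapply(kv, `[[`, "", 2)))
  num <- function(k, d) if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  cohort_config(
    chrom_count = num("chrom_count", 2L),
    chrom_length = num("chrom_length", 70000L),
    species_tree = if ("species_tree" %in% names(vals)) vals[["species_tree"]]
    else "(((red,gray),ceylon),green);",
    insertions_per_branch = num("insertions_per_branch", 10L),
    read_length = num("read_length", 100L),
    fragment_mean = num("fragment_mean", 400L),
    fragment_sd = num("fragment_sd", 40L),
    coverage = num("coverage", 30),
    error_rate = num("error_rate", 0),
    seed = num("seed", 1L),
    min_spacing = num("min_spacing", 4L * num("fragment_mean", 400L)),
    decoys_per_chrom = num("decoys_per_chrom", 2L)
  )
}
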