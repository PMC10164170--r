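#' LTR query library
#'
#' An LTR library is a list of entries, one per named LTR sequence, each
#' annotated with the retroviral U3 / R / U5 sub-regions and a family label.
#' The four EAV entries are mosaics built from shared region prototypes:
#' LTR-A and LTR-D carry the same R+U5 block but different U3 blocks, and
#' LTR-B and LTR-C share an R+U5 block distinct from the A/D one, mirroring
#' the recombination structure observed among avian EAV LTRs.
#'
#' @name ltr_library
NULL

EAV_MOSAICS <- list(A = c(u3 = "U3-I",   ru5 = "RU5-I"),
                    B = c(u3 = "U3-I",   ru5 = "RU5-II"),
                    C = c(u3 = "U3-II",  ru5 = "RU5-II"),
                    D = c(u3 = "U3-III", ru5 = "RU5-I"))

#' Default region-prototype specification for the LTR library
#'
#' Generates three U3 prototypes (I, II, III) and two R+U5 prototypes
#' (I, II) as random sequences, plus one full-length sequence for each of
#' the non-EAV families (ALV-E, Ovex1, MLV-related).  Region lengths default
#' to U3 = 170, R = 60, U5 = 116 so the assembled EAV LTRs are 346 bp.
#'
#' @param seed integer seed; the spec of prototypes is fully deterministic
#'   given the seed.
#' @param u3_len,r_len,u5_len region lengths in bp for the EAV prototypes.
#' @return a list with elements `u3` (named list of 3 sequences), `ru5`
#'   (named list of 2 lists with `r` and `u5` sequences) and `other`
#'   (named list of sequences for ALV-E, Ovex1, MLV-related with their own
#'   region boundaries).
#' @export
default_ltr_patterns <- function(seed = 1L, u3_len = 170L, r_len = 60L,
                                 u5_len = 116L) {
  set.seed(seed)
  u3 <- setNames(as.list(random_dna(rep(u3_len, 3))),
                 c("U3-I", "U3-II", "U3-III"))
  ru5 <- list(
    "RU5-I"  = list(r = random_dna(r_len), u5 = random_dna(u5_len)),
    "RU5-II" = list(r = random_dna(r_len), u5 = random_dna(u5_len))
  )
  other_len <- c("ALV-E" = 280L, "Ovex1" = 310L, "MLV-related" = 400L)
  other <- lapply(seq_along(other_len), function(i) {
    len <- other_len[[i]]
    # arbitrary but valid U3/R/U5 split: ~55% / 15% / 30%
    b1 <- as.integer(round(len * 0.55))
    b2 <- as.integer(round(len * 0.70))
    list(sequence = random_dna(len), u3_end = b1, r_end = b2)
  })
  names(other) <- names(other_len)
  list(u3 = u3, ru5 = ru5, other = other)
}

new_ltr_entry <- function(name, family, sequence, u3_end, r_end,
                          region_types = c(u3 = NA_character_,
                                           ru5 = NA_character_)) {
  len <- nchar(sequence)
  stopifnot(u3_end >= 0, r_end >= u3_end, len >= r_end)
  structure(list(
    name = name, family = family, sequence = sequence,
    u3 = c(start = 0L, end = as.integer(u3_end)),
    r  = c(start = as.integer(u3_end), end = as.integer(r_end)),
    u5 = c(start = as.integer(r_end), end = as.integer(len)),
    region_types = region_types
  ), class = "ltr_entry")
}

#' Build the LTR query library
#'
#' Assembles the four EAV LTR types (A-D) as mosaics of shared U3 and R+U5
#' prototypes -- A = U3-I + RU5-I, B = U3-I + RU5-II, C = U3-II + RU5-II,
#' D = U3-III + RU5-I -- plus one entry each for ALV-E, Ovex1 and the
#' MLV-related family.  Consequently A and D share identical R and U5
#' regions (with distinct U3), as do B and C, while A and B share U3.
#'
#' @param pattern_spec region-prototype definitions, as returned by
#'   [default_ltr_patterns()].  Must define at least 2 U3 prototypes and at
#'   least 2 R+U5 prototypes.
#' @param seed used only when `pattern_spec` is NULL, to generate the
#'   default prototypes deterministically.
#' @return an object of class `ltr_library`: a named list of `ltr_entry`
#'   objects.
#' @examples
#' lib <- build_ltr_library(seed = 7)
#' names(lib)
#' @export
build_ltr_library <- function(pattern_spec = NULL, seed = 1L) {
  if (is.null(pattern_spec)) pattern_spec <- default_ltr_patterns(seed)
  if (length(pattern_spec$u3) < 2 || length(pattern_spec$ru5) < 2) {
    stop("pattern_spec must define >= 2 U3 and >= 2 R+U5 prototypes")
  }
  assert_acgt(unlist(pattern_spec$u3), "U3 prototype")
  for (p in pattern_spec$ru5) assert_acgt(c(p$r, p$u5), "R/U5 prototype")

  entries <- list()
  for (letter in names(EAV_MOSAICS)) {
    m <- EAV_MOSAICS[[letter]]
    u3 <- pattern_spec$u3[[m[["u3"]]]]
    ru5 <- pattern_spec$ru5[[m[["ru5"]]]]
    seqn <- paste0(u3, ru5$r, ru5$u5)
    entries[[paste0("EAV-LTR-", letter)]] <- new_ltr_entry(
      name = paste0("EAV-LTR-", letter), family = "EAV", sequence = seqn,
      u3_end = nchar(u3), r_end = nchar(u3) + nchar(ru5$r),
      region_types = c(u3 = m[["u3"]], ru5 = m[["ru5"]])
    )
  }
  for (fam in names(pattern_spec$other)) {
    o <- pattern_spec$other[[fam]]
    assert_acgt(o$sequence, paste(fam, "prototype"))
    entries[[paste0(fam, "-LTR")]] <- new_ltr_entry(
      name = paste0(fam, "-LTR"), family = fam, sequence = o$sequence,
      u3_end = o$u3_end, r_end = o$r_end
    )
  }
  structure(entries, class = "ltr_library")
}

#' @export
print.ltr_library <- function(x, ...) {
  cat(sprintf("LTR library with %d entries:\n", length(x)))
  for (e in x) {
    cat(sprintf("  %-16s %-12s %4d bp  U3[%d,%d) R[%d,%d) U5[%d,%d)\n",
                e$name, e$family, nchar(e$sequence),
                e$u3["start"], e$u3["end"], e$r["start"], e$r["end"],
                e$u5["start"], e$u5["end"]))
  }
  invisible(x)
}

#' Region sequence of a library entry
#' @param entry an `ltr_entry`.
#' @param region one of "u3", "r", "u5", "ru5".
#' @return the region substring.
#' @export
ltr_region <- function(entry, region = c("u3", "r", "u5", "ru5")) {
  region <- match.arg(region)
  if (region == "ru5") {
    return(substr0(entry$sequence, entry$r[["start"]], entry$u5[["end"]]))
  }
  iv <- entry[[region]]
  substr0(entry$sequence, iv[["start"]], iv[["end"]])
}

#' Sequences and family labels of a library
#' @param library an `ltr_library`.
#' @return named character vector.
#' @export
library_sequences <- function(library) {
  vapply(library, function(e) e$sequence, character(1))
}

#' @rdname library_sequences
#' @export
library_families <- function(library) {
  vapply(library, function(e) e$family, character(1))
}

#' Write an LTR library to FASTA
#' @param library an `ltr_library`.
#' @param path output FASTA path.
#' @export
write_ltr_library_fasta <- function(library, path) {
  seqs <- Biostrings::DNAStringSet(library_sequences(library))
  names(seqs) <- vapply(library, function(e) {
    sprintf("%s family=%s u3_end=%d r_end=%d", e$name, e$family,
            e$u3[["end"]], e$r[["end"]])
  }, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
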