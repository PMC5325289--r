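#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   mcols<- strand<- start<- end<- granges findOverlaps countOverlaps sort
#'   shift resize reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits metadata metadata<- DataFrame
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#'   seqinfo Seqinfo
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement consensusMatrix extractAt
#' @importFrom methods is
#' @importFrom stats pchisq rnorm runif setNames t.test
#' @importFrom utils write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Accept a DNAStringSet, DNAString, character vector or FASTA path and
## return a named, uppercased DNAStringSet.
as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    gs <- genome
  } else if (is(genome, "DNAString")) {
    gs <- DNAStringSet(genome)
  } else if (is.character(genome) && length(genome) == 1L &&
             file.exists(genome) && !grepl("^[ACGTNacgtn]+$", genome)) {
    gs <- readDNAStringSet(genome)
  } else if (is.character(genome)) {
    gs <- DNAStringSet(toupper(genome))
  } else {
    stop("`genome` must be a DNAStringSet, character sequence(s) or FASTA path")
  }
  if (length(gs) == 0L || sum(width(gs)) == 0L) {
    stop("genome is empty")
  }
  if (is.null(names(gs))) {
    names(gs) <- paste0("seq", seq_along(gs))
  }
  ## FASTA headers often carry descriptions after the first word
  names(gs) <- sub("\\s.*$", "", names(gs))
  gs
}

genome_seqinfo <- function(gs) {
  Seqinfo(seqnames = names(gs), seqlengths = width(gs))
}

check_base <- function(base) {
  base <- toupper(as.character(base))
  if (length(base) != 1L || !base %in% DNA_BASES) {
    stop("`base` must be one of A, C, G, T")
  }
  base
}

#' Find exact homopolymer tracts
#'
#' Scans each sequence for maximal runs of a single nucleotide of at least
#' `min_len` bases. Runs are maximal: the characters immediately flanking a
#' reported tract (where they exist) differ from `base`. `N` never matches.
#'
#' @param genome a `DNAStringSet`, a character vector of sequences, or the
#'   path to a FASTA file.
#' @param base the homopolymer nucleotide, one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param min_len minimum tract length in bases.
#' @return a `GRanges` (1-based, closed intervals as usual for `GRanges`;
#'   BED export converts to 0-based half-open) with metadata columns `base`
#'   and `n_mismatches` (always 0 for exact tracts), sorted by position.
#' @examples
#' find_exact_tracts("CCTTTTTTTTTTTTGG", "T", 12)
#' @seealso [find_tolerant_tracts()], [tract_census()]
#' @export
find_exact_tracts <- function(genome, base, min_len = 12L) {
  gs <- as_genome(genome)
  base <- check_base(base)
  min_len <- as.integer(min_len)
  if (is.na(min_len) || min_len < 1L) stop("`min_len` must be >= 1")
  pat <- sprintf("%s{%d,}", base, min_len)
  per_seq <- lapply(seq_along(gs), function(i) {
    m <- gregexpr(pat, as.character(gs[[i]]), perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    GRanges(names(gs)[i],
            IRanges(as.integer(m), width = attr(m, "match.length")))
  })
  per_seq <- per_seq[!vapply(per_seq, is.null, logical(1))]
  gr <- if (length(per_seq)) {
    suppressWarnings(do.call(c, per_seq))
  } else {
    GRanges()
  }
  seqlevels(gr) <- names(gs)
  seqlengths(gr) <- width(gs)
  mcols(gr)$base <- if (length(gr)) base else character(0)
  mcols(gr)$n_mismatches <- integer(length(gr))
  sort(gr)
}

## Tolerant tracts on one character sequence; returns IRanges.
## A position is reported iff it is covered by at least one window of
## length >= min_len that starts and ends with `base`, contains at most
## max_mm non-`base` characters and no N. For every start position with
## s[i] == base the rightmost admissible window end is found with a prefix
## sum of mismatch weights (N weighs max_mm + 1, so any window containing
## an N is disqualified); the union of these maximal windows equals the
## union of all qualifying windows.
tolerant_ranges_one <- function(chars, base, min_len, max_mm) {
  n <- length(chars)
  if (n < min_len) return(IRanges())
  w <- ifelse(chars == base, 0L, ifelse(chars == "N", max_mm + 1L, 1L))
  cw <- c(0L, cumsum(w))            # cw[j + 1] = mismatches in s[1..j]
  idx <- seq_len(n)
  is_b <- chars == base
  last_b <- cummax(ifelse(is_b, idx, 0L))
  starts <- which(is_b)
  if (!length(starts)) return(IRanges())
  jmax <- findInterval(cw[starts] + max_mm, cw) - 1L
  jend <- last_b[pmin(jmax, n)]
  keep <- jend - starts + 1L >= min_len
  if (!any(keep)) return(IRanges())
  reduce(IRanges(starts[keep], jend[keep]))
}

#' Find mismatch-tolerant homopolymer tracts
#'
#' Reports merged maximal intervals covered by at least one window of length
#' at least `min_len` that starts and ends with `base` and contains at most
#' `max_mm` non-`base` characters. Windows containing `N` never qualify, and
#' windows may not be padded with mismatches at their edges. With
#' `max_mm = 0` the result equals [find_exact_tracts()].
#'
#' @inheritParams find_exact_tracts
#' @param max_mm maximum number of mismatching bases per window; must be
#'   smaller than `min_len`.
#' @return a `GRanges` with metadata columns `base` and `n_mismatches` (the
#'   number of non-`base` characters inside each reported interval).
#' @examples
#' find_tolerant_tracts("TTTTTGTTTTTT", "T", 12, 2)
#' @export
find_tolerant_tracts <- function(genome, base, min_len = 12L, max_mm = 2L) {
  gs <- as_genome(genome)
  base <- check_base(base)
  min_len <- as.integer(min_len)
  max_mm <- as.integer(max_mm)
  if (is.na(max_mm) || max_mm < 0L) stop("`max_mm` must be >= 0")
  if (is.na(min_len) || min_len <= max_mm) {
    stop("`min_len` must be greater than `max_mm`")
  }
  per_seq <- lapply(seq_along(gs), function(i) {
    chars <- strsplit(as.character(gs[[i]]), "", fixed = TRUE)[[1L]]
    ir <- tolerant_ranges_one(chars, base, min_len, max_mm)
    if (!length(ir)) return(NULL)
    n_mm <- vapply(seq_along(ir), function(k) {
      sum(chars[start(ir)[k]:end(ir)[k]] != base)
    }, integer(1))
    gr <- GRanges(names(gs)[i], ir)
    mcols(gr)$base <- base
    mcols(gr)$n_mismatches <- n_mm
    gr
  })
  per_seq <- per_seq[!vapply(per_seq, is.null, logical(1))]
  gr <- if (length(per_seq)) {
    suppressWarnings(do.call(c, per_seq))
  } else {
    g <- GRanges()
    mcols(g)$base <- character(0)
    mcols(g)$n_mismatches <- integer(0)
    g
  }
  seqlevels(gr) <- names(gs)
  seqlengths(gr) <- width(gs)
  sort(gr)
}

#' Genome-wide homopolymer tract census
#'
#' Counts exact maximal homopolymer tracts of each nucleotide at a range of
#' length thresholds, for use as the genomic normalization in enrichment
#' statistics. Both the number of tracts of exactly each length and the
#' cumulative number of tracts at least that long are reported, since a
#' census may be consumed either way.
#'
#' @inheritParams find_exact_tracts
#' @param min_len_range integer vector of length thresholds to tabulate.
#' @return a `data.frame` of class `tract_census` with columns `base`,
#'   `length`, `n_exact` (tracts of exactly that length) and `n_ge` (tracts
#'   of at least that length); the genome size in bases is attached as
#'   attribute `genome_size`.
#' @examples
#' tract_census("TTTTTTTTTTTTCCCCC", min_len_range = c(5, 12))
#' @export
tract_census <- function(genome, min_len_range = 5:25) {
  gs <- as_genome(genome)
  min_len_range <- sort(unique(as.integer(min_len_range)))
  if (!length(min_len_range) || any(min_len_range < 1L)) {
    stop("`min_len_range` must be a non-empty set of positive lengths")
  }
  rows <- lapply(DNA_BASES, function(b) {
    tr <- find_exact_tracts(gs, b, min_len = min(min_len_range))
    wd <- width(tr)
    data.frame(
      base = b,
      length = min_len_range,
      n_exact = vapply(min_len_range, function(L) sum(wd == L), integer(1)),
      n_ge = vapply(min_len_range, function(L) sum(wd >= L), integer(1))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "genome_size") <- sum(width(gs))
  class(out) <- c("tract_census", "data.frame")
  out
}

#' Look up a census count
#'
#' @param census a [tract_census()] result.
#' @param base nucleotide.
#' @param min_len length threshold; must be one of the tabulated thresholds.
#' @return the number of tracts of `base` with length at least `min_len`.
#' @export
census_count <- function(census, base, min_len = 12L) {
  stopifnot(inherits(census, "tract_census"))
  base <- check_base(base)
  hit <- census$base == base & census$length == as.integer(min_len)
  if (!any(hit)) {
    stop("threshold ", min_len, " not tabulated in this census; ",
         "rebuild with `min_len_range` covering it")
  }
  census$n_ge[hit]
}

#' Write tracts as a BED6 file
#'
#' Exports tract intervals as 0-based half-open BED with the tract base in
#' the name column, the mismatch count in the score column and strand `+`.
#'
#' @param tracts a `GRanges` from [find_exact_tracts()] or
#'   [find_tolerant_tracts()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_tracts_bed <- function(tracts, path) {
  out <- granges(tracts)
  mcols(out)$name <- mcols(tracts)$base
  nm <- mcols(tracts)$n_mismatches
  mcols(out)$score <- if (is.null(nm)) integer(length(out)) else nm
  strand(out) <- "+"
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read tract intervals from a BED file
#'
#' Reads a BED file written by [export_tracts_bed()] (or any BED whose name
#' column holds the tract nucleotide and score column the mismatch count).
#'
#' @param path BED file.
#' @return a `GRanges` with metadata columns `base` and `n_mismatches`.
#' @export
import_tracts_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  base <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else
    stop("tract BED needs the base in the name column")
  score <- if (!is.null(mcols(gr)$score)) as.integer(mcols(gr)$score) else
    integer(length(gr))
  gr <- granges(gr)
  mcols(gr)$base <- base
  mcols(gr)$n_mismatches <- score
  gr
}
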