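## Strand-aware windows used for tract adjacency. The fragment interval is
## extended by `distance` bases on the tail side (right for +, left for -),
## reproducing `bedtools window -r d -l 0` / `-r 0 -l d` half-open overlap
## arithmetic: at distance 1 a tract beginning at the base immediately
## after the tailed end overlaps the window by exactly one base.
tail_windows <- function(fragments, distance, end = c("tail", "first")) {
  end <- match.arg(end)
  stopifnot(distance >= 0)
  plus <- as.character(strand(fragments)) == "+"
  st <- start(fragments)
  en <- end(fragments)
  if (end == "tail") {
    en[plus] <- en[plus] + distance
    st[!plus] <- st[!plus] - distance
  } else {
    ## vicinity window downstream (3'-wards) of the first-read end
    en[plus] <- st[plus] + distance
    st[!plus] <- en[!plus] - distance
  }
  GRanges(seqnames(fragments), IRanges(st, en), strand = strand(fragments))
}

drop_unknown_tracts <- function(fragments, tracts) {
  unknown <- setdiff(as.character(unique(seqnames(tracts))),
                     as.character(unique(seqnames(fragments))))
  if (length(unknown)) {
    warning("ignoring tracts on chromosome(s) absent from the fragments: ",
            paste(unknown, collapse = ", "))
    tracts <- tracts[!as.character(seqnames(tracts)) %in% unknown]
  }
  tracts
}

#' Tract adjacency of fragment ends
#'
#' Relates each fragment to the homopolymer tracts its tail-side window
#' touches. A `+` fragment is counted for a tract iff the tract overlaps
#' the fragment extended `distance` bases to the right; a `-` fragment iff
#' the tract overlaps the fragment extended `distance` bases to the left.
#' A tract strictly inside the fragment therefore also counts (overlap
#' case), matching the "overlapped or ended exactly adjacent" definition.
#' With `end = "first"` the window is instead anchored at the first-read
#' end and extends `distance` bases in the 3' direction, the vicinity mode
#' used for single-end data (typically `distance = 250`).
#'
#' @param fragments a fragment `GRanges`.
#' @param tracts a tract `GRanges` with metadata column `base`.
#' @param distance window extension in bases (default 1: a tract beginning
#'   at the very next base counts).
#' @param end `"tail"` (second-read 3' end; whole fragment plus extension)
#'   or `"first"` (first-read 5' vicinity).
#' @return an `adjacency_table` object holding the fragment-tract hits,
#'   the total fragment count and the window parameters. Summarize with
#'   [adjacency_counts()] or [adjacency_counts_by_length()].
#' @export
adjacent_fragments <- function(fragments, tracts, distance = 1L,
                               end = c("tail", "first")) {
  end <- match.arg(end)
  if (is.null(mcols(tracts)$base)) {
    stop("`tracts` needs a `base` metadata column")
  }
  tracts <- drop_unknown_tracts(fragments, tracts)
  win <- tail_windows(fragments, distance, end)
  ov <- findOverlaps(win, tracts, ignore.strand = TRUE)
  hits <- data.frame(
    fragment = queryHits(ov),
    base = mcols(tracts)$base[subjectHits(ov)],
    tract_len = width(tracts)[subjectHits(ov)],
    strand = as.character(strand(fragments))[queryHits(ov)],
    stringsAsFactors = FALSE
  )
  structure(
    list(hits = hits, n_total = length(fragments),
         distance = distance, end = end),
    class = "adjacency_table"
  )
}

#' @export
print.adjacency_table <- function(x, ...) {
  cat("Adjacency table:", x$n_total, "fragments,",
      nrow(x$hits), "fragment-tract hits",
      sprintf("(distance = %d, end = %s)\n", x$distance, x$end))
  print(adjacency_counts(x))
  invisible(x)
}

#' Adjacency counts per base and strand
#'
#' Counts, for each tract nucleotide and fragment strand, the fragments
#' adjacent to at least one tract of length at least `min_len`. Each
#' fragment is counted at most once per base class.
#'
#' @param at an [adjacent_fragments()] result.
#' @param min_len minimum tract length.
#' @return a `data.frame` with columns `base`, `strand`, `count` and
#'   `n_total` (all strata present, zero-filled).
#' @export
adjacency_counts <- function(at, min_len = 12L) {
  stopifnot(inherits(at, "adjacency_table"))
  h <- at$hits[at$hits$tract_len >= min_len, , drop = FALSE]
  h <- unique(h[c("fragment", "base", "strand")])
  grid <- expand.grid(base = DNA_BASES, strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  cnt <- as.data.frame(table(base = h$base, strand = h$strand),
                       stringsAsFactors = FALSE)
  out <- merge(grid, cnt, all.x = TRUE)
  out$Freq[is.na(out$Freq)] <- 0L
  out <- out[order(match(out$base, DNA_BASES), out$strand, decreasing = FALSE), ]
  rownames(out) <- NULL
  data.frame(base = out$base, strand = out$strand,
             count = as.integer(out$Freq), n_total = at$n_total,
             stringsAsFactors = FALSE)
}

#' Adjacency counts per base, strand and exact tract length
#'
#' @param at an [adjacent_fragments()] result.
#' @param lengths exact tract lengths to tabulate.
#' @return a `data.frame` with columns `base`, `strand`, `length`, `count`.
#'   A fragment adjacent to several tracts of the same base and length is
#'   counted once in that stratum.
#' @export
adjacency_counts_by_length <- function(at, lengths = 5:25) {
  stopifnot(inherits(at, "adjacency_table"))
  lengths <- sort(unique(as.integer(lengths)))
  h <- at$hits[at$hits$tract_len %in% lengths, , drop = FALSE]
  h <- unique(h)
  grid <- expand.grid(base = DNA_BASES, strand = c("+", "-"),
                      length = lengths, stringsAsFactors = FALSE)
  if (nrow(h)) {
    cnt <- aggregate(list(count = h$fragment),
                     by = list(base = h$base, strand = h$strand,
                               length = h$tract_len),
                     FUN = length)
    out <- merge(grid, cnt, all.x = TRUE)
    out$count[is.na(out$count)] <- 0L
  } else {
    out <- grid
    out$count <- 0L
  }
  out <- out[order(match(out$base, DNA_BASES), out$strand, out$length), ]
  rownames(out) <- NULL
  out$count <- as.integer(out$count)
  out
}

#' Per-fragment tract adjacency predicate
#'
#' Logical vector: is each fragment's tail-side window touching a
#' qualifying tract? With `strand_specific = TRUE` (the bias mechanism's
#' geometry) `+` fragments are tested against poly(dT) tracts and `-`
#' fragments against poly(dA) tracts; otherwise any supplied tract counts.
#'
#' @inheritParams adjacent_fragments
#' @param min_len minimum tract length to consider.
#' @param strand_specific restrict to the strand-matched tract base.
#' @return a logical vector along `fragments`.
#' @export
tail_adjacent <- function(fragments, tracts, distance = 1L, min_len = 1L,
                          strand_specific = TRUE, end = "tail") {
  tracts <- tracts[width(tracts) >= min_len]
  tracts <- drop_unknown_tracts(fragments, tracts)
  win <- tail_windows(fragments, distance, end)
  if (strand_specific) {
    if (is.null(mcols(tracts)$base)) {
      stop("strand-specific adjacency needs a `base` metadata column")
    }
    plus <- as.character(strand(fragments)) == "+"
    res <- logical(length(fragments))
    res[plus] <- countOverlaps(win[plus], tracts[mcols(tracts)$base == "T"],
                               ignore.strand = TRUE) > 0L
    res[!plus] <- countOverlaps(win[!plus], tracts[mcols(tracts)$base == "A"],
                                ignore.strand = TRUE) > 0L
    res
  } else {
    countOverlaps(win, tracts, ignore.strand = TRUE) > 0L
  }
}
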