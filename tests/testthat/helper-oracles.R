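suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

random_seq <- function(n, prob = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
}

## Independent oracle for exact maximal runs: run-length encoding of the
## character vector (the implementation uses a regex scan).
oracle_exact_runs <- function(s, base, min_len) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- r$values == base & r$lengths >= min_len
  cbind(start = starts[hit], end = ends[hit])
}

## Independent oracle for tolerant-tract coverage: enumerate every window
## [i, j] of length >= min_len directly from the definition (endpoints are
## `base`, at most max_mm non-`base` characters, no N) and union the
## qualifying windows. Quadratic in sequence length.
oracle_tolerant_coverage <- function(s, base, min_len, max_mm) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  mm <- cumsum(ch != base)
  hasN <- cumsum(ch == "N")
  covered <- logical(n)
  for (i in seq_len(n - min_len + 1L)) {
    if (ch[i] != base) next
    j <- (i + min_len - 1L):n
    ok <- ch[j] == base &
      (mm[j] - if (i > 1L) mm[i - 1L] else 0L) <= max_mm &
      (hasN[j] - if (i > 1L) hasN[i - 1L] else 0L) == 0L
    if (any(ok)) covered[i:max(j[ok])] <- TRUE
  }
  covered
}

coverage_from_granges <- function(gr, n) {
  covered <- logical(n)
  for (k in seq_along(gr)) covered[start(gr)[k]:end(gr)[k]] <- TRUE
  covered
}

## All-pairs interval oracle for tail-side adjacency: a + fragment is
## adjacent iff the tract overlaps [start, end + d], a - fragment iff the
## tract overlaps [start - d, end].
oracle_adjacent <- function(frags, tracts, distance) {
  fs <- start(frags); fe <- end(frags)
  plus <- as.character(strand(frags)) == "+"
  ws <- ifelse(plus, fs, fs - distance)
  we <- ifelse(plus, fe + distance, fe)
  fc <- as.character(seqnames(frags))
  tc <- as.character(seqnames(tracts))
  ts <- start(tracts); te <- end(tracts)
  vapply(seq_along(frags), function(i) {
    any(tc == fc[i] & ts <= we[i] & te >= ws[i])
  }, logical(1))
}

## A small genome plus a deterministic fragment set around one tract, for
## boundary-exact adjacency fixtures.
make_toy_fragments <- function(chrom = "chr1", spans, strands) {
  GRanges(chrom, IRanges(spans[, 1], spans[, 2]), strand = strands)
}
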