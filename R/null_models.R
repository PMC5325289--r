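#' Shift-randomize fragment coordinates
#'
#' Translates every fragment by `offset` bases along its chromosome,
#' wrapping around the chromosome end, which destroys sequence-specific
#' positioning while preserving fragment lengths, strands and the
#' per-chromosome read structure. Fragments that would straddle the
#' chromosome origin after wrapping are dropped and counted; for offsets
#' far below the chromosome length this loses well under 1% of fragments.
#'
#' @param fragments a fragment `GRanges`.
#' @param offset positive shift in bases (conventional choices: 500,
#'   1000, 10000).
#' @param chrom_sizes named vector of chromosome lengths; taken from
#'   `seqlengths(fragments)` when `NULL`.
#' @return the shifted `GRanges`; the number of dropped fragments is in
#'   `metadata(result)$n_dropped`.
#' @export
shift_fragments <- function(fragments, offset, chrom_sizes = NULL) {
  offset <- as.integer(offset)
  if (is.na(offset) || offset <= 0L) stop("`offset` must be positive")
  if (is.null(chrom_sizes)) chrom_sizes <- seqlengths(fragments)
  chrom <- as.character(seqnames(fragments))
  if (any(is.na(chrom_sizes[chrom]))) {
    stop("chromosome length unknown for: ",
         paste(unique(chrom[is.na(chrom_sizes[chrom])]), collapse = ", "))
  }
  L <- unname(chrom_sizes[chrom])
  if (any(offset >= L)) stop("`offset` must be smaller than every chromosome")
  new_start0 <- (start(fragments) - 1L + offset) %% L
  keep <- new_start0 + width(fragments) <= L
  out <- fragments[keep]
  out <- GRanges(seqnames(out),
                 IRanges(start = new_start0[keep] + 1L,
                         width = width(out)),
                 strand = strand(out),
                 seqlengths = seqlengths(fragments))
  mcols(out) <- mcols(fragments[keep])
  metadata(out)$n_dropped <- sum(!keep)
  out
}

#' Uniformly reposition fragments
#'
#' Places every fragment at a uniformly random position on its chromosome,
#' preserving fragment lengths, strands and metadata. A fixed-offset shift
#' ([shift_fragments()]) destroys sequence-specific positioning but leaves
#' exact end-coincidences intact (all ends translate together), so the
#' coincident-end cluster null needs this stronger randomization, which
#' breaks both positioning and coincidence while keeping the length
#' structure of the library.
#'
#' @param fragments a fragment `GRanges` with seqlengths.
#' @param seed optional integer for reproducibility.
#' @return a `GRanges` parallel to the input.
#' @export
randomize_fragments <- function(fragments, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sl <- seqlengths(fragments)
  chrom <- as.character(seqnames(fragments))
  if (any(is.na(sl[chrom]))) stop("fragments need seqlengths")
  L <- unname(sl[chrom])
  w <- width(fragments)
  if (any(w > L)) stop("fragment longer than its chromosome")
  st <- 1L + as.integer(floor(runif(length(fragments)) * (L - w + 1L)))
  out <- GRanges(chrom, IRanges(st, width = w), strand = strand(fragments),
                 seqlengths = sl)
  mcols(out) <- mcols(fragments)
  out
}

#' Random-fragment tract-content simulation
#'
#' Draws `n` fragments uniformly over the genome with lengths resampled
#' from an empirical length distribution and reports the fraction whose
#' span overlaps any poly(dA) or poly(dT) tract of at least `min_len`
#' bases. This is the null rate at which unbiased fragments would merely
#' contain such a tract — an upper bound on what mapping artifacts could
#' produce, to be compared with the observed adjacency rate.
#'
#' @param genome genome as for [find_exact_tracts()].
#' @param length_sample non-empty vector of fragment lengths to resample.
#' @param n number of random fragments.
#' @param min_len minimum tract length.
#' @param seed optional integer for reproducibility.
#' @return a list: `fraction`, `n`, `n_tracts` (A/T tracts considered).
#' @export
simulate_random_fragments <- function(genome, length_sample, n,
                                      min_len = 12L, seed = NULL) {
  gs <- as_genome(genome)
  if (!length(length_sample)) stop("`length_sample` is empty")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  length_sample <- as.integer(length_sample)
  lens <- length_sample[sample.int(length(length_sample), n, replace = TRUE)]
  if (min(lens) > max(width(gs))) {
    stop("sampled fragments are longer than every contig")
  }
  chrom_w <- width(gs)
  ci <- sample.int(length(gs), n, replace = TRUE,
                   prob = chrom_w / sum(chrom_w))
  ## clamp lengths to the chosen contig
  lens <- pmin(lens, chrom_w[ci])
  st <- 1L + floor(runif(n) * (chrom_w[ci] - lens + 1L))
  frags <- GRanges(names(gs)[ci], IRanges(st, width = lens))
  tracts <- suppressWarnings(c(find_exact_tracts(gs, "A", min_len),
                               find_exact_tracts(gs, "T", min_len)))
  hit <- countOverlaps(frags, tracts, ignore.strand = TRUE) > 0L
  list(fraction = mean(hit), n = n, n_tracts = length(tracts))
}
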