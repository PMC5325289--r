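## Fragment records are plain GRanges: the range is the outer fragment span,
## the strand is read 1's orientation, and metadata column `has_gap` flags
## alignments whose CIGAR contains an insertion or deletion (NA for BED
## input, which carries no CIGAR).

sam_to_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = TRUE)
  }
  path
}

#' Load aligned fragments
#'
#' Builds one fragment record per sequenced molecule from a coordinate
#' file. For paired alignments the fragment is the outer span of the two
#' mates and its strand is read 1's orientation: the tailed end (where the
#' terminal-transferase poly(dT) was appended, i.e. the 3' end of the
#' second read) is the rightmost coordinate of `+` fragments and the
#' leftmost coordinate of `-` fragments. Unmapped, secondary, supplementary
#' and low-mapping-quality alignments are excluded; the mapping-quality cut
#' stands in for "uniquely mapped" since multi-mappers receive low MAPQ
#' from standard aligners.
#'
#' @param x path to a SAM/BAM file (paired or single-end) or a BED6 file
#'   with a strand column, or an existing fragment `GRanges` (returned
#'   unchanged apart from validation).
#' @param format `"auto"` (by extension), `"bam"`, `"sam"` or `"bed"`.
#' @param mode `"paired"` (fragments from proper pairs) or `"single"`
#'   (each primary alignment becomes one record spanning the read).
#' @param min_mapq minimum mapping quality for SAM/BAM input.
#' @return a `GRanges` of fragments with metadata column `has_gap`.
#' @export
load_fragments <- function(x, format = c("auto", "bam", "sam", "bed"),
                           mode = c("paired", "single"), min_mapq = 10L) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (is(x, "GRanges")) {
    if (any(!as.character(strand(x)) %in% c("+", "-"))) {
      stop("fragment records need a + or - strand")
    }
    if (is.null(mcols(x)$has_gap)) mcols(x)$has_gap <- NA
    return(x)
  }
  stopifnot(is.character(x), length(x) == 1L, file.exists(x))
  if (format == "auto") {
    format <- if (grepl("\\.bed$", x, ignore.case = TRUE)) "bed"
      else if (grepl("\\.sam$", x, ignore.case = TRUE)) "sam"
      else "bam"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(x, format = "BED")
    if (any(!as.character(strand(gr)) %in% c("+", "-"))) {
      stop("BED input must carry a strand column (+ or -) for every record")
    }
    out <- granges(gr)
    mcols(out)$has_gap <- NA
    return(out)
  }
  bam <- sam_to_bam(x)
  flag0 <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  if (mode == "paired") {
    param <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE,
                                    isProperPair = TRUE),
      what = "mapq")
    ga <- GenomicAlignments::readGAlignmentPairs(bam, param = param,
                                                 strandMode = 1L)
    mq1 <- mcols(GenomicAlignments::first(ga))$mapq
    mq2 <- mcols(GenomicAlignments::last(ga))$mapq
    keep <- !is.na(mq1) & !is.na(mq2) & mq1 >= min_mapq & mq2 >= min_mapq
    ga <- ga[keep]
    frag <- granges(ga)
    gap1 <- grepl("[ID]", GenomicAlignments::cigar(GenomicAlignments::first(ga)))
    gap2 <- grepl("[ID]", GenomicAlignments::cigar(GenomicAlignments::last(ga)))
    mcols(frag)$has_gap <- gap1 | gap2
  } else {
    param <- Rsamtools::ScanBamParam(flag = flag0, what = "mapq")
    ga <- GenomicAlignments::readGAlignments(bam, param = param)
    mq <- mcols(ga)$mapq
    ga <- ga[!is.na(mq) & mq >= min_mapq]
    frag <- granges(ga)
    mcols(frag)$has_gap <- grepl("[ID]", GenomicAlignments::cigar(ga))
  }
  frag
}

#' Tailed-end and first-end coordinates
#'
#' `tail_end()` returns the genomic coordinate of the tailed end of each
#' fragment (the 3' end of the second read, where internal priming leaves
#' its footprint): the last base of `+` fragments, the first base of `-`
#' fragments. `first_end()` returns the opposite end (the 5' start of read
#' 1).
#'
#' @param fragments a fragment `GRanges`.
#' @return an integer vector of 1-based coordinates.
#' @export
tail_end <- function(fragments) {
  ifelse(as.character(strand(fragments)) == "+",
         end(fragments), start(fragments))
}

#' @rdname tail_end
#' @export
first_end <- function(fragments) {
  ifelse(as.character(strand(fragments)) == "+",
         start(fragments), end(fragments))
}

#' Remove duplicate fragments and over-represented end positions
#'
#' First removes exact duplicates (identical chromosome, start, end and
#' strand), then drops every fragment whose tailed-end coordinate hosts
#' more than `max_per_position` fragment ends. Positions exceeding the cap
#' almost always sit in repetitive sequence; exactly `max_per_position`
#' fragments at one position are kept.
#'
#' @param fragments a fragment `GRanges`.
#' @param max_per_position cap on fragments per tailed-end coordinate.
#' @return a list with `fragments` (the kept records) and `report` (counts
#'   removed at each step and the capped positions).
#' @export
dedup_and_cap <- function(fragments, max_per_position = 100L) {
  n_input <- length(fragments)
  key <- paste(seqnames(fragments), start(fragments), end(fragments),
               strand(fragments))
  fr <- fragments[!duplicated(key)]
  n_dup <- n_input - length(fr)
  pos_key <- paste(seqnames(fr), tail_end(fr))
  tab <- table(pos_key)
  hot <- names(tab)[tab > max_per_position]
  capped <- pos_key %in% hot
  out <- fr[!capped]
  list(
    fragments = out,
    report = list(
      n_input = n_input,
      n_duplicates = n_dup,
      n_capped = sum(capped),
      capped_positions = data.frame(
        position = hot,
        count = as.integer(tab[hot]),
        stringsAsFactors = FALSE
      ),
      n_kept = length(out)
    )
  )
}

#' Coincident tailed-end clusters
#'
#' Fraction of fragments whose tailed end falls at a genomic coordinate
#' (chromosome, position and strand) shared by at least `min_cluster`
#' fragments. Piles of second reads ending at the exact same base are the
#' fingerprint of priming at fixed genomic poly(dT)/poly(dA) tracts; in an
#' unbiased library at typical coverage this fraction is near zero.
#'
#' @param fragments a fragment `GRanges`; must be non-empty.
#' @param min_cluster minimum fragments per position to call a cluster.
#' @return a list with `fraction` (in \[0, 1\]) and `clusters` (a
#'   `data.frame` of cluster positions and their fragment counts).
#' @export
end_position_clusters <- function(fragments, min_cluster = 5L) {
  if (!length(fragments)) stop("no fragments: cluster fraction is undefined")
  if (min_cluster < 2L) stop("`min_cluster` must be >= 2")
  key <- paste(seqnames(fragments), strand(fragments), tail_end(fragments))
  tab <- table(key)
  in_cluster <- tab[key] >= min_cluster
  big <- tab[tab >= min_cluster]
  list(
    fraction = mean(in_cluster),
    clusters = data.frame(
      position = names(big),
      count = as.integer(big),
      stringsAsFactors = FALSE
    )
  )
}

#' Fraction of gapped alignments
#'
#' Fraction of primary alignments whose CIGAR contains an insertion or
#' deletion. Gapped alignments can artificially shift a read end toward a
#' nearby homopolymer tract, so this fraction bounds how much of an
#' observed adjacency signal mis-mapping could explain.
#'
#' @param x path to a SAM/BAM file.
#' @return a fraction in \[0, 1\].
#' @export
gapped_fraction <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("\\.bed$", x, ignore.case = TRUE)) {
    stop("gapped_fraction needs CIGAR strings; BED input is unsupported")
  }
  bam <- sam_to_bam(x)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = "cigar")
  cig <- Rsamtools::scanBam(bam, param = param)[[1L]]$cigar
  if (!length(cig)) stop("no primary alignments in ", x)
  mean(grepl("[ID]", cig))
}

#' Write fragments as a BED6 file
#'
#' @param fragments a fragment `GRanges`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_fragments_bed <- function(fragments, path) {
  out <- granges(fragments)
  mcols(out)$name <- paste0("frag", seq_along(out))
  mcols(out)$score <- 0L
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}
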