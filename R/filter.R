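#' Filter reads adjacent to mismatch-tolerant poly(dA)/poly(dT) tracts
#'
#' The recommended mitigation for internal-priming bias: remove every
#' fragment whose tail-side window touches a mismatch-tolerant poly(dT)
#' tract (`+` fragments) or poly(dA) tract (`-` fragments) of at least
#' `min_len` bases with up to `max_mm` mismatches. Tolerating mismatches
#' matters because many read clusters sit next to tracts interrupted by a
#' single variant base, which an exact scanner misses. The cost — the
#' fraction of the library removed — and the coincident-end cluster
#' fraction before and after filtering are reported.
#'
#' @param fragments a fragment `GRanges`.
#' @param genome genome for tolerant tract scanning (as for
#'   [find_exact_tracts()]); may be omitted when `tracts` is supplied.
#' @param tracts optional precomputed tolerant tract `GRanges` (with a
#'   `base` metadata column), e.g. from [import_tracts_bed()].
#' @param min_len minimum tract length (default 12).
#' @param max_mm maximum mismatches per tract (default 2).
#' @param distance adjacency window extension (default 1).
#' @param both_strands remove fragments near both tract bases regardless
#'   of strand (conservative variant); default is the strand-specific rule
#'   matching the bias geometry.
#' @param min_cluster cluster threshold for the before/after diagnostic.
#' @return a list: `kept` and `removed` fragment `GRanges`, and `report`,
#'   a `filter_report` with `n_input`, `n_removed`, `fraction_removed`,
#'   `cluster_before`, `cluster_after` and the parameters used.
#' @export
filter_reads <- function(fragments, genome = NULL, tracts = NULL,
                         min_len = 12L, max_mm = 2L, distance = 1L,
                         both_strands = FALSE, min_cluster = 5L) {
  if (is.null(tracts)) {
    if (is.null(genome)) {
      stop("supply either `genome` (for tract scanning) or `tracts`")
    }
    gs <- as_genome(genome)
    tracts <- suppressWarnings(c(
      find_tolerant_tracts(gs, "T", min_len, max_mm),
      find_tolerant_tracts(gs, "A", min_len, max_mm)
    ))
  }
  hit <- tail_adjacent(fragments, tracts, distance = distance,
                       min_len = min_len,
                       strand_specific = !both_strands)
  kept <- fragments[!hit]
  removed <- fragments[hit]
  cl_before <- if (length(fragments)) {
    end_position_clusters(fragments, min_cluster)$fraction
  } else NA_real_
  cl_after <- if (length(kept)) {
    end_position_clusters(kept, min_cluster)$fraction
  } else NA_real_
  report <- structure(list(
    n_input = length(fragments),
    n_removed = length(removed),
    fraction_removed = if (length(fragments)) {
      length(removed) / length(fragments)
    } else NA_real_,
    cluster_before = cl_before,
    cluster_after = cl_after,
    params = list(min_len = min_len, max_mm = max_mm, distance = distance,
                  both_strands = both_strands, min_cluster = min_cluster)
  ), class = "filter_report")
  list(kept = kept, removed = removed, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "Filtered %d / %d fragments (%.1f%%); cluster fraction %.3f -> %.3f\n",
    x$n_removed, x$n_input, 100 * x$fraction_removed,
    x$cluster_before, x$cluster_after))
  cat(sprintf("  (tracts >= %d bp, <= %d mismatches, distance %d, %s)\n",
              x$params$min_len, x$params$max_mm, x$params$distance,
              if (x$params$both_strands) "both strands" else "strand-specific"))
  invisible(x)
}

#' Serialize a filter report as JSON
#'
#' @param report a `filter_report` from [filter_reads()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
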