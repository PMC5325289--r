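#' Cramer's phi effect size
#'
#' For a chi-squared goodness-of-fit statistic over `k` categories on `N`
#' observations, `phi = sqrt(chi2 / (N * (k - 1)))`. Unlike a p-value it
#' does not inflate with sample size, which matters here because adjacency
#' counts run into the millions and every chi-squared test is "significant".
#'
#' @param chi2 chi-squared statistic (>= 0).
#' @param N total observation count (>= 1).
#' @param k number of categories (>= 2).
#' @return the effect size, 0 when `chi2 = 0`, 1 when `chi2 = N * (k - 1)`.
#' @examples
#' cramers_phi(50, 200, 2)  # 0.5
#' @export
cramers_phi <- function(chi2, N, k) {
  if (any(k < 2)) stop("`k` must be >= 2")
  if (any(chi2 < 0) || any(N < 1)) stop("need chi2 >= 0 and N >= 1")
  sqrt(chi2 / (N * (k - 1)))
}

#' Chi-squared goodness of fit with Cramer's phi
#'
#' Compares observed category counts against expected proportions.
#' Categories with zero expected proportion and zero observed count are
#' dropped; a positive count in a zero-expectation category is an error.
#' With no observations at all the statistic is defined as 0.
#'
#' @param observed named or unnamed vector of non-negative counts.
#' @param expected_prop expected proportions (rescaled to sum to 1).
#' @return a `gof_result` list: `chi2`, `N`, `k`, `dof`, `phi`, `p_value`,
#'   plus the observed and expected counts.
#' @export
gof_test <- function(observed, expected_prop) {
  if (length(observed) != length(expected_prop)) {
    stop("observed and expected_prop lengths differ")
  }
  if (any(observed < 0) || any(expected_prop < 0)) {
    stop("counts and proportions must be non-negative")
  }
  bad <- expected_prop == 0 & observed > 0
  if (any(bad)) {
    stop("observed counts in categories with zero expectation: ",
         paste(which(bad), collapse = ", "))
  }
  keep <- expected_prop > 0
  observed <- observed[keep]
  expected_prop <- expected_prop[keep] / sum(expected_prop[keep])
  k <- length(observed)
  if (k < 2) stop("fewer than 2 usable categories")
  N <- sum(observed)
  if (N == 0) {
    res <- list(chi2 = 0, N = 0L, k = k, dof = k - 1L, phi = 0, p_value = 1,
                observed = observed, expected = expected_prop * 0)
    class(res) <- "gof_result"
    return(res)
  }
  expected <- N * expected_prop
  chi2 <- sum((observed - expected)^2 / expected)
  res <- list(
    chi2 = chi2, N = N, k = k, dof = k - 1L,
    phi = cramers_phi(chi2, N, k),
    p_value = pchisq(chi2, df = k - 1L, lower.tail = FALSE),
    observed = observed, expected = expected
  )
  class(res) <- "gof_result"
  res
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf(
    "Chi-squared GOF: chi2 = %.4g, N = %d, k = %d, phi = %.4f, p = %.3g\n",
    x$chi2, x$N, x$k, x$phi, x$p_value))
  invisible(x)
}

#' Forward/reverse fold ratios by tract length
#'
#' Internal priming is strand-asymmetric: second-read ends pile up next to
#' poly(dT) downstream on `+` fragments and next to poly(dA) upstream on
#' `-` fragments, while both strands sample C/G tracts evenly. The
#' forward/reverse count ratio per exact tract length therefore traces the
#' minimum tract length the priming mechanism engages. For T, C and G the
#' forward/reverse ratio is reported; for A the reverse/forward ratio, so
#' a biased library shows T and A curves rising together.
#'
#' @param at an [adjacent_fragments()] result (both strands).
#' @param lengths exact tract lengths.
#' @param pseudocount when the denominator is zero, report
#'   `(num + 1) / (den + 1)` and flag the point, rather than `Inf`.
#' @return a `data.frame` with columns `base`, `length`, `numerator`,
#'   `denominator`, `ratio`, `flagged`.
#' @export
fold_ratio_by_length <- function(at, lengths = 5:25, pseudocount = TRUE) {
  cnt <- adjacency_counts_by_length(at, lengths)
  fwd <- cnt[cnt$strand == "+", ]
  rev <- cnt[cnt$strand == "-", ]
  m <- merge(fwd[c("base", "length", "count")],
             rev[c("base", "length", "count")],
             by = c("base", "length"), suffixes = c("_fwd", "_rev"))
  num <- ifelse(m$base == "A", m$count_rev, m$count_fwd)
  den <- ifelse(m$base == "A", m$count_fwd, m$count_rev)
  flagged <- den == 0
  ratio <- ifelse(flagged,
                  if (pseudocount) (num + 1) / (den + 1) else Inf,
                  num / den)
  out <- data.frame(base = m$base, length = m$length,
                    numerator = num, denominator = den,
                    ratio = ratio, flagged = flagged,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$base, DNA_BASES), out$length), ]
  rownames(out) <- NULL
  out
}

#' Genomically normalized adjacency enrichment
#'
#' Converts adjacency counts into fragments-per-million adjacent to tracts
#' of each nucleotide, then divides by the genomic number of such tracts,
#' since poly(dA)/poly(dT) tracts outnumber poly(dC)/poly(dG) roughly
#' 100-fold and raw counts alone would mostly restate that. A chi-squared
#' goodness of fit per strand compares the observed adjacency counts
#' across the four bases to the expectation given by the genomic tract
#' frequencies, with Cramer's phi as the effect size.
#'
#' @param at an [adjacent_fragments()] result.
#' @param census a [tract_census()] of the same genome.
#' @param min_len minimum tract length (default 12, where internal priming
#'   becomes pronounced).
#' @param joint also compute a single 8-category (base x strand) test.
#' @return an `enrichment_report`: `table` (per base/strand raw count,
#'   per-million rate, census count, normalized value, `flagged` where the
#'   census count is zero so the normalized value is undefined) and `gof`,
#'   a list of per-strand `gof_result`s (plus `joint` if requested).
#' @export
normalized_enrichment <- function(at, census, min_len = 12L, joint = FALSE) {
  cnt <- adjacency_counts(at, min_len)
  cens <- vapply(cnt$base, function(b) census_count(census, b, min_len),
                 numeric(1))
  per_million <- cnt$count / at$n_total * 1e6
  flagged <- cens == 0
  normalized <- ifelse(flagged, NA_real_, per_million / cens)
  tab <- data.frame(base = cnt$base, strand = cnt$strand,
                    count = cnt$count, per_million = per_million,
                    census_count = cens, normalized = normalized,
                    flagged = flagged, stringsAsFactors = FALSE)
  gof <- lapply(c(`+` = "+", `-` = "-"), function(s) {
    sub <- tab[tab$strand == s, ]
    gof_test(setNames(sub$count, sub$base),
             sub$census_count / sum(sub$census_count))
  })
  if (joint) {
    gof$joint <- gof_test(setNames(tab$count, paste(tab$base, tab$strand)),
                          rep(tab$census_count[tab$strand == "+"], 2) /
                            (2 * sum(tab$census_count[tab$strand == "+"])))
  }
  structure(list(table = tab, gof = gof, min_len = min_len),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("Adjacency enrichment (tracts >=", x$min_len, "bp):\n")
  print(x$table, digits = 4)
  for (s in c("+", "-")) {
    cat("strand", s, ": ")
    print(x$gof[[s]])
  }
  invisible(x)
}

#' Positional base frequencies and information content around fragment ends
#'
#' Samples fragment ends per strand, extracts the `2 * w` bases of
#' forward-genome sequence centered on the end boundary and tabulates base
#' frequencies per position. Information content is `2 - H` bits, with `H`
#' the Shannon entropy (base 2) of the frequency vector, the quantity a
#' sequence-logo renderer plots. Ends within `w` bases of a contig edge
#' are skipped and counted. No small-sample correction is applied: at the
#' default 1,000 ends it is below 0.01 bit.
#'
#' @param fragments a fragment `GRanges`.
#' @param genome genome as for [find_exact_tracts()].
#' @param w half-window in bases (window spans offsets `-(w-1) .. w`
#'   relative to the end coordinate).
#' @param sample_size ends sampled per strand (all ends if fewer).
#' @param end which end, `"tail"` or `"first"`.
#' @param seed optional integer for reproducible sampling.
#' @return a list of class `info_matrix` with one entry per strand, each
#'   holding `freq` (4 x 2w matrix), `bits` (per-position information
#'   content), `n_used` and `n_skipped`.
#' @export
info_content <- function(fragments, genome, w = 10L, sample_size = 1000L,
                         end = c("tail", "first"), seed = NULL) {
  end <- match.arg(end)
  gs <- as_genome(genome)
  if (!is.null(seed)) set.seed(seed)
  pos_all <- if (end == "tail") tail_end(fragments) else first_end(fragments)
  out <- lapply(c(`+` = "+", `-` = "-"), function(s) {
    sel <- which(as.character(strand(fragments)) == s)
    if (length(sel) > sample_size) {
      sel <- sample(sel, sample_size)
    }
    chrom <- as.character(seqnames(fragments))[sel]
    p <- pos_all[sel]
    st <- p - w + 1L
    en <- p + w
    lens <- setNames(width(gs), names(gs))
    if (any(!chrom %in% names(gs))) {
      stop("fragments on chromosome(s) absent from the genome: ",
           paste(setdiff(chrom, names(gs)), collapse = ", "))
    }
    ok <- st >= 1L & en <= lens[chrom]
    n_skipped <- sum(!ok)
    chrom <- chrom[ok]; st <- st[ok]; en <- en[ok]
    if (!length(st)) {
      return(list(freq = matrix(NA_real_, 4, 2 * w,
                                dimnames = list(DNA_BASES, NULL)),
                  bits = rep(NA_real_, 2 * w),
                  n_used = 0L, n_skipped = n_skipped))
    }
    wins <- DNAStringSet(lapply(seq_along(st), function(i) {
      gs[[chrom[i]]][st[i]:en[i]]
    }))
    cm <- consensusMatrix(wins, as.prob = TRUE, baseOnly = TRUE)
    freq <- cm[DNA_BASES, , drop = FALSE]
    ## renormalize over A/C/G/T in case of Ns
    freq <- sweep(freq, 2, colSums(freq), "/")
    ent <- apply(freq, 2, function(f) {
      f <- f[f > 0]
      -sum(f * log2(f))
    })
    colnames(freq) <- c(-(w - 1):0, seq_len(w))
    list(freq = freq, bits = setNames(2 - ent, colnames(freq)),
         n_used = length(st), n_skipped = n_skipped)
  })
  structure(out, class = "info_matrix", w = w, end = end)
}

#' @export
print.info_matrix <- function(x, ...) {
  for (s in names(x)) {
    cat("strand", s, ":", x[[s]]$n_used, "ends; peak information",
        sprintf("%.2f bits\n", suppressWarnings(max(x[[s]]$bits, na.rm = TRUE))))
  }
  invisible(x)
}

#' Write an information-content matrix as TSV
#'
#' One row per strand and position: `strand`, `position`, `fA`, `fC`, `fG`,
#' `fT`, `bits` — directly consumable by a logo renderer.
#'
#' @param x an [info_content()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_info_tsv <- function(x, path) {
  stopifnot(inherits(x, "info_matrix"))
  rows <- do.call(rbind, lapply(names(x), function(s) {
    m <- x[[s]]
    data.frame(strand = s, position = colnames(m$freq),
               fA = m$freq["A", ], fC = m$freq["C", ],
               fG = m$freq["G", ], fT = m$freq["T", ],
               bits = m$bits, stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare lengths of tract-adjacent versus other fragments
#'
#' Internally primed fragments are truncated at the genomic tract, so
#' fragments whose tailed end abuts a poly(dA)/poly(dT) tract should be
#' shorter than the rest of the library. Welch's two-sample t-test on
#' fragment lengths split by strand-specific tail adjacency.
#'
#' @inheritParams tail_adjacent
#' @param min_len minimum tract length defining adjacency (default 12).
#' @return a list: `mean_adjacent`, `mean_other`, `t`, `p_value`,
#'   `n_adjacent`, `n_other`. Degenerate zero-variance groups with equal
#'   means return `t = 0`, `p = 1`.
#' @export
fragment_length_compare <- function(fragments, tracts, distance = 1L,
                                    min_len = 12L, strand_specific = TRUE) {
  adj <- tail_adjacent(fragments, tracts, distance = distance,
                       min_len = min_len, strand_specific = strand_specific)
  la <- width(fragments)[adj]
  lo <- width(fragments)[!adj]
  if (length(la) < 2L) stop("fewer than 2 tract-adjacent fragments")
  if (length(lo) < 2L) stop("fewer than 2 non-adjacent fragments")
  if (stats::var(la) == 0 && stats::var(lo) == 0) {
    same <- mean(la) == mean(lo)
    return(list(mean_adjacent = mean(la), mean_other = mean(lo),
                t = if (same) 0 else sign(mean(la) - mean(lo)) * Inf,
                p_value = if (same) 1 else 0,
                n_adjacent = length(la), n_other = length(lo)))
  }
  tt <- t.test(la, lo)
  list(mean_adjacent = mean(la), mean_other = mean(lo),
       t = unname(tt$statistic), p_value = tt$p.value,
       n_adjacent = length(la), n_other = length(lo))
}
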