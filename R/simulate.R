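#' Simulation configuration
#'
#' Parameters for the synthetic genome and library generators. Defaults
#' emulate a sonicated human-like DNA library sequenced 2x50: fragment
#' lengths approximately normal with mean 220 bp and sd 60 bp, truncated
#' below at the read length; a genome whose poly(dA)/poly(dT) tracts
#' outnumber poly(dC)/poly(dG) roughly 100:1 (about 500 A- and T-tracts of
#' at least 8 bp per Mb, close to the human genome's density, with
#' geometrically decaying lengths); and a template-switching capture in
#' which a fragment containing a genomic poly(dT) run of at least
#' `L_prime` bases (in tail orientation) is re-primed at that run with
#' probability `p_internal` instead of at the appended tail, truncating
#' the fragment there.
#'
#' @param genome_length genome size in bases.
#' @param base_comp named base composition (proportions for A, C, G, T).
#' @param tract_rates planted tracts per Mb for each base.
#' @param tract_len_min,tract_len_max planted tract length range (bases).
#' @param tract_len_decay geometric decay of planted tract lengths:
#'   `P(length = L)` proportional to `decay^(L - tract_len_min)`.
#' @param frag_mean,frag_sd fragment length distribution (bases).
#' @param read_len read length (bases).
#' @param n_fragments default library size.
#' @param p_internal probability that a fragment containing a qualifying
#'   genomic run is internally primed there.
#' @param L_prime minimum genomic run length the primer can anneal to.
#' @param chrom_name contig name for generated genomes.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 1e6,
                       base_comp = c(A = 0.295, C = 0.205,
                                     G = 0.205, T = 0.295),
                       tract_rates = c(A = 500, C = 5, G = 5, T = 500),
                       tract_len_min = 8L, tract_len_max = 40L,
                       tract_len_decay = 0.85,
                       frag_mean = 220, frag_sd = 60, read_len = 50L,
                       n_fragments = 200000L, p_internal = 0.15,
                       L_prime = 12L, chrom_name = "chr1") {
  stopifnot(
    genome_length >= 10 * frag_mean,
    all(DNA_BASES %in% names(base_comp)),
    abs(sum(base_comp) - 1) < 1e-6, all(base_comp > 0),
    all(DNA_BASES %in% names(tract_rates)), all(tract_rates >= 0),
    tract_len_min >= 2, tract_len_max >= tract_len_min,
    tract_len_decay > 0, tract_len_decay <= 1,
    frag_mean > 0, frag_sd >= 0, read_len >= 1,
    frag_mean >= read_len,
    n_fragments >= 1,
    p_internal >= 0, p_internal <= 1,
    L_prime >= 1
  )
  structure(list(
    genome_length = as.integer(genome_length),
    base_comp = base_comp[DNA_BASES],
    tract_rates = tract_rates[DNA_BASES],
    tract_len_min = as.integer(tract_len_min),
    tract_len_max = as.integer(tract_len_max),
    tract_len_decay = tract_len_decay,
    frag_mean = frag_mean, frag_sd = frag_sd,
    read_len = as.integer(read_len),
    n_fragments = as.integer(n_fragments),
    p_internal = p_internal, L_prime = as.integer(L_prime),
    chrom_name = chrom_name
  ), class = "sim_config")
}

sample_other_base <- function(current) {
  vapply(current, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
}

#' Generate a genome with planted homopolymer tracts
#'
#' Background bases are i.i.d. at the configured composition with every
#' run of 8 or more identical bases broken by resampling, so that all
#' homopolymers of at least 8 bp are planted and hence exactly known.
#' Planted tracts are placed without overlap with flanking bases forced to
#' differ from the tract base (and from their outer neighbor), keeping
#' every planted tract maximal and of exact length. Scanning the emitted
#' genome with [find_exact_tracts()] at any threshold of at least 8 bp
#' recovers exactly the truth set at or above that length.
#'
#' @param config a [sim_config()].
#' @param seed optional integer for reproducibility.
#' @return a list with `genome` (a named `DNAStringSet`) and `tracts`
#'   (truth `GRanges` with metadata column `base`).
#' @export
make_genome <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$genome_length
  ch <- sample(DNA_BASES, n, replace = TRUE, prob = config$base_comp)
  ## break background runs >= 8 (replacements can merge neighboring runs,
  ## so iterate to a fixed point; converges in a handful of passes)
  repeat {
    r <- rle(ch)
    long <- which(r$lengths >= 8L)
    if (!length(long)) break
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    pos <- unlist(lapply(long, function(i) {
      seq(run_start[i] + 7L, run_end[i], by = 8L)
    }))
    ch[pos] <- sample_other_base(ch[pos])
  }
  ## plant tracts
  lens_choices <- config$tract_len_min:config$tract_len_max
  len_prob <- config$tract_len_decay^(lens_choices - config$tract_len_min)
  counts <- round(config$tract_rates * n / 1e6)
  occupied <- logical(n)
  occupied[c(1L, n)] <- TRUE   # keep flanks inside the contig
  plant <- list()
  k <- 0L
  for (b in DNA_BASES) {
    cnt <- counts[[b]]
    if (cnt < 1L) next
    for (j in seq_len(cnt)) {
      L <- sample(lens_choices, 1L, prob = len_prob)
      placed <- FALSE
      for (try in seq_len(1000L)) {
        st <- sample.int(n - L - 1L, 1L) + 1L   # st in [2, n - L]
        span <- (st - 1L):(st + L)
        if (!any(occupied[span])) {
          occupied[span] <- TRUE
          ch[st:(st + L - 1L)] <- b
          ## flanks: differ from tract base and from the outer neighbor
          lf <- st - 1L
          rf <- st + L
          avoid_l <- c(b, if (lf > 1L) ch[lf - 1L])
          avoid_r <- c(b, if (rf < n) ch[rf + 1L])
          ch[lf] <- sample(setdiff(DNA_BASES, avoid_l), 1L)
          ch[rf] <- sample(setdiff(DNA_BASES, avoid_r), 1L)
          k <- k + 1L
          plant[[k]] <- c(st, L, match(b, DNA_BASES))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place tract ", j, " of base ", b,
             ": planting density infeasible")
      }
    }
  }
  genome <- DNAStringSet(setNames(paste(ch, collapse = ""),
                                  config$chrom_name))
  if (length(plant)) {
    pm <- do.call(rbind, plant)
    tracts <- GRanges(config$chrom_name,
                      IRanges(pm[, 1L], width = pm[, 2L]),
                      seqlengths = setNames(n, config$chrom_name))
    mcols(tracts)$base <- DNA_BASES[pm[, 3L]]
    tracts <- sort(tracts)
  } else {
    tracts <- GRanges(seqlengths = setNames(n, config$chrom_name))
    mcols(tracts)$base <- character(0)
  }
  list(genome = genome, tracts = tracts)
}

## Uniform sonication draws: chromosome by length, fragment length from
## the truncated normal, start uniform among valid positions.
draw_uniform_frags <- function(gs, config, m) {
  W <- setNames(width(gs), names(gs))
  ci <- sample.int(length(gs), m, replace = TRUE, prob = W / sum(W))
  rl <- config$read_len
  len <- as.integer(round(rnorm(m, config$frag_mean, config$frag_sd)))
  repeat {
    bad <- which(len < rl | len > W[ci])
    if (!length(bad)) break
    len[bad] <- as.integer(round(rnorm(length(bad), config$frag_mean,
                                       config$frag_sd)))
  }
  st <- 1L + as.integer(floor(runif(m) * (W[ci] - len + 1L)))
  list(chrom = names(gs)[ci], start = st, end = st + len - 1L,
       strand = sample(c("+", "-"), m, replace = TRUE))
}

## For fragments drawn in tail orientation, which contain a qualifying
## run the primer could anneal to (leaving at least one read length of
## fragment after truncation), and where is the run closest to the tail?
## + fragments: a poly(dT) run starting within [start + read_len, end]
## (runs straddling the fragment's 3' boundary qualify: the terminal
## case); the closest is the one with the largest start. - fragments:
## mirrored onto poly(dA) runs in forward coordinates, closest = smallest
## run end.
find_priming_sites <- function(fr, tracts, config) {
  rl <- config$read_len
  m <- length(fr$start)
  site <- rep(NA_integer_, m)      # truncation coordinate (new tail end)
  tid <- rep(NA_integer_, m)       # index into `tracts`
  idxT <- which(mcols(tracts)$base == "T" & width(tracts) >= config$L_prime)
  idxA <- which(mcols(tracts)$base == "A" & width(tracts) >= config$L_prime)
  plus <- which(fr$strand == "+" & fr$end - fr$start + 1L > rl)
  if (length(plus) && length(idxT)) {
    iv <- GRanges(fr$chrom[plus], IRanges(fr$start[plus] + rl, fr$end[plus]))
    pts <- resize(granges(tracts[idxT]), 1L, fix = "start")
    ov <- findOverlaps(iv, pts, ignore.strand = TRUE)
    if (length(ov)) {
      q <- queryHits(ov)
      ts <- start(pts)[subjectHits(ov)]
      best <- vapply(split(seq_along(q), q),
                     function(ii) ii[which.max(ts[ii])], integer(1))
      sel <- plus[as.integer(names(best))]
      site[sel] <- ts[best] - 1L
      tid[sel] <- idxT[subjectHits(ov)[best]]
    }
  }
  minus <- which(fr$strand == "-" & fr$end - fr$start + 1L > rl)
  if (length(minus) && length(idxA)) {
    iv <- GRanges(fr$chrom[minus], IRanges(fr$start[minus], fr$end[minus] - rl))
    pts <- resize(granges(tracts[idxA]), 1L, fix = "end")
    ov <- findOverlaps(iv, pts, ignore.strand = TRUE)
    if (length(ov)) {
      q <- queryHits(ov)
      te <- start(pts)[subjectHits(ov)]
      best <- vapply(split(seq_along(q), q),
                     function(ii) ii[which.min(te[ii])], integer(1))
      sel <- minus[as.integer(names(best))]
      site[sel] <- te[best] + 1L
      tid[sel] <- idxA[subjectHits(ov)[best]]
    }
  }
  list(site = site, tract_id = tid)
}

## Shared fragment generator. The library is a mixture: a
## Binomial(n, p_internal) number of fragments is internally primed —
## drawn from the sonication pool conditioned on containing a qualifying
## genomic run (rejection sampling, which is what preferential capture of
## such fragments amounts to) and truncated at the run closest to the
## tail — and the rest are tail-primed, drawn uniformly.
sim_library_core <- function(genome, tracts, config, n_fragments,
                             p_internal, seed = NULL) {
  gs <- as_genome(genome)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_fragments)
  n_int <- if (p_internal > 0 && length(tracts)) {
    stats::rbinom(1L, n, p_internal)
  } else 0L
  base_fr <- draw_uniform_frags(gs, config, n)
  st <- base_fr$start; en <- base_fr$end
  chrom <- base_fr$chrom; str <- base_fr$strand
  orig_start <- st; orig_end <- en
  primed <- logical(n)
  tract_id <- rep(NA_integer_, n)
  if (n_int > 0L) {
    acc <- NULL
    tries <- 0L
    while (is.null(acc) || length(acc$site) < n_int) {
      tries <- tries + 1L
      if (tries > 200L) {
        stop("internal-priming rejection sampling failed: qualifying ",
             "poly(dA)/poly(dT) runs are too rare in this genome")
      }
      fr <- draw_uniform_frags(gs, config, max(2L * n_int, 20000L))
      ps <- find_priming_sites(fr, tracts, config)
      ok <- which(!is.na(ps$site))
      if (!length(ok)) next
      piece <- list(chrom = fr$chrom[ok], start = fr$start[ok],
                    end = fr$end[ok], strand = fr$strand[ok],
                    site = ps$site[ok], tract_id = ps$tract_id[ok])
      acc <- if (is.null(acc)) piece else {
        Map(c, acc, piece)
      }
    }
    sel <- seq_len(n_int)
    slots <- sample.int(n, n_int)   # scatter internal fragments
    chrom[slots] <- acc$chrom[sel]
    str[slots] <- acc$strand[sel]
    orig_start[slots] <- acc$start[sel]
    orig_end[slots] <- acc$end[sel]
    st[slots] <- ifelse(acc$strand[sel] == "+", acc$start[sel],
                        acc$site[sel])
    en[slots] <- ifelse(acc$strand[sel] == "+", acc$site[sel],
                        acc$end[sel])
    primed[slots] <- TRUE
    tract_id[slots] <- acc$tract_id[sel]
  }
  out <- GRanges(chrom, IRanges(st, en), strand = str,
                 seqlengths = setNames(width(gs), names(gs)))
  mcols(out) <- DataFrame(primed_internally = primed,
                          tract_id = tract_id,
                          orig_start = orig_start,
                          orig_end = orig_end)
  metadata(out)$p_internal <- p_internal
  metadata(out)$n_internal <- sum(primed)
  out
}

#' Simulate a template-switching (SMART) DNA library
#'
#' Emulates a capture process in which fragments already carrying a
#' genomic poly(dT) run compete with tailing-dependent fragments: a
#' `Binomial(n_fragments, p_internal)` share of the library is internally
#' primed — drawn from the sonication pool conditioned on containing (in
#' tail orientation) a genomic poly(dT) run of at least `L_prime` bases,
#' and truncated at the qualifying run closest to the original tailed end
#' — while the remainder is tail-primed and lands uniformly. An internally
#' primed fragment's tailed end abuts the run's 5' edge: immediately 5' of
#' genomic poly(dT) for `+` fragments, of poly(dA) for `-` fragments in
#' forward coordinates, and the fragment is shortened accordingly.
#' Per-fragment truth labels travel in the metadata columns.
#'
#' @param genome genome as for [find_exact_tracts()].
#' @param tracts tract `GRanges` for the genome (e.g. the truth set from
#'   [make_genome()], or a [find_exact_tracts()] scan).
#' @param config a [sim_config()].
#' @param n_fragments library size (defaults to the config value).
#' @param p_internal internal-priming probability (defaults to the config
#'   value).
#' @param seed optional integer for reproducibility.
#' @return a fragment `GRanges` with truth metadata columns
#'   `primed_internally`, `tract_id` (index into `tracts`, NA when tail
#'   primed), `orig_start`, `orig_end`.
#' @export
simulate_smart_library <- function(genome, tracts, config = sim_config(),
                                   n_fragments = config$n_fragments,
                                   p_internal = config$p_internal,
                                   seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (p_internal > 0) {
    nq <- sum(mcols(tracts)$base %in% c("A", "T") &
                width(tracts) >= config$L_prime)
    if (nq == 0L) {
      warning("no poly(dA)/poly(dT) run of length >= ", config$L_prime,
              " in the genome: internal-priming mechanism is inert")
    }
  }
  sim_library_core(genome, tracts, config, n_fragments, p_internal, seed)
}

#' Simulate an unbiased ligation library
#'
#' The negative control: identical fragmentation and length distribution,
#' with the internal-priming mechanism disabled. Adjacency enrichment on
#' its output reflects only the genomic tract landscape.
#'
#' @inheritParams simulate_smart_library
#' @return a fragment `GRanges` (truth columns present, all tail-primed).
#' @export
simulate_ligation_library <- function(genome, config = sim_config(),
                                      n_fragments = config$n_fragments,
                                      seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sim_library_core(genome, GRanges(), config, n_fragments,
                   p_internal = 0, seed = seed)
}

#' Write simulated fragments as a paired-end SAM file
#'
#' Emits one proper read pair per fragment (read 1 at the first end, read
#' 2 at the tailed end, MAPQ 60). Optionally a fraction of second reads
#' receives a 2 bp deletion in its CIGAR, for exercising gapped-alignment
#' accounting; reads are otherwise ungapped.
#'
#' @param fragments a fragment `GRanges` with seqlengths.
#' @param path output SAM path.
#' @param read_len read length.
#' @param indel_fraction fraction of second reads given a deletion CIGAR.
#' @param seed optional integer for reproducibility.
#' @return invisibly, a list with `path` and `gapped_read_fraction` (the
#'   planted fraction over all emitted reads).
#' @export
write_read_pairs_sam <- function(fragments, path, read_len = 50L,
                                 indel_fraction = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sl <- seqlengths(fragments)
  if (any(is.na(sl))) stop("fragments need seqlengths for SAM output")
  n <- length(fragments)
  chrom <- as.character(seqnames(fragments))
  st <- start(fragments)
  en <- end(fragments)
  plus <- as.character(strand(fragments)) == "+"
  len <- width(fragments)
  cig <- sprintf("%dM", read_len)
  ## second-read deletion: reference span read_len + 2
  del_cig <- sprintf("%dM2D%dM", read_len %/% 2L, read_len - read_len %/% 2L)
  has_del <- runif(n) < indel_fraction
  r2_span <- ifelse(has_del, read_len + 2L, read_len)
  ## keep deletions only where the reference span still fits the fragment
  bad <- has_del & (len < r2_span)
  has_del[bad] <- FALSE
  r2_span[bad] <- read_len
  r2_cig <- ifelse(has_del, del_cig, cig)
  ## read 1 sits at the first end, read 2 at the tailed end
  r1_pos <- ifelse(plus, st, en - read_len + 1L)
  r2_pos <- ifelse(plus, en - r2_span + 1L, st)
  r1_flag <- ifelse(plus, 99L, 83L)
  r2_flag <- ifelse(plus, 147L, 163L)
  tlen <- ifelse(plus, len, -len)
  qn <- sprintf("frag%07d", seq_len(n))
  l1 <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t*\t*",
                qn, r1_flag, chrom, r1_pos, cig, r2_pos, tlen)
  l2 <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t*\t*",
                qn, r2_flag, chrom, r2_pos, r2_cig, r1_pos, -tlen)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sl), unname(sl)))
  writeLines(c(hdr, l1, l2), path)
  invisible(list(path = path, gapped_read_fraction = sum(has_del) / (2 * n)))
}
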