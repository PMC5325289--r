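test_that("Cramer's phi closed forms and bounds hold", {
  expect_equal(cramers_phi(0, 1000, 4), 0)
  expect_equal(cramers_phi(50, 200, 2), 0.5)
  for (N in c(10, 500, 12345)) {
    for (k in c(2, 4, 8)) {
      expect_equal(cramers_phi(N * (k - 1), N, k), 1)
    }
  }
  expect_error(cramers_phi(5, 100, 1), "k")
  expect_error(cramers_phi(-1, 100, 4), "chi2")
})

test_that("phi is invariant to rescaling all counts", {
  obs <- c(A = 160, C = 1, G = 1, T = 2)
  p <- c(0.4, 0.1, 0.1, 0.4)
  g1 <- gof_test(obs, p)
  g2 <- gof_test(obs * 37, p)
  expect_equal(g2$chi2, 37 * g1$chi2)
  expect_equal(g1$phi, g2$phi)
})

test_that("goodness of fit agrees with the stats::chisq.test oracle", {
  set.seed(9)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    p <- runif(k); p <- p / sum(p)
    obs <- rmultinom(1, size = sample(100:5000, 1), prob = p)[, 1]
    got <- gof_test(obs, p)
    ref <- suppressWarnings(chisq.test(obs, p = p))
    expect_equal(got$chi2, unname(ref$statistic))
    expect_equal(got$p_value, unname(ref$p.value))
    expect_equal(got$phi, sqrt(got$chi2 / (sum(obs) * (k - 1))))
  }
})

test_that("perfectly proportional counts give zero chi2 and phi", {
  cens <- c(50000, 500, 500, 50000)
  obs <- cens / 10
  g <- gof_test(obs, cens / sum(cens))
  expect_equal(g$chi2, 0)
  expect_equal(g$phi, 0)
  z <- gof_test(c(0, 0, 0, 0), rep(0.25, 4))
  expect_equal(z$chi2, 0)
  expect_equal(z$phi, 0)
})

test_that("fold ratios are symmetric on balanced counts and flag zeros", {
  ## balanced synthetic table: every base/length 40 on each strand
  hits <- expand.grid(fragment = 1:40, base = c("A", "C", "G", "T"),
                      strand = c("+", "-"), tract_len = c(8L, 12L),
                      stringsAsFactors = FALSE)
  hits$fragment <- seq_len(nrow(hits))   # distinct fragments
  at <- structure(list(hits = hits, n_total = nrow(hits),
                       distance = 1L, end = "tail"),
                  class = "adjacency_table")
  fr <- fold_ratio_by_length(at, c(8, 12))
  expect_true(all(fr$ratio == 1))
  expect_false(any(fr$flagged))

  ## zero denominator: pseudocount policy and flag
  hits2 <- data.frame(fragment = 1:61, base = "T", strand = "+",
                      tract_len = 12L, stringsAsFactors = FALSE)
  at2 <- structure(list(hits = hits2, n_total = 61L,
                        distance = 1L, end = "tail"),
                   class = "adjacency_table")
  fr2 <- fold_ratio_by_length(at2, 12)
  t_row <- fr2[fr2$base == "T", ]
  expect_true(t_row$flagged)
  expect_equal(t_row$ratio, 62 / 1)     # (61 + 1) / (0 + 1)
  ## the A ratio is reverse/forward
  hits3 <- data.frame(fragment = 1:10, base = "A", strand = "-",
                      tract_len = 12L, stringsAsFactors = FALSE)
  at3 <- structure(list(hits = hits3, n_total = 10L,
                        distance = 1L, end = "tail"),
                   class = "adjacency_table")
  fr3 <- fold_ratio_by_length(at3, 12)
  expect_equal(fr3$numerator[fr3$base == "A"], 10)
})

test_that("normalized enrichment divides per-million rates by tract counts", {
  ## homopolymer-free background with one T tract at [300, 311] and one
  ## A tract at [612, 623]; no C/G tract exists at all
  b1 <- paste0(strrep("ACGT", 74), "ACG")
  b2 <- paste0("C", strrep("ACGT", 74), "ACG")
  b3 <- paste0("C", strrep("ACGT", 74))
  s <- paste0(b1, strrep("T", 12), b2, strrep("A", 12), b3)
  tr <- suppressWarnings(c(find_exact_tracts(s, "T", 12),
                           find_exact_tracts(s, "A", 12)))
  expect_equal(start(tr), c(300L, 612L))
  ## + fragment ends right before the T tract; - fragment starts right
  ## after the A tract
  frags <- GRanges("seq1", IRanges(c(101, 624), c(299, 800)),
                   strand = c("+", "-"))
  at <- adjacent_fragments(frags, tr, 1)
  cen <- tract_census(s, c(5, 12))
  er <- normalized_enrichment(at, cen, 12)
  tb <- er$table
  expect_equal(tb$count[tb$base == "T" & tb$strand == "+"], 1L)
  expect_equal(tb$count[tb$base == "A" & tb$strand == "-"], 1L)
  expect_equal(tb$per_million[tb$base == "T" & tb$strand == "+"], 5e5)
  expect_equal(tb$normalized[tb$base == "T" & tb$strand == "+"], 5e5 / 1)
  ## zero-census bases are flagged, not zero
  expect_true(all(tb$flagged[tb$base %in% c("C", "G")]))
  expect_true(all(is.na(tb$normalized[tb$base %in% c("C", "G")])))
})

test_that("information content hits the degenerate closed forms", {
  ## all-T genome: every window column is pure T, 2 bits
  sT <- strrep("T", 400)
  frT <- GRanges("seq1", IRanges(51, 200), strand = "+")
  icT <- info_content(rep(frT, 5), sT, w = 10, seed = 1)
  expect_equal(unname(icT[["+"]]$bits), rep(2, 20))
  expect_equal(unname(icT[["+"]]$freq["T", ]), rep(1, 20))

  ## ACGT-repeat genome, four ends offset by 1: uniform columns, 0 bits
  s4 <- strrep("ACGT", 100)
  fr4 <- GRanges("seq1", IRanges(41, 200 + 0:3), strand = "+")
  ic4 <- info_content(fr4, s4, w = 10, seed = 1)
  expect_equal(unname(ic4[["+"]]$bits), rep(0, 20), tolerance = 1e-12)

  ## AC-repeat genome, two ends offset by 1: half/half columns, 1 bit
  s2 <- strrep("AC", 200)
  fr2 <- GRanges("seq1", IRanges(41, 200 + 0:1), strand = "+")
  ic2 <- info_content(fr2, s2, w = 10, seed = 1)
  expect_equal(unname(ic2[["+"]]$bits), rep(1, 20), tolerance = 1e-12)

  ## ends too close to the contig edge are skipped and counted
  fredge <- GRanges("seq1", IRanges(1, 397), strand = "+")
  ice <- info_content(fredge, sT, w = 10)
  expect_equal(ice[["+"]]$n_skipped, 1L)
})

test_that("info matrices are reproducible given a seed and exportable", {
  set.seed(77)
  frags <- GRanges("chr1", IRanges(sample.int(5000, 300) + 200, width = 150),
                   strand = sample(c("+", "-"), 300, TRUE))
  s <- setNames(random_seq(6000), "chr1")
  a <- info_content(frags, s, sample_size = 100, seed = 42)
  b <- info_content(frags, s, sample_size = 100, seed = 42)
  expect_equal(a[["+"]]$freq, b[["+"]]$freq)
  path <- tempfile(fileext = ".tsv")
  export_info_tsv(a, path)
  tsv <- read.delim(path)
  expect_equal(nrow(tsv), 40L)
  expect_true(all(abs(rowSums(tsv[, c("fA", "fC", "fG", "fT")]) - 1) < 1e-9))
})

test_that("fragment length comparison detects a planted shortening", {
  g <- make_genome(sim_config(genome_length = 3e5), seed = 13)
  cfg <- sim_config(genome_length = 3e5)
  lib <- simulate_smart_library(g$genome, g$tracts, cfg,
                                n_fragments = 20000, p_internal = 0.25,
                                seed = 14)
  fl <- fragment_length_compare(lib, g$tracts)
  expect_lt(fl$mean_adjacent, fl$mean_other)
  expect_lt(fl$p_value, 0.01)

  ## identical constant groups: degenerate variance handled
  frc <- GRanges("chr1", IRanges(c(1001, 2001, 3001, 4001), width = 200),
                 strand = "+")
  trc <- GRanges("chr1", IRanges(c(1201, 2201), width = 12))
  mcols(trc)$base <- "T"
  fl2 <- fragment_length_compare(frc, trc, min_len = 12)
  expect_equal(fl2$t, 0)
  expect_equal(fl2$p_value, 1)
})

test_that("type-I error of the length comparison is near nominal", {
  ## both groups drawn from the same length distribution: p should be
  ## roughly uniform, so rejections at 0.05 stay near 5%
  set.seed(100)
  rej <- 0L
  n_rep <- 200L
  tr <- GRanges("chr1", IRanges(seq(5000, 95000, by = 5000), width = 12))
  mcols(tr)$base <- "T"
  for (r in seq_len(n_rep)) {
    fr <- GRanges("chr1", IRanges(sample.int(9e4, 400),
                                  width = sample(150:300, 400, TRUE)),
                  strand = "+")
    p <- fragment_length_compare(fr, tr)$p_value
    rej <- rej + (p < 0.05)
  }
  expect_lt(rej / n_rep, 0.12)
})
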