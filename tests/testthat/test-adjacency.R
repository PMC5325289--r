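tract_gr <- function(start0, end0, base = "T", chrom = "chr1") {
  ## convenience: 0-based half-open spec -> GRanges
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  mcols(gr)$base <- base
  gr
}

test_that("distance-1 adjacency matches the boundary arithmetic exactly", {
  frag <- GRanges("chr1", IRanges(101, 150), strand = "+")  # [100,150)
  adj <- function(tr, d = 1) {
    at <- adjacent_fragments(frag, tr, distance = d)
    nrow(at$hits) > 0
  }
  expect_true(adj(tract_gr(150, 162)))    # tract begins at the next base
  expect_false(adj(tract_gr(151, 163)))   # one-base gap beyond the window
  expect_true(adj(tract_gr(120, 135)))    # contained tract overlaps
  expect_true(adj(tract_gr(149, 161)))    # overlaps the last base
  expect_false(adj(tract_gr(150, 162), d = 0))  # no extension: abutting misses
  expect_true(adj(tract_gr(120, 135), d = 0))   # overlap still counts at d = 0

  ## mirrored for a - fragment: window extends left
  fragm <- GRanges("chr1", IRanges(101, 150), strand = "-")
  adjm <- function(tr, d = 1) {
    nrow(adjacent_fragments(fragm, tr, distance = d)$hits) > 0
  }
  expect_true(adjm(tract_gr(88, 100)))    # tract ends at base before start
  expect_false(adjm(tract_gr(87, 99)))    # one-base gap upstream
  expect_true(adjm(tract_gr(120, 135)))
})

test_that("adjacency is monotone in distance", {
  set.seed(21)
  frags <- GRanges("chr1", IRanges(sample.int(5e4, 300), width = 200),
                   strand = sample(c("+", "-"), 300, TRUE))
  tr <- GRanges("chr1", IRanges(sample.int(5e4, 80), width = 12))
  mcols(tr)$base <- "T"
  prev <- rep(FALSE, 300)
  for (d in c(0, 1, 2, 5, 20)) {
    cur <- tail_adjacent(frags, tr, distance = d, strand_specific = FALSE)
    expect_true(all(cur[prev]))           # supersets as distance grows
    prev <- cur
  }
})

test_that("adjacency matches the all-pairs interval oracle", {
  set.seed(33)
  for (rep in 1:5) {
    frags <- GRanges("chr1", IRanges(sample.int(1e5, 300), width =
                                       sample(80:300, 300, TRUE)),
                     strand = sample(c("+", "-"), 300, TRUE))
    tr <- GRanges("chr1", IRanges(sample.int(1e5, 200),
                                  width = sample(5:30, 200, TRUE)))
    mcols(tr)$base <- sample(c("A", "C", "G", "T"), 200, TRUE)
    d <- sample(0:3, 1)
    got <- tail_adjacent(frags, tr, distance = d, strand_specific = FALSE)
    expect_equal(got, oracle_adjacent(frags, tr, d))
  }
})

test_that("strand mirror symmetry preserves adjacency counts", {
  ## reverse-complement the genome, mirror all coordinates and flip
  ## strands: counts must be invariant with base -> complement(base)
  set.seed(44)
  L <- 20000L
  s <- random_seq(L)
  rc <- as.character(reverseComplement(DNAString(s)))
  frags <- GRanges("seq1", IRanges(sample.int(L - 300, 200), width = 150),
                   strand = sample(c("+", "-"), 200, TRUE))
  tracts <- suppressWarnings(c(find_exact_tracts(s, "A", 5),
                               find_exact_tracts(s, "T", 5),
                               find_exact_tracts(s, "C", 5),
                               find_exact_tracts(s, "G", 5)))
  m_frags <- GRanges("seq1",
                     IRanges(L - end(frags) + 1L, L - start(frags) + 1L),
                     strand = ifelse(strand(frags) == "+", "-", "+"))
  ## sanity: the fixture is not vacuous
  expect_gt(sum(adjacency_counts(adjacent_fragments(frags, tracts, 1),
                                 min_len = 5)$count), 0L)
  m_tracts <- suppressWarnings(c(find_exact_tracts(rc, "A", 5),
                                 find_exact_tracts(rc, "T", 5),
                                 find_exact_tracts(rc, "C", 5),
                                 find_exact_tracts(rc, "G", 5)))
  a1 <- adjacency_counts(adjacent_fragments(frags, tracts, 1), min_len = 5)
  a2 <- adjacency_counts(adjacent_fragments(m_frags, m_tracts, 1), min_len = 5)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- c(`+` = "-", `-` = "+")
  for (i in seq_len(nrow(a1))) {
    j <- a2$base == comp[[a1$base[i]]] & a2$strand == flip[[a1$strand[i]]]
    expect_equal(a1$count[i], a2$count[j])
  }
})

test_that("per-length counts aggregate consistently with per-base counts", {
  set.seed(55)
  s <- random_seq(30000, prob = c(A = 0.35, C = 0.15, G = 0.15, T = 0.35))
  frags <- GRanges("seq1", IRanges(sample.int(29000, 500), width = 180),
                   strand = sample(c("+", "-"), 500, TRUE))
  tracts <- suppressWarnings(c(find_exact_tracts(s, "A", 5),
                               find_exact_tracts(s, "T", 5)))
  at <- adjacent_fragments(frags, tracts, 1)
  bylen <- adjacency_counts_by_length(at, 5:40)
  tot <- adjacency_counts(at, min_len = 5)
  expect_gt(sum(tot$count), 0L)
  for (i in seq_len(nrow(tot))) {
    sub <- bylen[bylen$base == tot$base[i] & bylen$strand == tot$strand[i], ]
    ## per-length strata can double-count a fragment adjacent to several
    ## lengths, so the sum bounds the unique count from above
    expect_gte(sum(sub$count), tot$count[i])
  }
})

test_that("tracts on unknown chromosomes are ignored with a warning", {
  frag <- GRanges("chr1", IRanges(101, 150), strand = "+")
  tr <- tract_gr(150, 162)
  tr2 <- GRanges("chrUn", IRanges(10, 30))
  mcols(tr2)$base <- "T"
  both <- suppressWarnings(c(tr, tr2))
  expect_warning(at <- adjacent_fragments(frag, both, 1), "ignoring")
  expect_equal(nrow(at$hits), 1L)
})

test_that("first-end vicinity mode anchors at the opposite end", {
  ## + fragment [1001,1200]: first end 1001; a tract 100 bp downstream of
  ## it is inside the 250 bp vicinity but far from the fragment 3' window
  frag <- GRanges("chr1", IRanges(1001, 1200), strand = "+")
  tr <- tract_gr(1100, 1112)
  hit_first <- tail_adjacent(frag, tr, distance = 250, end = "first",
                             strand_specific = FALSE)
  expect_true(hit_first)
  far <- tract_gr(1400, 1412)   # beyond the 250 window
  expect_false(tail_adjacent(frag, far, distance = 250, end = "first",
                             strand_specific = FALSE))
})
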