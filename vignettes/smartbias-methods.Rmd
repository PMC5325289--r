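---
title: "Quantifying poly dA/dT priming bias in template-switching DNA libraries"
author: "smartbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying poly dA/dT priming bias in template-switching DNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Template-switching ("SMART") DNA library preparation replaces adapter
ligation with terminal-transferase (TdT) tailing: a poly(dT) tail is
appended to each fragment's 3' end and a poly(dA)-tailed primer anneals to
it. When tailing is incomplete, the poly(dA) primer can instead anneal to
a *genomic* poly(dT) run carried by the fragment itself — at the
fragment's 3' terminus or internally, in which case the captured molecule
is truncated at the run. Libraries built this way become heavily skewed
toward fragments whose tailed ends abut long genomic poly(dT) (forward
strand) or poly(dA) (reverse strand, because the reported sequence is
always the forward genome) tracts. The skew matters for any counting
assay — ChIP-seq, CNV, ATAC-seq — because poly(dA/dT) runs are roughly a
hundred times more common in mammalian genomes than poly(dC/dG) runs, and
the affected reads pile up at fixed genomic coordinates.

`smartbias` measures this bias in an aligned library, provides
randomization nulls to calibrate it, implements the mitigation (discard
reads adjacent to mismatch-tolerant poly(dA/dT) tracts), and ships a
truth-labeled simulator so every stage can be validated end to end
without external data.

## Objects and conventions

Fragments and tracts are `GRanges` (1-based, closed intervals), the
native container of the R/Bioconductor genomics stack; all disk formats
(BED6, TSV) follow the usual 0-based half-open BED convention via
`rtracklayer`. The *tailed end* of a fragment is the 3' end of its second
read — the right edge of a `+` fragment, the left edge of a `-` fragment
(`tail_end()`); the *first end* is the opposite edge.

## Tract scanning

`find_exact_tracts()` reports maximal single-nucleotide runs of at least
`min_len` bases; `N` never matches. `find_tolerant_tracts()` reports the
merged coverage of every window of length at least `min_len` that starts
and ends with the target base and contains at most `max_mm` other bases.
Three rules make this coverage predicate well-behaved:

* windows must start and end with the target base, so a tract can never
  be padded outward with mismatches;
* windows containing `N` are disqualified (an unknown base is not
  evidence of a tract);
* with `max_mm = 0` the tolerant scanner reduces exactly to the exact
  scanner.

The scanner computes, for every admissible start, the rightmost
admissible window end from a prefix sum of mismatch weights, then unions
the maximal windows; the union of maximal windows equals the union of all
qualifying windows because shorter windows at the same start are nested
inside the maximal one. Tests verify both scanners against brute-force
oracles (run-length encoding; exhaustive window enumeration).

`tract_census()` tabulates, per base, both the number of tracts of
exactly each length and the number at least each length: published genome
censuses are sometimes one and sometimes the other, so both are carried
and the normalization below states which it uses (cumulative,
`census_count()`).

## Adjacency

Following the operational definition used with `bedtools window`, a `+`
fragment is *adjacent* to a tract when the tract overlaps the fragment
extended by `distance` bases to the right (left for `-` fragments). At
the default `distance = 1` this admits exactly two geometries: the tract
overlaps the fragment, or the tract begins at the base immediately after
the tailed end — the footprint internal priming leaves. Adjacency is
resolved by interval search (`findOverlaps`), is monotone in `distance`,
and is validated against a quadratic all-pairs oracle and against
`bedtools window -r 1 -l 0 -u` / `-r 0 -l 1 -u` on boundary fixtures with
gaps of −1, 0, +1 and +2 bases.

For single-end data the vicinity mode (`end = "first"`, typically
`distance = 250`) asks instead whether a tract lies within 250 bases
3'-ward of the first-read end; the bias is invisible at 1 bp from the
first read but reappears at this scale because the tract sits at the far
end of the unobserved fragment.

## Statistics

**Fold ratio by tract length** (`fold_ratio_by_length()`): the
forward/reverse count ratio of fragments adjacent to tracts of exactly
each length (reverse/forward for A, so that an affected library shows T
and A curves rising together). Unbiased libraries sit at 1 for every base
and length; the curve rises sharply at the minimum run length the primer
engages. When a denominator is zero the ratio is reported as
`(num + 1) / (den + 1)` and flagged rather than infinite — plotted curves
through sparse C/G counts need a finite convention, and the flag keeps
the convention visible.

**Normalized enrichment** (`normalized_enrichment()`): fragments per
million adjacent to tracts of each base, divided by the genomic number of
such tracts (cumulative census at the same `min_len`; tract counts rather
than base-pair coverage, with the count convention stated here as the
package's canonical unit — "fragments per million per genomic tract"). A
base with zero census count yields a flagged `NA`, not zero. Per strand,
a chi-squared goodness of fit compares observed adjacency counts across
the four bases with expectations proportional to the census, and reports
Cramér's phi,

$$\phi_c = \sqrt{\chi^2 / (N (k - 1))},$$

which unlike the p-value does not inflate with library size (with
millions of reads every such test is "significant"). The default is
`k = 4` base categories per strand; a joint 8-category variant is
available (`joint = TRUE`). Categories with zero expectation and zero
observation are dropped; zero observations overall define
`chi2 = 0, phi = 0`.

**Information content** (`info_content()`): per strand, up to
`sample_size = 1000` fragment ends are sampled (a sequence-logo
convention; the whole-library matrix is available by raising the limit)
and the `2w = 20` bases of forward-genome sequence centered on the end
boundary are tabulated into base frequencies; information content is
`2 − H` bits per position. No small-sample correction is applied — at
1,000 ends it is below 0.01 bit. Ends within `w` of a contig edge are
skipped and counted.

**Fragment length comparison** (`fragment_length_compare()`): Welch's
two-sample t-test on fragment lengths split by strand-specific tail
adjacency. Internal priming truncates fragments, so tract-adjacent
fragments run shorter; Welch rather than pooled variance because the two
groups have no reason to share a variance. Two degenerate constant groups
with equal means return `t = 0, p = 1`.

## Hygiene filters

`load_fragments()` keeps primary, mapped, proper-pair alignments with
MAPQ of at least 10 on both mates — mapping quality is how modern
aligners encode "maps to a single location", and the threshold is
configurable. `dedup_and_cap()` removes exact duplicates
(chrom/start/end/strand) and then every fragment whose tailed end sits at
a coordinate hosting more than 100 fragment ends (strictly more: 100
exactly is kept). The cap is applied per exact coordinate — the strictest
reading of "locations with very large numbers of reads", configurable.
`end_position_clusters()` reports the fraction of fragments whose tailed
end coincides (chromosome, strand, base pair) with at least 4 others —
piles of second reads at one coordinate are the fingerprint of priming at
fixed tracts. `gapped_fraction()` reports the share of primary alignments
whose CIGAR contains an indel, bounding how much adjacency mis-mapped
gapped reads could fake.

## Null models

`shift_fragments()` translates every fragment by a fixed offset (500,
1,000 or 10,000 bases are conventional), wrapping around the chromosome;
fragments that would straddle the origin are dropped and counted (well
under 1% at these offsets). Wrapping preserves library size and
per-chromosome counts; the drop policy is this package's explicit choice.
Shifting destroys sequence-specific positioning — tract adjacency
collapses to background — but note that it *cannot* destroy exact
end-coincidence: all ends translate together, so the cluster fraction is
invariant under a constant shift. For the cluster null the package
provides `randomize_fragments()`, which repositions every fragment
uniformly on its chromosome while preserving lengths and strands; this is
the correct "unbiased expectation" for both the cluster fraction and a
length-matched adjacency background. The distinction matters in practice:
internally primed fragments are shorter, and overlap-inclusive adjacency
rates depend on fragment length, so comparing a shifted library against a
control with a different length mix confounds composition with signal.

`simulate_random_fragments()` draws fragments uniformly with lengths
resampled from an observed length list (resampling, not a parametric fit
— the empirical distribution is the stated reference) and reports the
fraction whose span overlaps any poly(dA/dT) tract at all: the ceiling on
what fragment *content*, as opposed to end placement, could explain.

## The recommended filter

`filter_reads()` removes every fragment whose tail-side window touches a
mismatch-tolerant poly(dT) tract (`+` strand) or poly(dA) tract (`-`
strand) of at least 12 bases with up to 2 mismatches. Mismatch tolerance
is essential: many read piles sit next to tracts interrupted by a single
variant base that an exact scanner misses. Filtering is strand-specific
by default because the mechanism is strand-specific; `both_strands =
TRUE` gives the conservative variant. The filter is idempotent, its
removed set is monotone in `max_mm` and `distance` and antitone in
`min_len`, and the report carries the cost (fraction removed) plus the
cluster fraction before and after. Removed fragments are returned, not
discarded, so they can be written to a rejects file.

## The simulator

`make_genome()` produces a genome in which truth is exact: background
bases are i.i.d. at the configured composition with every run of 8 or
more identical bases broken by resampling, so that *all* homopolymers of
at least 8 bp are planted and recorded. Planted tracts get flanks forced
to differ from the tract base (and from the outer neighbor, so a flank
can never seed a new long run), keeping each planted tract maximal and of
exact length; a scan of the emitted FASTA recovers the truth BED exactly.
Defaults: 1 Mb, human-like composition (59% A+T), 500 A- and 500 T-tracts
per Mb versus 5 C- and 5 G-tracts per Mb (the ~100:1 imbalance of
mammalian genomes; the A/T density matches the human genome's roughly 500
runs of at least 8 bp per Mb), lengths 8–40 with geometric decay 0.85.

`simulate_smart_library()` emulates the capture competition: a
`Binomial(n, p_internal)` share of the library is internally primed —
drawn from the sonication pool *conditioned on containing* (in tail
orientation) a genomic poly(dT) run of at least `L_prime = 12` bases,
then truncated at the qualifying run closest to the original tailed end —
and the remainder is tail-primed and lands uniformly. Rejection sampling
implements the conditioning exactly, which is what preferential capture
of tract-bearing fragments amounts to. A single nearest run is chosen
because competition between multiple internal runs within one fragment is
not quantified by any data we model. Fragment lengths are normal (mean
220 bp, sd 60 — between the observed means of tract-adjacent and other
fragments in real sonicated libraries) truncated below at the read length
(50 bp, as in 2x50 sequencing). `p_internal` is a free parameter — real
kits' tailing-failure rates are unknown — and the default 0.15 simply
sits mid-sweep; parameter-recovery tests sweep 0 to 0.30 and verify the
measured adjacent fraction tracks the truth-label fraction plus
background. `simulate_ligation_library()` disables the mechanism and is
the negative control. Reads are emitted error-free; sequencing error is
outside the mechanism, though `write_read_pairs_sam()` can plant deletion
CIGARs to exercise gapped-read accounting.

What the simulator does *not* emulate — PCR duplication, GC amplification
bias, mappability, repeat structure, correlated tract clustering (runs
are planted independently and uniformly) — bounds what passing tests
show: they validate the measurement and filtering machinery against a
clean rendition of the priming mechanism, not performance on any
particular real genome. One visible consequence of the clean rendition:
off-target fold-ratio bins in a biased simulated library reflect
small-number coincidences among the few hundred distinct priming loci
rather than a smooth background.

## Numerical and scale choices

Property tests run the exact scanner against its oracle on 1,000 random
10 kb sequences, the tolerant scanner on 400 bp sequences (its oracle is
quadratic), the null-behavior check on a 1M-fragment ligation library
over a 1 Mb genome, and the parameter-recovery sweep at 200,000 fragments
per level — sizes at which the binomial standard errors are a few times
smaller than the effects being asserted, chosen from power calculations
recorded in the tests. Fold-ratio assertions in the null check are
restricted to strata with at least 3,000 counts per strand
(`sd(log ratio) ≈ sqrt(2/count)`, so ±10% is a 3.8σ statement there);
sparser strata — all C/G strata under the 100:1 census — carry no power
at that tolerance and are reported but not asserted. The acceptance
script (`scripts/acceptance.R`) reruns the full pipeline at these scales
and writes the headline numbers as JSON.

## Known limitations

* The MAPQ proxy for unique mapping is aligner-dependent; with aligners
  that do not deflate multi-mapper MAPQ, pre-filter the BAM.
* The tolerant-tract dialect (merged qualifying windows) is one of
  several reasonable readings of mismatch-tolerant pattern matching;
  it is defined by the coverage predicate the downstream filter needs.
* The per-coordinate `>100` cap treats "genomic location" as one base
  pair; a windowed variant would need the cap re-calibrated.
* RNA-seq internal priming at poly(A) is mechanistically analogous but
  not modeled; the simulator is DNA-mode only.
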