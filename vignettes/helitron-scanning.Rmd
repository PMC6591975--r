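---
title: "Structural Helitron scanning and density analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural Helitron scanning and density analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helscan)
```

## The model: what counts as a Helitron candidate

Helitrons are Class II DNA transposons that move by rolling-circle
replication. They carry no terminal inverted repeats, so homology-free
detection has to rely on their short conserved structural signature:

* a 5' terminus beginning `TC`,
* a 3' terminus ending in `CTRR` (almost always `CTAG`),
* a GC-rich palindromic hairpin a few bases upstream of the 3' terminus,
  believed to act as the transposition stop signal,
* a preference for insertion into `AT` target sites, so that the element is
  typically flanked by `A...T`.

`scan_genome()` searches both strands of every input sequence for this
signature. A candidate is anchored on the 3' terminal motif; the hairpin
must end 2--10 nt before it, and candidate 5' `TC` starts are collected up
to 20 kb upstream. The 3' terminus is the unit that is counted: 5' ends are
poorly conserved and one 3' end can pair with several 5' ends, so element
counts and all density statistics are defined on distinct 3' termini.

### Hairpin definition

The literature says "GC-rich hairpin" without a printed grammar, so the arm
definition is an explicit, configurable decision of this package:

* arm length 6--20 nt (`arm_min`, `arm_max`),
* the arm begins and ends with G or C and contains at least
  `ceiling(gc_min * length)` G/C bases (`gc_min = 0.8`),
* the right arm is the *exact* reverse complement of the left arm
  (no mismatches),
* loop of at most 10 nt between the arms (`loop_max`),
* 2--10 nt spacer between the right arm and the terminal motif
  (`spacer_min`, `spacer_max`).

These defaults bracket the classical description of a 16--20 nt hairpin
sitting 10--15 nt upstream of the 3' end. Any window containing `N` never
matches; input is upper-cased before scanning.

### Motif stringency (fuzzy levels)

The terminal motif is matched at one of four nested stringency levels:
level 0 `CTAGT` (the motif plus the target-site T), level 1 `CTAG` (the
default), level 2 `CTRR`, level 3 `CT..`. The levels are nested by
construction, so the candidate set at a stricter level is always a subset
of the set at a looser level. To keep that property exact, `end3_pos` is
always the last base of the four-base `CTRR` core; the trailing T at
level 0 is treated as a constraint on the flanking base, not as part of the
terminus coordinate.

### Resolution of ambiguous matches

Several hairpins can license the same motif and several arm lengths can fit
at one locus. The scan is deterministic: for each motif occurrence the
smallest spacer wins, then the longest arm, then the shortest loop, and at
most one candidate is kept per distinct (sequence, strand, 3' end
position). The standalone `find_hairpins()` uses the same greedy rule
anchored on the left arm and reports only maximal stems. The unit tests
compare the scanner against a brute-force enumerator of every (arm length,
arm start, loop, spacer) combination on seeded sequences up to 2 kb, so
the greedy search provably returns the same candidate set as exhaustive
enumeration under these tie-breaks.

The target-site preference (`A` before the 5' `TC`, `T` after the 3'
motif) is biology, not grammar: by default it is only *reported*
(`target_site_ok`), not filtered on (`target_site_filter = FALSE`).

## Helitron density as a genome characteristic

Density is the number of distinct 3' termini divided by genome size in Mb,
with all bases (including `N`) counted in the size. It is stable within a
species while genome size and raw counts fluctuate between assemblies,
which motivates two downstream analyses:

* `lda_classify()` -- classical linear discriminant analysis on the two
  features (genome size, density) with pooled within-class covariance and
  class-proportional priors (the default of the underlying `MASS::lda()`
  fit; the source tables do not state priors, so the default is documented
  here as a choice). On the shipped 36-row feature table, training on the
  34 labelled genomes and predicting all 36 rows (self-prediction plus two
  de novo drafts) classifies every row correctly.
* `median_cluster()` -- median-linkage (WPGMC) agglomeration on the same
  features, for dendrograms of related genomes.

`dispersion()` reports mean, SD and CV. It uses the sample (n-1) divisor
by default. The published dispersion figures for these tables are
internally inconsistent: the density pairs match the sample divisor, while
the 18-ecotype count SD (27.7) matches the population divisor (the sample
value is 28.5). The package standardizes on the sample divisor and exposes
`population = TRUE` for reproducing the population-divisor figures.

`pearson_bootstrap()` wraps `cor.test()` and a seeded `boot` resampling
(1000 replicates, seed 1234 by default) with a BCa interval. The source
analyses do not define their bootstrap p value; here it is twice the
smaller tail fraction of resampled r values at or across zero, capped at
one. The point estimate is the closed-form product-moment r regardless of
the seed.

`sliding_windows()` tiles each sequence with 1 Mb windows advancing by
500 kb (the last partial window is retained) and counts Helitron 3' termini
and gene starts per window. Membership is by representative point (3' end
position and gene start respectively), the simplest reading of local
density; windows overlap, so a feature can appear in up to `window/step`
windows.

## Insertion typing and locus markers

`classify_insertions()` places each candidate's 3' end against gene
annotation into `CDS`, `intron/UTR` (inside a gene span but outside CDS)
or `intergenic`; genes on either strand count, and the three categories
partition the candidates. The representative point is the 3' terminus
because it is the conserved, well-defined end of the element; full-span
overlap would require trusting the predicted 5' end, which is exactly the
unreliable part. `chisq_insertion_test()` compares category counts against
the genomic fraction of each category.

`nearest_downstream_gene()` derives cross-assembly locus (LOC) markers:
the first gene starting at or after the 3' end on the forward strand
within a configurable distance (default 500 bp). The original marker
derivation aligned 500 bp of downstream sequence against a reference CDS
set; on assembled genomes with annotation, the coordinate-based rule
preserves the marker semantics without an aligner, and the distance bound
plays the role of the alignment span. `build_loc_matrix()` then forms the
union of markers over ecotypes, assigns `LOC` ids in sorted gene-id order
and flags polymorphic loci (neither all-present nor all-absent).

## Association rules

`mine_rules()` relates locus presence/absence to a categorical phenotype
(here flowering time). Absence items (`LOC=0`) are materialized explicitly
so both states are minable. Antecedents of one or two locus items are
enumerated exhaustively (maxlen 3 counting the consequent), and a rule
passes only when support, confidence and lift all *strictly* exceed their
thresholds (defaults 0.1, 0.8, 1.1 -- printed as strict inequalities in
the source protocol). With 18 ecotypes split 5 late / 13 intermediate, a
locus carried by three ecotypes, all late, yields
support 3/18 = 0.1667, confidence 1 and lift 18/5 = 3.6; a locus carried
by 16 ecotypes of which 13 are intermediate yields confidence 0.8125 and
lift 1.125. `paired_rules()` extracts loci whose presence *and* absence
rules both pass. The miner is verified against a direct-counting oracle on
every fixture up to 20 transactions x 30 loci.

## Random genomes and the false-positive rate

`estimate_fpr()` draws i.i.d. genomes at a measured base composition
(`composition_spec()` normalizes published frequency vectors that sum to
slightly less than one because they were measured over an assembly
containing `N`), scans them, and reports
`100 * mean(candidate count) / reference_count`. Structure found in random
sequence cannot be a real element, so the yield relative to the real-genome
count estimates the false-call fraction. "Shuffling" is implemented as
i.i.d. sampling at the measured frequencies rather than a permutation of
the actual bases -- with mononucleotide frequencies fixed, the two are
equivalent for this purpose.

The reference conditions are the measured composition
A:T:G:C = 0.319414:0.319033:0.179905:0.180095 at 119,667,750 bp with
reference count 665. The acceptance runs use three full-length genomes
(per-genome counts are Poisson-like with mean well above 30, so three
replicates already give a relative standard error under 10%). Under this
package's hairpin grammar the estimate is ~11--12%, about twice the
originally reported 5.91%. The discrepancy is expected: the original
scanner's exact regular expression (arm-length bounds, GC threshold,
allowed mismatches) was never published, and the false-positive yield on
random sequence is extremely sensitive to it -- a back-of-envelope
calculation with this package's arm rule predicts ~85 chance hits per
genome before deduplication, matching what is observed, while the original
figure corresponds to ~39. The grammar here follows the documented
structural description rather than reverse-engineering a stricter
unpublished pattern, and the measured rate is reported as-is.

## What the synthetic data does and does not show

`make_planted_genome()` plants canonical cassettes
`A|TC ... [arm][loop][rc-arm](spacer)CTAG|T` into an A/T-only background.
Such a background cannot form hairpin arms or terminal motifs by chance,
so recovery must be exact (precision = recall = 1) and every planted
coordinate is checked field by field; the filler base immediately before
the arm is forced to `A` so the planted 5' end is the unique nearest `TC`.
This validates the scanner's bookkeeping, not its specificity on real
chromatin: real genomes contain GC-rich repeats, N runs and nested
elements that the generator deliberately does not emulate (no TE families,
no nesting). Specificity is instead characterized by the random-genome
false-positive harness, and sensitivity on real data ultimately depends on
the hairpin grammar discussed above.

`make_ecotype_matrix()` reproduces requested phenotype margins and planted
carrier patterns exactly, so rule metrics are arithmetic consequences of
the construction -- useful for verifying the miner, silent on biological
effect sizes.

## Numerical and engineering notes

* Coordinates are 0-based half-open internally (C++ core) and 1-based
  inclusive on the forward strand everywhere user-facing, including GFF3.
* Reverse-strand candidates report forward-strand coordinates; `hp_left_*`
  / `hp_right_*` always refer to the scanned-strand left/right arm.
* `ceiling(gc_min * L)` is evaluated with a 1e-9 guard against binary
  floating-point artifacts (so 80% of 5 is 4, not 5).
* Scanning is embarrassingly parallel over records (`worker_count`), with
  per-record results concatenated in input order, so output is
  byte-identical for any worker count.
* Problem sizes in the test-suite: oracle comparisons on sequences up to
  2 kb; planted genomes of 10--60 kb; three full-length (119.67 Mb) random
  genomes for the false-positive estimate, which take on the order of half
  a minute each on one core.
* Degenerate inputs: empty record sets, all-`N` records, constant vectors
  in correlations, single-class training sets and infeasible planted
  patterns all raise early, specific errors.
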