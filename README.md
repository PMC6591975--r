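# helscan

Structural annotation of **Helitron** transposons in nucleotide sequences,
plus the genome-level analytics that treat Helitron density as a genome
characteristic. It is aimed at plant (and general eukaryotic) genomics work
where Helitrons must be located without a repeat library: de novo
assemblies, ecotype panels, comparative studies across related species.

Helitrons transpose by rolling-circle replication and lack terminal
inverted repeats, so they are found from their conserved structure rather
than by homology: a 5′-`TC` start, a 3′-`CTRR` (mostly `CTAG`) end, and a
GC-rich palindromic hairpin 2–10 nt upstream of the 3′ end. `helscan`
scans both strands of whole-genome FASTA for

```
5'-A | TC ....... [arm] (loop) [rc-arm] (spacer 2-10 nt) CTAG | T-3'
        <= 20 kb   6-20 nt, >= 80% G/C, exact reverse-complement arms
```

anchoring each candidate on the 3′ terminal motif (one candidate per
distinct 3′ end and strand), and writes 3′-end, 5′-end and full-length
FASTA plus GFF3. Counting is done on 3′ termini because 5′ ends are
multiple and poorly conserved; **Helitron density** is

```
density (HM^-1) = number of distinct 3' termini / genome size in Mb
```

On top of the scanner the package implements: density dispersion
statistics, seeded bootstrap Pearson correlation (BCa intervals),
1 Mb / 500 kb sliding-window densities, linear discriminant classification
of genomes from (size, density), median-linkage clustering, insertion-site
typing against gene annotation (CDS / intron-UTR / intergenic) with a
chi-square non-randomness test, composition-matched random-genome
false-positive estimation, nearest-downstream-gene locus (LOC) markers,
and apriori-style association-rule mining of locus presence/absence
against a categorical phenotype.

## Worked example

Plant three canonical cassettes into a synthetic A/T background, scan, and
summarize:

```r
library(helscan)
g <- make_planted_genome(n_cassettes = 3, background_length = 12000,
                         strands = c("+", "-"), seed = 7)
cand <- scan_genome(g$records)
print(cand)
#> Helitron candidates: 3 termini on 1 sequence(s) (+: 2, -: 1)
#>         id seqid strand end3_pos end3_motif loop_len n_five_prime
#> 1   chr1H1  chr1      +     2166       CTAG        4            1
#> 2 trchr1H1  chr1      -     4138       CTAG        4            2
#> 3   chr1H2  chr1      +    10661       CTAG        4            3
helitron_summary(cand, g$records, genome = "planted")
#>    genome n_sequences total_bases n_helitrons density
#> 1 planted           1       12000           3     250
```

All three planted termini are recovered, with ids `<seqid>H<k>` on the
forward strand and `tr<seqid>H<k>` on the reverse strand; the density is
3 elements / 0.012 Mb = 250 HM⁻¹. `write_helitron_outputs(cand, g$records,
"out")` would write `out.3.txt`, `out.5.fa`, `out.full.fa` and `out.gff3`.

Classify genomes by species group from (genome size, density) using the
shipped 36-row feature table (34 training genomes from seven species
groups plus two de novo A. thaliana drafts):

```r
feat <- genome_feature_table()
fit <- lda_classify(feat[feat$role == "train", ], newdata = feat)
sum(fit$class == feat$group)
#> 36        # all 36 rows correct, including both de novo drafts
```

Mine flowering-time association rules from an ecotype panel with the
published phenotype margins (5 late / 13 intermediate):

```r
m <- make_ecotype_matrix(c(late = 5, intermediate = 13),
       planted = list(list(name = "LOC384", n = 3, class = "late", state = 1)))
head(mine_rules(m$transactions), 2)
#>   antecedent      consequent   support confidence lift
#> 1   LOC384=1         FT=late 0.1666667  1.0000000  3.6
#> 2   LOC384=0 FT=intermediate 0.7222222  0.8666667  1.2
```

A locus carried by three ecotypes, all late-flowering, gives
support 3/18, confidence 1 and lift 18/5 = 3.6 toward the late class;
its absence side passes toward the intermediate class, making it a
"paired" locus (`paired_rules()`).

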