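# mitocode

Comparative analysis of annotated insect mitochondrial genomes, built around
one question: **what does a codon mean in each taxon?** Insect mitogenomes
occasionally reassign codons — the flagship case being AGG, serine under the
invertebrate mitochondrial code but decoded as lysine in several true-bug
lineages, in step with point mutations at the wobble position of tRNA-Lys
(CUU → UUU) and tRNA-Ser(AGN) (GCU → UCU). `mitocode` implements the full
comparative workflow around that inference for anyone studying
mitochondrial genome evolution: genome I/O, composition statistics,
codon-meaning prediction, anticodon analysis, and control-region repeat
architecture, plus a synthetic-genome simulator that makes every stage
testable without downloading data.

## The core method

For a target codon *c* and focal taxon *t*, the predictor asks what the
other taxa write at the alignment positions where *t* writes *c*:

1. translate each protein-coding gene under the baseline invertebrate
   mitochondrial code and build a codon-aware multiple alignment
   (progressive profile alignment with BLOSUM62; or supply your own aligned
   FASTA);
2. keep columns with occupancy ≥ 0.8 and top amino-acid fraction ≥ 0.5
   among non-target cells (target cells never vote on their own meaning);
3. for every occurrence of *c* in *t*, tally the other taxa's amino acids at
   that column (cells equal to *c* excluded, breaking circularity between
   taxa sharing a reassignment); call the occurrence by majority if the
   majority fraction ≥ 0.5 and ≥ 3 taxa are informative, else `?`;
4. the taxon-level call is the majority over occurrences — `UNPREDICTED` on
   ties or all-ambiguous evidence, `UNUSED` if the codon never occurs.

The anticodon side is handled independently: anticodons are read from
annotation or located structurally, decoded under wobble rules
(`CUU → AAG`, `UUU → AAA,AAG`, `GCU → AGC,AGU`, `UCU → AGA,AGG`), and the
2×2 association between anticodon state and inferred meaning is tested with
a two-sided Fisher exact test.

## Worked example

Simulate a 12-taxon genome set (one clade translating AGG as Ser with the
mutated anticodons, three clades as Lys with the typical ones) and run the
whole pipeline:

```r
library(mitocode)
sim    <- simulate_mitogenomes(sim_config(seed = 1))
report <- run_pipeline(run_config(sim$genomes, dmttf_reference = "TACTAAA"))

head(report$assignments, 6)
#>   taxon codon n_occurrences predicted support
#> 1    A1   AGG             5         S       1
#> 2    A2   AGG             5         S       1
#> 3    A3   AGG             5         S       1
#> 4    B1   AGG             5         K       1
#> 5    B2   AGG             5         K       1
#> 6    B3   AGG             5         K       1
```

Every planted AGG = Ser / AGG = Lys state is recovered, each backed by 5
codon occurrences with unanimous support. The anticodon table shows the
correlated tRNA states, and the association test quantifies it:

```r
report$association[["tRNA-Ser(S1)"]]
#>          predicted
#> anticodon S K
#>       GCU 0 9
#>       UCU 3 0
#> two-sided Fisher exact p = 0.004545
```

Control-region tandem repeats are annotated per genome; here the planted
60 bp × 11 (+58 bp partial) and 24 bp × 6 (+20 bp partial) arrays:

```r
report$cr_architecture[["A1"]]$repeats[, 1:5]
#>   start unit_length full_copies partial_length span
#> 1    80          60          11             58  718
#> 2   878          24           6             20  164
```

After masking the repeats, control regions are ~96% identical within a
clade and far less similar between clades — the intra- versus inter-genus
contrast seen in real plant-bug control regions.

On real data, pass GenBank flat-file paths instead of simulated genomes:
`run_pipeline(run_config(c("NC_022677.gb", ...)))`. `write_report(report, dir)`
emits the TSV tables (`composition.tsv`, `codon_usage.tsv`,
`agg_assignments.tsv`, `anticodons.tsv`, `ncr_census.tsv`,
`cr_architecture.tsv`, `identity.tsv`) plus a provenance block, and
`annotate_tree()` writes predictions onto the tips of a user-supplied tree.
A thin CLI wrapping the same functions lives at
`system.file("cli", "mitocode.R", package = "mitocode")` with verbs
`simulate`, `run`, `codons`, `repeats`, `report`.

## Documentation

The methods vignette (`vignettes/codon-reassignment.Rmd`) describes the
model and its assumptions, all tunable thresholds with their defaults and
rationale, what the simulator does and does not emulate, and known
limitations.
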