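---
title: "Inferring mitochondrial codon reassignments from conserved alignment columns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring mitochondrial codon reassignments from conserved alignment columns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocode)
```

## The problem

Insect mitochondrial genomes are compact (about 15-17 kb), AT-rich, and
usually carry the same 37 genes in the ancestral arrangement: 13
protein-coding genes (PCGs), 22 tRNAs, two rRNAs, and one major non-coding
control region (CR) between `srRNA` and `tRNA-Ile`. Although the
invertebrate mitochondrial genetic code is broadly stable, a handful of
codons have been reassigned repeatedly across arthropod lineages. The case
this package is built around is AGG: under the invertebrate mitochondrial
code AGG encodes serine (the AGN family), but in several heteropteran
lineages it is decoded as lysine instead. The switch is mirrored by point
mutations at the wobble position of two tRNAs: the lysine tRNA (anticodon
CUU vs UUU) and the AGN-serine tRNA (GCU vs UCU).

`mitocode` packages the comparative analyses needed to detect and
characterize such a reassignment in a set of annotated mitogenomes:

1. genome I/O and strand-aware gene extraction (`parse_genbank`,
   `parse_feature_table`, `gene_sequence`, `concatenated_pcgs`);
2. composition statistics (`skews`, `gc_by_position`, `garp_fraction`,
   `fit_gc_garp`);
3. the core inference: per-taxon prediction of a target codon's amino-acid
   meaning from conserved alignment columns (`build_codon_alignment`,
   `filter_columns`, `predict_all`);
4. tRNA anticodon extraction, wobble decoding, and a formal test of
   association between anticodon state and inferred meaning
   (`extract_anticodon`, `decoded_codons`, `anticodon_code_association`);
5. non-coding region census and control-region tandem-repeat architecture
   (`noncoding_census`, `locate_control_region`, `find_tandem_repeats`,
   `mask_repeats`, `pairwise_identity`);
6. a synthetic mitogenome generator with planted ground truth
   (`simulate_mitogenomes`) used to validate every stage end to end.

## The codon-meaning predictor

The predictor follows the logic of codon-usage-in-conserved-columns methods
(GenDecoder-style). Intuition: if a taxon writes AGG at alignment positions
where every other taxon writes lysine, AGG means lysine in that taxon.

Given per-taxon CDS sets, each gene is translated under the baseline
invertebrate mitochondrial code and aligned at the amino-acid level by
progressive profile alignment (guide order from k-mer distances; pairwise
global alignment with BLOSUM62 and affine gaps, gap open 10, extension 0.5;
profiles merged through their consensus sequences), then back-translated to
codons. An externally computed codon-aware MSA (aligned FASTA, row width a
multiple of 3) can be supplied instead and is treated identically.

Columns are then filtered on two criteria:

* **occupancy** — the non-gap fraction must be at least `min_occupancy`
  (default 0.8);
* **conservation** — the most frequent amino acid among informative cells
  must reach `min_conservation` (default 0.5). Cells carrying the *target*
  codon are excluded from this calculation entirely (numerator and
  denominator): a column where the focal taxa write AGG is exactly the
  evidence we want to evaluate, and counting those cells would either
  self-filter candidate columns or let the codon vote on its own meaning. A
  column whose informative cells are all target codons has undefined
  conservation and is retained on occupancy alone; downstream it yields an
  ambiguous call rather than a prediction.

For each occurrence of the target codon in the focal taxon, the amino acids
of the other taxa at that column are tallied (again excluding cells that are
themselves the target codon, which avoids circularity between taxa sharing
the reassignment). The occurrence is called as the majority amino acid when
its fraction reaches `majority_threshold` (default 0.5) and at least
`min_informative` taxa (default 3) are informative; otherwise it is `?`. The
taxon-level prediction is the majority over occurrence-level calls:
`UNPREDICTED` when all occurrences are ambiguous or the majority ties, and
`UNUSED` when the taxon never uses the codon. The reported `support` is the
top amino acid's share of the tally aggregated over all occurrences.

Two defaults deserve comment, since the qualitative rule ("highly variable
positions give `?`") leaves them open. "Highly variable" is operationalized
as top-fraction below `majority_threshold` or fewer than `min_informative`
informative taxa. And non-focal taxa are translated under the *baseline*
code in a single pass rather than iterating per-taxon codes to convergence:
the single pass is what the tabulated worked examples of this method show,
it is order-independent, and on data with a clear signal iteration changes
nothing; all thresholds are exposed as arguments.

Ties at any level yield `UNPREDICTED`, never an arbitrary pick, and raising
`majority_threshold` can only move calls toward `UNPREDICTED` on
well-behaved data (checked as a property test).

## Anticodons and wobble decoding

Anticodons are stored in standard 5'-to-3' notation (CUU for the lysine tRNA
that reads AAG). When the annotation carries an anticodon offset it is used
directly; otherwise a structural heuristic finds the best-pairing 5-bp stem
closing a 7-nt loop (Watson-Crick plus G-U pairs, at least 3 of 5 required,
ties broken toward the sequence midpoint) and takes loop positions 3-5. The
heuristic also reports whether a second stem-loop exists 5' of the anticodon
arm, a crude proxy for DHU-arm presence.

Wobble decoding maps anticodon positions 35-36 to codon positions 1-2 by
reverse complement and expands the third codon position by the wobble rules
`G -> {C,U}`, `U -> {A,G}`, `C -> {G}`, `A -> {U}` (overridable). These
defaults reproduce the textbook decodings relevant here: CUU reads AAG, UUU
reads AAA+AAG, GCU reads AGC+AGU, UCU reads AGA+AGG — which is precisely why
the UCU mutation of the AGN-serine tRNA tracks AGG = Ser and the UUU
mutation of the lysine tRNA tracks AGG = Lys. A separate helper,
`decoding_coverage`, checks that a full 22-anticodon set reads all 62 sense
codons without conflicts; it additionally models the modified-wobble
extensions known from mitochondria (a sole U34 tRNA reading a whole
fourfold-degenerate box; modified C34/G34 reading the A-ending codon of its
two-codon set), which the plain per-anticodon rules deliberately do not.

The association between anticodon state and inferred meaning is summarized
as a 2x2 table (taxa with `UNUSED`/`UNPREDICTED` are excluded, since a taxon
that never uses the codon is uninformative about its meaning) with a
two-sided Fisher exact probability. The formal test is this package's
addition; the original observation was qualitative.

## Non-coding regions and repeat architecture

`noncoding_census` reports every inter-feature gap of at least 1 bp on the
circular genome; overlapping annotations are logged separately, never
counted as non-coding. The control region is the annotated one when present,
otherwise the srRNA-to-tRNA-Ile gap in circular order.

`find_tandem_repeats` is a seed-and-extend detector over candidate unit
lengths (default 10-300 bp, bracketing the units reported for insect control
regions; tolerance `max_mismatch` default 0.1; at least 2 full copies). For
each period p it computes the lag-p self-match vector; exact runs seed
candidate arrays, and a candidate absorbs an adjacent mismatch gap together
with the exact run beyond it only when the pair locally satisfies the
tolerance (gap/(gap+run) and gap/p both at most `max_mismatch`). Arrays
therefore always end on exact self-matches: the detector bridges occasional
substitutions inside degraded copies but cannot spend the budget of a long
exact core on unrelated flanking sequence, and exact arrays are recovered
with exact boundaries. Overlapping candidates from different periods are
resolved greedily by descending span, then ascending unit length, then
position — so a 60-bp array is reported once at period 60, not again at 120.
The trailing partial copy is reported as `partial_length`; masking removes
arrays outright (zero copies retained, matching the "repeats removed"
convention; `retain_one = TRUE` keeps one unit for sensitivity analyses).

Pairwise identity uses Needleman-Wunsch alignment (match +1, mismatch -1,
gap open -2, gap extend -1) with identity = matches / aligned columns, gap
columns included; the gap-excluded convention is available via
`gap_columns = "exclude"` since published identity values rarely state
their convention. Because co-optimal alignments can differ in realized match
counts, the aligned pair is put into a canonical orientation and order
first, which makes the result symmetric and invariant under joint reverse
complement. Multi-sequence summaries (`mean_pairwise_identity`) are the mean
of all pairwise identities — a deliberate simplification over building a
nucleotide-level multiple alignment for one summary number; the matrix of
pairwise values is returned alongside.

The termination-factor site search (`dmttf_search`) is a local alignment of
a user-supplied reference (for example the 16-bp D. melanogaster DmTTF
binding site, which must be provided as input) against a non-coding region,
reporting the best window, its offset and percent identity.

## The synthetic generator

`simulate_mitogenomes` emulates the data regime the inference targets, with
planted, machine-readable truth:

* **Coding sequences.** All taxa descend from one AT-biased root (codons
  drawn with per-base weights matching `at_content`, stop codons and the
  target codon excluded) through a two-level clade tree (root to clade
  ancestor to taxon), substituting whole codons with probability
  `subst_rate` (default 0.05) per branch. A `conserved_fraction` (default
  0.6) of amino-acid columns only ever changes synonymously, so these
  columns are invariant at the protein level — exactly the signal the
  predictor uses. AGG codons are planted only at conserved lysine columns in
  AGG = Lys taxa and conserved serine columns in AGG = Ser taxa (5 per taxon
  by default), so each emitted genome translates without internal stops
  under its own code. The generator errs out if the demand exceeds the
  available code-consistent conserved columns.
* **tRNAs.** Fixed 66-nt scaffolds with two planted stem-loops (a DHU-like
  arm and the anticodon arm; all filler is A/C and cannot pair), the
  anticodon substituted at a fixed offset. Only the anticodon matters
  downstream; there is no structural evolution.
* **Control region.** Clade-shared random background (mutated 2 percent per
  taxon) plus exact planted tandem arrays. The flanking bases around each
  array are forced to mismatch the unit's continuation, so every planted
  array is maximal and the detector's coordinates can be compared to truth
  exactly. Defaults plant a 60 bp x 11 + 58 bp partial array and a
  24 bp x 6 + 20 bp partial array, sizes typical of plant-bug control
  regions.
* **Layout.** Ancestral insect gene order on both strands, with two small
  planted non-coding gaps: 2 bp between `tRNA-Pro` and `ND6` and a fixed
  7-bp motif between `tRNA-Ser(S2)` and `ND1` standing in for the conserved
  termination-factor site at that strand switch point.

Default scale: 12 taxa in four clades of three (within the 9-22 taxon range
of the comparative studies this mirrors), 13 PCGs totalling 11.1 kb at
realistic per-gene lengths, whole genomes around 15.7 kb. One clade is
AGG = Ser with the mutated anticodons (UUU/UCU); the other three are
AGG = Lys with the typical ones (CUU/GCU). A fixed seed gives byte-identical
output.

What the generator does **not** emulate: indels in coding sequence (the
aligner is exercised on explicit indel cases instead), rate heterogeneity
and realistic phylogenetic branch lengths, tRNA/rRNA sequence evolution,
degraded repeat copies, and composition heterogeneity along the genome.
Passing the recovery suites therefore demonstrates correctness of the
inference machinery under clean, well-posed conditions — not robustness to
every pathology of real data. The real-data checks are tied to the
published GenBank accessions, which must be fetched separately.

## Numerical and design notes

* Coordinates are 0-based half-open internally, 1-based inclusive in all
  files; `+` is the J-strand and all skews are computed on it. Features with
  `end` beyond the genome length wrap the origin (modulo length).
* N bases count toward lengths but are excluded from composition
  denominators; an undefined skew (A+T = 0 or G+C = 0) is `NA` with a
  warning, never silently 0.
* G+C and GARP percentages for the regression are computed on the same
  concatenated PCG set, with terminal stop codons stripped first.
* Degenerate 2x2 margins (all taxa sharing one anticodon) give Fisher
  p = 1 by convention.
* Reported TSVs round to 2 decimals; full precision is kept in the report
  object. All stages are deterministic given inputs and configuration.
* Problem sizes in the validation suites — 20 replicates of the default
  12-taxon configuration for code recovery, 264 tRNA extractions, 24 planted
  arrays, oracle sweeps over strings up to 60 bp and tables up to n = 12 —
  were chosen as the smallest sets that exercise every code path with
  non-trivial multiplicity.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_mitogenomes(sim_config(seed = 1))
report <- run_pipeline(run_config(sim$genomes, dmttf_reference = "TACTAAA"))
head(report$assignments)
report$association[["tRNA-Ser(S1)"]]
write_report(report, "mitocode-report")
```

On real data, replace `sim$genomes` with a character vector of GenBank flat
file paths. The same stages can be driven from a shell through the thin CLI
at `system.file("cli", "mitocode.R", package = "mitocode")` (verbs
`simulate`, `run`, `codons`, `repeats`, `report`).

## Known limitations

* The internal aligner is a consensus-based progressive profile aligner,
  adequate for the high-identity mitochondrial proteins it is used on, but
  not a substitute for a production MSA tool on divergent data; external
  alignments are first-class inputs for that reason.
* The anticodon heuristic assumes a recognizable 5-bp anticodon stem; tRNAs
  with heavily eroded arms need annotated offsets.
* The repeat detector reports arrays with units between `min_unit` and
  `max_unit` only, and its conservative boundary rule truncates copies whose
  edges are themselves degraded.
* Codon-meaning predictions are only as good as the alignment columns
  backing them; taxa with very low target-codon usage legitimately come out
  `UNPREDICTED` rather than being forced to a call.
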