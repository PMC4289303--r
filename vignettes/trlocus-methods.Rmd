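---
title: "Methods: rules, models and simulation design in trlocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rules, models and simulation design in trlocus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trlocus)
```

`trlocus` analyses the evolution of TRA/TRD locus V-gene repertoires:
which germline V genes are functionally competent, how they cluster into
subgroups, how the locus expanded by duplication of multi-gene "homology
units", and how the expressed TRA/TRD repertoires relate to the genomic
catalog. This vignette documents the rules, models, parameter choices and
known limitations; the README shows the corresponding worked example.

## Functional competence rules

A V gene contributes to the expressed repertoire only if it can be
transcribed, spliced, translated into a V domain with an intact framework,
and recombined by the RAG machinery. The classifier therefore checks, per
gene:

1. **Splice sites** — the intron between the leader exon and the V exon
   must begin `GT` and end `AG` (coding orientation). Violations are
   `splice_donor_mut` / `splice_acceptor_mut` lesions.
2. **Open reading frame** — the leader and V exons are spliced in silico
   and translated in frame 0 from the initiator. A V-exon length that
   differs from the subgroup reference length by a non-multiple of 3 is a
   `frameshift` (checked against the reference rather than by de novo ORF
   search, because duplicated pseudogene copies typically share one
   ancestral indel); otherwise any internal stop codon is a
   `premature_stop` with its codon index.
3. **Conserved anchors** — the V domain must carry cysteine, tryptophan
   and cysteine at IMGT unique-numbering positions 23, 41 and 104. IMGT
   positions are mapped onto the candidate translation by global alignment
   (BLOSUM62, gap open 10 / extend 0.5) against a per-subgroup reference
   peptide whose anchor indices are known; positions falling on an
   alignment gap are reported as "unalignable" anchor lesions. Without a
   reference the positional map `leader_codons + position` is used.
4. **Recombination signal** — the RS must have a heptamer starting with
   the invariant `CAC` and matching the `CACAGTG` consensus at ≥5/7
   positions, a nonamer matching `ACAAAAACC` at ≥6/9 positions, and a
   spacer within ±1 bp of the expected 23 (V) or 12 (J). The literature
   defers RS quality to recombination-efficiency studies without giving a
   desk-checkable rule; these thresholds are explicit, configurable
   defaults chosen so that the invariant `CAC` is mandatory while common
   neutral spacer-length and margin polymorphisms pass.
5. **Location** — genes mapping neither to the locus chromosome nor to an
   unassigned contig receive an `unmapped_location` lesion.

Status aggregation: any missing part sequence makes the gene
**incomplete** (competence not assessable — this outranks pseudogene, so a
truncated gene with a visible lesion still counts as incomplete); any
lesion makes it a **pseudogene**; otherwise it is **functional**. J genes
are functional when the coding region translates with the canonical FGxG
motif, the 12-RS is valid and the 3′ splice donor is `GT`.

One open point is deliberately conservative: any leader-ORF disruption
(initiator loss, leader stop) is counted as a lesion, since the published
accounting does not separate leader-only defects.

`summarize_catalog()` reports per-subgroup totals with percent functional
computed over **all** genes of the subgroup, incomplete included — the
denominator convention implied by a totals row in which 215 functional of
371 total genes gives 58.0%.

## Subgroups and orthology naming

Pairwise nucleotide identity is computed per pair by deterministic global
alignment (match +1, mismatch −1, gap open −4, extend −1) followed by
p-distance with pairwise deletion, rather than through one multiple
alignment: pairwise alignment is self-contained, order-independent and
reproducible. Subgroups are the connected components of the ≥75% identity
graph. Because the 75% convention is not transitive, the clustering
reports diagnostics instead of adjudicating: within-cluster pairs joined
through intermediates that fall below the threshold (observed down to
~68% in heavily expanded subgroups) and cross-cluster pairs within two
points of it.

Clusters inherit a reference subgroup name when mean identity to that
reference subgroup is maximal, at least 0.631 (the lower end of
identities observed between orthologous subgroup pairs across species;
configurable), and — when a joint tree is supplied — the cluster is
monophyletic with that reference. Conflicting claims resolve to the higher
mean identity; everything else receives alphabetic designations issued in
genomic order of the cluster's first member, which makes naming
deterministic.

## Phylogenetics

Trees are built by neighbour-joining on uncorrected p-distances, the
standard choice for large sets of short, closely related sequences;
model-based distances are deliberately out of scope. NJ is exact on
additive matrices — the suite verifies this against an exhaustive
least-squares oracle over all unrooted topologies at small leaf counts and
against the generating tree up to 12 leaves. Negative branch-length
estimates are clamped to zero for display with raw values retained
(`raw.edge.length`). NJ is undefined for two taxa; the single edge is
split equally by convention. UPGMA and an OLS minimum-evolution builder
(NJ followed by nearest-neighbour interchanges) sit behind the same
interface as robustness checks.

Bootstrap support resamples alignment columns with replacement, rebuilds
the tree per replicate, and reports the percentage of replicates
containing each original bipartition; a fixed seed gives identical
supports. Rooting places the root at the midpoint of the outgroup's
pendant edge, which preserves all leaf-to-leaf path lengths.
Phylogenetic groups are defined by user-supplied anchor leaves — each
group is the smallest rooted clade containing its anchors — because the
four canonical V-gene groups are defined by tree topology, not by any
formula; overlapping anchor clades are a structured error rather than a
silent choice.

## Homology units

Repeat detection operates on subgroup labels in genomic order (the
field's motif notation), not on gene ids, and ignores strand for matching
while recording it. All maximal repeated label subsequences with at least
two greedily resolved, non-overlapping occurrences are candidate motifs.
Two array-specific reductions follow: periodic composites (a short motif
repeated whole) are reduced to their period, and "array windows" —
motifs readable at some phase from the tandem repetition of a shorter
candidate, such as `B-A` or `A-B-A` inside an `A-B` array — are dropped.
A tandem array of seven `V2-V3` copies therefore yields the two-gene unit
with seven replicons rather than a zoo of self-overlapping composites.
Surviving motifs claim token positions longest first (then by instance
count, then lexicographically). Two recovery passes then pick up variant
replicons: unclaimed token runs are aligned against each unit consensus
and absorbed when within `merge_edit_distance` (default 2) label edits of
it, and the instances of each unit co-extend outward in lock-step while
at least two of them agree on the next gene label, skipping over up to
`merge_edit_distance` copy-specific inserted genes. The co-extension is
what reconstructs the full-length unit when exact repeat finding only
sees the core shared by two copies that differ by an inserted gene;
together the passes recover copies carrying post-duplication gains or
losses.
Per-replicon alignment to the consensus produces missing/extra-gene
calls; terminal gaps flag `variable_content` (differing 5′/3′ extent of
duplication), internal gaps flag `post_replication_indel`.

The dotplot profiler (exact k-mer seeds chained along diagonals, both
strands) is confirmatory evidence for unit boundaries; units are defined
by gene-order motifs alone.

Composite units assembled from fragmentary copies across contig breaks are
merged only through the edit-distance rule; fragments beyond that distance
are reported separately rather than stitched by ad hoc rules.

## Expressed-repertoire matching

Each expressed V segment is globally aligned to every catalog V-REGION;
the best hit is the maximum percent identity with ties broken by genomic
order. Categories: **identical** requires 100%; **allelic_or_unassembled**
is ≥97.0% and <100% (the middle class is not capped at the highest
observed non-identical value, which is an observation, not a rule); and
**novel** is <97.0%, the conventional cross-species threshold for calling
products of distinct germline V genes. Exactly 97.0% lands in the middle
class so the boundary is deterministic. Trichotomy counting deduplicates
to unique V-segment nucleotide sequences first. Usage frequencies are
computed over productive transcripts per chain, with novel transcripts
taking their best hit's subgroup; representation bias calls a subgroup
over-/under-represented at expressed:genomic ratios ≥2 / ≤0.5
(configurable — the published analyses state the calls without a numeric
rule). Dual-usage subgroups are those with at least one productive
transcript in both chains.

## The simulator: what it emulates, and what it does not

`simulate_locus()` generates the statistical structure the analysis
assumes, with complete ground truth:

- **Subgroup templates.** Each subgroup label seeds a deterministic
  template: 16 leader codons, an 87 bp `GT..AG` intron, a 312 bp V exon
  (104 IMGT codons) with the C23/W41/C104 anchors, and a consensus
  heptamer–23 bp spacer–nonamer RS. Templates of the same subgroup differ
  by ~2–4% (two jittered copies stay well inside the 75% convention);
  different subgroups are unrelated random sequences (~35% identity).
  A fresh template always classifies as functional — construction and
  classifier are kept consistent by design.
- **Duplication.** Configured events copy a span of genes in tandem next
  to its source, the mechanism behind alternating-gene arrays; each copy
  accumulates substitutions (uniform over unconstrained sites, 2:1
  transition bias, stop codons repaired) at the configured per-copy rate.
  Inversions and indels outside the lesion menu are not modelled, which
  keeps identity arithmetic exact for tests.
- **Death.** Each duplicated gene is pseudogenized with its subgroup's
  death probability by planting one lesion drawn from the menu
  (premature stop; 1/2/4 bp frameshifting deletion; splice donor/acceptor;
  C23/W41/C104 loss; RS heptamer), or truncated (RS lost, modelling a
  contig break) with a separate probability — heterogeneous death rates
  across subgroups are the signature of birth-and-death evolution the
  pipeline is meant to expose. A small post-duplication deletion
  probability removes whole copied genes, creating the missing-gene
  replicon variants the unit builder must absorb.
- **Transcripts.** Expressed V segments are drawn from functional genes
  with per-chain subgroup usage weights (TRD dominated ~90% by the
  DV1-like subgroup, TRA spread with ~23% and ~11% concentrations, as in
  published usage patterns), with an exact number of substituted sites per
  transcript: none for the identical fraction (39% of non-novel), 1–9 of
  312 sites (0.3–2.9%) for allelic variants, and an 11% novel fraction
  drawn from a hidden gene diverged 3.6–7.9% and excluded from the
  annotation — emulating genes absent from a fragmented assembly.

Default scale is 8 subgroups and ~40 V genes from three duplication
events, plus 12+3 J genes — small enough that the whole suite, including
all-pairs alignments, runs in minutes while every recovery property is
still exercised. The defaults are study conditions, not tuning knobs: the
recovery tests assert exact lesion and category recovery under them.

What passing these tests does **not** show about real data: the simulator
plants one lesion per dead gene (real pseudogenes accumulate several — the
classifier handles combinations, but set-equality recovery is only
asserted for the planted menu), substitutes uniformly (no rate
heterogeneity, gene conversion or recombination hotspots), duplicates only
in tandem, and generates clean annotation coordinates (no assembly gaps
inside genes other than the modelled RS truncation). Real-locus analyses
additionally face fragmented assemblies where homology units must be
pieced together across contigs; the unit builder merges fragments only via
the edit-distance rule and will report such composites as separate units.

## Numerical and degenerate-input choices

- p-distance is undefined with zero comparable sites (error, not `NaN`);
  aligned inputs of unequal length are an error.
- Identity between unaligned sequences of equal length is computed
  site-wise: wherever identity decisions bite (the 75% subgroup and 97%
  transcript thresholds, IMGT anchor mapping of a colinear translation)
  the optimal global alignment of equal-length sequences is gap-free, so
  the site-wise value equals the alignment value at a fraction of the
  cost; unequal lengths always go through the full global alignment.
- All randomness flows from a single seed per entry point; identical
  configuration gives byte-identical FASTA/GFF3/TSV outputs (report
  headers carry the configuration hash and seed).
- Coordinates are 0-based half-open in memory and 1-based inclusive in
  GFF3; the conversion lives in one module. Minus-strand part sequences
  are always handed to analysis code reverse-complemented, so the rules
  never see genomic orientation. Gene parts are encoded in GFF3 as child
  features (`five_prime_leader_exon`, `V_exon`/`J_exon`,
  `recombination_signal`, `splice_donor`) with `Parent` attributes; there
  is no standard type for RS features, so the dialect is documented and
  self-consistent (round-trip tested) rather than borrowed.
- Catalog tie-breaks (equal-identity best hits) resolve by genomic order;
  alphabetic subgroup names issue in genomic order; motif claiming is
  coverage-then-length-then-lexicographic — every tie in the pipeline has
  a documented deterministic rule.

## Bundled count tables

Three plain-text tables transcribed from the published bovine UMD3.1
TRA/TRD annotation (per-subgroup germline counts; unique expressed
sequence trichotomy counts; cross-species functional repertoire sizes) are
bundled so that repertoire accounting — totals row, the 60-member
TRDV1 subgroup, the 35.1/53.9/11.0 trichotomy, the 77.6% unit coverage
and the 2.5× bovine:murine ratio — can be recomputed by the package's own
summary functions without downloading a genome. The per-subgroup table was
reconstructed from the published row percentages and column totals, which
admit a unique consistent solution; its sums are verified in the test
suite.

## Limitations

- Orthology naming needs a reference set aligned into the same sequence
  space; without a joint tree the monophyly condition is vacuous.
- Group assignment requires anchors; there is no formula-based fallback.
- The identity matrix is all-pairs quadratic; for catalogs beyond a few
  hundred genes a banded or seeded pre-filter would be needed.
- Allele-level functionality (distinct functional and non-functional
  alleles of one gene) is out of scope: calls are single-haplotype.
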