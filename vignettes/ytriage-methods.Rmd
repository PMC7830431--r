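---
title: "Methods: triage and annotation of a flow-sorted Y assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triage and annotation of a flow-sorted Y assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and design decisions
behind `ytriage`. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The analytical problem

Flow sorting isolates one chromosome type, but the sorted fraction is never
pure: a sequenced and assembled flow-sorted Y contains autosomal
contaminants, and the Y itself carries a pseudoautosomal region (PAR) that
is near-identical to the X. Annotating such an assembly therefore means
(i) separating male-specific (MSY), pseudoautosomal and contaminant
contigs, (ii) profiling sequence composition, (iii) reconstructing gene
models and copy numbers from testis transcripts, (iv) locating the
pseudoautosomal boundary (PAB), (v) validating relative copy numbers by
qPCR, and (vi) placing the genes in a comparative phylogenetic context.
`ytriage` implements that chain as composable functions over tibbles plus
a one-call pipeline (`run_all()`).

## Triage model

A contig is compared against a female reference whose scaffolds are
class-annotated (`X`, `AUTOSOME`, `UNPLACED`). The decision rule, in
order:

1. `length < length_threshold` (default 8,034 bases, the mean long-read
   length of the assembly the default study emulates) gives `TOO_SHORT`;
   such contigs are never homology-checked. Whether short contigs should
   also be homology-classified is genuinely open; we let the length filter
   short-circuit because it mirrors how a read-length cutoff is applied
   before classification.
2. Hits with identity at or above `min_identity` (default 0.95) are
   unioned per scaffold class; a class whose union covers at least
   `min_coverage` (default 0.25) of the contig passes. Autosome or
   unplaced pass means `AUTOSOMAL_CONTAMINANT`; an X pass means
   `PAR_CANDIDATE`; no pass means `PUTATIVE_MSY`.
3. When both autosome and X pass, contamination wins (removal precedes
   X-assignment in the procedure this mirrors) and the tie is recorded.

Evidence within `near_margin` (0.02) identity of the gate is flagged
`near_threshold` so borderline contigs are visible in reports. Every
report partitions the input bases exactly; this is asserted by tests.

Male-specificity evidence is modeled solely by in-silico PCR against the
male contig set and the female reference: a primer site anneals with at
most `max_mismatch` (2) substitutions and none in its `three_prime_exact`
(5) 3'-terminal bases; convergent site pairs within the size window are
products. At least one male product and none in the female is
`MALE_SPECIFIC`; more than three male products is `AMBIGUOUS` — the
ladder-like pattern repetitive templates produce. The ladder threshold of
3 is a design choice; the phenomenon is real but no canonical count
exists. A contig is *validated MSY* when labeled `PUTATIVE_MSY` and
carrying at least one male-specific marker.

## The alignment engine

All homology in the package flows through one seed-and-extend local
aligner (Rcpp):

- k-mer index of the forward reference strand (default `k = 15`); seeds
  containing `N` are skipped; minus-strand queries are handled by aligning
  the reverse complement of the query.
- Seeds are grouped per target into diagonal clusters (drift <= `band`,
  default 30 bases; clusters split at query gaps > `chain_gap`, 500).
- Each cluster is extended gaplessly along its dominant diagonal with an
  x-drop criterion (default 20), scored matches − mismatches; identity is
  matches over aligned columns and `N` never matches.
- Equal-score hits order deterministically by (target, start).

Gapless extension is a deliberate simplification: the synthetic-data
divergence model is substitution-only (below), so on package data the
gapless optimum equals the full local-alignment optimum, which the test
suite verifies against an independent full-DP aligner
(`Biostrings::pairwiseAlignment`) on instances up to 2 kb (identity within
±0.5 points, interval Jaccard >= 0.9). On real indel-containing data the
engine splits alignments at indels; the coverage-union semantics of triage
make classification robust to such splits, but reported per-hit identities
exclude indel columns rather than counting them as differences.

E-value significance gates of database-search tools are replaced by
identity/length gates (nucleotide default: identity >= 0.80 over >= 100
bases) because this engine does not model extreme-value alignment
statistics. This is a documented divergence from the E-value cutoffs such
analyses conventionally quote.

Spliced transcript-to-contig alignment chains exon-candidate hits by
colinearity (ascending in the transcript; ascending or descending in the
contig for direct/inverted chains; contig gaps <= `max_intron`, default
10 kb). Chains are extracted greedily by matched bases with a small
per-base intron penalty (0.005/base) whose only role is to make exons of
tandem arrays pair with their nearest colinear partner; any penalty small
relative to an exon's matches and positive breaks the tie identically.

## Gene models and copy numbers

Each chain becomes a gene model. Status rules:

- matched homology < 200 bases: `FRAGMENT` (incompletely assembled copy or
  pseudogene) — reported but excluded from copy totals;
- otherwise `FULL` if every reference exon is represented at >= 80% of its
  length *and* the chain covers >= 90% of the transcript, else
  `TRUNCATED`. The reference exon structure is taken from the
  best-covering chain when not supplied; the transcript-coverage condition
  prevents a partial copy from being declared complete against itself when
  no full copy exists anywhere (the split-gene case).
- Two chains are distinct copies when their contig footprints overlap
  < 20%; tandem-array copies are individually counted, overlapping
  re-descriptions of one locus are resolved to the higher-coverage chain.
- Two `TRUNCATED` models on different contigs whose transcript coverage is
  complementary (overlap <= 30 bases, combined coverage >= 0.9) merge into
  one `SPLIT` single-copy call — an assembly break inside a gene, not two
  copies.
- Cross-species annotation (locating a gene with a diverged transcript
  from another species) relaxes the identity gate to 0.75 and reports
  `LOCATED_ONLY` when no chain resolves the exon structure.

ORF finding scans all six frames for ATG-to-stop runs of at least 100
residues (stop excluded from the count), reporting stop-less runs as
partial; the tests prove equivalence to an exhaustive scan.

## Pseudoautosomal boundary

The boundary detector computes X-coverage over sliding windows (default
10 kb window, 2 kb step; these defaults resolve a boundary to well under
the ±1 kb acceptance band while keeping a 300 kb contig profile in
seconds) and chooses the two-segment split maximising
`mean(left) − mean(right)` with at least `min_flank_windows` (5) windows a
side. A call requires a clearly pseudoautosomal left flank (mean coverage
>= 0.5) and a clearly X-free right flank (<= 0.1); otherwise no boundary
is reported. The coarse window boundary is refined to base precision by
re-aligning the two-window transition region and taking the furthest
X-homologous base — equivalent in effect to per-base bisection, and the
refinement is asserted stable (±1 step) under window/step halving.

`gametolog_divergence()` reports the length-weighted identity of the best
colinear chain between an X and a Y copy of a gene, the statistic used to
argue which gene is the last pseudoautosomal one. `par_coverage()` reports
assembled-PAR/estimated-PAR both at one decimal and as a round-half-up
integer: published figures of this kind are sometimes rounded from a
coarser size estimate (3.74/7.0 = 53.4% can print as 54% when the 7 Mb
estimate is itself rounded), so both are exposed rather than silently
matching either convention.

## qPCR copy number

The design has no calibrator sample (a single animal), so the classic
double delta collapses to a single delta against the single-copy reference
gene; this is stated explicitly because the two-sample form is the common
textbook presentation. Per assay `dCt = mean Ct(target) − mean Ct(ref)`,
fold `= (1+E)^-dCt` with efficiency `E = 1` by default (an efficiency
parameter is exposed but no calibration data is modeled). Duplicate assays
are combined by geometric mean — fold changes are multiplicative — and
dispersion is the pooled per-replicate fold standard deviation within
assays. The reference's own estimate is exactly 1 by construction, and
estimates are invariant to constant Ct shifts; both are asserted.

## Neighbor-joining trees

Distances are p-distances (mismatches over compared columns; gap or `N`
columns excluded pairwise) — no substitution model is assumed, and a
Jukes–Cantor correction sits behind a flag. The tree is built by canonical
Saitou–Nei agglomeration implemented in the package so that two details
are pinned: Q-matrix ties join the lowest (row, column) pair, and negative
branch estimates are clamped to zero with the deficit moved to the sibling
so the joined pair's path length is preserved. `ape::nj` serves as an
independent cross-check in the tests, which also verify exact recovery of
additive matrices up to 12 taxa (path lengths within 1e−9). Rooting is by
outgroup (which must be monophyletic; the error names the offending taxa)
or by midpoint. Candidate-set construction from database searches is out
of scope: the tree functions accept any pre-aligned multi-FASTA.

## The synthetic study and what it does (not) show

`generate_fixture()` builds a complete study from one seed: female
reference (two X scaffolds, two autosomes, one unplaced), PAR contigs as
substrings of X at 99% identity, contaminants at 97% (the source analysis
states only the 95% gate; 97% is a free parameter chosen to sit clearly
inside the gate), sub-threshold junk, and MSY contigs carrying the full
multicopy architecture the package is designed to recover: an HSFY array
of 15 direct + 1 inverted copies plus 9 more on a second contig and 1 on
the boundary contig (26 countable copies), a 7-exon EIF1AY full copy with
an inverted exon-1–4 pseudogene, a 28-exon UTY split 1–16/17–28 across two
contigs, three RBMY copies plus two 150-base fragments, three TSPY copies
and a single-exon SRY whose coding sequence is exactly one 240-residue
ORF. The boundary contig is 307,557 bases with an X-derived prefix of
177,307 at 99.1% identity. Repeats (LINE-dominated, with SINE and LTR) and
~1% microsatellite content are planted in non-genic intervals; intron
lengths default to a few hundred bases so spliced alignment is exercised
while the whole study stays near 1.3 Mb and a full pipeline run takes
about 15 s on one CPU.

Divergence is simulated by substitutions only, with an exact mutation
count at uniformly drawn positions. This keeps every planted coordinate
exact in the truth manifest (the manifest and FASTA are asserted mutually
consistent) at the price of realism: real assemblies contain indels,
segmental duplications, heterogeneous repeat landscapes and base-calling
error. Background sequence is i.i.d. uniform, so spurious identity between
unrelated sequences stays far below the 95% gate ("no significant
similarity" is trivially true). Passing tests on this fixture therefore
demonstrate the correctness of the decision rules and estimators under
their stated assumptions — not robustness to indel-rich or
repeat-confounded real data, which would need an alignment back-end with
gapped extension.

Ct tables are simulated per replicate as
`Normal(base_ct − log2(ratio), sd)` with the documented design seed 7 and
sd 0.15 — duplicate assays of triplicates. The qPCR parameter-recovery
suite (1,000 simulated tables over dosages 1–26) bounds the median
estimation error at ±10%.

## Numerical and reporting conventions

- Intervals are 0-based half-open internally; GFF3 and human-readable
  reports are 1-based inclusive; BED is 0-based half-open.
- Report percentages print at one decimal; summary rows of per-contig
  feature tables are size-weighted means (the convention that reproduces
  the published table this report format mirrors — the unweighted GC mean
  of that table differs from its printed summary, which pins the
  convention), and the size column totals exactly.
- `Total repetitive` is the union of masked bases over the contig length,
  never the column sum; tandem-array purity is Hamming distance to a
  perfect tandem extension of the unit, and arrays are trimmed at their
  score maximum so pure arrays are not padded with flanking noise.
- All randomness in a pipeline run flows from the single config seed;
  identical config and seed give byte-identical outputs.

## Problem sizes used in the checks

The default synthetic study is ~0.72 Mb of Y contigs against a ~0.52 Mb
female reference; property suites use 20 randomly seeded miniature studies
(~50 kb each), DP-oracle alignment instances up to 2 kb, NJ matrices up to
12 taxa, and 1,000 simulated Ct tables. These sizes were chosen so the
full suite completes in a few minutes on a single CPU while every decision
rule is still exercised at its boundary.

## Known limitations

- No gapped extension: indel-containing homology is reported as split
  hits; E-value statistics are not modeled.
- Repeat masking is identity-gated homology to a user-supplied consensus
  library; no repeat-family discovery, no divergence-aware scoring of the
  kind dedicated repeat annotators perform.
- qPCR efficiency is fixed at 1 unless overridden; no dilution-series
  calibration or melting-curve analysis.
- Trees require pre-aligned input; no multiple alignment or bootstrap.
- The PAB detector assumes a single boundary per contig (two-segment
  model); a contig with interleaved X-homologous blocks would need a
  multi-changepoint extension.
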