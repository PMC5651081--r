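---
title: "Designing array content with panelforge: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing array content with panelforge: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelforge)
```

panelforge implements the content-design pipeline used for high-density
Infinium-style SNP genotyping arrays in crop species: given a large set of
candidate variants called from sequencing data (typically exome capture of
a diversity panel), it selects a fixed-size marker panel that balances
gene coverage against the peculiar recombination landscape of large cereal
genomes, builds the probe-design manifests, reconciles the new content
with a legacy marker set, and computes the quality-control statistics used
to judge the fabricated chip. This vignette explains the procedure, its
assumptions, and the choices made where the design was genuinely open.

## The selection model

### Why recombination stratification

In barley and its relatives, recombination is concentrated in the distal
chromosome arms; the pericentromeric region — often more than half the
physical chromosome — is nearly devoid of crossovers. Markers there sit in
near-complete linkage disequilibrium: physically dense, genetically
redundant. A panel chosen uniformly along the physical map would waste a
large share of its budget on markers that segregate as one block.

panelforge therefore works with a **five-zone partition** of each
chromosome: short arm high recombination, short arm low, pericentromeric,
long arm low, long arm high. Zone boundaries are physical (bp); each zone
carries the genetic length (cM) it spans. Boundaries are user input —
historically they were set by eye from Marey-map plots (genetic vs.
physical position of anchor markers). `suggest_partition()` automates that
visual step with a five-segment piecewise-linear fit chosen by dynamic
programming over candidate breakpoints; its output is advisory and never
overrides an explicit partition table.

### Stage A: gene coverage

Candidates passing lenient thresholds — missing-call rate at most 20%,
assay design score at least 0.6, boundaries **inclusive** — are reduced to
one SNP per annotated gene. Within a gene the survivor is the candidate
with the highest design score, ties broken by lower missing rate, then
lower position, then id, so the stage is fully deterministic. Candidates
with no gene association form singleton groups and always survive this
step; in real exome-capture inputs they are rare.

### Stage B: distal enrichment

A per-chromosome budget is apportioned across the four distal zones in
proportion to their genetic span, with the pericentromeric zone receiving
**zero** quota. Fractional shares are integerised by the largest-remainder
method (remainder ties broken in zone order short-high, short-low,
long-low, long-high), so quotas always sum to the budget and each sits
within one marker of its exact rational share.

Within a zone, candidates must pass stricter thresholds — missing rate
below 5%, design score above 0.8, boundaries **exclusive**, exactly as the
constraints are printed for the original design; both inclusivity flags
are configurable because the printed convention is likely looser than the
original code. Per-zone overrides relax the thresholds where the
genetic-to-physical ratio is extreme; the default configuration carries
one such override, for the short arm of chromosome 5H (missing < 20%,
score > 0.6). Survivors are ranked by the same deterministic key as stage
A and taken up to quota, with a combined cap of two SNPs per gene counted
**across both stages** — a gene that already contributed a stage-A pick
can gain at most one more.

Zones whose qualifying candidates run out return their unused quota, which
is re-apportioned by largest remainder over the chromosome's remaining
distal zones (never across chromosomes, preserving per-chromosome
genetic-map proportionality). Shortfall that no zone can absorb is
reported, never silently filled.

### The funnel

`design_funnel()` tracks the arithmetic of the full design: stage totals
combine into the pre-redundancy count, alignment-detected duplicates
against the legacy set are removed, legacy markers are added back, and
fabrication attrition is expressed by `conversion_stats()` (working /
designed and scorable / working). These identities are what the package's
acceptance checks reproduce from the published design-stage counts.

## Manifests and redundancy

A manifest is the SNP base plus 60 bp of reference flanking sequence on
each side — 121 bases, with the polymorphism encoded either as `[A/G]` or
as the single IUPAC two-base ambiguity character (R here). Manifests are
always emitted on the forward reference strand; legacy markers keep their
historic orientation as metadata rather than being re-complemented, so
allele calling stays comparable across array generations. SNPs closer
than 60 bp to a chromosome end are rejected outright: a truncated probe
context is not assayable.

Redundancy against the legacy set is detected by aligning legacy manifests
(queries) against new-set manifests (subjects), both IUPAC-rendered, and
flagging pairs whose best hit reaches ≥98% query coverage and ≥95%
identity (inclusive). On 121-mers the identity threshold falls exactly
between six mismatches (115/121 = 95.04%) and seven (114/121 = 94.2%),
which the tests pin with a hand-count oracle.

### The aligner

Alignment is performed by an internal k-mer-seeded (k = 11) ungapped
extension with match +1 / mismatch −2. Bit scores use the published
ungapped nucleotide Karlin–Altschul constants for that scoring
(λ = 1.33, K = 0.621) and are compared after rounding to one decimal,
the precision at which bit scores are conventionally reported — "equal
bit scores" is defined at reported precision. Gapped alignment is
deliberately absent: for 121 bp high-identity probe queries, an ungapped
HSP carries all the signal the downstream logic consumes (identity, query
coverage, a score monotone in matches). HSPs scoring below 20 are
suppressed; this noise floor plays the role an e-value cutoff plays in a
full aligner, removing spurious seed-length diagonal hits on random
background. An IUPAC ambiguity position matches either of its bases on
both the query and the subject side. `read_tabular_hits()` accepts
conventional 12-column tabular output for users who prefer an external
aligner.

### Legacy placement and validation

Hits for a legacy marker are filtered to ≥95% identity. A unique top bit
score places the marker at the subject base aligned opposite query
position 61; if that position falls outside the aligned segment the
marker is unmapped, since the SNP coordinate is the deliverable. Two or
more tied top scores make the marker *ambiguously mappable*, with every
tied location exported. A placed marker is *validated* when an
independent variant catalog holds a SNP at the predicted coordinate whose
allele pair matches the manifest's, compared unordered and
strand-normalized (A/G ≡ T/C), and *unvalidated* otherwise.

## Effect annotation

`annotate_effects()` assigns each SNP exactly one of 17 categories
(splice-site acceptor/donor, stop gained/lost, start lost,
non-synonymous/synonymous start, non-synonymous/synonymous coding,
synonymous stop, start gained, splice-site region, 5'/3' UTR, intron,
upstream, downstream, intergenic), in the single-effect reporting style of
SnpEff-era annotation pipelines. When a position supports several labels,
a fixed severity order decides (most severe first, as listed in
`EFFECT_CLASSES`); when several genes cover a position, the gene giving
the most severe effect wins, ties broken by lower gene start then gene id.

Conventions, all configurable through `effect_config()`:

* up/downstream windows: 5,000 bp beyond the transcript span;
* splice donor/acceptor: the first/last 2 intronic bases of each intron;
* splice region: intronic bases 3–8 from an exon boundary, and exonic
  bases 1–3 from an intron-adjacent boundary (a coding consequence
  outranks the exonic splice-region label);
* `start_gained`: a 5'-UTR substitution creating a new ATG anywhere in a
  frame-agnostic scan of the mRNA;
* `start_lost`: any substitution destroying a canonical ATG start codon
  (a simultaneous stop gain outranks it); `non_synonymous_start`: an
  amino-acid change in a non-ATG first codon;
* exonic positions of non-coding transcripts have no category of their
  own in this vocabulary and are reported as `intron`, the
  transcript-interior label.

The classifier is checked against an exhaustive oracle that re-derives
each label from first principles — mutating the chromosome, re-extracting
and translating the whole CDS, scanning the whole transcript — at every
position of 50 synthetic genes on both strands.

## QC metrics

* **Agreement**: per sample, over the intersected marker set, excluding
  pairs with a missing call on either side; a heterozygous call against a
  homozygous one counts as disagreement. Both conventions are flags
  (`exclude_het`) because the original comparison protocol is not fully
  specified. Agreement is symmetric by construction.
* **Polymorphism rate**: a marker is polymorphic when at least two
  distinct non-missing call states are observed.
* **Ts/Tv**: transitions (A↔G, C↔T) over transversions; errors out with a
  count report when no transversion is present.
* **Conversion**: working/designed and scorable/working, percentages
  rounded half-up to one decimal (plain `round()` would turn 97.45 into
  97.4 under banker's rounding); ratios are reported to two decimals.
* **Order concordance**: per chromosome, Spearman rank correlation
  (average-tie handling) between genetic and physical position, the count
  of adjacent-pair inversions in genetic order, and unlinked markers —
  placements on another chromosome, or further than a configurable
  distance from the physical position interpolated from their genetic
  neighbours. Outliers are peeled greedily (flag the worst leave-one-out
  deviation, re-interpolate, repeat) so one displaced marker does not
  drag its neighbours' expectations with it. Chromosomes with fewer than
  three usable markers are flagged, not scored.

## The synthetic-data generator

Every stage is testable without external downloads because
`simulate_design_inputs()` fabricates the full input bundle with planted
ground truth: an i.i.d. uniform ACGT genome (at these scales no 121-mer
repeats except where planted), gene models inscribed into the sequence
(ATG start, TAA stop, internal in-frame stops rewritten so every CDS
translates cleanly), candidate variants, legacy manifests, and paired
genotype call sets. A single root seed drives named substreams — one per
generator — so adding a generator never perturbs another's draws, and two
runs with one seed are byte-identical.

Defaults are the study conditions the package models: transition:
transversion odds 1.92; per-call disagreement rates 0.019 and 0.061
(the legacy-marker and exome-capture agreement scales); 97.3% of call-set
markers polymorphic; 70% of candidates genic (exome-capture candidates
are overwhelmingly so); five-zone genetic spans (40, 7, 7, 18, 66) cM at
fractional physical breaks (0, 0.12, 0.25, 0.76, 0.88, 1); distal
candidate density three to four times the pericentromeric density.
Problem sizes are desk-scale by design — chromosomes of a few hundred kb,
candidate sets of 2,000–50,000, call matrices up to 148 samples × 5,000
markers — and are stated here as the package's own choices.

What the generator does **not** emulate: linkage disequilibrium and
demography, exome-capture coverage bias, assay-intensity clustering, and
real repeat structure. Passing tests therefore demonstrate algorithmic
correctness against planted truth, not performance on real genomes; in
particular, placement behaviour on genuinely repetitive references will
show more ambiguity than the simulator's clean background suggests.

## Numerical and degenerate-input conventions

* All interface coordinates are 1-based inclusive (VCF/GFF3 convention);
  zone intervals are half-open `[start, end)` with the final zone closed
  at the chromosome end, so every base belongs to exactly one zone.
* Phased genotype separators are treated as unphased; any genotype
  containing `.` is missing. Multiallelic records are dropped, not split:
  the assays being designed are biallelic.
* Scoreless candidates (no design-score sidecar entry) fail every
  selection filter rather than erroring.
* Every ranking used in selection ends in an id tie-break; identical
  inputs give identical selections.
* Zero budgets yield zero quotas; a positive budget over all-zero distal
  spans is an error; an empty placement or spectrum input is an error;
  zero working assays reports a flagged scorable rate of 0.

## Known limitations

The aligner indexes the whole subject once per call set and is sized for
manifest-scale queries against desk-scale references, not for multi-Gbp
assemblies (the non-goal the original pipeline met with BLASTN). Effect
annotation handles SNVs only — no MNVs, indels or frameshifts. The
partition-suggestion fit assumes a monotone genetic map per chromosome.
Stage-B ranking within a zone is a declared convention (score, then
missingness, then position); the original publication does not state the
key it used, so reproduction of its exact marker list is not claimed —
only of its arithmetic and its selection properties.
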