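---
title: "Quantifying post-transformation intraclonal IGHV-IGHD-IGHJ diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying post-transformation intraclonal IGHV-IGHD-IGHJ diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intraclone)
```

## The problem

Chronic lymphocytic leukemia (CLL) clones are classified in the clinic by the
somatic mutation load of their expressed IGHV gene (M-CLL vs U-CLL), a status
that is essentially fixed at the clonal level. Deep, UMI-tagged sequencing of
the full IGHV-IGHD-IGHJ rearrangement nevertheless reveals ongoing
*intraclonal* diversification: a clinically dominant clone (CDC) surrounded by
hundreds of lower-frequency descendant subclones that differ from it by one
or more nucleotides. `intraclone` implements the complete analysis of that
phenomenon: subclone detection and quantification, a replicate-based
sensitivity threshold for calling genuine subclonal *expansion*, lineage-tree
reconstruction and complexity classification, attribution of the new
mutations to candidate mutational machineries, estimation of
antigen-selection pressure on them, and association of lineage complexity
with clinical course. A synthetic-repertoire generator with complete ground
truth stands in for patient data and validates every stage.

Because each mRNA molecule is tagged with a unique molecular identifier
(UMI), abundance is measured in distinct mRNA molecules, not reads. Unique
sequences are admitted only with at least 3 distinct UMIs and consensus
support of at least 5 reads (`filter_by_umi_support()`); this is the error
bar that makes single-nucleotide subclone calls interpretable. When only an
aggregate read count is available the per-UMI requirement is applied as
`read_count >= min_umis * min_reads_per_umi`; a `umi_read_counts` list-column
switches the filter to the exact per-UMI rule.

## Clonal families, the CDC, and subclone statistics

Rearrangements are partitioned by V gene, J gene and junction length
(alleles collapsed) and then clustered by single-linkage on the normalized
junction hamming distance with a 0.07 cutoff (`cluster_clones()`), the
standard clonotyping construction for BCR repertoires; single linkage is
used deliberately, since a CLL family is a dense cloud around one dominant
sequence and chaining is the desired behavior. Positions carrying N in
either sequence are excluded from every distance and mutation computation,
so ambiguous base calls can never create phantom subclones.

The CDC is the unique sequence with maximal aggregated UMI count
(`identify_cdc()`; ties broken by lexicographically smallest sequence, so
results are order-independent). Subclones are members differing from the CDC
anywhere in the aligned V(D)J (N wildcard-equal); `subclone_stats()` reports
the variant fraction, and the predominant subclone (PSC) as a fraction of
the family and of the variants. Putative PCR chimeras — members whose
mutation set is exactly the union of two non-nested other members — are
flagged by `flag_chimeras()` but never silently removed; reproducibility is
preferred over curation.

## The expansion sensitivity threshold

Samples sequenced as several aliquots of 25,000 cells from one blood draw
let genuine expansion be separated from sampling noise: a subclone recurring
in at least three quarters of the aliquots must derive from expanded cells.
`concordant_subclones()` collects those sequences with their pooled
frequency (summed UMIs over summed family UMIs; a per-replicate-mean mode is
available, since the choice between the two is a genuine free parameter —
pooling was chosen as the variance-minimizing estimate).
`expansion_threshold()` takes the 25th percentile of the pooled distribution
across all replicate-bearing samples as the cohort-wide cutoff, using linear
interpolation between order statistics (R's type-7 quantile, pinned for
reproducibility). Two cells in a 25,000-cell aliquot correspond to a
frequency of 0.008%, the scale this threshold is designed to resolve.
`absolute_abundance()` converts frequencies to cells/µl via the absolute
lymphocyte count and the CD5+CD19+ fraction; calls at the threshold are
inclusive.

## Lineage trees and complexity

Each subclone is summarized by its mutation set relative to the CDC. In the
regime the analysis targets, descendant sets strictly contain ancestral sets,
and the lineage is exactly the Hasse diagram of set inclusion.
`build_lineage()` closes the observed sets under pairwise intersection
(recovering unobserved branch points as inferred intermediates), assigns
each node the largest proper-subset node as parent, and splices out inferred
nodes with fewer than two children. This construction is deterministic,
dependency-free, and parsimony-exact when sets nest; under homoplasy it
attaches a sequence to its maximal shared-subset ancestor, which among
subset candidates also minimizes the symmetric difference. Equal-size parent
candidates are resolved lexicographically on the sorted mutation-key string,
and observed sequences with identical mutation sets collapse onto one node,
so reconstruction is invariant to input order.

`classify_complexity()` counts observed (never inferred) sequences in each
subtree hanging off an initial branch from the CDC: any branch with four or
more makes the sample High, one to three on every branch makes it Low, and
a tree without subclones is reported undetermined. The per-branch *max* rule
was chosen because a single elaborate branch is what distinguishes the
complex archetype; a total-count alternative (`rule = "total"`) is provided
because the boundary case — several branches of size ≤ 3 summing past 4 —
is not decidable from the definition alone.

## Mutation-mechanism attribution

Mutations are assumed to have occurred on the CDC background. Built-in
motif contexts (`builtin_motifs()`), each scanned on both strands:

| motif | pattern (mutated base underlined position) | base class |
|---|---|---|
| AID hotspot | WRC / GYW | G:C |
| AID coldspot | SYC / GRS | G:C |
| Pol-eta hotspot | WA / TW | A:T |
| APOBEC3A/B | TC / GA | G:C |
| aging signature | C>T at NCG | G:C |
| cancer signature | T>C at ApTpN | A:T |

The last two carry substitution constraints (the complementary substitution
is matched on the reverse strand). `classify_mutations()` assigns each
mutation to exactly one of four categories (AID hotspot, AID coldspot,
Pol-eta hotspot, other/unclear); hotspot and coldspot patterns are disjoint
by construction, so this is a true partition.

`enrichment_test()` pools a sample's mutations (each distinct mutation
counted once per unique sequence carrying it — the pooled counting means
mutations shared along a lineage path are counted in every descendant, which
is deliberate and matches per-unique-sequence accounting; a
lineage-deduplicated sensitivity mode can be built from `mutation_keys()`),
computes hotspot/non-hotspot counts `h:n` within the motif's base class, and
tests one-sided against the expected proportion `p0` = motif sites /
base-class sites on the CDC, using the exact binomial upper tail — no normal
approximation. Positions whose context window runs off the sequence end are
excluded from both `p0` and the eligible mutations. Benjamini-Hochberg
correction (`bh_correct()`, a wrapper over the standard step-up adjustment)
is applied across samples within each motif family by default; adjusting
across motifs within a sample is available and recorded in the result's
metadata, since "sample-level correction" admits both readings.

Transitions are A↔G and C↔T; `ts_tv_ratio()` and `ts_tv_by_sample()` report
per-sample ratios and group medians, excluding infinite ratios (no
transversions) from medians with a warning. Non-productive rearrangements at
or above the expansion threshold (`select_nonproductive_comparators()`)
provide a mutation record that cannot have been antigen-selected; their
mutations are called against their own family consensus.

## Selection strength

`selection_strength()` is a focused Bayesian R:S analysis in the BASELINe
tradition, deliberately simplified to pooled counts: with observed
replacement and silent counts R and S in a region and expected replacement
fraction π₀ (from `expected_r_fraction()`, which enumerates every
position × substitution in the region under a targeting model), the flat
Beta(1,1) prior gives posterior Beta(R+1, S+1) on the true replacement
fraction θ, and selection strength is the log odds ratio
Σ = log[(θ/(1−θ)) / (π₀/(1−π₀))]. The posterior density is transformed onto
a fixed Σ grid (default [−10, 10] in 0.01 steps) with the exact Jacobian;
the mode is closed-form, the 95% credible interval comes from the trapezoid
CDF with linear interpolation, and group comparisons integrate
P(Σ₁ > Σ₂) over the two grids. Stop-producing substitutions are excluded
from observed and expected counts by default (`stop_policy = "as_R"`
alternative). The default targeting model is uniform; any odd-width k-mer
weight table can be supplied, so published SHM targeting tables drop in
unchanged. Pooling counts rather than convolving per-sequence posteriors
reproduces sign, ordering and null behavior — the quantities this analysis
interprets — but narrows intervals relative to a full per-sequence
convolution; it is documented as an approximation and isolated behind this
one function.

Mutations are referenced to the CDC for post-CDC groups and to the germline
for the CDC epoch, reflecting the two mutation eras of a transformed clone.

## The synthetic-repertoire generator

`simulate_repertoire()` emits exactly the structure the analysis assumes,
with every latent variable returned as ground truth. Its defaults *are* the
study conditions and are not tuned per experiment:

- 366 nt codon-aligned V(D)J with an IMGT-like region map; germline drawn
  stop-free at random (or supplied as FASTA via `read_germline_fasta()`).
- CDC share 0.92 of family mRNA — the 8% median variant fraction regime —
  with remaining mass power-law distributed (exponent 1.5) over subclones.
- Machinery mixture AID 0.45 / Pol-eta 0.20 / context-free 0.35, hotspot
  weight multiplier 5, transition probability 0.6 for the physiologic
  machineries (the ~1.5:1 Ts:Tv of canonical SHM) and 1/3 (unbiased) for the
  context-free component.
- Lineages attach each new subclone uniformly to an existing node with
  1 + Poisson(0.3) mutations per edge; mutated positions are globally unique
  within a lineage, so emitted mutation sets nest strictly and topology
  recovery can be scored exactly.
- Four replicates of 25,000 cells multinomially sampled from clone shares;
  UMIs per clone are Poisson(cells × 5), modeling ~5 captured mRNA molecules
  per cell (a modeling choice — no per-cell mRNA law is prescribed by the
  data); read counts guarantee ≥ 5 reads per UMI.
- Non-productive comparator families with frameshifted (length ≢ 0 mod 3)
  junctions and their own V gene, mutated by the same machinery without any
  selection filter.
- `simulate_clinical()` draws exponential event times per stratum with
  hazard ratios (vs the M-CLL/Low baseline) of 1.02 for M-CLL/High, 2 for
  U-CLL/Low and 2 × 2.59 for U-CLL/High — planting the published-scale
  interaction pattern — with independent exponential censoring.

What the generator does *not* emulate: junctional V(D)J recombination
diversity (all family members share coordinates by construction), homoplasy
and back-mutation, PCR chimeras, sequencing error surviving UMI consensus,
per-cell mRNA overdispersion, and selection acting during lineage growth
(a CDR-replacement penalty would be the natural extension). Passing tests
therefore certify the estimators under clean nesting and known machinery —
not robustness to artifacts upstream error correction is supposed to remove.

## Numerical choices and degenerate inputs

- Quantiles: type-7 linear interpolation everywhere, inclusive endpoints.
- Binomial tails: exact (`pbinom`), validated against term-by-term pmf
  summation.
- Σ posterior: closed-form mode; trapezoid CDF for intervals (grid step
  0.01 gives interval error below 2×10⁻³); densities normalized to
  integrate to 1 on their grid.
- Ties: CDC and lineage-parent ties break on lexicographic sequence /
  set-key order; junction clusters relabel deterministically.
- Degenerate inputs: empty families, CDC-only families, zero base-class
  mutations, all-censored cohorts and empty strata are reported as
  undetermined/untestable with diagnostics rather than silently dropped.
- Coordinates are 1-based closed intervals throughout (the AIRR/R
  convention).

## Problem sizes

The bundled validation suite runs, per invocation: ~1,000-instance oracle
cross-checks for each core numeric; 200 synthetic samples of ~50 G:C
mutations for enrichment calibration and power; 100 homoplasy-free lineages
of 20–200 subclones for topology and complexity recovery; 10⁴ mutations for
the Ts:Tv estimator; 100 selection runs of 100 mutations; and 50 simulated
clinical cohorts of 500 subjects per stratum. These sizes were chosen so
each Monte-Carlo bound has comfortable margin while the whole suite stays
desk-scale.

## Known limitations

Pooled-count selection inference narrows credible intervals relative to
per-sequence convolution; the Hasse lineage construction is heuristic under
homoplasy; cohort-scale biological quantities (variant-fraction
distributions, fraction of AID-significant samples, Ts:Tv medians, hazard
ratios) depend on patient data and are reproduced here only in the sense
that the estimators recover the generator's planted values.
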