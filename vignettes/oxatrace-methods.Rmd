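---
title: "Methods: taxon-resolved detection of oxalate degradation genes and transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxon-resolved detection of oxalate degradation genes and transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Oxalate is degraded in the mammalian gut exclusively by microbes. Two enzyme
systems exist: a single-step oxidase/decarboxylase (OXDD), and the
CoA-dependent two-step pathway of formyl-CoA transferase (FRC) and oxalyl-CoA
decarboxylase (OXC). Knowing which community members *carry* these genes says
little about who actually *degrades* oxalate in vivo: gene carriage
(metagenome) and transcription (metatranscriptome) can diverge sharply — a
species may be abundant and gene-rich yet transcriptionally silent, while a
specialist such as *Oxalobacter formigenes* transcribes its oxalate pathway
essentially whenever it is present. `oxatrace` implements the in-silico
pipeline for resolving this: detecting oxalate-degrading-enzyme (ODE) reads
in shotgun DNA and RNA data, attributing them to species, and quantifying
each species' population-level contribution to the function.

# The detection model

## Translated best-hit search

Reads are translated in all six frames with the standard code (`N`-containing
codons become `X`), frames are split at stop codons, and every stop-free
fragment of at least 15 residues is aligned to every reference protein with
exhaustive Smith–Waterman (BLOSUM62, gap open 11, extend 1 — a gap of length
L costs 11 + L). The single best hit per read is kept; ties are resolved by
higher identity, longer alignment, lexicographically smaller accession, then
frame order, which makes the search deterministic irrespective of iteration
order. There is no seeding heuristic: correctness is preferred over speed,
and the alignment kernel is implemented in C++ so that exhaustive search over
a curated reference remains practical at cohort scale (roughly 5 × 10^8
dynamic-programming cells per second on one core).

Two thresholds control what counts as a detection:

* **Score floor 40.** A 15-residue perfect match scores well above 40, while
  random 15-mers essentially never reach it against a desk-scale reference
  (measured as a property test: at most a few percent of random fragments per
  100 trials, each against a 200-residue protein). The floor suppresses
  spurious short matches before any identity reasoning applies.
* **Identity filter, ≥ 90%.** Hits below 90% identity (identical residues
  over all alignment columns, gaps included; `X` never counts) are discarded.
  The boundary is kept: a 90.0% hit passes. The cutoff is justified by the
  reference itself: within-species homolog identity is high (~97%) while
  between-species identity is far lower (~80%), so a ≥ 90% alignment
  identifies the source species reliably. `identity_by_rank()` reproduces
  this analysis for any reference and reports the fraction of between-species
  pairs exceeding the cutoff (0 at the simulated divergences).

Reads that fail the filter are *dropped*, never reassigned. At sequencing
error around 0.1–0.5% per base this costs well under 1% of true reads; at a
stress level of 1% per base, reads carrying three or more amino-acid changes
in a ~30-residue fragment legitimately fall below 90% (about 1–2% of reads).
They are false negatives by design, and they are never misassigned to a
related species — the property the cutoff exists to guarantee.

## Two identity conventions

The package deliberately uses two different identity definitions, as the two
serve different roles:

* Reference curation (`pairwise_identity()`, clustering): global alignment
  with BLOSUM62-guided gap placement (open 10 / extend 1), identity =
  matches / columns where **neither** sequence is gapped. The distance
  `d = sqrt(1 - f)` is reported alongside, and `pct = 100(1 - d^2) = 100 f`
  round-trips exactly. This mirrors the identity convention of classic
  alignment-distance tools operating on curated multiple alignments.
* Read search (`align_local()`): BLAST convention, identity = matches / all
  alignment columns **including** gap columns. This is the convention read
  mappers report and the one the 90% filter is calibrated against.

## RPKM quantification

Per homolog and sample, abundance is reads per kilobase of reference per
million sample reads:

```
rpkm = hits / ((3 * protein_len_aa / 1000) * (total_reads / 1e6))
```

The reference length is expressed in nucleotides (3 × amino-acid length) so
read counts and reference length share a unit; any fixed alternative rescales
every value by the same constant and cancels from all share-based statistics.
The denominator is the sample's *total* quality-filtered reads (from the
manifest), not the ODE-mapped reads, preserving cross-sample comparability.
Homolog values roll up to species × enzyme class by exact summation, and
subjects sampled repeatedly are represented by the zero-including arithmetic
mean of their samples within each omics layer. Detection is strict
positivity of the subject-level value — one identity-passing read in one
sample suffices (the `min_reads` parameter, default 1, raises this if
desired).

# Attribution

## Co-detection

For a subject with both omics layers, each species × enzyme is classified by
the 2 × 2 table gene±/transcript±. Subjects missing a layer are excluded
from co-detection outputs (and counted); this is the matched-analysis
convention.

## Population-level contribution

In sample (or subject) *j*, species *i* contributes its share of the
enzyme's total abundance:

```
c_ij = z_ij / sum_i(z_ij)   (0 when the sample is enzyme-negative)
C_i  = sum_j(c_ij)          so  sum_i(C_i) = number of positive samples
R_i  = C_i / sum_k(C_k)     relative scale, sums to 1
```

`C_i` blends prevalence and within-sample dominance; because it grows with
cohort size, only the relative scale `R` is compared across cohorts or
layers, each normalized independently (`relative_scale()`). Contributions
are computed per subject by default (one row per subject, matching cohort
presentations); per-sample mode is available by passing sample-level
profiles. `R` is reported to 3 decimals in pipeline outputs, and ties for
the largest contributor are reported as ties.

`deconvolve_single_copy()` supplies the complementary top-down route:
given a sample's total gene abundance and the community's taxonomic profile,
the function attributes abundance to known encoder species proportionally to
their relative abundance under an assumed single gene copy per genome — the
assumption of record when per-genome copy numbers are unavailable.

# Marker peptides

The marker route trades sensitivity for specificity. Homologs are clustered
greedily by decreasing length at ≥ 85% global identity; the founding
(longest) member is the family centroid. A 30-residue window slides over the
centroid; windows matching any background protein at ≥ 90% (best ungapped
placement) mask their span, and maximal unmasked runs of ≥ 8 residues become
markers. The background must exclude the homolog set itself. Reads are
quantified against markers at ≥ 90% identity over ≥ 50% of the shorter of
marker and fragment, above the same score floor; each read is assigned to
the family of its single best passing alignment, so conserved stretches
shared with a sibling family do not double-count reads. Family RPKM uses the
summed marker length as reference length.

Very short markers are a real failure mode: a marker of ~8 residues cannot
reach the score floor even when perfectly matched, so a family whose unique
sequence was fragmented into sub-16-residue pieces becomes undetectable.
`merge_adjacent()` repairs this by merging markers one residue apart
(transitively, idempotently), restoring a quantifiable marker — the package
ships a hand-built fixture (`marker_rescue_fixture()`) reproducing failure
and rescue.

# Cohort statistics

Prevalence differences use the two-proportion chi-square test without
continuity correction; abundance differences use the two-sided Mann–Whitney
test (normal approximation with tie and continuity corrections), computed
among detected subjects only for detection-conditional panels (the default)
or among all subjects. Families of comparisons are adjusted per panel with
Benjamini–Hochberg — the field default, chosen here as the multiplicity
method. Monotone associations use Spearman correlation (average ranks,
two-sided t approximation). Metabolite levels are normalized per sample to
percent of total observed metabolites before comparison; log10 display maps
zeros to missing rather than inventing a pseudocount.

Calibration is tested, not assumed: under the null (n = 25 per group, 2000
replicates) the Mann–Whitney rejection rate at α = 0.05 must lie in
5% ± 1.5%, and power against a one-SD normal shift must exceed 90%.

# The synthetic-data generator

Every stage is validated against simulated data with recorded ground truth.

* **Reference.** One ancestor protein per enzyme class (130 residues by
  default, roughly a third of a real oxalyl-CoA decarboxylase — long enough
  for realistic alignment statistics, small enough for exhaustive search);
  species diverge from the ancestor and homologs from the species sequence by
  substitution only. Substitution counts are fixed (not drawn per site) and
  solved so that realized pairwise identities between homologs of different
  species hit the inter-species target (80%) after compounding with the
  intra-species divergence (97%); realized identities land within ±2 points
  of the targets. No indels are simulated — indel robustness is exercised by
  hand-built gapped fixtures in the search tests instead — which keeps the
  identity targets controllable.
* **Cohorts.** Per subject, each species is carried with a group-specific
  prevalence; carried species get a lognormal-jittered gene abundance
  (expected fraction of sample reads from their ODE genes) and transcribe
  with a group-specific probability. DNA reads are drawn multinomially from
  carried species' genes; RNA reads only from transcribing species, weighted
  by abundance × transcription rate. Background reads come from a random
  sequence with the shuffled nucleotide composition of the ODE genes — they
  stress the identity filter rather than trivially failing the score floor.
  Substitution errors are applied per base (1% in the bundled scenarios —
  a deliberately pessimistic error level). Every read's origin is recorded.
* **Metabolites.** The target metabolite follows
  `log10(target) = b0 + coupling * z + noise * e` with `z` the standardized
  true transcription activity; the remaining metabolites are a fixed
  log-normal background shared across subjects, so with zero noise the
  target's relative abundance is strictly monotone in activity.

## Bundled scenarios and what they show

* `scenario_recovery()` — 30 subjects, one sample each, 30,000 reads of
  90 nt at 1% error, six OXC-coding species with two homologs each. One
  species is the designated dominant transcriber (always transcribing, high
  rate; the *O. formigenes* role), one is gene-rich but rarely transcribing
  (the *E. coli* role). The pipeline's transcriptomic `R` for the dominant
  species must be the largest and within 0.10 of the same statistic computed
  from true read origins (observed agreement is within about 0.01).
* `scenario_layer_contrast()` — two groups; the disease group carries the
  silent species more and the transcriber less. At the population level the
  silent species dominates DNA contributions while the transcriber dominates
  RNA contributions, in every seeded replicate — the qualitative
  gene/transcript dichotomy the contribution statistic exists to expose.

Problem sizes in the test suite (replicate counts, reads per sample for the
smaller scenarios) are chosen so the full suite exercises cohort-scale
behavior in minutes on one core; the bundled recovery scenario runs at its
stated size.

## What passing these tests does not show

The generator emulates the statistical structure the analysis assumes —
divergence-calibrated homolog families, known read origins, expression
states, substitution error. It does not emulate strain-level mixtures,
indels or frameshifts in reads, coverage bias, paired-end structure, host
contamination, or compositional coupling between species. Recovery on
synthetic cohorts therefore validates the pipeline's logic and its
thresholds against its own model assumptions, not performance on any
particular real cohort.

# Numerical and design choices

* Exhaustive search, no seed-and-extend: at desk-scale references the oracle
  property (best hit = exhaustive Smith–Waterman, exactly) holds by
  construction.
* Deduplication keeps the lexicographically smallest accession;
  dedupe is idempotent and order-independent.
* Gap-only pairs in pairwise identity are recorded as distance 1 with a
  warning; `X` residues never count as matches anywhere.
* Reads shorter than 45 nt are skipped (counted, not silently dropped);
  translated fragments shorter than 15 residues are discarded.
* Paired-end mates are treated as independent single-end reads.
* Marker coverage is judged against the shorter of marker and fragment — a
  90 nt read cannot be asked to span a 130-residue marker; requiring
  pctlength of the marker itself would make whole-centroid markers
  undetectable by construction.
* All randomness is seed-controlled; every generator output and every
  pipeline stage is byte-identical across reruns under a fixed seed.

# Known limitations

* RPKM length normalization assumes full-length reference proteins; truncated
  database entries would inflate their apparent abundance.
* The contribution statistic attributes reads, not activity: a species can
  transcribe without degrading oxalate downstream.
* Marker discovery here is a simplification of full marker-based profiling
  (greedy clustering instead of CD-Hit; sliding-window masking instead of
  BLAST screening; no quasi-markers), adequate for the failure/rescue
  analysis it supports but not a drop-in replacement for those tools.
* With repeated sampling, subject aggregation before contribution analysis
  is one defensible convention; per-sample mode is provided because the
  choice is not forced by the statistic itself.
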