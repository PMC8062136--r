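# oxatrace

Who *can* degrade oxalate in a gut microbiome, and who actually *does*?

Oxalate — the principal component of most kidney stones — is degraded in the
mammalian intestine only by microbes, through two enzyme systems: the
single-step oxalate oxidase/decarboxylase (OXDD) and the CoA-dependent
two-step pathway of formyl-CoA transferase (FRC) and oxalyl-CoA decarboxylase
(OXC). Shotgun metagenomes show which community members carry these genes,
but gene carriage and transcription diverge sharply: an abundant, gene-rich
species can be transcriptionally silent while a low-abundance specialist
transcribes the pathway whenever present. `oxatrace` is an R package for
resolving this from paired metagenome/metatranscriptome data: it detects
oxalate-degrading-enzyme (ODE) reads, attributes them to species, and
quantifies each species' population-level contribution to the function in
each omics layer.

## What the package does

* **Reference curation** — load an ODE protein-homolog reference
  (FASTA + taxonomy TSV), drop 100%-identical homologs, and compute the
  within-species vs between-species pairwise-identity analysis
  (`pct = 100(1 − d²)`, `d = sqrt(1 − f)`) that justifies the 90% alignment
  identity cutoff.
* **Translated search** — six-frame translation, exhaustive Smith–Waterman
  (BLOSUM62, gap 11/1; C++ core) against every homolog, one best hit per
  read, then the ≥ 90% identity filter.
* **Quantification** — RPKM per homolog, rolled up to species × enzyme,
  per sample and per subject (zero-including mean over a subject's samples),
  per omics layer.
* **Attribution** — gene/transcript co-detection categories per subject and
  species; population-level contribution `C_i = Σ_j z_ij / Σ_i z_ij` with
  relative scaling `R_i` for cross-layer comparison; single-copy
  deconvolution of total gene abundance into encoder taxa.
* **Marker peptides** — family clustering, unique-marker mining against a
  background proteome, the adjacent-marker merge repair for improperly
  fragmented markers, and marker-based quantification.
* **Cohort statistics** — proportion tests on prevalence, multiple-adjusted
  Mann–Whitney tests on abundance, Spearman correlation, and metabolite
  relative-abundance normalization.
* **Synthetic data** — a seeded generator for homolog references (calibrated
  intra-/inter-species identity), two-group cohorts with known per-read
  origins and expression states, and coupled metabolite tables, so every
  stage is validated against recorded ground truth.

## Worked example

Simulate a cohort in which `Species_01` is gene-rich but rarely transcribing
while `Species_02` transcribes whenever present, run the full detection
path, and compare the layers:

```r
library(oxatrace)

sc     <- scenario_layer_contrast(seed = 7, n_per_group = 6,
                                  reads_per_sample = 2000)
cohort <- generate_cohort(sc$hs, sc$design, seed = 7)
det    <- detect_cohort(cohort, sc$hs)      # search + filter + profiles

contribution_from_profiles(det$taxon_subject, "OXC", "DNA")
#> contribution_result (OXC, DNA): 4 species over 12 samples (12 positive)
#>   top relative contributions:
#>     Species_01                     R = 0.621
#>     Species_03                     R = 0.175
#>     Species_02                     R = 0.149
#>     Species_04                     R = 0.056

contribution_from_profiles(det$taxon_subject, "OXC", "RNA")
#> contribution_result (OXC, RNA): 4 species over 12 samples (8 positive)
#>   top relative contributions:
#>     Species_02                     R = 0.474
#>     Species_04                     R = 0.377
#>     Species_03                     R = 0.150
#>     Species_01                     R = 0.000
```

The gene-rich silent species dominates the metagenomic contribution
(R = 0.621) yet contributes nothing to the metatranscriptome, where the
always-transcribing species takes over (R = 0.474) — the gene/transcript
dichotomy the contribution statistic is designed to expose. The same
structure appears in the co-detection table:

```r
cod <- codetection_table(det$taxon_subject)
table(cod$category, cod$taxon)[, c("Species_01", "Species_02")]
#>                    Species_01 Species_02
#>   gene+transcript+          0          4
#>   gene+transcript-         10          0
#>   gene-transcript+          0          0
#>   gene-transcript-          2          8
```

Every subject carrying `Species_01` is gene+transcript− for it; every
subject in which `Species_02`'s gene is detected also shows its transcript.

See `vignette("oxatrace-methods")` for the model, thresholds, identity
conventions, and what the synthetic validation does and does not show.

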