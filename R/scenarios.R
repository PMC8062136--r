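#' Bundled end-to-end recovery scenario
#'
#' The reference validation cohort: 30 healthy subjects, one sample per
#' subject and layer, 30,000 reads of 90 nt per sample at 1% substitution
#' error, against a simulated OXC reference of six species with two homologs
#' each (97% intra- / 80% inter-species identity, 130-residue proteins). One
#' species is the designated dominant transcriber — always transcribing, at a
#' high rate — emulating the role of Oxalobacter formigenes; a second species
#' is gene-rich but rarely transcribing, emulating Escherichia coli; the rest
#' are minor contributors.
#'
#' @param seed RNG seed for reference and cohort.
#' @param n_subjects,reads_per_sample cohort size knobs (defaults are the
#'   validation conditions).
#' @return list with `hs` (reference), `design`, and `dominant` (the species
#'   label of the designated dominant transcriber).
#' @export
scenario_recovery <- function(seed = 1L, n_subjects = 30L,
                              reads_per_sample = 30000L) {
  hs <- generate_homolog_set(n_species = 6L, homologs_per_species = 2L,
                             intra_identity = 97, inter_identity = 80,
                             protein_length = 130L, enzyme_classes = "OXC",
                             seed = seed)
  species <- data.frame(
    species = sprintf("Species_%02d", 1:6),
    base_abundance = c(0.004, 0.012, 0.005, 0.003, 0.002, 0.002),
    transcription_rate = c(8, 1, 2, 1, 1.5, 1),
    stringsAsFactors = FALSE)
  groups <- data.frame(group = "healthy", n_subjects = n_subjects,
                       stringsAsFactors = FALSE)
  prevalence <- matrix(c(0.9, 0.9, 0.7, 0.6, 0.5, 0.4), 1L,
                       dimnames = list("healthy", species$species))
  expression <- matrix(c(1.0, 0.12, 0.35, 0.30, 0.25, 0.20), 1L,
                       dimnames = list("healthy", species$species))
  design <- cohort_design(groups, species, prevalence, expression,
                          samples_per_subject = 1L,
                          reads_per_sample = reads_per_sample,
                          read_length = 90L, error_rate = 0.01)
  list(hs = hs, design = design, dominant = "Species_01")
}

#' Bundled gene/transcript layer-contrast scenario
#'
#' Two-group cohort emulating the healthy-versus-IBD contrast: a gene-rich
#' but rarely transcribing species (high metagenomic prevalence, transcription
#' in about one carrier in ten) against an always-transcribing species that
#' is less prevalent genomically. The disease group carries the silent
#' species more often and the transcriber less often. At the population
#' level, the silent species should dominate metagenomic contributions while
#' the transcriber dominates metatranscriptomic ones.
#'
#' @param seed RNG seed for the reference.
#' @param n_per_group subjects per group.
#' @param reads_per_sample reads per sample and layer.
#' @return list with `hs`, `design`, `silent`, `transcriber` (species labels).
#' @export
scenario_layer_contrast <- function(seed = 1L, n_per_group = 12L,
                                    reads_per_sample = 3000L) {
  hs <- generate_homolog_set(n_species = 4L, homologs_per_species = 1L,
                             intra_identity = 97, inter_identity = 80,
                             protein_length = 130L, enzyme_classes = "OXC",
                             seed = seed)
  species <- data.frame(
    species = sprintf("Species_%02d", 1:4),
    base_abundance = c(0.015, 0.004, 0.003, 0.002),
    transcription_rate = c(1, 8, 1, 1),
    stringsAsFactors = FALSE)
  groups <- data.frame(group = c("healthy", "disease"),
                       n_subjects = c(n_per_group, n_per_group),
                       stringsAsFactors = FALSE)
  prevalence <- rbind(healthy = c(0.60, 0.70, 0.5, 0.4),
                      disease = c(0.95, 0.25, 0.5, 0.4))
  expression <- rbind(healthy = c(0.10, 1.0, 0.3, 0.25),
                      disease = c(0.08, 1.0, 0.3, 0.25))
  colnames(prevalence) <- colnames(expression) <- species$species
  design <- cohort_design(groups, species, prevalence, expression,
                          samples_per_subject = 1L,
                          reads_per_sample = reads_per_sample,
                          read_length = 90L, error_rate = 0.01)
  list(hs = hs, design = design,
       silent = "Species_01", transcriber = "Species_02")
}

#' Contribution result computed from ground-truth read origins
#'
#' The truth-level oracle for recovery testing: per-sample species RPKM is
#' computed from the recorded read origins (not from alignment), rolled up to
#' subjects, and fed through the same contribution statistic. Comparing this
#' against the pipeline's contribution isolates detection error (filtered or
#' misassigned reads) from sampling noise.
#'
#' @param origins origin table from [generate_cohort()] / [generate_reads()].
#' @param manifest matching manifest.
#' @param hs reference (for homolog lengths).
#' @param layer omics layer to analyse.
#' @return a [population_contribution()] result.
#' @export
truth_contribution <- function(origins, manifest, hs, layer) {
  manifest <- read_manifest(manifest)
  o <- origins[origins$layer == layer & origins$species != "background", ]
  m <- manifest[manifest$layer == layer, ]
  subjects <- sort(unique(m$subject_id))
  spp <- sort(unique(hs$info$species))
  z <- matrix(0, length(subjects), length(spp),
              dimnames = list(subjects, spp))
  if (nrow(o)) {
    len <- nchar(hs$sequences)[o$homolog]
    total <- m$total_reads[match(o$sample_id, m$sample_id)]
    subj <- m$subject_id[match(o$sample_id, m$sample_id)]
    val <- rpkm(1L, len, total)
    agg <- tapply(val, list(subj, o$species), sum)
    agg[is.na(agg)] <- 0
    # subject mean over its samples
    nsamp <- tapply(m$sample_id, m$subject_id, function(x) length(unique(x)))
    agg <- agg / as.numeric(nsamp[rownames(agg)])
    z[rownames(agg), colnames(agg)] <- agg
  }
  population_contribution(z, enzyme_class = hs$info$enzyme_class[1L],
                          layer = layer)
}
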