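#' Pipeline configuration
#'
#' Collects the paths and thresholds shared by the pipeline stages. Any field
#' can be overridden per call; [load_pipeline_config()] reads the same
#' structure from a YAML file.
#'
#' @param reference_fasta,taxonomy reference inputs (see [load_homologs()]).
#' @param reads_dir directory holding per-sample reads files.
#' @param manifest manifest TSV path (see [read_manifest()]).
#' @param out_dir output directory for all artifacts.
#' @param min_identity percent-identity filter for read hits.
#' @param min_reads minimum hits per homolog for detection.
#' @param score_floor Smith-Waterman score floor.
#' @param marker_id,pctlength marker quantification thresholds.
#' @param marker_window,marker_bg_identity,marker_min_len,merge_gap
#'   marker discovery settings; `merge_markers` applies the adjacent-marker
#'   repair after discovery.
#' @param background_fasta optional background proteome for marker discovery.
#' @param adjust_method multiple-testing adjustment for group comparisons.
#' @param detection_conditional compare abundances among detected subjects
#'   only (the convention for detection-conditional panels).
#' @param max_identity_n skip the all-vs-all identity matrix when the
#'   deduplicated reference exceeds this many records.
#' @param seed seed for stages that simulate.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_fasta = NULL, taxonomy = NULL,
                            reads_dir = NULL, manifest = NULL,
                            out_dir = "oxatrace_out",
                            min_identity = 90, min_reads = 1L,
                            score_floor = 40L, marker_id = 90,
                            pctlength = 0.5, marker_window = 30L,
                            marker_bg_identity = 90, marker_min_len = 8L,
                            merge_gap = 1L, merge_markers = TRUE,
                            background_fasta = NULL, adjust_method = "BH",
                            detection_conditional = TRUE,
                            max_identity_n = 200L, seed = NULL) {
  cfg <- as.list(environment())
  stopifnot(min_identity >= 0 && min_identity <= 100,
            min_reads >= 1, pctlength > 0 && pctlength <= 1,
            marker_id >= 0 && marker_id <= 100)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @param ... overrides applied on top of the file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  bad <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

ensure_dir <- function(d) {
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

log_msg <- function(...) message(sprintf("[oxatrace] %s", sprintf(...)))

#' Stage: curate the homolog reference
#'
#' Loads and validates the reference, removes 100%-identical homologs, and
#' (for references small enough for all-vs-all alignment) writes the pairwise
#' identity matrix and the within/between-species identity summary that
#' motivates the 90% alignment-identity cutoff. Artifacts go to
#' `<out_dir>/reference/`. Re-running on the same input reproduces identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return the deduplicated [homolog_set()], invisibly.
#' @export
run_curate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hs <- load_homologs(config$reference_fasta, config$taxonomy)
  hs <- dedupe_identical(hs)
  dir <- ensure_dir(file.path(config$out_dir, "reference"))
  write_homolog_set(hs, file.path(dir, "homologs_dedup.fasta"),
                    file.path(dir, "homologs_dedup.tsv"))
  map <- attr(hs, "dedupe_map")
  write_tsv(map, file.path(dir, "dedupe_map.tsv"))
  log_msg("curate: %d homologs after deduplication (%d removed)",
          length(hs), nrow(map))
  if (length(hs) >= 2 && length(hs) <= config$max_identity_n) {
    im <- pairwise_identity(hs)
    pm <- data.frame(accession = im$labels, im$pct_identity,
                     check.names = FALSE)
    write_tsv(pm, file.path(dir, "identity_matrix.tsv"))
    rk <- identity_by_rank(im, hs, cutoff = config$min_identity)
    write_tsv(rk$summary, file.path(dir, "identity_by_rank.tsv"))
    log_msg("curate: identity summary at cutoff %s%% written",
            config$min_identity)
  }
  invisible(hs)
}

read_curated <- function(config) {
  dir <- file.path(config$out_dir, "reference")
  fa <- file.path(dir, "homologs_dedup.fasta")
  if (!file.exists(fa)) return(run_curate(config))
  load_homologs(fa, file.path(dir, "homologs_dedup.tsv"),
                provenance = "curated reference")
}

#' Stage: translated search and quantification over a cohort
#'
#' Runs the six-frame best-hit search with the identity filter on every
#' manifest sample, writes per-sample hit tables, and builds the abundance
#' profiles: per-homolog per sample, per-homolog per subject (mean over the
#' subject's samples, within layer), and the species x enzyme rollups of
#' both. Artifacts go to `<out_dir>/hits/` and `<out_dir>/profiles/`.
#'
#' @param config a [pipeline_config()]; `reads_dir` must contain one reads
#'   file per manifest row (`file` column, or `<sample_id>_<layer>.fasta`).
#' @return list of profile data frames, invisibly.
#' @export
run_detect <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- read_manifest(config$manifest)
  hs <- read_curated(config)
  files <- manifest$file %||%
    sprintf("%s_%s.fasta", manifest$sample_id, manifest$layer)
  paths <- file.path(config$reads_dir, files)
  missing <- !file.exists(paths)
  if (any(missing))
    stopf("reads file(s) missing for sample(s): %s",
          paste(manifest$sample_id[missing], collapse = ", "))
  hits_dir <- ensure_dir(file.path(config$out_dir, "hits"))
  prof_dir <- ensure_dir(file.path(config$out_dir, "profiles"))
  sample_profiles <- vector("list", nrow(manifest))
  log_msg("detect: %d samples; identity filter >= %s%%, score floor %d",
          nrow(manifest), config$min_identity, config$score_floor)
  for (i in seq_len(nrow(manifest))) {
    reads <- read_reads(paths[i], sample_id = manifest$sample_id[i])
    hits <- search_reads(reads, hs, score_floor = config$score_floor)
    hits <- filter_identity(hits, config$min_identity)
    write_hits(hits, file.path(hits_dir, sprintf(
      "%s_%s_hits.tsv", manifest$sample_id[i], manifest$layer[i])))
    sample_profiles[[i]] <- profile_sample(
      hits, hs, manifest$sample_id[i], manifest$total_reads[i],
      manifest$layer[i], min_reads = config$min_reads)
  }
  homolog_sample <- do.call(rbind, c(sample_profiles,
                                     list(make.row.names = FALSE)))
  homolog_subject <- aggregate_subjects(homolog_sample, manifest)
  taxon_sample <- rollup_taxon(homolog_sample, hs)
  taxon_subject <- rollup_taxon(homolog_subject, hs)
  profiles <- list(homolog_sample = homolog_sample,
                   homolog_subject = homolog_subject,
                   taxon_sample = taxon_sample,
                   taxon_subject = taxon_subject)
  for (nm in names(profiles))
    write_tsv(profiles[[nm]], file.path(prof_dir, sprintf("%s.tsv", nm)))
  invisible(profiles)
}

#' In-memory detection and quantification of a simulated cohort
#'
#' Equivalent of [run_detect()] for a cohort held in memory (as returned by
#' [generate_cohort()]): runs the translated best-hit search with the
#' identity filter on every sample and builds the homolog- and taxon-level
#' profiles without touching disk.
#'
#' @param cohort a [generate_cohort()] result.
#' @param hs the reference the cohort was simulated from.
#' @param min_identity,min_reads,score_floor see [pipeline_config()].
#' @return list with `hits` (filtered, all samples) and the four profile
#'   data frames of [run_detect()].
#' @export
detect_cohort <- function(cohort, hs, min_identity = 90, min_reads = 1L,
                          score_floor = 40L) {
  manifest <- read_manifest(cohort$manifest)
  profiles <- vector("list", nrow(manifest))
  hits_all <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    key <- paste(manifest$sample_id[i], manifest$layer[i], sep = "_")
    reads <- cohort$reads[[key]]
    if (is.null(reads)) stopf("cohort lacks reads for %s", key)
    hits <- filter_identity(search_reads(reads, hs, score_floor = score_floor),
                            min_identity)
    hits$sample_id <- if (nrow(hits)) manifest$sample_id[i] else character()
    hits$layer <- if (nrow(hits)) manifest$layer[i] else character()
    hits_all[[i]] <- hits
    profiles[[i]] <- profile_sample(hits, hs, manifest$sample_id[i],
                                    manifest$total_reads[i],
                                    manifest$layer[i], min_reads = min_reads)
  }
  homolog_sample <- do.call(rbind, c(profiles, list(make.row.names = FALSE)))
  homolog_subject <- aggregate_subjects(homolog_sample, manifest)
  list(hits = do.call(rbind, c(hits_all, list(make.row.names = FALSE))),
       homolog_sample = homolog_sample,
       homolog_subject = homolog_subject,
       taxon_sample = rollup_taxon(homolog_sample, hs),
       taxon_subject = rollup_taxon(homolog_subject, hs))
}

#' Stage: co-detection and population-level contribution
#'
#' Consumes subject-level taxon profiles and emits the co-detection table
#' (subjects with both layers) and, per enzyme class and layer, the
#' population-level contributions C with their relative scale R. Relative
#' contributions are reported to 3 decimals; ties for the largest contributor
#' are reported as ties.
#'
#' @param config a [pipeline_config()] whose `out_dir` holds `run_detect()`
#'   outputs (or pass `profiles` directly).
#' @param profiles optional taxon-level subject profiles data frame.
#' @return list with `codetection` and `contributions` data frames,
#'   invisibly.
#' @export
run_attribute <- function(config, profiles = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(profiles)) {
    path <- file.path(config$out_dir, "profiles", "taxon_subject.tsv")
    if (!file.exists(path)) stopf("no profiles at %s; run run_detect first", path)
    profiles <- read_tsv(path)
  }
  dir <- ensure_dir(file.path(config$out_dir, "attribution"))
  cod <- codetection_table(profiles)
  n_excl <- attr(cod, "n_excluded_subjects")
  if (n_excl > 0)
    log_msg("attribute: %d subject(s) without both layers excluded", n_excl)
  write_tsv(cod, file.path(dir, "codetection.tsv"))
  combos <- unique(profiles[c("enzyme_class", "layer")])
  contribs <- list()
  for (k in seq_len(nrow(combos))) {
    cr <- contribution_from_profiles(profiles, combos$enzyme_class[k],
                                     combos$layer[k])
    contribs[[k]] <- data.frame(
      taxon = names(cr$C), enzyme_class = combos$enzyme_class[k],
      layer = combos$layer[k], C = unname(cr$C),
      R = round(unname(cr$R), 3), n_positive = cr$n_positive_samples,
      stringsAsFactors = FALSE)
  }
  contribs <- do.call(rbind, c(contribs, list(make.row.names = FALSE)))
  write_tsv(contribs, file.path(dir, "contributions.tsv"))
  invisible(list(codetection = cod, contributions = contribs))
}

#' Stage: cohort group comparisons
#'
#' For every taxon x enzyme x layer, compares the first two manifest groups:
#' prevalence by two-proportion chi-square, and abundance by Mann-Whitney —
#' among detected subjects only when `detection_conditional` is set (the
#' convention for detection-conditional abundance panels), otherwise among
#' all subjects. P-values are adjusted per (enzyme, layer, test) family with
#' the configured method.
#'
#' @param config a [pipeline_config()].
#' @param profiles optional taxon-level subject profiles data frame.
#' @return comparisons data frame, invisibly.
#' @export
run_compare <- function(config, profiles = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(profiles)) {
    path <- file.path(config$out_dir, "profiles", "taxon_subject.tsv")
    if (!file.exists(path)) stopf("no profiles at %s; run run_detect first", path)
    profiles <- read_tsv(path)
  }
  manifest <- read_manifest(config$manifest)
  subj_group <- unique(manifest[c("subject_id", "group")])
  groups <- unique(subj_group$group)
  if (length(groups) < 2L) stopf("need two groups to compare")
  g1 <- groups[1L]; g2 <- groups[2L]
  s1 <- subj_group$subject_id[subj_group$group == g1]
  s2 <- subj_group$subject_id[subj_group$group == g2]
  if (!length(s1) || !length(s2)) stopf("a group has zero subjects")
  rows <- list()
  combos <- unique(profiles[c("taxon", "enzyme_class", "layer")])
  for (k in seq_len(nrow(combos))) {
    p <- profiles[profiles$taxon == combos$taxon[k] &
                    profiles$enzyme_class == combos$enzyme_class[k] &
                    profiles$layer == combos$layer[k], ]
    v1 <- setNames(rep(0, length(s1)), s1)
    v2 <- setNames(rep(0, length(s2)), s2)
    v1[intersect(p$subject_id, s1)] <-
      p$rpkm[match(intersect(p$subject_id, s1), p$subject_id)]
    v2[intersect(p$subject_id, s2)] <-
      p$rpkm[match(intersect(p$subject_id, s2), p$subject_id)]
    label <- sprintf("%s %s %s", combos$taxon[k], combos$enzyme_class[k],
                     combos$layer[k])
    prev <- prevalence_test(sum(v1 > 0), length(v1), sum(v2 > 0), length(v2),
                            comparison = label)
    x <- if (config$detection_conditional) v1[v1 > 0] else v1
    y <- if (config$detection_conditional) v2[v2 > 0] else v2
    abund <- if (length(x) && length(y)) abundance_test(x, y, comparison = label)
             else group_comparison(label, "Mann-Whitney", NA_real_, NA_real_,
                                   length(x), length(y))
    prev$panel <- sprintf("prevalence %s %s", combos$enzyme_class[k],
                          combos$layer[k])
    abund$panel <- sprintf("abundance %s %s", combos$enzyme_class[k],
                           combos$layer[k])
    rows[[k]] <- rbind(cbind(combos[k, ], prev, row.names = NULL),
                       cbind(combos[k, ], abund, row.names = NULL))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  for (panel in unique(out$panel)) {
    sel <- out$panel == panel & !is.na(out$p_value)
    out$p_adjusted[sel] <- adjust_p(out$p_value[sel],
                                    method = config$adjust_method)
  }
  dir <- ensure_dir(file.path(config$out_dir, "comparisons"))
  write_tsv(out, file.path(dir, "group_comparisons.tsv"))
  log_msg("compare: %s vs %s, %d comparisons, adjust = %s",
          g1, g2, nrow(combos), config$adjust_method)
  invisible(out)
}

#' Stage: marker discovery and quantification
#'
#' Clusters the curated homologs into families, mines marker peptides for
#' each family centroid against the configured background proteome (which
#' must exclude the homolog set itself; without one, whole centroids serve
#' as markers), optionally applies the adjacent-marker merge repair, and
#' quantifies every manifest sample against the markers.
#'
#' @param config a [pipeline_config()].
#' @return list with `families`, `markers`, and `quantification`, invisibly.
#' @export
run_markers <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hs <- read_curated(config)
  manifest <- read_manifest(config$manifest)
  fams <- cluster_homologs(hs)
  centroids <- attr(fams, "centroids")
  bg <- if (!is.null(config$background_fasta))
    as.character(Biostrings::readAAStringSet(config$background_fasta))
  else character()
  markers <- list()
  for (fid in names(centroids)) {
    mk <- find_markers(fid, centroids[[fid]], bg,
                       window = config$marker_window,
                       bg_identity = config$marker_bg_identity,
                       min_marker = config$marker_min_len)
    if (config$merge_markers && nrow(mk))
      mk <- merge_adjacent(mk, centroids[[fid]], max_gap = config$merge_gap)
    markers[[fid]] <- mk
  }
  markers <- do.call(rbind, c(markers, list(make.row.names = FALSE)))
  dir <- ensure_dir(file.path(config$out_dir, "markers"))
  write_tsv(fams, file.path(dir, "families.tsv"))
  if (nrow(markers)) write_markers(markers, file.path(dir, "markers.fasta"))
  quant <- list()
  if (nrow(markers)) {
    files <- manifest$file %||%
      sprintf("%s_%s.fasta", manifest$sample_id, manifest$layer)
    for (i in seq_len(nrow(manifest))) {
      reads <- read_reads(file.path(config$reads_dir, files[i]))
      q <- quantify_markers(reads, markers, manifest$total_reads[i],
                            id = config$marker_id,
                            pctlength = config$pctlength,
                            score_floor = config$score_floor)
      q$sample_id <- manifest$sample_id[i]
      q$layer <- manifest$layer[i]
      quant[[i]] <- q
    }
  }
  quant <- if (length(quant))
    do.call(rbind, c(quant, list(make.row.names = FALSE)))
  else data.frame()
  if (nrow(quant)) write_tsv(quant, file.path(dir, "marker_rpkm.tsv"))
  log_msg("markers: %d families, %d markers", length(centroids), nrow(markers))
  invisible(list(families = fams, markers = markers, quantification = quant))
}

#' Stage: simulate a bundled scenario to disk
#'
#' Writes a complete synthetic cohort (reads, manifest, reference, truth) for
#' one of the bundled scenarios, ready for `run_curate`/`run_detect`.
#'
#' @param config a [pipeline_config()] providing `out_dir` and `seed`.
#' @param scenario `"recovery"` or `"layer_contrast"`.
#' @param ... scenario size overrides (see [scenario_recovery()]).
#' @return the [generate_cohort()] result, invisibly.
#' @export
run_simulate <- function(config, scenario = c("recovery", "layer_contrast"),
                         ...) {
  stopifnot(inherits(config, "pipeline_config"))
  scenario <- match.arg(scenario)
  seed <- config$seed %||% 1L
  sc <- switch(scenario,
               recovery = scenario_recovery(seed = seed, ...),
               layer_contrast = scenario_layer_contrast(seed = seed, ...))
  dir <- ensure_dir(file.path(config$out_dir, "simulated"))
  write_homolog_set(sc$hs, file.path(dir, "reference.fasta"),
                    file.path(dir, "taxonomy.tsv"))
  cohort <- generate_cohort(sc$hs, sc$design, seed = seed, out_dir = dir)
  log_msg("simulate: scenario %s written to %s (%d samples)",
          scenario, dir, nrow(cohort$manifest))
  invisible(cohort)
}
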