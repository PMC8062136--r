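#' Read and validate a sample manifest
#'
#' The manifest maps samples to subjects, group labels and omics layers.
#' Required columns: `sample_id`, `subject_id`, `group`, `layer` (`DNA` or
#' `RNA`), `total_reads` (quality-filtered reads in the sample, the RPKM
#' denominator). An optional `file` column gives the reads file per sample.
#'
#' @param path manifest TSV, or a data frame to validate in place.
#' @return validated manifest data frame.
#' @export
read_manifest <- function(path) {
  m <- if (is.data.frame(path)) path else read_tsv(path)
  required <- c("sample_id", "subject_id", "group", "layer", "total_reads")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols))
    stopf("manifest lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (!all(m$layer %in% c("DNA", "RNA")))
    stopf("manifest layer must be DNA or RNA")
  if (any(m$total_reads < 1)) stopf("manifest total_reads must be >= 1")
  key <- paste(m$sample_id, m$layer)
  if (anyDuplicated(key))
    stopf("duplicated (sample_id, layer): %s",
          paste(unique(key[duplicated(key)]), collapse = ", "))
  m
}

#' Reads per kilobase of reference per million sample reads
#'
#' `rpkm = hits / ((3 * protein_len_aa / 1000) * (total_reads / 1e6))`. The
#' reference length is expressed in nucleotides as three times the amino-acid
#' length, keeping reads and reference in the same unit.
#'
#' @param hit_count number of identity-passing best hits (vectorized).
#' @param protein_len_aa reference protein length in residues (>= 1).
#' @param total_reads total quality-filtered reads in the sample (>= 1).
#' @return RPKM value(s).
#' @export
rpkm <- function(hit_count, protein_len_aa, total_reads) {
  if (any(total_reads < 1)) stopf("total_reads must be >= 1")
  if (any(protein_len_aa < 1)) stopf("protein_len_aa must be >= 1")
  hit_count / ((3 * protein_len_aa / 1000) * (total_reads / 1e6))
}

#' Per-homolog abundance profile of one sample
#'
#' Counts identity-passing best hits per homolog and converts them to RPKM.
#' Homologs with no hits are present with value 0, so profiles from different
#' samples share one axis. Homologs hit fewer than `min_reads` times are
#' treated as undetected (count set to 0); the default of 1 means a single
#' passing read establishes detection.
#'
#' @param hits filtered hits of this sample (see [filter_identity()]).
#' @param hs the [homolog_set()] searched against.
#' @param sample_id sample label.
#' @param total_reads RPKM denominator for this sample.
#' @param layer `"DNA"` or `"RNA"`.
#' @param min_reads minimum hit count for a homolog to be counted.
#' @return data frame: `accession`, `sample_id`, `layer`, `rpkm`.
#' @export
profile_sample <- function(hits, hs, sample_id, total_reads, layer,
                           min_reads = 1L) {
  stopifnot(inherits(hs, "homolog_set"))
  acc <- hs$info$accession
  unknown <- setdiff(hits$protein_accession, acc)
  if (length(unknown))
    stopf("hit(s) reference unknown accession(s): %s",
          paste(unknown, collapse = ", "))
  counts <- table(factor(hits$protein_accession, levels = acc))
  counts <- as.integer(counts)
  counts[counts < min_reads] <- 0L
  data.frame(accession = acc, sample_id = sample_id, layer = layer,
             rpkm = rpkm(counts, nchar(hs$sequences[acc]), total_reads),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Subject-level profile as the mean over a subject's samples
#'
#' When a subject was sampled at several timepoints, the subject is
#' represented by the arithmetic mean of its per-sample values within one
#' omics layer. The mean includes zero samples: a subject with one positive
#' sample out of three is averaged over all three.
#'
#' @param profiles row-bound per-sample profiles (from [profile_sample()] or
#'   [rollup_taxon()]) belonging to one subject; must all share one layer.
#' @param subject_id subject label for the output.
#' @return data frame: axis column (`accession` or `taxon` + `enzyme_class`),
#'   `subject_id`, `layer`, `rpkm`.
#' @export
aggregate_subject <- function(profiles, subject_id) {
  if (length(unique(profiles$layer)) > 1L)
    stopf("cannot aggregate across omics layers")
  n_samples <- length(unique(profiles$sample_id))
  axis_cols <- intersect(c("accession", "taxon", "enzyme_class"), names(profiles))
  key <- do.call(paste, c(profiles[axis_cols], sep = "\r"))
  sums <- tapply(profiles$rpkm, key, sum)
  first <- !duplicated(key)
  out <- profiles[first, axis_cols, drop = FALSE]
  out$subject_id <- subject_id
  out$layer <- profiles$layer[1L]
  out$rpkm <- as.numeric(sums[key[first]]) / n_samples
  rownames(out) <- NULL
  out
}

# subject aggregation over a whole cohort, layer by layer
aggregate_subjects <- function(profiles, manifest) {
  manifest <- read_manifest(manifest)
  map <- manifest[match(paste(profiles$sample_id, profiles$layer),
                        paste(manifest$sample_id, manifest$layer)), ]
  if (anyNA(map$subject_id)) stopf("profile sample(s) missing from manifest")
  parts <- split(seq_len(nrow(profiles)),
                 list(map$subject_id, profiles$layer), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(i)
    aggregate_subject(profiles[i, , drop = FALSE], map$subject_id[i[1L]])))
  rownames(out) <- NULL
  out
}

#' Roll homolog profiles up to species x enzyme class
#'
#' Sums homolog RPKM within each (species, enzyme class) pair. Homologs
#' without a species name aggregate at their lowest named rank, labeled
#' `"<name> (<rank>)"`; homologs with no named rank at all are labeled
#' `"unclassified"`.
#'
#' @param profile per-homolog profile rows (any number of samples/subjects).
#' @param hs the matching [homolog_set()].
#' @return data frame: `taxon`, `enzyme_class`, id column(s) carried over
#'   (`sample_id` or `subject_id`), `layer`, `rpkm`.
#' @export
rollup_taxon <- function(profile, hs) {
  stopifnot(inherits(hs, "homolog_set"))
  idx <- match(profile$accession, hs$info$accession)
  if (anyNA(idx)) stopf("profile accession(s) missing from homolog set")
  taxon <- taxon_label(hs)[idx]
  ec <- hs$info$enzyme_class[idx]
  id_col <- intersect(c("sample_id", "subject_id"), names(profile))
  key <- paste(taxon, ec, profile[[id_col]], profile$layer, sep = "\r")
  sums <- tapply(profile$rpkm, key, sum)
  first <- !duplicated(key)
  out <- data.frame(taxon = taxon[first], enzyme_class = ec[first],
                    stringsAsFactors = FALSE)
  out[[id_col]] <- profile[[id_col]][first]
  out$layer <- profile$layer[first]
  out$rpkm <- as.numeric(sums[key[first]])
  rownames(out) <- NULL
  out
}

# display label per homolog: species, or lowest named rank
taxon_label <- function(hs) {
  info <- hs$info
  lab <- info$species
  for (rank in rev(TAXONOMY_RANKS[-length(TAXONOMY_RANKS)])) {
    blank <- !nzchar(lab)
    if (!any(blank)) break
    named <- blank & nzchar(info[[rank]])
    lab[named] <- sprintf("%s (%s)", info[[rank]][named], rank)
  }
  lab[!nzchar(lab)] <- "unclassified"
  lab
}

#' Detection call from a subject-level RPKM value
#'
#' An enzyme (or a species' enzyme) is called detected in a subject when the
#' subject-level RPKM is strictly positive, i.e. at least one
#' identity-passing best hit in at least one of the subject's samples.
#'
#' @param value subject-level RPKM value(s), >= 0.
#' @return logical vector.
#' @export
is_detected <- function(value) {
  if (any(value < 0)) stopf("RPKM must be >= 0")
  value > 0
}
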