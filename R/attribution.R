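CODETECT_LEVELS <- c("gene+transcript+", "gene+transcript-",
                     "gene-transcript+", "gene-transcript-")

#' Gene/transcript co-detection category
#'
#' Classifies a subject's status for one species' enzyme by whether the gene
#' (metagenome) and the transcript (metatranscriptome) are detected: the 2x2
#' truth table `gene+transcript+`, `gene+transcript-`, `gene-transcript+`,
#' `gene-transcript-`.
#'
#' @param gene_detected,transcript_detected logical vectors (recycled).
#' @return factor with the four co-detection levels.
#' @export
codetect <- function(gene_detected, transcript_detected) {
  stopifnot(is.logical(gene_detected), is.logical(transcript_detected))
  lab <- paste0(ifelse(gene_detected, "gene+", "gene-"),
                ifelse(transcript_detected, "transcript+", "transcript-"))
  factor(lab, levels = CODETECT_LEVELS)
}

#' Co-detection table over a cohort
#'
#' Builds the per-subject, per-species, per-enzyme co-detection
#' classification from subject-level taxon profiles. Only subjects with both
#' omics layers are classified; subjects missing a layer are excluded and
#' counted in the `n_excluded_subjects` attribute.
#'
#' @param subject_profiles taxon-level subject profiles (see
#'   [rollup_taxon()] and [aggregate_subject()]) containing both layers.
#' @return data frame: `subject_id`, `taxon`, `enzyme_class`, `category`.
#' @export
codetection_table <- function(subject_profiles) {
  p <- subject_profiles
  stopifnot(all(c("taxon", "enzyme_class", "subject_id", "layer", "rpkm") %in%
                  names(p)))
  by_subj <- split(p$layer, p$subject_id)
  complete <- names(by_subj)[vapply(by_subj, function(l)
    all(c("DNA", "RNA") %in% l), TRUE)]
  n_excluded <- length(by_subj) - length(complete)
  p <- p[p$subject_id %in% complete, , drop = FALSE]
  key <- paste(p$subject_id, p$taxon, p$enzyme_class, sep = "\r")
  dna <- p[p$layer == "DNA", ]
  rna <- p[p$layer == "RNA", ]
  kd <- paste(dna$subject_id, dna$taxon, dna$enzyme_class, sep = "\r")
  kr <- paste(rna$subject_id, rna$taxon, rna$enzyme_class, sep = "\r")
  all_keys <- union(kd, kr)
  g <- setNames(rep(0, length(all_keys)), all_keys)
  t <- g
  g[kd] <- dna$rpkm
  t[kr] <- rna$rpkm
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  out <- data.frame(subject_id = parts[, 1L], taxon = parts[, 2L],
                    enzyme_class = parts[, 3L],
                    category = codetect(is_detected(unname(g)),
                                        is_detected(unname(t))),
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$taxon, out$enzyme_class), ]
  rownames(out) <- NULL
  attr(out, "n_excluded_subjects") <- n_excluded
  out
}

#' Per-sample contribution shares of species to an enzyme
#'
#' In one sample, the contribution of species i is its share of the total
#' enzyme RPKM: `c_i = z_i / sum(z)` when the sample is enzyme-positive
#' (`sum(z) > 0`), so shares of a positive sample sum to 1; all shares of an
#' enzyme-negative sample are 0.
#'
#' @param z non-negative per-species RPKM vector for one sample.
#' @return share vector of the same length (and names).
#' @export
contribution_per_sample <- function(z) {
  if (any(z < 0)) stopf("RPKM values must be >= 0")
  s <- sum(z)
  if (s > 0) z / s else z * 0
}

#' Population-level contribution of species to an enzyme
#'
#' Sums per-sample shares over samples: `C_i = sum_j c_ij`, so a species'
#' population-level contribution grows with both its prevalence and its
#' within-sample dominance. `sum(C)` equals the number of enzyme-positive
#' samples exactly. Because `C` increases monotonically with the number of
#' samples, the relative contribution `R_i = C_i / sum(C)` is used whenever
#' cohorts or omics layers of different size are compared.
#'
#' @param z matrix of per-species RPKM (rows = samples or subjects,
#'   columns = species), or a matrix of shares if `shares = TRUE`.
#' @param shares set to `TRUE` when `z` already holds per-sample shares.
#' @param enzyme_class,layer optional labels carried into the result.
#' @return object of class `contribution_result`: list with per-sample share
#'   matrix `shares`, totals `C`, relative contributions `R`,
#'   `n_positive_samples`, and the labels.
#' @export
population_contribution <- function(z, shares = FALSE, enzyme_class = NA_character_,
                                    layer = NA_character_) {
  z <- as.matrix(z)
  if (any(z < 0)) stopf("RPKM values must be >= 0")
  cmat <- if (shares) z else t(apply(z, 1L, contribution_per_sample))
  if (ncol(z) == 1L) cmat <- matrix(cmat, ncol = 1L, dimnames = dimnames(z))
  C <- colSums(cmat)
  n_positive <- sum(rowSums(cmat) > 0)
  R <- if (sum(C) > 0) C / sum(C) else C * 0
  structure(list(shares = cmat, C = C, R = R,
                 n_positive_samples = n_positive,
                 enzyme_class = enzyme_class, layer = layer),
            class = "contribution_result")
}

#' @export
print.contribution_result <- function(x, ...) {
  cat(sprintf("contribution_result (%s, %s): %d species over %d samples (%d positive)\n",
              x$enzyme_class, x$layer, length(x$C), nrow(x$shares),
              x$n_positive_samples))
  top <- sort(x$R, decreasing = TRUE)
  top <- top[seq_len(min(5L, length(top)))]
  cat("  top relative contributions:\n")
  for (nm in names(top)) cat(sprintf("    %-30s R = %.3f\n", nm, top[nm]))
  invisible(x)
}

#' Contribution result from cohort profiles
#'
#' Convenience wrapper: builds the sample-by-species RPKM matrix for one
#' enzyme class and layer from taxon-level profiles and computes
#' [population_contribution()]. Subject-level profiles (the default produced
#' by the pipeline) make the "samples" of the contribution formula one row
#' per subject; per-sample profiles can be passed for per-sample mode.
#'
#' @param taxon_profiles long data frame from [rollup_taxon()].
#' @param enzyme_class enzyme class to analyse.
#' @param layer `"DNA"` or `"RNA"`.
#' @return a `contribution_result`.
#' @export
contribution_from_profiles <- function(taxon_profiles, enzyme_class, layer) {
  p <- taxon_profiles[taxon_profiles$enzyme_class == enzyme_class &
                        taxon_profiles$layer == layer, , drop = FALSE]
  id_col <- intersect(c("subject_id", "sample_id"), names(p))[1L]
  ids <- sort(unique(p[[id_col]]))
  taxa <- sort(unique(p$taxon))
  z <- matrix(0, length(ids), length(taxa), dimnames = list(ids, taxa))
  z[cbind(match(p[[id_col]], ids), match(p$taxon, taxa))] <- p$rpkm
  population_contribution(z, enzyme_class = enzyme_class, layer = layer)
}

#' Rescale contribution totals for cross-cohort comparison
#'
#' Normalizes each cohort's (or layer's) totals `C` to sum 1 independently,
#' making contributions comparable across cohorts of different size. Rows of
#' all zeros are returned as zeros with a warning.
#'
#' @param C numeric vector of totals, or a matrix/data frame with one row per
#'   cohort or layer and one column per species.
#' @return object of the same shape with each row summing to 1 (or 0).
#' @export
relative_scale <- function(C) {
  if (is.null(dim(C))) {
    s <- sum(C)
    if (s == 0) { warnf("all-zero contribution totals"); return(C * 0) }
    return(C / s)
  }
  C <- as.matrix(C)
  s <- rowSums(C)
  if (any(s == 0)) warnf("all-zero contribution row(s): %s",
                         paste(rownames(C)[s == 0], collapse = ", "))
  sweep(C, 1L, ifelse(s == 0, 1, s), "/")
}

#' Single-copy deconvolution of a gene's abundance into taxa
#'
#' Attributes a sample's total gene abundance to the species known to encode
#' the gene, proportionally to their relative abundance in the community,
#' under the assumption of one gene copy per genome (used when per-genome
#' copy numbers are unknown). Species not encoding the gene receive 0; when
#' no encoder is present, everything is 0.
#'
#' @param function_abundance total gene RPKM of one sample (scalar).
#' @param taxa_abundance named non-negative vector of species relative
#'   abundances (summing to <= 1).
#' @param encoders character vector of species encoding the gene (subset of
#'   `names(taxa_abundance)`).
#' @return named vector of attributed abundance per species in
#'   `taxa_abundance`.
#' @export
deconvolve_single_copy <- function(function_abundance, taxa_abundance, encoders) {
  stopifnot(length(function_abundance) == 1L, function_abundance >= 0,
            !is.null(names(taxa_abundance)))
  if (any(taxa_abundance < 0)) stopf("taxa abundances must be >= 0")
  if (sum(taxa_abundance) > 1 + 1e-8)
    stopf("taxa relative abundances must sum to <= 1")
  bad <- setdiff(encoders, names(taxa_abundance))
  if (length(bad)) stopf("encoder(s) not in taxa table: %s",
                         paste(bad, collapse = ", "))
  out <- taxa_abundance * 0
  denom <- sum(taxa_abundance[encoders])
  if (denom > 0)
    out[encoders] <- function_abundance * taxa_abundance[encoders] / denom
  out
}
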