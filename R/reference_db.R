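#' Construct a homolog reference set
#'
#' A homolog set couples the amino-acid sequences of oxalate-degrading enzyme
#' (ODE) protein homologs with their enzyme class (OXDD, FRC or OXC) and
#' taxonomic lineage. It is the reference database every downstream stage
#' (translated search, quantification, marker mining) works against.
#'
#' @param info data frame with columns `accession`, `enzyme_class` and the
#'   taxonomy ranks `superkingdom` ... `species` (empty string = unknown rank).
#' @param sequences named character vector of amino-acid sequences (20
#'   standard residues plus `X`); names must match `info$accession`.
#' @param provenance free-text description of the source (kept as metadata).
#' @return an object of class `homolog_set`.
#' @export
homolog_set <- function(info, sequences, provenance = "") {
  stopifnot(is.data.frame(info), is.character(sequences))
  required <- c("accession", "enzyme_class", TAXONOMY_RANKS)
  missing_cols <- setdiff(required, names(info))
  if (length(missing_cols))
    stopf("taxonomy table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  info <- info[required]
  for (col in required) info[[col]] <- as.character(info[[col]])
  info[is.na(info)] <- ""
  if (anyDuplicated(info$accession))
    stopf("duplicated accession(s): %s",
          paste(unique(info$accession[duplicated(info$accession)]), collapse = ", "))
  bad_class <- setdiff(unique(info$enzyme_class), ENZYME_CLASSES)
  if (length(bad_class))
    stopf("unknown enzyme class(es): %s", paste(bad_class, collapse = ", "))
  if (!setequal(names(sequences), info$accession))
    stopf("sequence names and taxonomy accessions differ")
  sequences <- sequences[info$accession]
  if (any(!nzchar(sequences))) stopf("empty sequence(s) in homolog set")
  bad <- !grepl(paste0("^[", paste(AA_STANDARD, collapse = ""), "X]+$"), sequences)
  if (any(bad))
    stopf("invalid residues in: %s", paste(names(sequences)[bad], collapse = ", "))
  structure(list(info = info, sequences = sequences, provenance = provenance),
            class = "homolog_set")
}

#' @export
print.homolog_set <- function(x, ...) {
  cat(sprintf("homolog_set: %d proteins (%s)\n", length(x$sequences),
              paste(sprintf("%s: %d", names(table(x$info$enzyme_class)),
                            table(x$info$enzyme_class)), collapse = ", ")))
  n_sp <- length(unique(x$info$species[nzchar(x$info$species)]))
  cat(sprintf("  %d named species; provenance: %s\n", n_sp,
              if (nzchar(x$provenance)) x$provenance else "<none>"))
  invisible(x)
}

#' @export
length.homolog_set <- function(x) length(x$sequences)

subset_homologs <- function(hs, accessions) {
  keep <- hs$info$accession %in% accessions
  homolog_set(hs$info[keep, , drop = FALSE], hs$sequences[hs$info$accession[keep]],
              hs$provenance)
}

#' Load an enzyme-homolog reference from FASTA + taxonomy TSV
#'
#' Reads an amino-acid FASTA and a taxonomy table (columns `accession`,
#' `enzyme_class`, `superkingdom` ... `species`; blank = unknown rank) into a
#' validated [homolog_set()]. Records whose sequence contains residues outside
#' the 20-letter alphabet plus `X` (for example internal stop symbols `*`) are
#' excluded and counted in the `n_excluded` attribute. Every FASTA record must
#' have a taxonomy row; a missing row is an error naming the accession.
#'
#' @param fasta_path amino-acid FASTA file.
#' @param taxonomy_path tab-separated taxonomy table.
#' @param provenance optional free-text source description.
#' @return a `homolog_set`; attribute `n_excluded` reports dropped records.
#' @export
load_homologs <- function(fasta_path, taxonomy_path, provenance = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (length(seqs) == 0L) stopf("empty FASTA: %s", fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stopf("duplicated FASTA identifier(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tax <- read_tsv(taxonomy_path)
  if (!"accession" %in% names(tax)) stopf("taxonomy table lacks 'accession' column")
  absent <- setdiff(ids, tax$accession)
  if (length(absent))
    stopf("no taxonomy row for accession(s): %s", paste(absent, collapse = ", "))
  seq_chr <- setNames(as.character(seqs), ids)
  ok <- grepl(paste0("^[", paste(AA_STANDARD, collapse = ""), "X]+$"), seq_chr) &
    nzchar(seq_chr)
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    message(sprintf("excluded %d record(s) failing residue validation: %s",
                    n_excluded, paste(ids[!ok], collapse = ", ")))
  if (!any(ok)) stopf("no valid records in %s", fasta_path)
  ids <- ids[ok]
  tax <- tax[match(ids, tax$accession), , drop = FALSE]
  hs <- homolog_set(tax, seq_chr[ids],
                    provenance %||% sprintf("loaded from %s", basename(fasta_path)))
  attr(hs, "n_excluded") <- n_excluded
  hs
}

#' Remove 100%-identical protein homologs
#'
#' Collapses records with byte-identical sequences, keeping the
#' lexicographically smallest accession of each group so that the result does
#' not depend on input order. The removed-to-kept mapping is attached as the
#' `dedupe_map` attribute.
#'
#' @param hs a [homolog_set()].
#' @return deduplicated `homolog_set` with attribute `dedupe_map`
#'   (data frame `removed`, `kept`).
#' @export
dedupe_identical <- function(hs) {
  stopifnot(inherits(hs, "homolog_set"))
  acc <- hs$info$accession
  ord <- order(acc, method = "radix")
  grp <- split(acc[ord], unname(hs$sequences[acc[ord]]))
  kept <- vapply(grp, `[`, "", 1L)  # accessions sorted within group
  removed <- unlist(lapply(grp, `[`, -1L), use.names = FALSE)
  map <- data.frame(removed = removed,
                    kept = rep(kept, lengths(grp) - 1L),
                    stringsAsFactors = FALSE)
  out <- subset_homologs(hs, kept)
  out$provenance <- hs$provenance
  attr(out, "dedupe_map") <- map[order(map$removed), , drop = FALSE]
  out
}

# Global-alignment percent identity used for reference curation and homolog
# clustering: gaps are placed by a BLOSUM62 global alignment (gap open 10,
# extend 1); identity = matches / columns where neither sequence is gapped.
# X never counts as a match. Returns identity fraction in [0, 1], or NA when
# no alignable (gap-free) column exists.
global_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  both <- p != "-" & s != "-"
  if (!any(both)) return(NA_real_)
  sum(p[both] == s[both] & p[both] != "X") / sum(both)
}

#' Pairwise percent identity among homologs
#'
#' Computes, for every pair of homologs, a global alignment (BLOSUM62-guided
#' gap placement, gap open 10 / extend 1) and from it the identity fraction
#' `f` = matches / columns where neither sequence is gapped. The alignment
#' distance is `d = sqrt(1 - f)` and percent identity `100 * (1 - d^2)`,
#' which equals `100 * f` exactly. A pair with no alignable columns is
#' recorded as `d = 1` with a warning.
#'
#' @param hs a [homolog_set()] with at least two records.
#' @return object of class `identity_matrix`: list with `labels`, symmetric
#'   distance matrix `d`, and `pct_identity = 100 * (1 - d^2)`.
#' @export
pairwise_identity <- function(hs) {
  stopifnot(inherits(hs, "homolog_set"))
  n <- length(hs$sequences)
  if (n < 2L) stopf("pairwise identity needs at least 2 records")
  labels <- hs$info$accession
  f <- matrix(1, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      fij <- global_identity(hs$sequences[[i]], hs$sequences[[j]])
      if (is.na(fij)) {
        warnf("no alignable columns for pair %s / %s; recording d = 1",
              labels[i], labels[j])
        fij <- 0
      }
      f[i, j] <- f[j, i] <- fij
    }
  }
  d <- sqrt(1 - f)
  structure(list(labels = labels, d = d, pct_identity = 100 * (1 - d^2)),
            class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  off <- x$pct_identity[upper.tri(x$pct_identity)]
  cat(sprintf("identity_matrix: %d proteins; off-diagonal %% identity %.1f-%.1f (median %.1f)\n",
              length(x$labels), min(off), max(off), median(off)))
  invisible(x)
}

#' Within- vs between-species identity, per enzyme class
#'
#' Stratifies pairwise percent identities by taxonomy: within-species pairs
#' versus between-species pairs, separately per enzyme class, and reports the
#' fraction of between-species pairs exceeding a candidate alignment-identity
#' cutoff. This is the analysis that justifies filtering read alignments below
#' 90% identity: if between-species homolog identity rarely exceeds the
#' cutoff, reads passing it can be attributed to species reliably.
#'
#' Pairs in which either member lacks a species name are excluded from the
#' stratified distributions.
#'
#' @param im an [pairwise_identity()] result.
#' @param hs the matching [homolog_set()].
#' @param cutoff candidate percent-identity cutoff (default 90).
#' @return list with `pairs` (long data frame: enzyme_class, comparison,
#'   accession pair, pct_identity) and `summary` (per-class medians, pair
#'   counts and `frac_between_above_cutoff`).
#' @export
identity_by_rank <- function(im, hs, cutoff = 90) {
  stopifnot(inherits(im, "identity_matrix"), inherits(hs, "homolog_set"))
  idx <- match(im$labels, hs$info$accession)
  if (anyNA(idx)) stopf("identity matrix labels missing from homolog set")
  cls <- hs$info$enzyme_class[idx]
  spp <- hs$info$species[idx]
  pairs <- list()
  for (ec in unique(cls)) {
    sel <- which(cls == ec)
    if (length(sel) < 2L) {
      warnf("enzyme class %s has <2 records; empty distribution", ec)
      next
    }
    cmb <- utils::combn(sel, 2L)
    i <- cmb[1L, ]; j <- cmb[2L, ]
    known <- nzchar(spp[i]) & nzchar(spp[j])
    comparison <- ifelse(spp[i] == spp[j], "within_species", "between_species")
    pairs[[ec]] <- data.frame(
      enzyme_class = ec,
      accession1 = im$labels[i][known], accession2 = im$labels[j][known],
      comparison = comparison[known],
      pct_identity = im$pct_identity[cbind(i, j)][known],
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(enzyme_class = character(), accession1 = character(),
               accession2 = character(), comparison = character(),
               pct_identity = numeric(), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  summary <- do.call(rbind, lapply(split(pairs, pairs$enzyme_class), function(p) {
    w <- p$pct_identity[p$comparison == "within_species"]
    b <- p$pct_identity[p$comparison == "between_species"]
    data.frame(enzyme_class = p$enzyme_class[1L],
               n_within = length(w), n_between = length(b),
               median_within = if (length(w)) median(w) else NA_real_,
               median_between = if (length(b)) median(b) else NA_real_,
               frac_between_above_cutoff = if (length(b)) mean(b > cutoff) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(pairs = pairs, summary = summary, cutoff = cutoff)
}

#' Write a homolog set as FASTA + taxonomy TSV
#'
#' @param hs a [homolog_set()].
#' @param fasta_path,taxonomy_path output paths.
#' @export
write_homolog_set <- function(hs, fasta_path, taxonomy_path) {
  stopifnot(inherits(hs, "homolog_set"))
  x <- Biostrings::AAStringSet(hs$sequences)
  Biostrings::writeXStringSet(x, fasta_path)
  write_tsv(hs$info, taxonomy_path)
  invisible(hs)
}
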