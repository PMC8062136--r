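#' Greedy identity clustering of homologs into families
#'
#' Sequences are processed by decreasing length (ties broken by accession); a
#' sequence joins the first existing family whose representative it matches
#' at `>= id_threshold` percent global-alignment identity (identity counted
#' over gap-free columns, see [pairwise_identity()]), otherwise it founds a
#' new family. The representative is the founding (longest) member, the
#' centroid used for marker discovery.
#'
#' @param hs deduplicated [homolog_set()].
#' @param id_threshold percent identity for joining a family (default 85).
#' @return object of class `protein_families`: data frame `accession`,
#'   `family_id`, `centroid`, plus attribute `centroids` (named sequences).
#' @export
cluster_homologs <- function(hs, id_threshold = 85) {
  stopifnot(inherits(hs, "homolog_set"))
  acc <- hs$info$accession
  ord <- order(-nchar(hs$sequences[acc]), acc, method = "radix")
  acc <- acc[ord]
  centroid_acc <- character()
  assign_to <- integer(length(acc))
  for (k in seq_along(acc)) {
    joined <- 0L
    for (ci in seq_along(centroid_acc)) {
      f <- global_identity(hs$sequences[[acc[k]]],
                           hs$sequences[[centroid_acc[ci]]])
      if (!is.na(f) && 100 * f >= id_threshold) { joined <- ci; break }
    }
    if (joined == 0L) {
      centroid_acc <- c(centroid_acc, acc[k])
      joined <- length(centroid_acc)
    }
    assign_to[k] <- joined
  }
  fam_id <- sprintf("F%03d", seq_along(centroid_acc))
  out <- data.frame(accession = acc, family_id = fam_id[assign_to],
                    centroid = centroid_acc[assign_to],
                    stringsAsFactors = FALSE)
  out <- out[order(out$family_id, out$accession), ]
  rownames(out) <- NULL
  attr(out, "centroids") <- setNames(unname(hs$sequences[centroid_acc]), fam_id)
  class(out) <- c("protein_families", "data.frame")
  out
}

#' Marker peptides of a family centroid against a background proteome
#'
#' Slides a window of `window` residues over the centroid; every position
#' covered by a window that matches any background protein at
#' `>= bg_identity` percent (best ungapped placement of the window on the
#' background protein) is masked as "common". Maximal unmasked runs of at
#' least `min_marker` residues become marker peptides — regions unique to the
#' family at the threshold identity. A fully masked centroid yields zero
#' markers (flagged with a message): the failure mode that motivates
#' [merge_adjacent()].
#'
#' @param family_id family label for the output.
#' @param centroid centroid amino-acid sequence.
#' @param background character vector of background protein sequences (the
#'   homolog set itself must be excluded).
#' @param window masking window length in residues.
#' @param bg_identity percent identity at which a window is called common.
#' @param min_marker minimum marker length in residues.
#' @return data frame: `family_id`, `marker_id`, `start`, `end` (0-based
#'   half-open interval on the centroid), `sequence`.
#' @export
find_markers <- function(family_id, centroid, background, window = 30L,
                         bg_identity = 90, min_marker = 8L) {
  stopifnot(is.character(centroid), length(centroid) == 1L)
  mask <- if (length(background))
    .mask_windows_cpp(centroid, as.character(background), as.integer(window),
                      bg_identity / 100)
  else rep(FALSE, nchar(centroid))
  r <- rle(!mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_marker
  if (!any(keep)) {
    if (all(mask)) message(sprintf("centroid of %s fully masked: no markers",
                                   family_id))
    return(empty_markers())
  }
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(family_id = family_id,
             marker_id = sprintf("%s_m%02d", family_id, seq_along(starts)),
             start = starts, end = ends,
             sequence = substring(centroid, starts + 1L, ends),
             stringsAsFactors = FALSE)
}

empty_markers <- function() {
  data.frame(family_id = character(), marker_id = character(),
             start = integer(), end = integer(), sequence = character(),
             stringsAsFactors = FALSE)
}

#' Merge markers separated by small gaps
#'
#' Consecutive markers on one centroid whose gap is at most `max_gap`
#' residues are merged into a single marker spanning both, with the gap
#' residues filled in from the centroid. This repairs marker sets that were
#' improperly broken up from long continuous unique regions into fragments
#' too short to be quantifiable. Merging is transitive (a chain of markers
#' each one residue apart collapses into one) and idempotent.
#'
#' @param markers marker data frame (one centroid), as from [find_markers()].
#' @param centroid the centroid sequence the markers were cut from.
#' @param max_gap largest inter-marker gap (residues) to merge across.
#' @return merged marker data frame.
#' @export
merge_adjacent <- function(markers, centroid, max_gap = 1L) {
  if (nrow(markers) == 0L) return(markers)
  stopifnot(length(unique(markers$family_id)) == 1L)
  m <- markers[order(markers$start), , drop = FALSE]
  grp <- cumsum(c(1L, as.integer(m$start[-1L] - m$end[-nrow(m)] > max_gap)))
  starts <- tapply(m$start, grp, min)
  ends <- tapply(m$end, grp, max)
  data.frame(family_id = m$family_id[1L],
             marker_id = sprintf("%s_m%02d", m$family_id[1L],
                                 seq_along(starts)),
             start = as.integer(starts), end = as.integer(ends),
             sequence = substring(centroid, starts + 1L, ends),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Marker-based quantification of reads
#'
#' A read is assigned to the family of its best passing marker alignment:
#' among all (fragment, marker) alignments at `>= id` percent identity
#' (BLAST-convention identity over all alignment columns), covering at least
#' `pctlength` of the shorter of marker and fragment (a short read cannot be
#' required to span a marker longer than itself), and scoring at least
#' `score_floor`, the highest-scoring one wins (ties broken by identity,
#' coverage, then marker order). Competitive assignment keeps reads from a
#' related species' enzyme from inflating a family via short conserved
#' stretches. Family RPKM uses the
#' family's summed marker length (in nucleotides, 3 x residues) as reference
#' length, mirroring marker-based quantification semantics.
#'
#' @param reads data frame with `read_id`, `sequence`.
#' @param markers marker data frame (may span several families).
#' @param total_reads RPKM denominator for the sample.
#' @param id percent identity threshold (default 90).
#' @param pctlength minimum fraction of the marker covered (default 0.5).
#' @param score_floor minimum alignment score (default 40, as in the
#'   translated search).
#' @param min_fragment,min_read_length translation settings, see
#'   [search_reads()].
#' @return data frame: `family_id`, `n_reads`, `marker_len_aa`, `rpkm`.
#' @export
quantify_markers <- function(reads, markers, total_reads, id = 90,
                             pctlength = 0.5, score_floor = 40L,
                             min_fragment = 15L, min_read_length = 45L) {
  if (nrow(markers) == 0L) stopf("no markers to quantify against")
  fams <- sort(unique(markers$family_id))
  mlen <- vapply(split(nchar(markers$sequence), markers$family_id), sum, 0)
  counts <- setNames(integer(length(fams)), fams)
  fr <- translate_frames(reads$sequence, min_fragment = min_fragment,
                         min_read_length = min_read_length)
  if (nrow(fr)) {
    hits <- .sw_vs_markers_cpp(fr$peptide, markers$sequence, 11L, 1L,
                               as.integer(score_floor), id / 100, pctlength)
    if (nrow(hits)) {
      hit_read <- fr$read[hits$frag]
      # best passing alignment decides the read's family
      best <- order(hit_read, -hits$score, -hits$identity_pct,
                    -hits$marker_cover, hits$marker)
      best <- best[!duplicated(hit_read[best])]
      per_fam <- table(markers$family_id[hits$marker[best]])
      counts[names(per_fam)] <- as.integer(per_fam)
    }
  }
  data.frame(family_id = fams, n_reads = unname(counts),
             marker_len_aa = unname(mlen[fams]),
             rpkm = rpkm(unname(counts), unname(mlen[fams]), total_reads),
             stringsAsFactors = FALSE)
}

#' Write markers as amino-acid FASTA
#'
#' Headers carry the family and the 0-based half-open source interval on the
#' centroid: `>marker_id family=... interval=[start,end)`.
#'
#' @param markers marker data frame.
#' @param path output FASTA path.
#' @export
write_markers <- function(markers, path) {
  x <- Biostrings::AAStringSet(setNames(
    markers$sequence,
    sprintf("%s family=%s interval=[%d,%d)", markers$marker_id,
            markers$family_id, markers$start, markers$end)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
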