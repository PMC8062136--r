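#' Read shotgun reads from FASTA or FASTQ
#'
#' Qualities are ignored; gzip-compressed files are handled transparently.
#' Format is taken from the file extension (`.fq`/`.fastq` = FASTQ).
#'
#' @param path sequence file.
#' @param sample_id optional sample label attached to every read.
#' @return data frame with columns `read_id`, `sequence` and (if given)
#'   `sample_id`.
#' @export
read_reads <- function(path, sample_id = NULL) {
  base <- sub("\\.gz$", "", path)
  fmt <- if (grepl("\\.(fastq|fq)$", base, ignore.case = TRUE)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- data.frame(read_id = sub("\\s.*$", "", names(x)),
                    sequence = as.character(x), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(sample_id)) out$sample_id <- sample_id
  out
}

# frames in evaluation order; negative = reverse complement strand
FRAME_ORDER <- c(1L, 2L, 3L, -1L, -2L, -3L)

#' Six-frame translation of a nucleotide read
#'
#' Translates all six reading frames with the standard codon table (codons
#' containing `N` translate to `X`), splits each frame at stop codons, and
#' returns the stop-free peptide fragments of at least `min_fragment`
#' residues. `offset_aa` is the 0-based amino-acid offset of the fragment
#' within its frame translation.
#'
#' @param sequence a single nucleotide string (ACGTN).
#' @param min_fragment minimum fragment length in residues (default 15).
#' @return data frame with columns `frame` (+1..+3, -1..-3), `offset_aa`,
#'   `peptide`; zero rows when no fragment reaches `min_fragment`.
#' @export
six_frame_translate <- function(sequence, min_fragment = 15L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  fr <- translate_frames(sequence, min_fragment = min_fragment,
                         min_read_length = 1L)
  fr[c("frame", "offset_aa", "peptide")]
}

# Batch six-frame translation: `sequences` is a character vector of reads.
# Returns data frame (read = index into sequences, frame, offset_aa, peptide),
# ordered by read, then frame (+1,+2,+3,-1,-2,-3), then offset. Reads shorter
# than min_read_length are skipped and counted in attr n_too_short.
translate_frames <- function(sequences, min_fragment = 15L,
                             min_read_length = 45L) {
  n_too_short <- sum(nchar(sequences) < min_read_length)
  keep <- which(nchar(sequences) >= min_read_length)
  pieces <- vector("list", 6L)
  if (length(keep)) {
    x <- Biostrings::DNAStringSet(sequences[keep])
    rc <- Biostrings::reverseComplement(x)
    for (k in seq_along(FRAME_ORDER)) {
      f <- FRAME_ORDER[k]
      src <- if (f > 0) x else rc
      off <- abs(f) - 1L
      w <- Biostrings::width(src) - off
      w <- w - (w %% 3L)
      ok <- which(w >= 3L)
      if (!length(ok)) next
      sub <- Biostrings::subseq(src[ok], start = off + 1L, width = w[ok])
      aa <- as.character(suppressWarnings(
        Biostrings::translate(sub, if.fuzzy.codon = "X",
                              no.init.codon = TRUE)))
      frag <- strsplit(aa, "*", fixed = TRUE)
      nfrag <- lengths(frag)
      flat <- unlist(frag, use.names = FALSE)
      if (!length(flat)) next
      len <- nchar(flat)
      # fragment offset = residues of earlier fragments + one stop each
      offs <- unlist(lapply(frag, function(p) {
        if (!length(p)) return(integer())
        cumsum(c(0L, nchar(p[-length(p)]) + 1L))
      }), use.names = FALSE)
      sel <- len >= min_fragment
      if (!any(sel)) next
      pieces[[k]] <- data.frame(
        read = rep(keep, nfrag)[sel],
        frame = f,
        offset_aa = offs[sel],
        peptide = flat[sel],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(read = integer(), frame = integer(),
                      offset_aa = integer(), peptide = character(),
                      stringsAsFactors = FALSE)
  frame_rank <- match(out$frame, FRAME_ORDER)
  out <- out[order(out$read, frame_rank, out$offset_aa), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_too_short") <- n_too_short
  out
}

#' Local alignment of a peptide fragment to one homolog protein
#'
#' Smith-Waterman local alignment with BLOSUM62, gap open 11 / extend 1 (a
#' gap of length L costs `11 + L`). Identity uses the BLAST convention:
#' identical residues divided by all alignment columns, gap columns included;
#' `X` never counts as identical. Alignments scoring below `score_floor` are
#' rejected (returns `NULL`), which suppresses spurious short matches.
#'
#' @param peptide fragment string (>= 15 residues for search use).
#' @param protein homolog protein string.
#' @param gap_open,gap_extend,score_floor alignment parameters.
#' @return `NULL`, or a one-row data frame with `score`, `identity_pct`,
#'   `aln_len`, and 0-based half-open spans `q_start`, `q_end` (on the
#'   peptide) and `s_start`, `s_end` (on the protein).
#' @export
align_local <- function(peptide, protein, gap_open = 11L, gap_extend = 1L,
                        score_floor = 40L) {
  st <- .sw_pair_cpp(peptide, protein, as.integer(gap_open),
                     as.integer(gap_extend))
  if (st$score < score_floor) return(NULL)
  data.frame(score = st$score,
             identity_pct = 100 * st$matches / st$cols,
             aln_len = st$cols,
             q_start = st$qs, q_end = st$qe,
             s_start = st$ss, s_end = st$se)
}

#' Translated best-hit search of reads against a homolog reference
#'
#' The stand-in for a diamond-blastx step: every read is translated in six
#' frames, split at stop codons, and every fragment of >= `min_fragment`
#' residues is aligned (exhaustive Smith-Waterman, BLOSUM62, gap 11/1)
#' against every reference protein. The single best hit per read is kept
#' (ties broken by higher identity, longer alignment, lexicographically
#' smallest accession, then frame order +1,+2,+3,-1,-2,-3), provided it
#' reaches `score_floor`. No identity filter is applied here; see
#' [filter_identity()].
#'
#' @param reads data frame with columns `read_id`, `sequence` (see
#'   [read_reads()]).
#' @param hs deduplicated [homolog_set()].
#' @param min_read_length reads shorter than this many nucleotides are
#'   skipped (counted in attribute `n_too_short`).
#' @param min_fragment minimum translated fragment length (residues).
#' @param gap_open,gap_extend,score_floor Smith-Waterman parameters.
#' @param chunk_size reads are processed in chunks of this size to bound
#'   memory; does not affect results.
#' @return data frame of alignment hits, one row per read with a hit:
#'   `read_id`, `protein_accession`, `frame`, `score`, `identity_pct`,
#'   `aln_len`, `qstart`, `qend` (1-based inclusive nucleotide coordinates on
#'   the read; `qstart > qend` on the minus strand), `sstart`, `send`
#'   (1-based inclusive residue coordinates on the protein).
#' @export
search_reads <- function(reads, hs, min_read_length = 45L, min_fragment = 15L,
                         gap_open = 11L, gap_extend = 1L, score_floor = 40L,
                         chunk_size = 20000L) {
  stopifnot(inherits(hs, "homolog_set"),
            all(c("read_id", "sequence") %in% names(reads)))
  ord <- order(hs$info$accession, method = "radix")
  prot_acc <- hs$info$accession[ord]
  prot_seq <- unname(hs$sequences[prot_acc])
  n <- nrow(reads)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
  res <- vector("list", length(chunks))
  n_too_short <- 0L
  for (ci in seq_along(chunks)) {
    idx <- chunks[[ci]]
    fr <- translate_frames(reads$sequence[idx], min_fragment = min_fragment,
                           min_read_length = min_read_length)
    n_too_short <- n_too_short + attr(fr, "n_too_short")
    if (!nrow(fr)) next
    hits <- .sw_best_hits_cpp(fr$peptide, as.integer(fr$read - 1L), prot_seq,
                              as.integer(gap_open), as.integer(gap_extend),
                              as.integer(score_floor))
    if (!nrow(hits)) next
    frag <- fr[hits$frag + 1L, ]
    read_local <- hits$read + 1L
    read_global <- idx[read_local]
    L <- nchar(reads$sequence[read_global])
    aa0 <- frag$offset_aa + hits$qs     # aa span on the frame, 0-based
    aa1 <- frag$offset_aa + hits$qe
    n0 <- (abs(frag$frame) - 1L) + 3L * aa0   # nt span on frame strand
    n1 <- (abs(frag$frame) - 1L) + 3L * aa1
    plus <- frag$frame > 0
    qstart <- ifelse(plus, n0 + 1L, L - n0)
    qend <- ifelse(plus, n1, L - n1 + 1L)
    res[[ci]] <- data.frame(
      read_id = reads$read_id[read_global],
      protein_accession = prot_acc[hits$prot + 1L],
      frame = frag$frame,
      score = hits$score,
      identity_pct = 100 * hits$matches / hits$cols,
      aln_len = hits$cols,
      qstart = qstart, qend = qend,
      sstart = hits$ss + 1L, send = hits$se,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(read_id = character(), protein_accession = character(),
                      frame = integer(), score = integer(),
                      identity_pct = numeric(), aln_len = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_too_short") <- n_too_short
  out
}

#' Best hit of a single read
#'
#' Convenience wrapper around [search_reads()] for one read.
#'
#' @param read_sequence nucleotide string.
#' @param hs deduplicated [homolog_set()].
#' @param ... passed to [search_reads()].
#' @return one-row hit data frame, or `NULL` when the read has no hit at the
#'   score floor.
#' @export
best_hit <- function(read_sequence, hs, ...) {
  hits <- search_reads(data.frame(read_id = "read1",
                                  sequence = read_sequence,
                                  stringsAsFactors = FALSE), hs, ...)
  if (nrow(hits) == 0L) NULL else hits
}

#' Filter hits by percent identity
#'
#' Retains hits with `identity_pct >= min_identity`; the boundary value is
#' kept (a 90.0% hit passes the default filter, an 89.9% hit does not). The
#' filter is the specificity safeguard of the translated search: reads whose
#' best alignment is below the cutoff cannot be attributed to a species with
#' confidence and are discarded rather than reassigned.
#'
#' @param hits data frame from [search_reads()].
#' @param min_identity percent identity cutoff (default 90).
#' @return filtered hits.
#' @export
filter_identity <- function(hits, min_identity = 90) {
  stopifnot("identity_pct" %in% names(hits))
  out <- hits[hits$identity_pct >= min_identity, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write hits in a blast-tabular-like dialect
#'
#' Columns: qseqid, sseqid, pident, length, score, frame, qstart, qend,
#' sstart, send (1-based inclusive coordinates).
#'
#' @param hits data frame from [search_reads()].
#' @param path output TSV.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(qseqid = hits$read_id, sseqid = hits$protein_accession,
                    pident = round(hits$identity_pct, 2),
                    length = hits$aln_len, score = hits$score,
                    frame = hits$frame, qstart = hits$qstart,
                    qend = hits$qend, sstart = hits$sstart, send = hits$send)
  write_tsv(out, path)
}
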