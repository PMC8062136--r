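# fixtures built in code; no binary or on-disk test data

blank_ranks <- function(n) {
  out <- data.frame(superkingdom = rep("Bacteria", n), phylum = "P",
                    class = "C", order = "O", family = "F",
                    genus = "G", species = "S",
                    stringsAsFactors = FALSE)
  out
}

# minimal hand-built reference: two species x two OXC homologs
tiny_homolog_set <- function() {
  info <- data.frame(
    accession = c("OXC_A1", "OXC_A2", "OXC_B1", "OXC_B2"),
    enzyme_class = "OXC",
    superkingdom = "Bacteria", phylum = "P", class = "C", order = "O",
    family = "F",
    genus = c("GenusA", "GenusA", "GenusB", "GenusB"),
    species = c("SpeciesA", "SpeciesA", "SpeciesB", "SpeciesB"),
    stringsAsFactors = FALSE)
  base <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKV"
  seqs <- c(
    OXC_A1 = base,
    OXC_A2 = sub("TAY", "TAF", base),             # 1 substitution
    OXC_B1 = paste0(substr(base, 1, 30),
                    "PWNDERGHKLMCPWNDERGHKLMCPWNDER"), # diverged C-half
    OXC_B2 = paste0(substr(base, 1, 30),
                    "PWNDERGHKLMCPWNDERGHKLMCPWNDEK"))
  homolog_set(info, seqs, provenance = "hand-built test fixture")
}

write_reference_files <- function(hs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, "ref.fasta")
  tx <- file.path(dir, "tax.tsv")
  write_homolog_set(hs, fa, tx)
  list(fasta = fa, taxonomy = tx, dir = dir)
}

reads_df <- function(sequences, prefix = "r") {
  data.frame(read_id = sprintf("%s%03d", prefix, seq_along(sequences)),
             sequence = sequences, stringsAsFactors = FALSE)
}

# nucleotide encoding of a peptide, deterministic under the ambient RNG
encode_peptide <- function(peptide, seed = 1) {
  oxatrace:::with_seed(seed, oxatrace:::reverse_translate(peptide))
}

# Independent exhaustive translated-search oracle built on Biostrings: all
# six frames, all stop-free fragments >= 15 aa, local Smith-Waterman against
# every protein; best (score, identity, length, accession, frame order).
oracle_best_hit <- function(read_sequence, proteins, score_floor = 40) {
  stopifnot(!is.null(names(proteins)))
  frames <- list()
  x <- Biostrings::DNAString(read_sequence)
  rc <- Biostrings::reverseComplement(x)
  for (f in c(1, 2, 3, -1, -2, -3)) {
    src <- if (f > 0) x else rc
    off <- abs(f) - 1
    w <- (length(src) - off) %/% 3 * 3
    if (w < 3) next
    aa <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::subseq(src, start = off + 1, width = w),
      if.fuzzy.codon = "X", no.init.codon = TRUE)))
    for (piece in strsplit(aa, "*", fixed = TRUE)[[1]])
      if (nchar(piece) >= 15)
        frames[[length(frames) + 1]] <- list(frame = f, peptide = piece)
  }
  best <- NULL
  acc_sorted <- sort(names(proteins))
  for (k in seq_along(frames)) {
    for (acc in acc_sorted) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(frames[[k]]$peptide),
        Biostrings::AAString(proteins[[acc]]), type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
      sc <- Biostrings::score(pa)
      if (sc < score_floor) next
      cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
      cand <- list(accession = acc, score = sc,
                   identity = Biostrings::nmatch(pa) / cols, cols = cols,
                   ord = k)
      if (is.null(best) ||
          cand$score > best$score ||
          (cand$score == best$score && cand$identity > best$identity) ||
          (cand$score == best$score && cand$identity == best$identity &&
             cand$cols > best$cols) ||
          (cand$score == best$score && cand$identity == best$identity &&
             cand$cols == best$cols && cand$accession < best$accession))
        best <- cand
    }
  }
  best
}
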