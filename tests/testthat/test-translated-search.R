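test_that("six-frame translation recovers an exact coding substring", {
  peptide <- "MKTAYIAKQRQISFVKSHFSRQLE"   # 24 aa
  gene <- encode_peptide(peptide, seed = 4)
  read <- substr(gene, 1, 60)             # frame +1, first 20 codons
  fr <- six_frame_translate(read)
  plus1 <- fr[fr$frame == 1L, ]
  expect_equal(nrow(plus1), 1L)
  expect_equal(plus1$peptide, substr(peptide, 1, 20))
  expect_equal(plus1$offset_aa, 0L)
})

test_that("all-N reads translate without crashing", {
  fr <- six_frame_translate(strrep("N", 60))
  expect_true(nrow(fr) == 0L || all(grepl("^X+$", fr$peptide)))
})

test_that("internal stop codons split a frame into fragments", {
  left <- "MKTAYIAKQR"; right <- "ISFVKSHFSRQLE"
  gene <- paste0(encode_peptide(left, seed = 5), "TAA",
                 encode_peptide(right, seed = 6))
  fr <- six_frame_translate(gene, min_fragment = 1L)
  plus1 <- fr[fr$frame == 1L, ]
  expect_equal(plus1$peptide, c(left, right))
  expect_equal(plus1$offset_aa, c(0L, nchar(left) + 1L))
  # fragment lengths + 1 stop = full frame translation length
  expect_equal(sum(nchar(plus1$peptide)) + 1L, nchar(gene) / 3L)
})

test_that("reverse-strand reads are found in negative frames", {
  peptide <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIE"
  gene <- encode_peptide(peptide, seed = 7)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene)))
  fr <- six_frame_translate(rc)
  neg <- fr[fr$frame < 0, ]
  expect_true(any(vapply(neg$peptide, grepl, TRUE, x = peptide, fixed = TRUE) |
                    vapply(neg$peptide, function(p) grepl(p, peptide, fixed = TRUE), TRUE)))
})

test_that("align_local computes BLAST-convention identity", {
  prot <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLI"   # 30 aa
  hit <- align_local(prot, prot)
  expect_equal(hit$identity_pct, 100)
  expect_equal(hit$aln_len, 30L)
  expect_equal(c(hit$s_start, hit$s_end), c(0L, 30L))

  # 3 substitutions in 30 aligned columns, no gaps -> 90%
  mutated <- prot
  substr(mutated, 8, 8) <- "W"; substr(mutated, 15, 15) <- "W"
  substr(mutated, 22, 22) <- "C"
  hit <- align_local(mutated, prot)
  expect_equal(hit$aln_len, 30L)
  expect_equal(hit$identity_pct, 90)        # oracle: hand count 27/30
})

test_that("gapped alignments count gap columns in the identity denominator", {
  prot <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILS"
  # fragment with a 2-residue internal deletion: 36 matches over 38 columns
  frag <- paste0(substr(prot, 1, 18), substr(prot, 21, 38))
  hit <- align_local(frag, prot)
  expect_equal(hit$aln_len, 38L)
  expect_equal(hit$identity_pct, 100 * 36 / 38)
  expect_equal(c(hit$s_start, hit$s_end), c(0L, 38L))
  # independent check of the same alignment through Biostrings
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(frag), Biostrings::AAString(prot), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  expect_equal(hit$score, Biostrings::score(pa))
  expect_equal(hit$identity_pct,
               100 * Biostrings::nmatch(pa) /
                 nchar(as.character(Biostrings::alignedPattern(pa))))
})

test_that("score floor rejects almost all random fragments", {
  set.seed(42)
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  prot <- paste(sample(aa, 200, TRUE), collapse = "")
  n_hit <- 0L
  for (k in 1:100) {
    frag <- paste(sample(aa, 15, TRUE), collapse = "")
    if (!is.null(align_local(frag, prot))) n_hit <- n_hit + 1L
  }
  expect_lte(n_hit, 5L)   # none in >= 95% of trials
})

test_that("a perfect 15-residue match passes the score floor", {
  prot <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLI"
  frag <- substr(prot, 6, 20)
  hit <- align_local(frag, prot)
  expect_false(is.null(hit))
  expect_equal(hit$identity_pct, 100)
})

test_that("best_hit assigns mutated reads to their source protein", {
  hs <- tiny_homolog_set()
  genes <- vapply(hs$sequences, encode_peptide, "", seed = 8)
  read <- substr(genes[["OXC_B1"]], 10, 99)
  # one nucleotide substitution (~1% error)
  substr(read, 45, 45) <- if (substr(read, 45, 45) == "A") "C" else "A"
  hit <- best_hit(read, hs)
  expect_equal(hit$protein_accession, "OXC_B1")
})

test_that("ties are broken by the smallest accession", {
  info <- cbind(data.frame(accession = c("P_b", "P_a"), enzyme_class = "OXC",
                           stringsAsFactors = FALSE), blank_ranks(2))
  seq <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRV"
  hs <- homolog_set(info, c(P_b = seq, P_a = seq))
  read <- encode_peptide(substr(seq, 5, 34), seed = 9)
  hit <- best_hit(read, hs)
  expect_equal(hit$protein_accession, "P_a")
})

test_that("short reads are skipped with a counter", {
  hs <- tiny_homolog_set()
  reads <- reads_df(c(strrep("A", 30), encode_peptide(hs$sequences[[1]], seed = 2)))
  hits <- search_reads(reads, hs)
  expect_equal(attr(hits, "n_too_short"), 1L)
})

test_that("identity filter keeps the 90.0 boundary and drops 89.9", {
  hits <- data.frame(read_id = c("a", "b", "c"),
                     identity_pct = c(89.9, 90.0, 95.5))
  out <- filter_identity(hits)
  expect_equal(out$read_id, c("b", "c"))
  expect_equal(nrow(filter_identity(hits[0, ])), 0L)

  # oracle: direct threshold scan over 100 synthetic identities
  set.seed(3)
  syn <- data.frame(read_id = sprintf("r%03d", 1:100),
                    identity_pct = round(runif(100, 80, 100), 1))
  expect_equal(nrow(filter_identity(syn)), sum(syn$identity_pct >= 90))
})

test_that("best hits equal the exhaustive Biostrings oracle", {
  hs <- generate_homolog_set(n_species = 3, homologs_per_species = 2,
                             protein_length = 80, seed = 21)
  genes <- attr(hs, "genes")
  set.seed(22)
  reads <- character(12)
  for (i in 1:8) {   # reads from homologs, 2% error
    g <- genes[[sample(length(genes), 1)]]
    st <- sample(nchar(g) - 89, 1)
    r <- substr(g, st, st + 89)
    reads[i] <- oxatrace:::add_read_errors(r, 0.02)
  }
  for (i in 9:12)    # background
    reads[i] <- paste(sample(c("A","C","G","T"), 90, TRUE), collapse = "")
  hits <- search_reads(reads_df(reads), hs)
  for (i in seq_along(reads)) {
    ob <- oracle_best_hit(reads[i], hs$sequences)
    mine <- hits[hits$read_id == sprintf("r%03d", i), ]
    if (is.null(ob)) {
      expect_equal(nrow(mine), 0L)
    } else {
      expect_equal(nrow(mine), 1L)
      expect_equal(mine$protein_accession, ob$accession)
      expect_equal(mine$score, ob$score)
    }
  }
})

test_that("hits are deterministic and independent of read order", {
  hs <- generate_homolog_set(n_species = 2, homologs_per_species = 2,
                             protein_length = 80, seed = 31)
  genes <- attr(hs, "genes")
  set.seed(32)
  reads <- vapply(1:10, function(i) {
    g <- genes[[sample(length(genes), 1)]]
    st <- sample(nchar(g) - 89, 1)
    oxatrace:::add_read_errors(substr(g, st, st + 89), 0.01)
  }, "")
  rd <- reads_df(reads)
  h1 <- search_reads(rd, hs)
  h2 <- search_reads(rd, hs)
  expect_identical(h1, h2)
  perm <- sample(nrow(rd))
  h3 <- search_reads(rd[perm, ], hs)
  h3 <- h3[order(match(h3$read_id, h1$read_id)), ]
  rownames(h3) <- NULL
  attr(h3, "n_too_short") <- attr(h1, "n_too_short")
  expect_equal(h1, h3)
})

test_that("reads from one species never pass the filter as another species", {
  hs <- generate_homolog_set(n_species = 2, homologs_per_species = 2,
                             intra_identity = 97, inter_identity = 80,
                             seed = 41)
  genes <- attr(hs, "genes")
  a_homs <- hs$info$accession[hs$info$species == "Species_01"]
  make_reads <- function(n, error_rate) {
    vapply(seq_len(n), function(i) {
      g <- genes[[sample(a_homs, 1)]]
      st <- sample(nchar(g) - 89, 1)
      oxatrace:::add_read_errors(substr(g, st, st + 89), error_rate)
    }, "")
  }
  # platform-typical substitution error: essentially every read is assigned,
  # and only ever to its own species
  set.seed(42)
  reads <- make_reads(150, 0.005)
  hits <- filter_identity(search_reads(reads_df(reads), hs))
  hit_species <- hs$info$species[match(hits$protein_accession,
                                       hs$info$accession)]
  expect_true(all(hit_species == "Species_01"))  # none misassigned
  expect_gte(nrow(hits) / length(reads), 0.99)   # nearly all recovered
  # at a stress-level 1% error some reads legitimately fall below the 90%
  # cutoff: they must be filtered, never reassigned to the other species
  reads <- make_reads(150, 0.01)
  hits <- filter_identity(search_reads(reads_df(reads), hs))
  hit_species <- hs$info$species[match(hits$protein_accession,
                                       hs$info$accession)]
  expect_true(all(hit_species == "Species_01"))
  expect_gte(nrow(hits) / length(reads), 0.95)
})
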