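test_that("simulated references hit their divergence targets", {
  one <- generate_homolog_set(1, 1, seed = 1)
  expect_equal(length(one), 1L)

  two <- generate_homolog_set(2, 1, intra_identity = 97, inter_identity = 80,
                              seed = 2)
  ri <- attr(two, "realized_identity")
  inter <- ri$pct_identity[ri$type == "inter_species"]
  expect_true(all(inter >= 75 & inter <= 85))

  # medians on target across replicates
  for (s in 3:5) {
    hs <- generate_homolog_set(5, 2, seed = s)
    ri <- attr(hs, "realized_identity")
    med <- tapply(ri$pct_identity, ri$type, median)
    expect_lt(abs(med[["intra_species"]] - 97), 2)
    expect_lt(abs(med[["inter_species"]] - 80), 2)
  }

  expect_error(generate_homolog_set(2, 1, intra_identity = 80,
                                    inter_identity = 78, seed = 1),
               "intra_identity")
})

test_that("the same seed reproduces the reference byte for byte", {
  a <- generate_homolog_set(3, 2, seed = 9)
  b <- generate_homolog_set(3, 2, seed = 9)
  expect_identical(a$sequences, b$sequences)
  expect_identical(attr(a, "genes"), attr(b, "genes"))
})

test_that("genes back-translate to their proteins", {
  hs <- generate_homolog_set(2, 2, seed = 10)
  genes <- attr(hs, "genes")
  for (acc in names(genes)) {
    aa <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(genes[[acc]]), no.init.codon = TRUE)))
    expect_equal(aa, unname(hs$sequences[acc]))
  }
})

make_design <- function(n_subjects = 4, reads = 500, expression = 1,
                        prevalence = 1, rate = c(2, 1), n_groups = 1) {
  species <- data.frame(species = c("Species_01", "Species_02"),
                        base_abundance = c(0.02, 0.01),
                        transcription_rate = rate,
                        stringsAsFactors = FALSE)
  groups <- data.frame(group = paste0("g", seq_len(n_groups)),
                       n_subjects = rep(n_subjects, n_groups),
                       stringsAsFactors = FALSE)
  cohort_design(groups, species,
                prevalence = matrix(prevalence, n_groups, 2),
                expression = matrix(expression, n_groups, 2),
                reads_per_sample = reads, read_length = 90,
                error_rate = 0.01)
}

test_that("RNA reads come only from transcribing species", {
  hs <- generate_homolog_set(2, 1, seed = 11)
  truth <- draw_cohort_truth(make_design(expression = 0), seed = 11)
  rna <- generate_reads(truth, hs, "RNA", seed = 12)
  expect_true(all(rna$origins$species == "background"))

  truth2 <- draw_cohort_truth(make_design(expression = 1), seed = 13)
  rna2 <- generate_reads(truth2, hs, "RNA", seed = 14)
  expect_gt(sum(rna2$origins$species != "background"), 0)
})

test_that("per-species read counts match multinomial expectations", {
  hs <- generate_homolog_set(2, 1, seed = 15)
  design <- make_design(n_subjects = 1, reads = 20000)
  truth <- draw_cohort_truth(design, seed = 15)
  dna <- generate_reads(truth, hs, "DNA", seed = 16)
  n <- design$reads_per_sample
  for (sp in colnames(truth$abundance)) {
    p <- truth$abundance[1, sp]
    got <- sum(dna$origins$species == sp)
    expect_lt(abs(got - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  }
})

test_that("error-free reads from one homolog are recovered perfectly", {
  hs <- generate_homolog_set(2, 2, seed = 17)
  species <- data.frame(species = "Species_01", base_abundance = 0.3,
                        transcription_rate = 1, stringsAsFactors = FALSE)
  design <- cohort_design(
    data.frame(group = "g1", n_subjects = 1), species,
    prevalence = matrix(1, 1, 1), expression = matrix(1, 1, 1),
    reads_per_sample = 150, read_length = 90, error_rate = 0,
    abundance_jitter = 0)
  truth <- draw_cohort_truth(design, seed = 18)
  dna <- generate_reads(truth, hs, "DNA", seed = 19)
  keep <- dna$origins$species == "Species_01"
  hits <- search_reads(dna$reads[keep, ], hs)
  hits <- filter_identity(hits)
  expect_equal(nrow(hits), sum(keep))
  expect_equal(hits$identity_pct, rep(100, nrow(hits)))
  # oracle: the recorded origin of every read; where the two homologs are
  # identical over the read's window the tie goes to the smaller accession
  origin <- dna$origins$homolog[match(hits$read_id, dna$origins$read_id)]
  exact <- hits$protein_accession == origin
  expect_true(all(hits$protein_accession[!exact] <= origin[!exact]))
  expect_gt(mean(exact), 0.5)
})

test_that("cohorts are reproducible and degenerate designs run end to end", {
  hs <- generate_homolog_set(2, 1, seed = 20)
  design <- make_design(n_subjects = 1, reads = 200)
  c1 <- generate_cohort(hs, design, seed = 21)
  c2 <- generate_cohort(hs, design, seed = 21)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$reads, c2$reads)
  expect_identical(c1$truth$abundance, c2$truth$abundance)
  det <- detect_cohort(c1, hs)
  expect_true(all(c("taxon_subject", "homolog_sample") %in% names(det)))
})

test_that("written cohorts round-trip through FASTA and manifest", {
  hs <- generate_homolog_set(2, 1, seed = 22)
  design <- make_design(n_subjects = 2, reads = 100)
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(hs, design, seed = 23, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  m <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(m), 4L)   # 2 subjects x 2 layers
  r <- read_reads(file.path(dir, m$file[1]), sample_id = m$sample_id[1])
  key <- paste(m$sample_id[1], m$layer[1], sep = "_")
  expect_equal(r$sequence, cohort$reads[[key]]$sequence)
})

test_that("the disease regime lowers transcript prevalence by construction", {
  sc <- scenario_layer_contrast(seed = 24, n_per_group = 30)
  d <- sc$design
  tr <- sc$transcriber
  expect_gt(d$prevalence["healthy", tr] * d$expression["healthy", tr],
            d$prevalence["disease", tr] * d$expression["disease", tr])
  truth <- draw_cohort_truth(d, seed = 24)
  expressing <- truth$transcribing[, tr] & truth$abundance[, tr] > 0
  grp <- truth$subjects$group
  expect_gt(mean(expressing[grp == "healthy"]), mean(expressing[grp == "disease"]))
})

test_that("metabolite coupling reproduces the designed association", {
  hs <- generate_homolog_set(2, 1, seed = 25)
  truth <- draw_cohort_truth(make_design(n_subjects = 30), seed = 25)
  # noise 0, slope 0: constant target share
  m0 <- generate_metabolites(truth, coupling = 0, noise = 0, seed = 26)
  share <- metabolite_relative_abundance(m0, "oxalate")
  expect_lt(diff(range(share)), 1e-9)
  # noise 0, negative slope: perfect inverse rank association
  m1 <- generate_metabolites(truth, coupling = -1, noise = 0, seed = 27)
  act <- attr(m1, "activity")
  share <- metabolite_relative_abundance(m1, "oxalate")
  expect_equal(spearman_assoc(share, act)$estimate, -1)
})

test_that("recovered Spearman matches the closed-form expectation", {
  # activity constructed normal so the bivariate-normal rank formula applies:
  # rho_s = (6/pi) asin(rho/2), rho = |b| / sqrt(b^2 + sd^2)
  hs <- generate_homolog_set(1, 1, seed = 28)
  species <- data.frame(species = "Species_01", base_abundance = 0.01,
                        transcription_rate = 1, stringsAsFactors = FALSE)
  design <- cohort_design(data.frame(group = "g1", n_subjects = 200), species,
                          prevalence = matrix(1, 1, 1),
                          expression = matrix(1, 1, 1),
                          reads_per_sample = 100)
  truth <- draw_cohort_truth(design, seed = 28)
  set.seed(29)
  truth$abundance[, 1] <- rnorm(200, mean = 50, sd = 5)  # normal activity
  b <- -1; sdn <- 0.5
  m <- generate_metabolites(truth, coupling = b, noise = sdn, seed = 30)
  share <- metabolite_relative_abundance(m, "oxalate")
  got <- spearman_assoc(share, attr(m, "activity"))$estimate
  rho <- b / sqrt(b^2 + sdn^2)
  expected <- (6 / pi) * asin(rho / 2)
  expect_lt(abs(got - expected), 0.1)
})
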