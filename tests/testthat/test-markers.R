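test_that("clustering groups near-identical sequences and splits divergent ones", {
  # three mutually >=97%-identical sequences -> one family
  base <- strrep("MKTAYIAKQRQISFVKSHFSRQLEERLGLI", 2)   # 60 aa
  v2 <- base; substr(v2, 10, 10) <- "W"
  v3 <- base; substr(v3, 40, 40) <- "C"
  info <- cbind(data.frame(accession = c("H1", "H2", "H3"),
                           enzyme_class = "OXC", stringsAsFactors = FALSE),
                blank_ranks(3))
  hs <- homolog_set(info, c(H1 = base, H2 = v2, H3 = v3))
  fam <- cluster_homologs(hs)
  expect_equal(length(unique(fam$family_id)), 1L)
  expect_true(unique(fam$centroid) %in% fam$accession)

  # three mutually dissimilar sequences -> three singleton families
  set.seed(15)
  seqs <- vapply(1:3, function(i) oxatrace:::random_protein(60), "")
  hs2 <- homolog_set(info, setNames(seqs, info$accession))
  fam2 <- cluster_homologs(hs2)
  expect_equal(length(unique(fam2$family_id)), 3L)
})

test_that("clustering a simulated reference recovers the species", {
  hs <- generate_homolog_set(n_species = 5, homologs_per_species = 3,
                             intra_identity = 97, inter_identity = 80,
                             seed = 16)
  fam <- cluster_homologs(hs, id_threshold = 85)
  # oracle: the generator's species labels
  sp <- hs$info$species[match(fam$accession, hs$info$accession)]
  expect_equal(length(unique(fam$family_id)), 5L)
  expect_true(all(tapply(sp, fam$family_id,
                         function(x) length(unique(x))) == 1L))
})

test_that("marker discovery masks shared regions", {
  set.seed(17)
  unique_half <- oxatrace:::random_protein(30)
  shared_half <- oxatrace:::random_protein(30)
  centroid <- paste0(shared_half, unique_half)

  # empty background: the whole centroid is one marker
  m0 <- find_markers("F001", centroid, character())
  expect_equal(nrow(m0), 1L)
  expect_equal(m0$sequence, centroid)

  # background containing the centroid itself: fully masked, zero markers
  expect_message(m1 <- find_markers("F001", centroid, centroid), "fully masked")
  expect_equal(nrow(m1), 0L)

  # N-terminal half shared with a background protein: marker = C-terminal run
  bg <- paste0(shared_half, oxatrace:::random_protein(40))
  m2 <- find_markers("F001", centroid, bg)
  expect_equal(nrow(m2), 1L)
  # oracle: direct mask computation on the fixture (independent scan)
  cc <- strsplit(centroid, "")[[1]]; bb <- strsplit(bg, "")[[1]]
  mask <- rep(FALSE, length(cc))
  for (i in 0:(length(cc) - 30)) {
    for (j in 0:(length(bb) - 30)) {
      if (sum(cc[(i + 1):(i + 30)] == bb[(j + 1):(j + 30)]) >= 27) {
        mask[(i + 1):(i + 30)] <- TRUE
        break
      }
    }
  }
  run_start <- min(which(!mask))
  expect_equal(m2$start, run_start - 1L)
  expect_equal(m2$end, 60L)
  expect_equal(m2$sequence, substr(centroid, run_start, 60))
  expect_true(m2$start >= 30L)   # the shared half itself is never a marker
})

test_that("markers are exact substrings of their centroid", {
  set.seed(18)
  centroid <- oxatrace:::random_protein(120)
  bg <- paste0(substr(centroid, 31, 75), oxatrace:::random_protein(30))
  mk <- find_markers("F001", centroid, bg)
  for (i in seq_len(nrow(mk)))
    expect_equal(substr(centroid, mk$start[i] + 1L, mk$end[i]),
                 mk$sequence[i])
})

test_that("merge_adjacent merges one-residue gaps and is idempotent", {
  set.seed(19)
  centroid <- oxatrace:::random_protein(80)
  mk <- data.frame(family_id = "F001",
                   marker_id = c("F001_m01", "F001_m02"),
                   start = c(0L, 17L), end = c(16L, 33L),
                   sequence = c(substr(centroid, 1, 16),
                                substr(centroid, 18, 33)),
                   stringsAsFactors = FALSE)
  merged <- merge_adjacent(mk, centroid, max_gap = 1L)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(0L, 33L))
  expect_equal(merged$sequence, substr(centroid, 1, 33))
  expect_equal(merge_adjacent(merged, centroid), merged)

  # gap of 2 with max_gap 1 stays unmerged
  mk2 <- mk; mk2$start[2] <- 18L
  mk2$sequence[2] <- substr(centroid, 19, 33)
  expect_equal(nrow(merge_adjacent(mk2, centroid, max_gap = 1L)), 2L)

  # chain of 5 markers each one apart collapses transitively
  starts <- c(0L, 9L, 18L, 27L, 36L)
  chain <- data.frame(family_id = "F001",
                      marker_id = sprintf("F001_m%02d", 1:5),
                      start = starts, end = starts + 8L,
                      sequence = substring(centroid, starts + 1L, starts + 8L),
                      stringsAsFactors = FALSE)
  out <- merge_adjacent(chain, centroid)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(0L, 44L))
  # order-independence
  out2 <- merge_adjacent(chain[sample(5), ], centroid)
  expect_equal(out2, out)
})

test_that("marker quantification enforces coverage", {
  set.seed(20)
  centroid <- oxatrace:::random_protein(60)
  marker <- data.frame(family_id = "F001", marker_id = "F001_m01",
                       start = 15L, end = 45L,
                       sequence = substr(centroid, 16, 45),
                       stringsAsFactors = FALSE)
  gene <- encode_peptide(centroid, seed = 21)
  # read covering the full 30-aa marker
  full <- substr(gene, 3 * 15 + 1, 3 * 15 + 90)
  q <- quantify_markers(reads_df(full), marker, total_reads = 1e4)
  expect_equal(q$n_reads, 1L)
  expect_gt(q$rpkm, 0)
  # read covering only 40% of the marker at 100% identity -> rejected
  part <- substr(gene, 1, 3 * 27)   # last 12 marker residues only
  q2 <- quantify_markers(reads_df(part), marker, total_reads = 1e4)
  expect_equal(q2$n_reads, 0L)
})

test_that("short markers fail and the merge repair rescues detection", {
  fix <- marker_rescue_fixture()
  before <- quantify_markers(fix$reads, fix$markers, total_reads = 1e4)
  expect_equal(sum(before$n_reads), 0L)
  after <- quantify_markers(fix$reads, fix$merged, total_reads = 1e4)
  expect_gt(sum(after$n_reads), 0L)
  expect_gt(after$rpkm, 0)
})

test_that("marker and translated-search detection calls agree", {
  sc <- scenario_layer_contrast(seed = 23, n_per_group = 3,
                                reads_per_sample = 1200)
  cohort <- generate_cohort(sc$hs, sc$design, seed = 23, layers = "DNA")
  det <- detect_cohort(cohort, sc$hs)
  # marker path: families from clustering, markers vs a non-ODE background
  # (the background must exclude the homolog set itself)
  set.seed(24)
  bg <- vapply(1:5, function(i) oxatrace:::random_protein(200), "")
  fams <- cluster_homologs(sc$hs)
  centroids <- attr(fams, "centroids")
  markers <- do.call(rbind, lapply(names(centroids), function(fid)
    find_markers(fid, centroids[[fid]], bg)))
  fam_species <- sc$hs$info$species[match(
    fams$centroid[match(markers$family_id, fams$family_id)],
    sc$hs$info$accession)]
  manifest <- cohort$manifest
  agree <- 0L; total <- 0L
  for (i in seq_len(nrow(manifest))) {
    key <- paste(manifest$sample_id[i], manifest$layer[i], sep = "_")
    q <- quantify_markers(cohort$reads[[key]], markers,
                          manifest$total_reads[i])
    q$species <- fam_species[match(q$family_id, markers$family_id)]
    tp <- det$taxon_sample
    tp <- tp[tp$sample_id == manifest$sample_id[i], ]
    for (sp in unique(q$species)) {
      marker_call <- sum(q$n_reads[q$species == sp]) > 0
      search_call <- any(tp$rpkm[tp$taxon == sp] > 0)
      agree <- agree + (marker_call == search_call)
      total <- total + 1L
    }
  }
  expect_gte(agree / total, 0.9)
})
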