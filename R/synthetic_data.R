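# Approximate amino-acid background frequencies of bacterial proteomes
# (Robinson-Robinson style); used for ancestor proteins so that BLOSUM62
# alignment statistics behave like they do on real sequences.
AA_FREQS <- c(A = 0.079, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
              Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
              L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
              S = 0.068, T = 0.059, W = 0.014, Y = 0.032, V = 0.065)

random_protein <- function(length) {
  paste(sample(names(AA_FREQS), length, replace = TRUE, prob = AA_FREQS),
        collapse = "")
}

# Substitution probability per site such that two sequences independently
# mutated from a common ancestor at this rate have expected pairwise identity
# `target` (fraction): identity = (1-p)^2 + p^2/19 (both mutated positions
# coincide with probability 1/19).
solve_subrate <- function(target) {
  a <- 20 / 19
  (2 - sqrt(4 - 4 * a * (1 - target))) / (2 * a)
}

# substitute at exactly round(p * length) positions (random placement,
# uniform replacement among the 19 other residues): fixing the count rather
# than drawing it per site keeps realized pairwise identities tightly on
# target
mutate_protein <- function(seq, p) {
  chars <- strsplit(seq, "")[[1]]
  n_sub <- round(p * length(chars))
  if (n_sub > 0) {
    hit <- sample.int(length(chars), n_sub)
    repl <- vapply(chars[hit], function(a)
      sample(setdiff(names(AA_FREQS), a), 1L), "")
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

hamming_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  100 * mean(x == y)
}

# random synonymous reverse translation under the standard genetic code
reverse_translate <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  chars <- strsplit(aa, "")[[1]]
  paste(vapply(chars, function(a) {
    cods <- by_aa[[a]]
    if (length(cods) == 1L) cods else sample(cods, 1L)
  }, ""), collapse = "")
}

#' Simulate an enzyme-homolog reference with controlled divergence
#'
#' Simulates, per enzyme class, one ancestor protein; species sequences are
#' derived by substitution calibrated so that between-species pairwise
#' identity is close to `inter_identity`, and homologs within a species by
#' further substitution targeting `intra_identity`. Substitution-only
#' evolution (no indels) keeps realized identities controllable; realized
#' pairwise identities are recorded in the `realized_identity` attribute.
#' Nucleotide genes (random synonymous reverse translation) are attached as
#' the `genes` attribute for read simulation.
#'
#' @param n_species number of simulated species.
#' @param homologs_per_species homologs per species and enzyme class.
#' @param intra_identity,inter_identity target percent identities; must
#'   satisfy `intra_identity > inter_identity + 5`.
#' @param protein_length ancestor length in residues.
#' @param enzyme_classes subset of OXDD/FRC/OXC to simulate.
#' @param seed RNG seed (`NULL` = use ambient RNG state).
#' @return a [homolog_set()] with attributes `realized_identity` (data frame)
#'   and `genes` (named nucleotide sequences).
#' @export
generate_homolog_set <- function(n_species, homologs_per_species = 1L,
                                 intra_identity = 97, inter_identity = 80,
                                 protein_length = 130L,
                                 enzyme_classes = "OXC", seed = NULL) {
  if (!(intra_identity > inter_identity + 5))
    stopf("need intra_identity > inter_identity + 5 (got %s / %s)",
          intra_identity, inter_identity)
  stopifnot(all(enzyme_classes %in% ENZYME_CLASSES), n_species >= 1)
  with_seed(seed, {
    # inter-species identity is realized between homologs of different
    # species, i.e. after both the species- and the homolog-level
    # substitutions; solve for the species-level rate net of the homolog
    # divergence so that realized homolog pairs hit the targets
    p_intra <- solve_subrate(intra_identity / 100)
    e_total <- solve_subrate(inter_identity / 100)
    p_inter <- 1 - (1 - e_total) / (1 - p_intra)
    rows <- list(); seqs <- character(); genes <- character()
    for (ec in enzyme_classes) {
      ancestor <- random_protein(protein_length)
      for (i in seq_len(n_species)) {
        sp_seq <- mutate_protein(ancestor, p_inter)
        for (j in seq_len(homologs_per_species)) {
          acc <- sprintf("%s_SP%02d_H%02d", ec, i, j)
          seqs[acc] <- mutate_protein(sp_seq, p_intra)
          genes[acc] <- reverse_translate(seqs[acc])
          rows[[acc]] <- data.frame(
            accession = acc, enzyme_class = ec,
            superkingdom = "Bacteria", phylum = "SimPhylum",
            class = "SimClass", order = "SimOrder",
            family = sprintf("Family_%02d", i),
            genus = sprintf("Genus_%02d", i),
            species = sprintf("Species_%02d", i),
            stringsAsFactors = FALSE)
        }
      }
    }
    info <- do.call(rbind, rows)
    rownames(info) <- NULL
    hs <- homolog_set(info, seqs, provenance = sprintf(
      "simulated: %d species x %d homologs, intra %s%% / inter %s%%",
      n_species, homologs_per_species, intra_identity, inter_identity))
    attr(hs, "realized_identity") <- realized_identities(hs)
    attr(hs, "genes") <- genes
    hs
  })
}

# substitution-only simulation keeps sequences aligned: identity is the
# positionwise agreement
realized_identities <- function(hs) {
  info <- hs$info
  out <- list()
  for (ec in unique(info$enzyme_class)) {
    sel <- which(info$enzyme_class == ec)
    if (length(sel) < 2L) next
    cmb <- utils::combn(sel, 2L)
    out[[ec]] <- data.frame(
      enzyme_class = ec,
      accession1 = info$accession[cmb[1L, ]],
      accession2 = info$accession[cmb[2L, ]],
      type = ifelse(info$species[cmb[1L, ]] == info$species[cmb[2L, ]],
                    "intra_species", "inter_species"),
      pct_identity = mapply(hamming_identity,
                            hs$sequences[info$accession[cmb[1L, ]]],
                            hs$sequences[info$accession[cmb[2L, ]]]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Describe a synthetic cohort
#'
#' Bundles the study design a synthetic cohort is generated under: group
#' sizes, sampling depth, read properties, and the per-species ecological
#' parameters (prevalence and ODP expression probability per group, baseline
#' gene abundance as the expected fraction of a sample's reads originating
#' from the species' ODE genes, and the transcription rate multiplying that
#' fraction in RNA).
#'
#' @param groups data frame with columns `group`, `n_subjects`.
#' @param species data frame with columns `species`, `base_abundance`,
#'   `transcription_rate`.
#' @param prevalence,expression matrices (rows = groups, columns = species)
#'   of carriage and, among carriers, transcription probabilities.
#' @param samples_per_subject samples per subject and layer.
#' @param reads_per_sample reads per sample (the RPKM denominator).
#' @param read_length read length in nucleotides (>= 60).
#' @param error_rate per-base substitution sequencing error.
#' @param abundance_jitter log-sd of the per-subject lognormal abundance
#'   jitter around `base_abundance`.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(groups, species, prevalence, expression,
                          samples_per_subject = 1L, reads_per_sample = 30000L,
                          read_length = 90L, error_rate = 0.01,
                          abundance_jitter = 0.35) {
  stopifnot(is.data.frame(groups), all(c("group", "n_subjects") %in% names(groups)),
            is.data.frame(species),
            all(c("species", "base_abundance", "transcription_rate") %in%
                  names(species)))
  prevalence <- as.matrix(prevalence); expression <- as.matrix(expression)
  stopifnot(nrow(prevalence) == nrow(groups), ncol(prevalence) == nrow(species),
            nrow(expression) == nrow(groups), ncol(expression) == nrow(species))
  if (any(prevalence < 0 | prevalence > 1) || any(expression < 0 | expression > 1))
    stopf("prevalence and expression must be probabilities")
  if (read_length < 60) stopf("read_length must be >= 60 nt")
  if (error_rate < 0 || error_rate >= 1) stopf("invalid error_rate")
  # leave room for background reads even at maximal expression
  load <- sum(species$base_abundance * pmax(1, species$transcription_rate))
  if (load > 0.5)
    stopf("species read fractions too large (sum %.2f); keep total <= 0.5", load)
  dimnames(prevalence) <- dimnames(expression) <-
    list(groups$group, species$species)
  structure(list(groups = groups, species = species, prevalence = prevalence,
                 expression = expression,
                 samples_per_subject = as.integer(samples_per_subject),
                 reads_per_sample = as.integer(reads_per_sample),
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 abundance_jitter = abundance_jitter),
            class = "cohort_design")
}

#' Draw the latent state of a synthetic cohort
#'
#' Draws, per subject, which species are present (carriage), their ODE gene
#' abundance (baseline with lognormal jitter), and whether each carried
#' species transcribes its ODP genes. This latent state is the ground truth
#' reads are generated from and recovery is judged against.
#'
#' @param design a [cohort_design()].
#' @param seed RNG seed (`NULL` = ambient RNG).
#' @return object of class `synthetic_truth`: `subjects` data frame,
#'   `abundance` and `transcribing` matrices (subjects x species), and the
#'   design.
#' @export
draw_cohort_truth <- function(design, seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(seed, {
    subj <- data.frame(
      subject_id = sprintf("subj%03d", seq_len(sum(design$groups$n_subjects))),
      group = rep(design$groups$group, design$groups$n_subjects),
      stringsAsFactors = FALSE)
    ns <- nrow(subj); nsp <- nrow(design$species)
    spp <- design$species$species
    A <- matrix(0, ns, nsp, dimnames = list(subj$subject_id, spp))
    Tr <- matrix(FALSE, ns, nsp, dimnames = list(subj$subject_id, spp))
    for (s in seq_len(ns)) {
      g <- subj$group[s]
      present <- runif(nsp) < design$prevalence[g, ]
      A[s, present] <- design$species$base_abundance[present] *
        exp(rnorm(sum(present), 0, design$abundance_jitter))
      Tr[s, present] <- runif(sum(present)) < design$expression[g, present]
    }
    structure(list(subjects = subj, abundance = A, transcribing = Tr,
                   design = design, seed = seed),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d subjects (%s), %d species\n",
              nrow(x$subjects),
              paste(sprintf("%s n=%d", x$design$groups$group,
                            x$design$groups$n_subjects), collapse = ", "),
              ncol(x$abundance)))
  invisible(x)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# inject per-base substitution errors into reads (character vector)
add_read_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  len <- nchar(reads)
  n_err <- rbinom(length(reads), len, error_rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0)) {
    pos <- sample.int(len[i], n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  reads
}

#' Simulate shotgun reads for one omics layer
#'
#' DNA reads are drawn from each species' ODE genes proportionally to its
#' (jittered) gene abundance; RNA reads only from species whose latent state
#' is transcribing, proportionally to abundance x transcription rate. The
#' remaining reads are background: substrings of a random sequence with the
#' shuffled nucleotide composition of the ODE genes, which stresses the
#' identity filter rather than trivially failing the score floor. Per-base
#' substitution errors are applied at the design's error rate. Every read's
#' origin (species and homolog, or background) is recorded.
#'
#' @param truth a [draw_cohort_truth()] result.
#' @param hs the [generate_homolog_set()] reference the truth refers to
#'   (provides the `genes` attribute).
#' @param layer `"DNA"` or `"RNA"`.
#' @param seed RNG seed (`NULL` = ambient RNG).
#' @return list with `reads` (data frame `read_id`, `sequence`, `sample_id`)
#'   and `origins` (data frame `sample_id`, `layer`, `read_id`, `species`,
#'   `homolog`; background reads carry `"background"`).
#' @export
generate_reads <- function(truth, hs, layer = c("DNA", "RNA"), seed = NULL) {
  layer <- match.arg(layer)
  stopifnot(inherits(truth, "synthetic_truth"), inherits(hs, "homolog_set"))
  genes <- attr(hs, "genes")
  if (is.null(genes)) stopf("homolog set lacks simulated genes")
  design <- truth$design
  spp <- colnames(truth$abundance)
  sp_homologs <- split(hs$info$accession, hs$info$species)[spp]
  if (any(vapply(sp_homologs, is.null, TRUE)))
    stopf("truth species missing from homolog set")
  with_seed(seed, {
    bg_pool <- background_pool(genes, 100000L)
    reads_out <- vector("list", 0L); orig_out <- vector("list", 0L)
    L <- design$read_length
    for (s in seq_len(nrow(truth$subjects))) {
      subject <- truth$subjects$subject_id[s]
      w <- truth$abundance[s, ]
      if (layer == "RNA")
        w <- w * design$species$transcription_rate * truth$transcribing[s, ]
      for (k in seq_len(design$samples_per_subject)) {
        sample_id <- sprintf("%s_t%d", subject, k)
        n <- design$reads_per_sample
        counts <- as.vector(rmultinom(1L, n, c(w, 1 - sum(w))))
        seqs <- character(n); species_lab <- character(n); hom_lab <- character(n)
        pos <- 1L
        for (i in seq_along(spp)) {
          ci <- counts[i]
          if (ci == 0L) next
          homs <- sample(sp_homologs[[i]], ci, replace = TRUE)
          glen <- nchar(genes[homs])
          start <- 1L + floor(runif(ci) * (glen - L + 1L))
          rd <- substring(genes[homs], start, start + L - 1L)
          minus <- runif(ci) < 0.5
          if (any(minus)) rd[minus] <- revcomp(rd[minus])
          idx <- pos:(pos + ci - 1L)
          seqs[idx] <- rd; species_lab[idx] <- spp[i]; hom_lab[idx] <- homs
          pos <- pos + ci
        }
        nb <- counts[length(counts)]
        if (nb > 0L) {
          start <- 1L + floor(runif(nb) * (nchar(bg_pool) - L + 1L))
          idx <- pos:(pos + nb - 1L)
          seqs[idx] <- substring(bg_pool, start, start + L - 1L)
          species_lab[idx] <- "background"; hom_lab[idx] <- "background"
        }
        seqs <- add_read_errors(seqs, design$error_rate)
        read_id <- sprintf("%s_%s_r%06d", sample_id, layer, seq_len(n))
        reads_out[[sample_id]] <- data.frame(
          read_id = read_id, sequence = seqs, sample_id = sample_id,
          stringsAsFactors = FALSE)
        orig_out[[sample_id]] <- data.frame(
          sample_id = sample_id, layer = layer, read_id = read_id,
          species = species_lab, homolog = hom_lab, stringsAsFactors = FALSE)
      }
    }
    list(reads = do.call(rbind, c(reads_out, list(make.row.names = FALSE))),
         origins = do.call(rbind, c(orig_out, list(make.row.names = FALSE))))
  })
}

# random nucleotide pool with the pooled base composition of the ODE genes
background_pool <- function(genes, pool_length) {
  comp <- table(strsplit(paste(genes, collapse = ""), "")[[1]])
  comp <- comp[c("A", "C", "G", "T")]
  paste(sample(names(comp), pool_length, replace = TRUE,
               prob = as.numeric(comp)), collapse = "")
}

#' Generate a complete synthetic cohort
#'
#' Draws the latent cohort state ([draw_cohort_truth()]) and simulates reads
#' for the requested omics layers ([generate_reads()]), producing a manifest,
#' per-sample reads, and the full ground truth. With `out_dir`, per-sample
#' FASTA files, the manifest TSV and the truth (JSON) are written so the
#' cohort can be analysed by the file-based pipeline stages.
#'
#' @param hs reference from [generate_homolog_set()].
#' @param design a [cohort_design()].
#' @param seed RNG seed governing the whole cohort.
#' @param layers omics layers to simulate.
#' @param out_dir optional output directory.
#' @return list with `manifest`, `reads` (list per sample x layer), `truth`,
#'   and `origins`.
#' @export
generate_cohort <- function(hs, design, seed = NULL,
                            layers = c("DNA", "RNA"), out_dir = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(seed, {
    truth <- draw_cohort_truth(design)
    reads <- list(); origins <- list(); manifest <- list()
    for (layer in layers) {
      gen <- generate_reads(truth, hs, layer)
      for (sid in unique(gen$reads$sample_id)) {
        sel <- gen$reads$sample_id == sid
        reads[[paste(sid, layer, sep = "_")]] <- gen$reads[sel, , drop = FALSE]
      }
      origins[[layer]] <- gen$origins
      subj <- sub("_t\\d+$", "", unique(gen$reads$sample_id))
      manifest[[layer]] <- data.frame(
        sample_id = unique(gen$reads$sample_id),
        subject_id = subj,
        group = truth$subjects$group[match(subj, truth$subjects$subject_id)],
        layer = layer, total_reads = design$reads_per_sample,
        stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, c(manifest, list(make.row.names = FALSE)))
    origins <- do.call(rbind, c(origins, list(make.row.names = FALSE)))
    out <- list(manifest = manifest, reads = reads, truth = truth,
                origins = origins)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      manifest$file <- sprintf("%s_%s.fasta", manifest$sample_id, manifest$layer)
      for (i in seq_len(nrow(manifest))) {
        r <- reads[[paste(manifest$sample_id[i], manifest$layer[i], sep = "_")]]
        Biostrings::writeXStringSet(
          Biostrings::DNAStringSet(setNames(r$sequence, r$read_id)),
          file.path(out_dir, manifest$file[i]))
      }
      write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
      jsonlite::write_json(
        list(subjects = truth$subjects,
             abundance = as.data.frame(truth$abundance),
             transcribing = as.data.frame(truth$transcribing),
             seed = seed),
        file.path(out_dir, "truth.json"), digits = NA)
      out$manifest <- manifest
      out$dir <- out_dir
    }
    out
  })
}

#' Simulate a metabolite table coupled to ODP transcription
#'
#' Emulates an inverse relationship between a target metabolite (oxalate) and
#' the cohort's true ODP transcription activity: the target's abundance
#' follows a log-linear model `log10(target) = b0 + coupling * z + noise * e`
#' where `z` is the subject's standardized transcription activity
#' (`sum(abundance * rate * transcribing)` across species) and `e` standard
#' normal noise. The remaining metabolites form a fixed log-normal background
#' (drawn once, shared by all subjects), so with `noise = 0` the target's
#' relative abundance is strictly monotone in activity.
#'
#' @param truth a [draw_cohort_truth()] result.
#' @param coupling slope on standardized activity (negative = transcription
#'   depletes the metabolite).
#' @param noise log10-scale Gaussian noise SD.
#' @param n_background number of background metabolites.
#' @param target_name column name for the target metabolite.
#' @param seed RNG seed.
#' @return matrix (subjects x metabolites) with attribute `activity` (the
#'   true per-subject transcription activity).
#' @export
generate_metabolites <- function(truth, coupling = -1, noise = 0.25,
                                 n_background = 19L, target_name = "oxalate",
                                 seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), is.finite(coupling))
  with_seed(seed, {
    rate <- truth$design$species$transcription_rate
    activity <- rowSums(truth$abundance *
                          matrix(rate, nrow(truth$abundance),
                                 ncol(truth$abundance), byrow = TRUE) *
                          truth$transcribing)
    z <- if (stats::sd(activity) > 0) (activity - mean(activity)) / stats::sd(activity)
         else activity * 0
    n <- length(activity)
    target <- 10^(3 + coupling * z + noise * rnorm(n))
    bg <- matrix(10^rnorm(n_background, mean = 3, sd = 0.5),
                 nrow = n, ncol = n_background, byrow = TRUE)
    out <- cbind(target, bg)
    dimnames(out) <- list(truth$subjects$subject_id,
                          c(target_name,
                            sprintf("metabolite_%02d", seq_len(n_background))))
    attr(out, "activity") <- setNames(activity, truth$subjects$subject_id)
    out
  })
}

#' Short-marker failure/rescue fixture
#'
#' A hand-built fixture reproducing the short-marker under-detection mode:
#' a centroid whose marker set consists of two 8-residue markers one residue
#' apart, each too weak to reach the alignment score floor on its own, plus
#' error-free reads covering the region. Before [merge_adjacent()] the family
#' is undetectable; after merging the 17-residue marker is detected.
#'
#' @param n_reads number of reads covering the marker region.
#' @param seed RNG seed for the reverse translation.
#' @return list with `centroid`, `markers` (data frame), `merged` (data
#'   frame), and `reads`.
#' @export
marker_rescue_fixture <- function(n_reads = 6L, seed = 7L) {
  with_seed(seed, {
    # low self-score residues (A=4, S=4, T=5) keep an 8-mer below score 40
    left <- "ASTASTAS"; gap <- "G"; right <- "TSATSATS"
    prefix <- random_protein(30L); suffix <- random_protein(30L)
    centroid <- paste0(prefix, left, gap, right, suffix)
    p <- nchar(prefix)
    markers <- data.frame(
      family_id = "F001",
      marker_id = c("F001_m01", "F001_m02"),
      start = c(p, p + 9L), end = c(p + 8L, p + 17L),
      sequence = c(left, right), stringsAsFactors = FALSE)
    # reads: 90 nt windows of the centroid gene containing the full region
    gene <- reverse_translate(centroid)
    starts <- sample((3L * (p - 10L)):(3L * (p - 3L)), n_reads, replace = TRUE)
    reads <- data.frame(
      read_id = sprintf("fix_r%02d", seq_len(n_reads)),
      sequence = substring(gene, starts, starts + 89L),
      stringsAsFactors = FALSE)
    list(centroid = centroid, markers = markers,
         merged = merge_adjacent(markers, centroid, max_gap = 1L),
         reads = reads)
  })
}
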