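Package: oxatrace
Title: Taxon-Resolved Detection and Quantification of Oxalate Degradation Genes and Transcripts in Meta-Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies which microbial taxa encode versus actively transcribe
    oxalate degradation pathway enzymes (oxalate oxidase/decarboxylase, formyl-CoA
    transferase, oxalyl-CoA decarboxylase) in shotgun metagenomes and
    metatranscriptomes. Provides curation of an enzyme-homolog protein reference
    with pairwise-identity characterization, a translated (six-frame) best-hit
    homology search with an identity filter, RPKM quantification per homolog and
    per species, gene/transcript co-detection classification, a population-level
    taxon contribution statistic with relative scaling, marker-peptide mining and
    quantification, cohort comparison statistics, and a synthetic-data generator
    with recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
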