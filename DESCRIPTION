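Package: parevo
Title: Parallel Evolution of Polygenic Traits Across Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether alleles at human GWAS positions for polygenic
    traits have evolved in parallel across other species. Builds and filters
    a SNP-by-species allele matrix, computes per-species genomic scores
    (the proportion of trait-increasing allele matches), regresses score
    ranks on phenotype ranks by phylogenetic generalized least squares under
    a Brownian-motion covariance, and calibrates significance with
    permulations (phylogeny-aware permutations by rank-matching simulated
    Brownian trait values). Localizes signal to internal branches via
    ancestral state reconstruction and match/mismatch counting of
    clade-fixed substitutions, nominates putatively causative regulatory
    positions through per-position rank tests and an annotation cascade
    (cCRE overlap, conservation windows, TSS distance, cross-species
    synteny, cis-eQTL joins, transcription-factor motif disruption), and
    validates candidate signal in an inbred strain panel. Includes a
    synthetic-data generator emulating the statistical structure of the
    required inputs so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phytools,
    stats,
    utils
Suggests:
    nlme,
    jsonlite,
    optparse,
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
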