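Package: panvirome
Title: Comparative Genomics of Bacteriophage Cohorts: Pan-Virome
    Construction, Gene-Repertoire Classification and Host-Range Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative genomics of small cohorts of
    bacteriophage genomes, built around an orthology-based pan-virome.
    Provides all-vs-all Smith-Waterman protein comparison, bidirectional
    best-hit (COG-triangle) and Markov clustering with their intersection,
    presence/absence pan-genome matrices, hierarchical clustering with
    multiscale-bootstrap approximately-unbiased (AU) supports, relative
    synonymous codon usage and amino-acid composition PCA, terminase-based
    neighbor-joining phylogeny with DNA-packaging inference and saturation
    assessment, a Nei-Gojobori counting dN/dS scan with a
    column-resampling permutation test, spot-test host-range encoding and
    lysotyping, and one-step growth-curve burst-size estimation. A
    synthetic-cohort generator with full ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
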