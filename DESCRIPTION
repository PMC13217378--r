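Package: nervatlas
Title: Innervation-Density Archetypes of Mouse Limb Muscles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking the spatial density of sensory,
    sympathetic and motor neurons innervating mouse limb muscles to muscle
    phenotype and transcriptome. Provides mass normalization of retrograde
    tracing counts, per-segment distribution summaries, Monti-style consensus
    clustering with resampled k-means and CDF-area k selection, Pearson
    correlation screens with the absolute-r relevance rule, rank-based
    cross-platform expression indices, hypergeometric over-representation
    analysis against GMT gene sets, Livak 2^-ddCt relative quantification,
    and seeded synthetic-data generators with planted ground truth for
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
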