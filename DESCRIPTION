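Package: stygodelim
Title: Integrative Molecular Taxonomy for Cryptic Groundwater Amphipods
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative molecular-taxonomy pipeline for splitting
    complexes of morphologically cryptic species and re-ranking them for
    conservation. Implements pairwise Kimura two-parameter and patristic
    distance matrices with dual-threshold clustering, maximum-likelihood
    Poisson tree processes (PTP) species delimitation, haplotype-sharing
    screens across syntopic species pairs, character-based molecular
    diagnoses (pure character attributes), fair-proportion evolutionary
    distinctness, minimum-convex-polygon range metrics, endemism classes
    and richness accounting under alternative taxonomies. Includes a
    synthetic-data generator that emulates the divergence structure the
    analysis assumes, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    seqinr,
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
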