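Package: pteridodiv
Title: Gridded Diversity Analysis for the Ferns and Lycophytes of Japan
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reassessing fern and lycophyte diversity on Japan's
    10-km standard area mesh: decoding secondary mesh grid codes, loading
    trait-annotated checklists and presence-only occurrence records,
    computing species richness and Faith's phylogenetic diversity per grid
    cell, comparing range size and latitudinal breadth across reproductive
    modes, phenology and ploidy levels (one-way ANOVA, Tukey HSD, Student's
    t, implemented from first principles), exporting map layers as CSV or
    GeoJSON, and generating fully synthetic checklist/occurrence/tree
    datasets with the same statistical structure for testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante
Config/testthat/edition: 3
RoxygenNote: 7.3.3
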