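Package: salinispec
Title: Microbial Specificity and Source Generalism Along Salinity Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for inter-biome microbial dispersal under
    salinity stress. Implements rarefaction-averaged community tables and
    basic diversity, biome-overlap (Venn) partitioning of taxa with salinity
    binning, an IndVal-derived per-group specificity index with a
    label-reshuffling permutation null and observed-versus-null slope
    contrasts, environmental-ontology source-term generalism scoring, and a
    synthetic three-biome community generator with planted niche and
    generalism parameters for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
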