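Package: gynoclone
Title: Clonal Hybrid Lineage Surveys: Calling, Biogeography and Drift Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for latitudinal surveys of gynogenetic clonal hybrid fish
    (Chrosomus eos-neogaeus type complexes). Groups hybrid multilocus
    microsatellite genotypes into clonal lineages via consensus genotypes with
    single-step mutation tolerance, assigns triploids to their lineage of
    origin, classifies lineages as private (local hybridization) versus
    widespread (Pleistocene migrants), computes the occupancy and diversity
    statistics used to test latitudinal gradients in hybridization, and
    provides a forward clonal Wright-Fisher island-model simulator of lineage
    sorting with rarefaction-based effective-lineage estimation and
    diversity-to-time calibration. Includes a synthetic survey generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    igraph,
    readr,
    stats,
    tibble,
    tidyr
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
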