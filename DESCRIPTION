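Package: spvflock
Title: Hybrid Self-Propelled Voronoi-Vicsek Simulation and Collective
    Migration Statistics for Confluent Epithelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates confluent epithelial monolayers as active Voronoi
    tessellations with an area/perimeter shape energy, self-propulsion and
    Vicsek-style velocity alignment, and provides the image-derived motility
    statistics used to characterise serum-induced collective migration in
    keratinocyte sheets: instantaneous order parameters and 5-sigma velocity
    correlation lengths on gridded (PIV-type) velocity fields, fixed-lag mean
    square displacement and migration persistency indices on cell tracks,
    circular order statistics for division and nucleus-to-Golgi polarity,
    relative nuclear positioning, and a binomial model of asymmetric organelle
    partitioning between daughter cells. Includes seeded synthetic-data
    generators for every input class so the full pipeline is testable without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
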