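Package: tigersim
Title: Agent-Based Simulation of Transport-Infrastructure Effects on Territorial Tigers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatially explicit, individual-based model of a territorial tiger
    population on a prey-biomass raster, built to forecast the demographic
    consequences of roads and railways. Transport infrastructure acts through two
    mechanisms: reduced annual survival of breeding females whose territories
    intersect a road or railway, and linear depletion of prey biomass within a
    road-effect zone. The package provides landscape input/output (ESRI ASCII
    grids, GeoJSON road networks), a synthetic landscape generator emulating the
    Chitwan National Park layers, the monthly life-cycle scheduler (territory
    formation, male challenges, infanticide, starvation), a burn-in/activation
    scenario engine with replicated experiments, and analysis utilities
    (population trajectories with t-based confidence intervals, road-attributed
    mortality, Wilcoxon comparisons, and occupancy maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    yaml
Config/testthat/edition: 3
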