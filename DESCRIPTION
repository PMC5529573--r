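Package: maxenvelope
Title: Maximum-Abundance Envelope Models and Phylogenetic Diversity for
    Marine Microbial Community Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing marine planktonic 16S/18S OTU tables along
    environmental gradients: multiple rarefaction with sample filtering,
    Faith's phylogenetic diversity and weighted/unweighted UniFrac from rooted
    trees, Mantel comparisons of community and environmental distance
    matrices, mixed-layer-depth turbulence proxies with nutrient-by-turbulence
    scenario classification, and maximum-abundance (95th-percentile envelope)
    species distribution models fitted as observation-weighted Poisson
    polynomial regressions with AIC-guided degree selection. A synthetic
    community generator with known per-taxon response curves provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    phangorn,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
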