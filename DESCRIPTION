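Package: invgrad
Title: Invasion-Gradient Analysis of Vegetation Communities on Mitigation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the impact of invasive plants on native vegetation
    communities sampled along invasion gradients on wetland and stream
    compensatory mitigation sites. Provides the modified Daubenmire
    cover-class scale with subplot averaging, readers and writers for
    plot-by-species community tables, a seeded synthetic-community generator
    emulating the five-plot transect study design, floristic metrics (native
    richness, floristic quality index, 50/20 dominants, Renyi diversity
    profiles, species accumulation curves), Sorensen similarity and rank-based
    ANOSIM permutation tests, and a running-average threshold estimator that
    locates the invader relative-abundance level at which native richness
    begins to decline, supporting quantitative invasive-species performance
    standards.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, grDevices, jsonlite, yaml
Suggests: testthat (>= 3.0.0), vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
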