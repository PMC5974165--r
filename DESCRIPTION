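Package: richstack
Title: Stacked Species Distribution Models and Range Maps for Marine Species Richness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds ocean-scale species richness maps for reef-associated taxa
    by stacking per-species binary range estimates. Ranges come from a
    presence/background maximum-entropy distribution model fitted on
    PCA-reduced environmental raster layers, from minimum convex polygons,
    or from geodesic point buffers for data-poor species; all ranges are
    constrained to a buffered reef mask, summed cellwise into richness maps,
    and summarised as 3-degree binned latitudinal and longitudinal richness
    gradients. Includes a synthetic-biodiversity generator with known
    ground-truth niches so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
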