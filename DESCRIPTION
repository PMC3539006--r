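Package: lichenmix
Title: Symbiont Biomass Partitioning in Lichens from Stable Isotope Mass Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for partitioning lichen biomass between the fungal partner
    (mycobiont) and the algal partner (photobiont) using a concentration-dependent
    two-end-member nitrogen isotope mass-balance model. Includes validated tidy-CSV
    input/output for specimen-level isotope measurements, forward and inverse mixing
    model with a closed-form oracle, nonlinear mixing-line generation, substrate
    contrast statistics built on an exact Mann-Whitney U test, a synthetic-data
    generator that emulates field survey and biont-separation designs, and a
    reproducible analysis pipeline with a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
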