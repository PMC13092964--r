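Package: reefweb
Title: Mass-Balance Food-Web Modelling and Network Analysis for Oyster Reef Ecosystems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and balancing Ecopath-style mass-balance
    trophic models of coastal ecosystems, with ecological network analysis
    (trophic levels, total system throughput, connectance and omnivory
    indices, Finn's cycling index and mean path length, Lindeman spine
    transfer efficiencies, mixed trophic impacts), community diversity and
    dominance statistics, and a generator of random balanced food webs.
    Ships the 17-group Chudao oyster reef (Sanggou Bay) model inputs and
    the accompanying plankton and reef-fauna survey tables as worked
    example data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
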