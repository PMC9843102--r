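Package: lasimti
Title: Maritime Trade Connectivity and Invasive Vector Introduction Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to rank coastal countries by the likelihood of invasive
    Anopheles stephensi introduction through maritime trade. Computes the
    Liner Shipping Bilateral Connectivity Index (LSBCI) from its five raw
    shipping indicators, derives the introduction-risk score LASIMTI
    (LSBCI divided by days at sea) summed over source-population countries,
    combines it with a per-country Habitat Suitability Index, constructs the
    directed intracontinental trade network under a top-k/tie rule with an
    optional travel-time cutoff, and scores nodes with weighted directed
    PageRank centrality. A seeded synthetic-data generator emulates the
    bilateral connectivity, transit-time and habitat-suitability inputs so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
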