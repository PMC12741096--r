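Package: kindred
Title: Pedigree Graphs, n-Degree Relatives, and Path-Counting Kinship from Trio Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds population-level pedigree graphs from trio records
    (individual, father, mother), extracts all relatives of a proband up to
    an arbitrary degree, computes kinship matrices by counting edges on the
    shortest genealogical path through a most recent common ancestor
    (0.5^d * C), reconstructs trio tables from graphs, labels familial
    relationships (parent, pibling, first cousin twice removed, ...), and
    summarizes relation counts per proband. Includes a seeded synthetic
    pedigree simulator and canonical fixture families for testing and
    benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    grDevices,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
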