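Package: reprognet
Title: Network Analysis of Small-Molecule Targets for Cell Reprogramming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a systems-biology analysis of small molecules (SMs)
    used in chemically induced cell reprogramming. Cleans protein-protein
    interaction edge lists into a simple undirected interactome, aggregates
    chemical-protein interactions into target sets, computes the
    interconnectivity statistic (fraction of a query set inside the largest
    connected component of its induced subgraph), calibrates it against an
    empirical random-sampling null model with z-scores, fits a power law to
    degree distributions, performs Fisher-exact set-overlap tests and
    gene-set enrichment with Benjamini-Hochberg correction, and analyses
    the combinatorics of published SM reprogramming cocktails. Includes
    seeded synthetic-data generators (preferential-attachment and
    Erdos-Renyi interactomes, planted target modules, overlap universes)
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
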