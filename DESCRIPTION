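Package: spongenet
Title: Inference and Analysis of miRNA Sponge Interaction Networks and Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies competing endogenous RNA (ceRNA, miRNA sponge)
    interactions from miRNA-target tables, matched expression matrices and
    miRNA response element (MRE) tables using eight methods (miRHomology,
    pc, sppc, ppc, hermes, muTaME, cernia and a majority-vote integrator),
    detects miRNA sponge modules with four network clustering algorithms
    (fast greedy modularity, Markov clustering, link communities, MCODE),
    and validates and analyzes the results (ground-truth validation,
    gene-set over-representation, Cox/log-rank module survival analysis).
    Includes a synthetic-data generator with planted sponge structure and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
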