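Package: papcat
Title: Transcriptome Cataloguing of Papain-Family (C1) Cysteine Peptidases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds annotated catalogues of C1 (papain-family) cysteine
    peptidases from de novo transcriptome assemblies. Discovers candidate
    open reading frames in contigs, retains peptidase homologs by local
    alignment, collapses redundant partial sequences into unique peptidases
    with a Wagner-Fischer alignment core (95% identity / 10-residue overlap
    rule) and a majority-rule consensus, quantifies expression without a
    reference genome by RPKM with either multiread-as-one-unit or fractional
    "rescue" allocation, classifies each peptidase on papain and cathepsin-B
    reference numbering (catalytic tetrad Gln19/Cys25/His159/Asn175,
    occluding-loop type, S1/S2 subsite fingerprints), calls cross-species
    ortholog pairs and groups from bootstrapped neighbor-joining trees, and
    screens enzyme-substrate docking poses against geometric criteria for
    productive binding. Includes a seeded synthetic-data generator for
    paralogous gene families, multi-mapping reads and redundant contigs so
    every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    bio3d,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
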