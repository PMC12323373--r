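Package: pulrecon
Title: Polysaccharide Utilization Locus Prediction and Gene-Family
    Reconciliation for Marine Flavobacteria
Version: 0.1.0
Authors@R:
    person("pulrecon", "developers", email = "pulrecon@example.org",
           role = c("aut", "cre"))
Description: Rule-based prediction of polysaccharide utilization loci (PULs)
    from ordered gene tables and domain-hit evidence, with consensus CAZyme
    annotation, SusC/SusD marker calling, substrate classification (including
    alginate utilization loci), genome-level degradative-capacity statistics
    (CAZyme/peptidase/sulfatase densities, P/C ratio, fragment-based
    reciprocal best-hit average nucleotide identity, 16S rRNA identity), and
    event-cost parsimony reconciliation of gene trees against a species tree
    with duplication, transfer and loss. Includes synthetic-data generators
    with planted loci and planted evolutionary events for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
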