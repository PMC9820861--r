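Package: qtlcloner
Title: Positional Cloning of Diabetes QTL in Mouse Backcross Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for positional cloning of quantitative trait loci (QTL)
    in experimental mouse crosses, built around the workflow used to dissect
    blood-glucose QTL in New Zealand obese (NZO) outcross populations:
    marker-regression LOD scans over an N2 backcross with permutation-based
    genome-wide significance thresholds and 1.5-LOD support intervals,
    longitudinal diabetes phenotype metrics (prevalence, case fatality rate,
    severe hyperglycemia), identity-by-descent versus polymorphic haplotype
    block calling from strain SNP catalogs, candidate-gene prioritization by
    variant consequence impact and SIFT deleteriousness, islet-specificity
    Z-scoring of multi-tissue expression matrices, qPCR delta-Ct comparison,
    and residue-conservation flagging from protein alignments.  A synthetic
    data generator with planted causal signals makes every stage testable
    without access to animal cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
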