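Package: teisig
Title: Transcriptional Excitation-Inhibition Signatures of Brain Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building transcriptional excitation/inhibition (tE/I)
    signatures from bulk and single-cell expression tables: representative-probe
    selection by principal-axis exploratory factor analysis, age adjustment,
    proportional AMPA-receptor subunit contributions and fold enrichment,
    two-way Ward hierarchical clustering with multiscale-bootstrap AU/BP
    cluster support, Euclidean-distance inter-individual variability
    statistics, and the tE/I (sum of AMPAR subunit expression over sum of
    GABA-A receptor subunit expression) and KCC2/NKCC1 transporter ratios
    across brain regions, cell types and development. Includes synthetic-data
    generators that emulate the statistical structure of regional microarray,
    single-cell and developmental RNA-seq datasets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    ape,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
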