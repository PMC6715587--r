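Package: kinetophos
Title: Kinetochore Phosphatase Network Modelling and Phospho-Motif Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action ordinary differential equation model of the antagonism
    between kinases (MPS1, Aurora B, CDK1) and the two kinetochore phosphatase
    complexes PP1 and PP2A-B56 at the KNL1 scaffold, in which the catalytically
    identical phosphatases differ only in the phospho-dependence of their
    recruitment (PP1 binding is blocked, PP2A-B56 binding is enabled, by
    phosphorylation). Provides declarative in-silico mutants (phosphatase
    knockouts, catalytically dead B56, constitutive fusion constructs), stiff
    integration and steady-state analysis, kinase-inhibition protocols,
    dose-response and log-log sensitivity analysis, least-squares parameter
    fitting to normalised phospho-MELT time courses with a per-cell synthetic
    data generator emulating quantitative immunofluorescence, SBML import and
    export, and statistics for RVxF and LxxIxE phosphatase-docking short linear
    motifs (similarity-weighted position-specific scoring matrices, binomial
    enrichment, kinase-class annotation of phosphosites).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
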