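Package: cdvqtl
Title: Canopy Development Dissection and Kinship-Corrected GWAS for
    Tetraploid Potato under Contrasting Nitrogen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step analysis of potato canopy development and agronomy
    under contrasting nitrogen inputs. Eco-physiological curve models
    (a beta-function canopy growth curve on a thermal-time axis and a
    Gaussian tuber size-distribution curve) are fitted per field plot to
    produce model-parameter traits; genotype values estimated from a
    split-plot mixed model feed a kinship-corrected association scan on
    tetraploid SNP dosages; associations are consolidated into QTLs by
    linkage-disequilibrium windows, classified by nitrogen dependence,
    and flagged for colocalization with the chromosome-5 maturity locus,
    with and without correction for maturity class. A synthetic-data
    module generates genotypes, trait architectures, and plot-level
    observations so the whole pipeline can be exercised end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
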