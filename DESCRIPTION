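Package: tatasnp
Title: TATA-Box Regulatory SNP Analysis via TBP-Promoter Affinity Estimation
Version: 1.0.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the equilibrium dissociation constant (K_D) of the
    TATA-binding protein (TBP) for ancestral and minor alleles of core-promoter
    SNPs using a three-component model of TBP-promoter binding (site
    recognition by a position weight matrix, dinucleotide sliding affinity,
    and DNA bending propensity), decides significant over- or underexpression
    via a Z statistic with an A-E significance rank, houses a curated catalog
    of candidate Alzheimer's-disease promoter SNP markers, and provides exact
    binomial selection-pressure tests, a predicted-versus-measured concordance
    suite, a synthetic promoter generator with planted TATA elements, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
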