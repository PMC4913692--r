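Package: coassocnet
Title: Multi-Trait GWAS Co-Association Networks from SNP Effect Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multi-trait quantitative genetics data:
    Bayes-B Markov chain Monte Carlo estimation of SNP effects with
    contemporary-group fixed effects, 1-Mb window genetic variance and
    posterior probability of association, construction of an association
    weight matrix of posterior mean SNP effects across traits, network
    inference by the partial-correlation-and-information-theory (PCIT)
    algorithm, density-scored molecular-complex detection, and EASE-based
    gene-ontology term enrichment with annotation clustering. Includes a
    seeded simulator of half-sib genotype/phenotype data with sparse shared
    QTL architecture so the whole pipeline can be exercised and tested
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
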