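Package: ncvbench
Title: Benchmarking Framework for Noncoding Variant Pathogenicity Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating computational impact scores of noncoding
    single-nucleotide variants on the biological tasks those scores are used
    for: distinguishing pathogenic from non-pathogenic alleles at the same
    position, resolving causal variants among region- or LD-matched
    neighbours, and prioritising variants in candidate lists with heavy
    class imbalance. Includes a Fitch-parsimony per-site evolutionary rate
    estimator, a neutral HKY sequence-evolution simulator over a dated
    phylogeny, generators for synthetic variant catalogs and score tables
    with allelic, positional and regional variance components, builders for
    position-matched, region-matched, LD-matched and mixture test sets, and
    imbalance-aware evaluation statistics (AUROC with DeLong variance,
    average-precision AUPRC, matched-pair success rates, balanced-accuracy
    cutoffs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phytools,
    vcfR,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    phangorn,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
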