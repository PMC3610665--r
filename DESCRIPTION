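Package: mirrorphase
Title: Haplotype Phasing and Imputation Robust to Double Genotype Sharing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov-chain Monte-Carlo haplotype phasing engine built on the
    Li & Stephens haplotype-copying pair hidden Markov model, supporting both
    classical backward sampling and a mirror-subtraction sampling rule that
    prevents the chain from locking into its random initialization when two
    individuals carry identical genotypes over long regions (siblings,
    monozygotic twins, double cousins). Includes a minimac-style haploid
    imputation engine for masked markers against a phased reference panel, a
    synthetic pedigree and genotype simulator with LD-rich founders, trio
    children and twin augmentation, and evaluation metrics: switch-error
    counting, imputed-allele error counting, identity-by-state sharing-run
    statistics, per-marker error localization and a cross-validation flip-rate
    diagnostic.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
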