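Package: panotype
Title: Pangenome Genotyping from k-mer Counts and a Haplotype Panel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genotypes SNPs, indels and structural variants in a new
    short-read sample without read alignment, by combining counts of
    bubble-unique k-mers observed in the raw reads with a panel of fully
    phased haplotypes. Nearby panel variants are merged into bubbles of a
    pangenome graph; a hidden Markov model whose hidden states are ordered
    pairs of panel haplotype paths (Li-Stephens recombination transitions,
    Poisson/geometric k-mer count emissions) yields posterior genotype
    likelihoods per bubble via the forward-backward algorithm, which are
    decomposed back to the input variant records. Includes a synthetic
    panel/sample/read simulator and genotype evaluation metrics (weighted
    genotype concordance, adjusted precision/recall, Mendelian consistency,
    cohort reliability filters, Hardy-Weinberg tests) so the whole system
    is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
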