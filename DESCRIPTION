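Package: mutaccum
Title: Simulation and Analysis of Diploid Mutation-Accumulation Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing de novo mutations in diploid
    mutation-accumulation (MA) lines propagated through single-cell
    bottleneck passages, modelled on hybrid Saccharomyces cerevisiae
    (SK1/BY) experiments. Provides a forward simulator of mutator
    lineages with ground-truth event logs; variant class and zygosity
    calling from allelic ratios and copy number; loss-of-heterozygosity
    (LOH) segmentation over dense marker maps with interstitial/terminal
    tract classification; mechanistic classification of homozygous
    mutations (mitotic recombination/BIR, chromosome loss, deletion,
    double slippage); per-passage mutation trajectories with
    fixation/elimination detection linked to LOH events; 96-context
    trinucleotide mutational spectra refit against a signature matrix by
    non-negative least squares; and mutation-rate estimation including
    Luria-Delbruck fluctuation analysis by Ma-Sandri-Sarkar maximum
    likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml,
    Biostrings
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
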