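Package: repeatcn
Title: Relative Copy Number Inference from Repeat Amplicon Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers per-locus relative copy number (RCN) profiles from
    repeat-amplicon sequencing count data (FAST-SeqS-style assays). Counts
    are modelled with a beta-binomial noise model whose locus-specific bias
    is learnt from a panel of diploid control samples by
    Metropolis-Hastings MCMC, and per-sample copy number states are
    inferred with a sticky hierarchical Dirichlet process hidden Markov
    model (weak-limit blocked Gibbs sampler) run independently per
    chromosome arm. Includes the read-processing pipeline from FASTQ to
    the filtered count matrix, a synthetic-data generator drawn from the
    same generative model, count-level in silico tumour-purity dilution,
    posterior summarisation (marginal and state-based, with Stephens
    relabelling via the Hungarian algorithm), and cross-caller comparison
    utilities (total copy number to RCN conversion, gene-level weighted
    means, rank correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    KernSmooth,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
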