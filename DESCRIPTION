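Package: dmrhmm
Title: De Novo Detection of Differentially Methylated Regions from
    Bisulfite-Seq Read Counts by Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects differentially methylated regions (DMRs) between two
    bisulfite sequencing samples directly from per-CpG methylated and
    unmethylated read counts. Genome-wide methylation level distributions are
    modelled as constrained three-component beta mixtures (high, low, uniform)
    fitted by maximum likelihood on read counts from subsampled CpG sites;
    beta-binomial emission functions derived from the fitted mixtures score
    hypermethylation (Up), hypomethylation (Down) and no change (NoCh) at each
    CpG. A dual-unit hidden Markov model with silent gap states models
    inter-CpG distance distributions, transition probabilities are learned per
    dataset by Baum-Welch, and ranked DMRs are extracted as maximal
    log-likelihood-ratio segments. Includes a legacy pseudocount emission
    model, a count-level simulator with planted DMRs, and a reciprocal-overlap
    benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
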