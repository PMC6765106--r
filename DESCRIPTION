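Package: ampdenoise
Title: Denoising of Long-Read Amplicon Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs true template sequences and their frequencies from
    noisy long-read (PacBio CCS style) amplicon sequencing data. Provides a
    fast read-selection denoiser for the short/accurate regime (dereplication,
    abundance correction by the error-free fraction, and a Bonferroni-corrected
    Poisson offspring test), and a robust denoiser for the long/inaccurate
    regime (kmer-domain DP-means clustering with triangle-inequality pruning,
    recursive fine cluster splitting on high-variance kmers, and kmer-seeded
    alignment consensus polishing). Also implements the Sequence Mutation
    Distance, an earth mover's distance between weighted sequence populations,
    and a simulator of CCS-like reads with homopolymer-concentrated indel
    errors for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    boot,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
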