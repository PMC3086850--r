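Package: hmmCNA
Title: Predict DNA Copy-Number Alterations from Gene-Expression Profiles
    with Per-Chromosome Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers chromosomal copy-number gains and losses from
    gene-expression microarray data using a nine-state hidden Markov model
    per chromosome, trained by maximum likelihood on cohorts with paired
    expression and comparative genomic hybridization (CGH) calls.  Provides
    expression discretization, Viterbi and posterior decoding,
    cytoband-level smoothing by a multinomial log-of-odds (LOD) score,
    raw- and smoothed-expression baseline comparators, leave-one-out
    cross-validation, a permutation test linking recurrent abnormalities to
    coordinated expression change, and a synthetic paired-cohort generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
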