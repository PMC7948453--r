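Package: bruwave
Title: Nascent-RNA Wave-Front Analysis of Pol II Elongation Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing nascent-RNA (Bru-seq) coverage tracks:
    inference of RNA polymerase II elongation rates from drug-washout
    wave fronts in TSS-anchored metagene profiles, processivity and
    termination-readthrough ratios, peak-centred enhancer-RNA
    differential-synthesis classification with spike-in or library-size
    normalisation, and genomic-feature annotation of peak sets. Includes
    a stochastic simulator of promoter-proximal pause-release kinetics
    that generates stranded coverage with known ground truth, so the
    full pipeline can be exercised and validated without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
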