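Package: trisense
Title: Tripeptide Markov Features for Protein Sequences via Compressive
    Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts compact numeric features from protein amino-acid
    sequences by counting overlapping tripeptides into a 20 x 20 x 20
    Markov transfer-frequency tensor, flattening it to a sparse
    length-8000 signal, and compressing the signal with a seeded Gaussian
    random-projection measurement matrix. Includes an amino-acid
    composition baseline, fuzzy c-means clustering, cluster-validity
    indices (scatter-trace ratio, partition entropy, label-matched
    clustering accuracy), and an order-2 Markov simulator of labeled
    sequence sets for end-to-end benchmarking of subcellular-localization
    style discrimination tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
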