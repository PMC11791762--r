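Package: methylstore
Title: DNA Data Storage with a 5-Methylcytosine Expanded Alphabet
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encode arbitrary digital files into DNA sequences over the
    expanded five-letter alphabet {A, T, C, G, M}, where M is
    5-methylcytosine, using an N-ary rotational transcoding table, and
    decode them back. Provides XOR erasure redundancy over fixed-size
    addressed segments, an error-channel simulator with replicated
    recovery-rate statistics, GC-content and homopolymer profiling of
    encoded sequences, constrained design of 8-nt ligation adaptors,
    staged-assembly layout planning, and a consensus-based pipeline that
    decodes noisy methylation-aware reads emulating nanopore output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
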