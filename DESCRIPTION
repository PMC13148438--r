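Package: lemindex
Title: Long Locally Maximal Exact Match Queries on a Run-Length Compressed BWT Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a run-length compressed Burrows-Wheeler transform index whose
    move data structures answer LF, phi, phi-inverse and permuted-LCP (PLCP)
    queries in constant amortized time, and uses it to report all locally
    maximal exact matches (LEMs) of length at least a threshold between a query
    pattern and a repetitive text collection, in time linear in the pattern
    length plus the number of matches reported. Includes reference
    (uncompressed) suffix-structure construction, brute-force match enumerators
    used as testing oracles, a synthetic haplotype-panel generator for
    repetitive test texts, FASTA input, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Biostrings,
    optparse,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
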