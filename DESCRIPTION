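Package: lncwalk
Title: Prioritizing Disease-Associated lncRNAs by Network Propagation on
    Subpathway Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a heterogeneous lncRNA-gene network by fusing enriched
    k-clique subpathways with lncRNA-mRNA co-expression edges, prioritizes
    candidate lncRNAs by random walk with restart from known disease genes,
    assesses scores against a degree-preserving seed-permutation null, extracts
    the key module around top-ranked lncRNAs, and calls candidate competing
    endogenous RNA (ceRNA) pairs via shared miRNAs. Includes probe
    re-annotation filters for two-colour/oligo microarray probe-to-transcript
    alignments, a SAM-style permutation test for differential expression, and a
    synthetic-data generator emulating a two-phenotype microarray study for
    end-to-end testing.
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
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
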