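Package: polarmin
Title: Sequence-Specific Minimizer Schemes via Polar Sets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to design and evaluate sequence-specific minimizer schemes
    built from polar sets: k-mer sets whose occurrences on a reference
    sequence are spread far enough apart that every window contains at most
    one member. The package computes minimizer densities and charged
    contexts, per-context energies and their aggregates, validates (layered)
    polar sets, computes link energy both as a sum over linked occurrence
    pairs and through covered-context bookkeeping, evaluates the resulting
    upper and lower bounds on the expected number of selected positions, and
    constructs layered polar sets with randomized suffix-array driven
    heuristics backed by a constant-time linked-blocks structure. Synthetic
    sequence generators (uniform, periodic, planted perfect seeds, repeat
    mosaics) and baseline schemes (random minimizer, fixed-interval
    sampling) support benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, DataRepresentation, Software
RoxygenNote: 7.3.3
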