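Package: pairplan
Title: Affine-Plane Subset Designs for Parallelizing Pairwise Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Splits an all-pairs comparison problem over n individuals into
    roughly n + sqrt(n) subsets of roughly sqrt(n) individuals each, arranged
    so that every unordered pair of individuals occurs together in exactly one
    subset (the lines of an affine plane of prime order). Provides a
    brute-force coverage oracle that verifies the exact-once property, writers
    for per-subset keep-files and batched job manifests, a merger for
    per-subset segment result files, a seeded simulator of phased haplotype
    panels with planted identical-by-descent segments, and a deterministic
    exact-match segment caller used to demonstrate that subset-parallel
    calling, merged across the design, is identical to calling on the full
    sample.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
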