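Package: earmatch
Title: Ear Biometric Identification by Keypoint Descriptor Matching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identification of individuals from photographs of the ear.
    Images are conditioned by a fixed preprocessing pipeline (grayscale
    conversion, manual region-of-interest crop, resize to a fixed ear
    width, histogram equalization), represented as sets of 128-dimensional
    keypoint descriptors, and matched against an enrolled gallery by
    average nearest-neighbour squared Euclidean distance with an optional
    gender filter. Includes closed-set rank-1 to rank-10 recognition-rate
    evaluation, an ablation grid runner over preprocessing strategies, a
    persistent SQLite-backed gallery and descriptor cache, and a seeded
    synthetic ear-cohort generator for download-free end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    Rcpp,
    digest,
    jpeg,
    png,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
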