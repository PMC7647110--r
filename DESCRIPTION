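Package: kmerDim
Title: Counting Distinct Genomes in a Metagenome from k-mer Barcode Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates the number of distinct genomes in a metagenome from
    the k-mer "barcode spectra" of sequentially drawn samples of the medium,
    exploiting random fluctuations of per-genome copy numbers across samples.
    Provides double-stranded k-mer spectrum computation for genome sequences,
    a sample simulator with fragment-loss and substitution-error models,
    closed-form probability bounds for the sequential basis-building
    procedure, an exact incremental-rank estimator with a probabilistic
    termination rule for error-free data, a PCA residual "marker pattern"
    detector for noisy data, and virtual-sample augmentation against a
    library of known genome spectra for counting unknown genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
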