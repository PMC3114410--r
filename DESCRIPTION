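Package: pathweight
Title: Gene Weighting Schemes for Pathway-Based Analysis of Two-Group
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pathway (gene-set) association testing for two-group gene
    expression studies with nonuniform gene weights.  Implements the
    global test Q statistic with permutation p-values, four weighting
    schemes (absT, Qdiff, and the random-search schemes RWV and RWM),
    random-forest out-of-bag error as an alternative pathway score and
    search objective, a multivariate-normal pathway-data simulator with
    optional planted differential expression, and the screening,
    competition-ranking, top-k selection, overlap, rank-change and
    leave-one-out cross-validated prediction reports used to compare
    weighting schemes.  Readers and writers for tab-delimited expression
    matrices, GMT gene-set collections and CLS phenotype labels are
    included, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    class,
    e1071,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
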