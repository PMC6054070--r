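Package: radpair
Title: Quality Control for Paired ddRAD Libraries Prepared with and
    without Whole-Genome Amplification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess the impact of multiple displacement
    amplification (MDA) on double-digest RAD-seq (ddRAD) libraries by
    comparing libraries prepared with and without amplification from the
    same samples.  Reads and writes ipyrad-style .loci alignments and
    relaxed-phylip SNP matrices; computes per-library statistics
    (assembled-locus counts, read-depth dispersion, observed
    heterozygosity, GC content); builds locus-overlap and genetic
    distance matrices with a distance-based rule for flagging
    contaminated samples; classifies sequences against a de-replicated
    locus reference to quantify cross-taxon contamination; fits linear
    mixed models with backward elimination and a multivariate distance
    matrix regression (MDMR) with permutation inference; and provides
    population-genetics endpoints (missing-data matrix condensing,
    PCA + k-means clustering, Weir-Cockerham FST, Mantel tests of
    isolation by distance).  A built-in simulator generates multi-taxon
    ddRAD datasets with paired libraries exhibiting amplification
    artifacts (input-DNA-dependent locus dropout, coverage
    overdispersion, allelic dropout, cross-taxon contamination) together
    with ground truth for parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    vegan,
    geosphere,
    lme4,
    lmerTest,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
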