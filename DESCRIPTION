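Package: slrscan
Title: Detection of Sex-Linked Regions from Population Resequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed scans and locus-level screens for identifying
    sex-linked regions (SLRs) from male/female whole-genome resequencing
    cohorts. Implements per-site Weir-Cockerham F_ST between sexes with
    windowed aggregation and top-quantile candidate calling, log2
    male:female coverage-ratio tracks, within-sex SNP-density tracks,
    XY-pattern genotype consistency filters, per-individual sex-linkage
    scores with Fisher/Spearman co-occurrence tests across chromosomes,
    coverage-based male-specific marker extraction, pairwise dosage r2
    and LD-decay curves, binary-segmentation change-point detection,
    dosage PCA, identity-by-state distances, neighbor-joining trees, and
    male-class (M1/M2) assignment. A forward cohort simulator with
    planted SLRs, hemizygous Y segments, and two Y-haplotype male
    classes provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
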