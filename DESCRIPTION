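Package: ibdmapr
Title: Population-Based Linkage Analysis with Identity-by-Descent Segment Sharing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Case-control mapping of disease loci from pairwise
    identity-by-descent (IBD) segments detected among nominally unrelated
    individuals. Provides genotype panel quality control (minor allele
    frequency, exact Hardy-Weinberg test, missingness), two-stage
    nearest-neighbour outlier removal in principal-component space,
    readers and writers for refined-IBD segment text and genetic maps,
    centiMorgan interpolation, LOD and segment-length filtering, per-marker
    case-case sharing statistics normalised by genome-wide average sharing,
    permutation-based genome-wide significance with a low-IBD-coverage
    marker filter, and a synthetic-data generator (Pareto-distributed
    segment lengths, planted risk loci, telomeric detection depletion) for
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
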