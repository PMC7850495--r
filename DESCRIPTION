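Package: msiskew
Title: Tumor-Only Microsatellite Instability Calling from Read-Length Skewness
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls microsatellite instability (MSI) status from targeted
    sequencing of a single tumor sample, without a matched normal or a
    baseline cohort. For every microsatellite marker in a panel the package
    extracts per-read repeat-tract lengths from aligned reads by a CIGAR
    walk, normalizes them against the reference tract length, and scores the
    resulting length distribution with Pearson's skewness coefficient
    (3 * (mean - median) / sd). Markers covered by more than 20 spanning
    reads are valid; a valid marker is unstable when the coefficient exceeds
    1 in magnitude; a sample is MSI-high when the fraction of unstable valid
    markers reaches a tissue-type-specific cutoff (0.4 for fresh tissue and
    cell lines, 0.25 for FFPE). Includes a seeded cohort simulator (PCR
    stutter, tumor-allele contraction, FFPE coverage dispersion and dropout)
    that emits length tables or toy SAM/FASTA with ground truth, and an
    evaluation harness (confusion metrics, paired McNemar test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicAlignments,
    optparse
biocViews: Software, Sequencing, MicrosatelliteRepeat, SomaticMutation,
    Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'classify.R'
    'evaluate.R'
    'lengths.R'
    'markers.R'
    'methods-accessors.R'
    'msiskew-package.R'
    'psc.R'
    'simulate.R'
    'utils.R'
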