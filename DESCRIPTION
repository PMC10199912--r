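Package: admixscan
Title: Genome Scans for Positive Selection in Admixed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies signals of positive selection in
    admixed cohorts from phased genotypes. Implements per-SNP
    Weir-Cockerham FST, extended haplotype homozygosity statistics (iHS
    and XP-EHH) with frequency-bin and genome-wide normalisation, a
    rank-based Fisher's combined score on the intersection of FST and
    XP-EHH outliers, and a local-ancestry-deviation (LAD) scan that flags
    post-admixture selection from per-haplotype ancestry tracts.
    Candidate regions are merged, annotated against gene intervals, and
    classified as private to the admixed target, shared with a source
    population, or post-admixture. A forward simulator of pulse admixture
    with selective sweeps provides ground-truth datasets for calibration
    and power evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
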