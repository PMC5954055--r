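Package: pscqc
Title: Computational Assessment of Human Pluripotent Stem Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of the computational battery used to
    characterise human pluripotent stem cell (PSC) lines from transcriptome
    data: expression-based karyotyping of microarray profiles (e-Karyotyping),
    allelic-ratio karyotyping of RNA-seq SNP calls (eSNP-karyotyping), the
    embryoid-body lineage scorecard with moderated t-statistics and parametric
    gene-set scores, an RNA-seq TeratoScore for teratoma tissue composition,
    and a PluriTest-style platform-shift correction with least-squares
    projection scoring. A synthetic-data module generates all four input
    classes (probe matrices with mosaic chromosomal gains, per-SNP allele
    counts with trisomic imbalance, qPCR differentiation time courses, and
    teratomas as mixtures of tissue signatures) so that every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    stats,
    utils,
    vcfR,
    withr,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
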