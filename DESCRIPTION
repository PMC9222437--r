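Package: opsinmyopia
Title: Cone Opsin Exon-3 Haplotypes and Common Myopia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the association between X-linked cone
    opsin (OPN1LW/OPN1MW) exon-3 haplotypes and common myopia: haplotype
    parsing, amino-acid translation and enumeration over the eight-SNP
    exon-3 panel; spherical equivalent refraction calculated from ocular
    biometry; quantification of exon-3 skipping from primer-extension
    peak areas with per-SNP Mann-Whitney tests; cohort inclusion
    filtering and haplotype-group, allele-dichotomy and cone-ratio
    association tests; a split-halves haplotype risk-ranking resampling
    procedure with a scrambled-label null; X-linked Hardy-Weinberg
    carrier arithmetic; and paired-eye crossover lens-trial growth-rate
    analysis. Seeded synthetic-data generators emulate the cohort, the
    minigene splicing assay and the trial for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
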