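Package: restoromics
Title: Multiplexed Isobaric-Label Proteomics Evaluation of Dystrophin Gene-Therapy Restoration
Version: 0.1.0
Authors@R:
    person("Restoromics", "Developers", email = "restoromics@example.org", role = c("aut", "cre"))
Description: Tools for evaluating protein-level outcomes of AAV dystrophin
    gene therapy from multiplexed tandem-mass-tag (TMT) proteomics. Provides
    in-silico tryptic digestion and construct-discriminating peptide panels
    for micro-, midi- and full-length dystrophin constructs; within-plex
    normalization and pooled bridge-channel scaling across plexes; Grubbs
    single-outlier exclusion and quality filters; pairwise differential
    expression with geometric-mean fold changes, Student's t tests and
    Benjamini-Hochberg FDR control; one-way ANOVA with Tukey pairwise
    comparisons; Venn set algebra over DEP lists; and a per-protein,
    per-treatment therapeutic restoration taxonomy (restored, partial,
    unrestored, treatment-induced). A ground-truthed study simulator emulates
    the two-plex, five-group, six-replicate design with plex batch effects,
    coisolation interference, outliers and missing values, so the whole
    pipeline is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
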