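Package: h2scan
Title: Stratified Fine-Mapping and Association Analysis of the MAPT H1/H2 Inversion Haplotype
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the chr17q21 MAPT inversion haplotype (H1/H2)
    in case cohorts genotyped against external population controls. Provides a
    synthetic Ashkenazi-like Parkinson's disease cohort generator with an
    inversion-style perfect-LD block, founder-mutation subgroups and age at
    motor symptom onset; call- and variant-level VCF quality filters and a
    low-coverage interval scanner; tag-SNV linkage-disequilibrium scanning,
    haplotype-divergent SNV calling, recombinant-segment detection in tag
    homozygotes and minimal LD interval derivation; case versus external
    allele-frequency association under allelic, dominant and recessive models
    stratified by founder-mutation carrier status; a Monte-Carlo dual-carrier
    co-occurrence null; age-at-onset linear regression with carrier exclusion
    rules; and CADD/eQTL/sQTL threshold filters with cross-tissue consistency
    summaries. Results are tibbles throughout, with broom-style tidiers and
    ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    vcfR,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
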