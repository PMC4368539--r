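Package: rppacomp
Title: Compensation-Pattern Analysis of Reverse-Phase Protein Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for reverse-phase protein array (RPPA) studies of
    pharmacological rescue of learning in the Ts65Dn mouse model of Down
    syndrome. Generates factorial-design synthetic RPPA measurements with
    nested (mouse / dilution / spot) log-normal noise, applies total-protein
    normalization and published quality-control exclusion rules, fits a
    three-level mixed-effects model per protein for nine biologically relevant
    pairwise group comparisons with Bonferroni family-wise gating, and
    classifies each protein instance into rule-based compensation patterns
    that relate baseline abnormalities and drug-induced responses to the
    normal-learning response. Ships plain-text transcriptions of the printed
    summary tables for fixture-based verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
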