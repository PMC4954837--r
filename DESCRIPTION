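Package: macaffil
Title: Dominance, Parentage and Male-Infant Affiliation Analysis for Wild
    Macaque Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse male-infant affiliative relationships in wild
    multi-male primate groups: sequential Elo dominance ratings with daily
    within-sex standardization, multi-tube consensus genotyping of
    microsatellite PCR replicates with locus diagnostics (heterozygosity,
    PIC, Hardy-Weinberg, probability of identity), exclusion-based paternity
    assignment with likelihood (LOD) support, event-level permutation tests
    for non-random dyadic partner preference, assembly of daily dyad-level
    model tables, and binomial mixed models with Gaussian-kernel temporal
    autocorrelation terms, likelihood-ratio testing, interaction pruning and
    stability diagnostics. A seeded synthetic-data generator emulates the
    field and laboratory data (group composition, male migration, agonistic
    interactions, focal/scan sampling, Mendelian inheritance with allelic
    dropout) so every stage of the pipeline can be exercised and validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
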